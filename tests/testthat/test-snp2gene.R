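snp_tab <- function(...) {
  rows <- list(...)
  data.frame(rsid = vapply(rows, `[[`, "", 1), chrom = "chr1",
             pos = as.integer(seq_along(rows) * 1000),
             pvalue = vapply(rows, function(r) as.numeric(r[[2]]), 0),
             stringsAsFactors = FALSE)
}
ld_tab <- function(...) {
  rows <- list(...)
  data.frame(rsid1 = vapply(rows, `[[`, "", 1),
             rsid2 = vapply(rows, `[[`, "", 2),
             r2 = vapply(rows, function(r) as.numeric(r[[3]]), 0),
             stringsAsFactors = FALSE)
}
gene_tab <- function(gene_id = "G1", start = 50000, end = 60000,
                     strand = "+") {
  data.frame(gene_id = gene_id, chrom = "chr1", start = start, end = end,
              strand = strand,
              tss = ifelse(strand == "+", start + 1, end),
              stringsAsFactors = FALSE)
}

test_that("greedy pruning keeps the lowest-p SNP of each LD clump", {
  snps <- snp_tab(list("A", 1e-10), list("B", 1e-9), list("C", 1e-8))
  ld <- ld_tab(list("A", "B", 0.7), list("A", "C", 0.1),
               list("B", "C", 0.1))
  expect_equal(prune_independent(snps, ld)$rsid, c("A", "C"))
  # result is among the subsets satisfying the stated post-condition
  expect_true(list(c("A", "C")) %in% valid_independent_sets(snps, ld))

  one <- snp_tab(list("A", 1e-9))
  expect_equal(prune_independent(one, ld_tab())$rsid, "A")

  noLD <- snp_tab(list("A", 1e-10), list("B", 1e-9), list("C", 1e-8))
  expect_equal(nrow(prune_independent(noLD, ld_tab())), 3)

  dup <- rbind(snps, snps[1, ])
  expect_error(prune_independent(dup, ld), "duplicate")
})

test_that("pruning is idempotent and matches the exhaustive oracle", {
  set.seed(101)
  for (k in 1:40) {
    inst <- random_prune_instance(sample(2:9, 1))
    got <- prune_independent(inst$snps, inst$ld)
    valid <- valid_independent_sets(inst$snps, inst$ld)
    expect_true(list(sort(got$rsid)) %in% valid,
                info = paste("instance", k))
    again <- prune_independent(got, inst$ld)
    expect_equal(sort(again$rsid), sort(got$rsid))
  }
})

test_that("block expansion is boundary-inclusive and not transitive", {
  all_known <- snp_tab(list("A", 1e-10), list("D", 1e-4), list("E", 1e-4),
                       list("F", 1e-4))
  indep <- all_known[1, , drop = FALSE]
  ld <- ld_tab(list("A", "D", 0.65), list("A", "E", 0.59),
               list("D", "F", 0.7), list("A", "F", 0.1))
  got <- expand_to_blocks(indep, all_known, ld)
  expect_setequal(got$rsid, c("A", "D"))   # E below 0.6; F only via D
  # boundary: exactly 0.6 is included
  ld2 <- ld_tab(list("A", "D", 0.6))
  expect_setequal(expand_to_blocks(indep, all_known, ld2)$rsid, c("A", "D"))
  # closure oracle differs precisely by F
  closure <- c("A", "D", "F")
  expect_false(setequal(got$rsid, closure))
  expect_error(expand_to_blocks(snp_tab(list("Z", 1e-9)), all_known, ld),
               "subset")
})

test_that("positional mapping honours the 10 kb rule at the boundary", {
  genes <- gene_tab(start = 50000, end = 60000)  # 1-based span 50001..60000
  hit <- function(pos) {
    snps <- data.frame(rsid = "s", chrom = "chr1", pos = pos, pvalue = 1e-9)
    nrow(map_positional(snps, genes)) == 1
  }
  expect_true(hit(50001 - 9999))   # 9,999 bp upstream
  expect_false(hit(50001 - 10001)) # 10,001 bp upstream
  expect_true(hit(50001 - 10000))  # exactly 10 kb
  expect_true(hit(55000))          # inside the span
  expect_true(hit(60000 + 10000))  # downstream edge
  expect_false(hit(60000 + 10001))
})

test_that("positional mapping warns on chromosome mismatch", {
  genes <- gene_tab()
  snps <- data.frame(rsid = "s", chrom = "chr9", pos = 55000, pvalue = 1e-9)
  expect_warning(res <- map_positional(snps, genes), "chr9")
  expect_equal(nrow(res), 0)
})

test_that("eQTL mapping threshold is inclusive and ignores foreign SNPs", {
  snps <- snp_tab(list("A", 1e-9))
  eq <- function(rsid, fdr)
    data.frame(rsid = rsid, gene_id = "G1", tissue = "T", fdr = fdr)
  expect_equal(map_eqtl(snps, eq("A", 0.05))$gene_id, "G1")
  expect_equal(nrow(map_eqtl(snps, eq("A", 0.051))), 0)
  expect_equal(nrow(map_eqtl(snps, eq("B", 0.01))), 0)
})

test_that("raising thresholds never removes candidates (monotonicity)", {
  set.seed(202)
  genes <- gen_gene_models(sim_config(seed = 30, n_genes = 10))
  snps <- data.frame(rsid = sprintf("r%02d", 1:20), chrom = "chr1",
                     pos = sort(sample.int(max(genes$end), 20)),
                     pvalue = 10^-runif(20, 8, 12))
  eqtls <- data.frame(rsid = sample(snps$rsid, 15, replace = TRUE),
                      gene_id = sample(genes$gene_id, 15, replace = TRUE),
                      tissue = "T", fdr = runif(15, 0, 0.2))
  for (d in c(0, 1000, 10000, 50000)) {
    lo <- map_positional(snps, genes, max_dist_bp = d)$gene_id
    hi <- map_positional(snps, genes, max_dist_bp = d + 5000)$gene_id
    expect_true(all(lo %in% hi))
  }
  for (f in c(0.01, 0.05, 0.1)) {
    lo <- map_eqtl(snps, eqtls, fdr_thresh = f)$gene_id
    hi <- map_eqtl(snps, eqtls, fdr_thresh = f + 0.05)$gene_id
    expect_true(all(lo %in% hi))
  }
})

test_that("chromatin mapping requires opposite ends and significant FDR", {
  genes <- gene_tab(start = 50000, end = 60000, strand = "+")
  # promoter: [50001-250, 50001+500]
  snps <- data.frame(rsid = "s", chrom = "chr1", pos = 5000, pvalue = 1e-9)
  ints <- function(fdr, startB = 49000, endB = 51000)
    data.frame(chromA = "chr1", startA = 4000, endA = 6000,
               chromB = "chr1", startB = startB, endB = endB, fdr = fdr)
  expect_equal(map_chromatin(snps, ints(1e-7), genes)$gene_id, "G1")
  expect_equal(nrow(map_chromatin(snps, ints(1e-5), genes)), 0)
  expect_equal(map_chromatin(snps, ints(1e-6), genes)$gene_id, "G1")
  # ends are interchangeable (A/B order irrelevant)
  swapped <- data.frame(chromA = "chr1", startA = 49000, endA = 51000,
                        chromB = "chr1", startB = 4000, endB = 6000,
                        fdr = 1e-7)
  expect_equal(map_chromatin(snps, swapped, genes)$gene_id, "G1")
  # SNP and promoter on the SAME end only: no call (brute-force geometry:
  # the other end is far from everything)
  same_end <- data.frame(chromA = "chr1", startA = 4000, endA = 51000,
                         chromB = "chr1", startB = 900000, endB = 901000,
                         fdr = 1e-9)
  expect_equal(nrow(map_chromatin(snps, same_end, genes)), 0)
})

test_that("promoter windows are strand-aware (mirrored on minus strand)", {
  plus <- gene_tab(strand = "+")   # tss 50001, window [49751, 50501]
  minus <- gene_tab(strand = "-")  # tss 60000, window [59500, 60250]
  snps <- data.frame(rsid = "s", chrom = "chr1", pos = 5000, pvalue = 1e-9)
  int_at <- function(startB, endB)
    data.frame(chromA = "chr1", startA = 4000, endA = 6000,
               chromB = "chr1", startB = startB, endB = endB, fdr = 1e-8)
  # minus-strand gene: a region covering tss+251..tss+400 is outside the
  # mirrored window but inside the unmirrored one
  expect_equal(nrow(map_chromatin(snps, int_at(60250, 60400), minus)), 0)
  expect_equal(
    map_chromatin(snps, int_at(60250, 60400), minus,
                  strand_aware = FALSE)$gene_id, "G1")
  # plus-strand gene unaffected by the flag
  expect_equal(map_chromatin(snps, int_at(49800, 49900), plus)$gene_id,
               "G1")
})

test_that("candidate sets are invariant under coordinate reflection", {
  cfg <- sim_config(seed = 33, n_genes = 8, n_snps = 12, ld_block_size = 3)
  genes <- gen_gene_models(cfg)
  gw <- gen_gwas_inputs(cfg, genes)
  L <- max(genes$end, gw$snps$pos, gw$interactions$endB) + 1000
  p1 <- map_positional(gw$snps, genes)
  p2 <- map_positional(reflect_snps(gw$snps, L), reflect_genes(genes, L))
  expect_equal(p1[order(p1$gene_id), ], p2[order(p2$gene_id), ])
  c1 <- map_chromatin(gw$snps, gw$interactions, genes)
  c2 <- map_chromatin(reflect_snps(gw$snps, L),
                      reflect_interactions(gw$interactions, L),
                      reflect_genes(genes, L))
  expect_equal(sort(c1$gene_id), sort(c2$gene_id))
})

test_that("combining candidate sets unions genes and merges evidence", {
  a <- map_eqtl(snp_tab(list("A", 1e-9)),
                data.frame(rsid = "A", gene_id = c("G1", "G2"),
                           tissue = "T", fdr = 0.01))
  genes <- gene_tab(gene_id = "G3", start = 1000, end = 2000)
  b <- map_positional(data.frame(rsid = "B", chrom = "chr1", pos = 1500,
                                 pvalue = 1e-9), genes)
  comb <- combine_candidates(a, b)
  expect_equal(nrow(comb), 3)
  expect_true(all(comb$positional | comb$eqtl | comb$chromatin))

  same <- combine_candidates(
    b, map_eqtl(snp_tab(list("A", 1e-9)),
                data.frame(rsid = "A", gene_id = "G3", tissue = "T",
                           fdr = 0.01)))
  expect_equal(nrow(same), 1)
  expect_true(same$positional && same$eqtl && !same$chromatin)

  expect_equal(nrow(combine_candidates(map_eqtl(snp_tab(list("A", 1e-9)),
    data.frame(rsid = character(), gene_id = character(),
               tissue = character(), fdr = numeric())))), 0)
})
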