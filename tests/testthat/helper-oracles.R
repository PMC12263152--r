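# Independent oracles and small fixture builders used across tests.

# dense symmetric r2 matrix from the pair table (diag 1, absent pairs 0)
r2_matrix <- function(snps, ld) {
  n <- nrow(snps)
  m <- diag(n)
  dimnames(m) <- list(snps$rsid, snps$rsid)
  for (k in seq_len(nrow(ld))) {
    a <- ld$rsid1[k]; b <- ld$rsid2[k]
    if (a %in% snps$rsid && b %in% snps$rsid)
      m[a, b] <- m[b, a] <- ld$r2[k]
  }
  m
}

# all subsets of SNPs satisfying the pruning post-condition:
# pairwise r2 < thresh, and every excluded SNP in LD (>= thresh) with a
# retained SNP of smaller-or-equal p. Brute force over 2^n subsets.
valid_independent_sets <- function(snps, ld, thresh = 0.6) {
  m <- r2_matrix(snps, ld)
  n <- nrow(snps)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) >= 2) {
      sub <- m[S, S, drop = FALSE]
      if (max(sub[upper.tri(sub)]) >= thresh) next
    }
    excl <- setdiff(seq_len(n), S)
    covered <- vapply(excl, function(e) {
      length(S) > 0 &&
        any(m[e, S] >= thresh & snps$pvalue[S] <= snps$pvalue[e])
    }, logical(1))
    if (all(covered)) out[[length(out) + 1]] <- sort(snps$rsid[S])
  }
  out
}

# exact permutation p on a tiny sample: enumerate all case-index subsets
exhaustive_permutation_p <- function(burden, status) {
  y <- as.integer(status == "case")
  n1 <- sum(y)
  idx_sets <- utils::combn(length(y), n1)
  n0 <- length(y) - n1
  tot <- sum(burden)
  stat <- function(i) sum(burden[i]) / n1 - (tot - sum(burden[i])) / n0
  obs <- stat(which(y == 1))
  perms <- apply(idx_sets, 2, stat)
  mean(perms >= obs - 1e-12)
}

# random SNP/LD instance for the pruning oracle suite
random_prune_instance <- function(n, ld_prob = 0.4) {
  snps <- data.frame(rsid = sprintf("s%02d", seq_len(n)), chrom = "chr1",
                     pos = seq_len(n) * 1000,
                     pvalue = 10^-runif(n, 2, 12),
                     stringsAsFactors = FALSE)
  pairs <- if (n >= 2) t(utils::combn(snps$rsid, 2)) else
    matrix(character(0), 0, 2)
  keep <- runif(nrow(pairs)) < ld_prob
  ld <- data.frame(rsid1 = pairs[keep, 1], rsid2 = pairs[keep, 2],
                   r2 = runif(sum(keep)), stringsAsFactors = FALSE)
  list(snps = snps, ld = ld)
}

# reflect 1-based positions / 0-based half-open spans about chromosome
# of length L (used by the strand-symmetry checks)
reflect_snps <- function(snps, L) {
  snps$pos <- L - snps$pos + 1L
  snps
}
reflect_genes <- function(genes, L) {
  new_start <- L - genes$end
  new_end <- L - genes$start
  genes$start <- new_start
  genes$end <- new_end
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  genes$tss <- L - genes$tss + 1L
  genes
}
reflect_interactions <- function(ints, L) {
  sA <- L - ints$endA; eA <- L - ints$startA
  sB <- L - ints$endB; eB <- L - ints$startB
  ints$startA <- sA; ints$endA <- eA
  ints$startB <- sB; ints$endB <- eB
  ints
}

# one-row variant annotation with the pipeline's column dialect
variant_row <- function(csq_class, loftee = NA, spliceai = NA,
                        revel = NA, cadd = NA, popmax_af = 0,
                        cohort_ac = 1L, variant_id = "v1",
                        gene_id = "G1") {
  data.frame(variant_id = variant_id, gene_id = gene_id, chrom = "chr1",
             pos = 100L, ref = "A", alt = "T", csq_class = csq_class,
             loftee = loftee, spliceai = spliceai, revel = revel,
             cadd = cadd, popmax_af = popmax_af, cohort_ac = cohort_ac,
             stringsAsFactors = FALSE)
}

# random annotations spanning the whole input space (for fuzzing)
random_variants <- function(n) {
  cls <- sample(c("lof_canonical", "noncanonical_splice", "missense",
                  "inframe_indel", "other"), n, replace = TRUE)
  maybe <- function(x) ifelse(runif(n) < 0.2, NA, x)
  data.frame(variant_id = sprintf("v%04d", seq_len(n)),
             gene_id = sample(sprintf("G%02d", 1:5), n, replace = TRUE),
             csq_class = cls,
             loftee = ifelse(runif(n) < 0.3, NA,
                             sample(c("HC", "LC"), n, replace = TRUE)),
             spliceai = maybe(runif(n)),
             revel = maybe(runif(n)),
             cadd = maybe(runif(n, 0, 50)),
             popmax_af = 0, cohort_ac = 1L,
             stringsAsFactors = FALSE)
}
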