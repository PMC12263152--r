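#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# symmetric r2 lookup table as an environment keyed "rsidA|rsidB" (sorted)
.ld_env <- function(ld) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(ld)) {
    a <- pmin(ld$rsid1, ld$rsid2)
    b <- pmax(ld$rsid1, ld$rsid2)
    keys <- paste(a, b, sep = "|")
    for (k in seq_along(keys)) assign(keys[k], ld$r2[k], envir = env)
  }
  env
}

# r2 between two rsids; diagonal 1, missing pair 0
.ld_r2 <- function(env, a, b) {
  if (a == b) return(1)
  key <- paste(min(a, b), max(a, b), sep = "|")
  if (exists(key, envir = env, inherits = FALSE))
    get(key, envir = env, inherits = FALSE) else 0
}

.check_snps <- function(snps) {
  stopifnot(is.data.frame(snps),
            all(c("rsid", "chrom", "pos", "pvalue") %in% names(snps)))
  if (anyDuplicated(snps$rsid))
    stop("duplicate rsids in SNP table", call. = FALSE)
  if (nrow(snps) && (any(snps$pos < 1) ||
                     any(snps$pvalue <= 0 | snps$pvalue > 1)))
    stop("SNP table: pos must be >= 1 and p-values in (0, 1]",
         call. = FALSE)
  invisible(snps)
}

#' LD-prune significant SNPs to an independent set
#'
#' Greedy clumping in ascending p order: a SNP is retained if its
#' r-squared with every already-retained SNP is below `r2_thresh`
#' (independence means r2 < 0.6 under the default). Every discarded SNP
#' is therefore in LD (r2 >= threshold) with some retained SNP of
#' smaller or equal p. Pairs absent from the LD table are treated as
#' r2 = 0; ties in p are broken by rsid for determinism.
#'
#' @param snps data.frame with columns `rsid`, `chrom`, `pos`, `pvalue`.
#' @param ld data.frame with columns `rsid1`, `rsid2`, `r2` (symmetric;
#'   missing pairs are uncorrelated).
#' @param r2_thresh Independence threshold; retained SNPs have pairwise
#'   r2 strictly below it.
#' @return The retained rows of `snps`, in ascending p order.
#' @examples
#' snps <- data.frame(rsid = c("a", "b"), chrom = "chr1", pos = c(1, 2),
#'                    pvalue = c(1e-10, 1e-9))
#' ld <- data.frame(rsid1 = "a", rsid2 = "b", r2 = 0.7)
#' prune_independent(snps, ld)  # only "a" survives
#' @export
prune_independent <- function(snps, ld, r2_thresh = 0.6) {
  .check_snps(snps)
  if (nrow(snps) == 0) return(snps)
  env <- .ld_env(ld)
  ord <- order(snps$pvalue, snps$rsid)
  kept <- character(0)
  for (i in ord) {
    rs <- snps$rsid[i]
    r2s <- vapply(kept, function(k) .ld_r2(env, rs, k), numeric(1))
    if (!length(kept) || all(r2s < r2_thresh)) kept <- c(kept, rs)
  }
  out <- snps[match(kept, snps$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand independent SNPs to their LD blocks
#'
#' Adds every known SNP whose r-squared with at least one independent
#' SNP is at or above `r2_thresh` (block membership is r2 >= 0.6 under
#' the default, boundary inclusive). No transitive closure: a SNP linked
#' only to another block member, not to an independent SNP itself, is
#' not added.
#'
#' @param independent Independent SNPs (a subset of `all_known`).
#' @param all_known The full SNP table eligible for gene mapping.
#' @inheritParams prune_independent
#' @return Rows of `all_known` for the union, in `all_known` order.
#' @export
expand_to_blocks <- function(independent, all_known, ld, r2_thresh = 0.6) {
  .check_snps(all_known)
  stopifnot(is.data.frame(independent))
  if (!all(independent$rsid %in% all_known$rsid))
    stop("expand_to_blocks: independent SNPs must be a subset of all_known",
         call. = FALSE)
  env <- .ld_env(ld)
  in_block <- vapply(all_known$rsid, function(rs) {
    any(vapply(independent$rsid,
               function(i) .ld_r2(env, rs, i) >= r2_thresh, logical(1)))
  }, logical(1))
  keep <- all_known$rsid %in% independent$rsid | in_block
  out <- all_known[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- candidate gene sets -------------------------------------------------

.empty_candidates <- function() {
  data.frame(gene_id = character(), positional = logical(),
             eqtl = logical(), chromatin = logical(),
             snps_positional = character(), snps_eqtl = character(),
             snps_chromatin = character(), stringsAsFactors = FALSE)
}

# build a one-evidence candidate set from (gene_id, rsid) support pairs
.candidates_from_pairs <- function(pairs, evidence) {
  out <- .empty_candidates()
  if (nrow(pairs) == 0) return(out)
  genes <- sort(unique(pairs$gene_id))
  support <- vapply(genes, function(g)
    paste(sort(unique(pairs$rsid[pairs$gene_id == g])), collapse = ","), "")
  out <- data.frame(gene_id = genes, positional = FALSE, eqtl = FALSE,
                    chromatin = FALSE, snps_positional = "",
                    snps_eqtl = "", snps_chromatin = "",
                    stringsAsFactors = FALSE)
  out[[evidence]] <- TRUE
  out[[paste0("snps_", evidence)]] <- unname(support)
  out
}

#' Map SNPs to genes by position
#'
#' A gene is a positional candidate if some SNP lies within its span or
#' within `max_dist_bp` of either span edge (the 10 kb rule for
#' intergenic SNPs; intragenic SNPs map to their containing gene).
#'
#' @param snps SNP table (rsid, chrom, pos 1-based, pvalue).
#' @param genes Gene models (gene_id, chrom, start, end 0-based
#'   half-open, strand, tss 1-based).
#' @param max_dist_bp Maximum distance from a span edge, in bp.
#' @return A candidate-gene data.frame (gene_id, evidence flags,
#'   supporting SNPs per evidence type).
#' @export
map_positional <- function(snps, genes, max_dist_bp = 10000) {
  .check_snps(snps)
  if (nrow(snps) == 0 || nrow(genes) == 0) return(.empty_candidates())
  missing_chrom <- !snps$chrom %in% genes$chrom
  if (any(missing_chrom))
    warning("map_positional: no gene models on chromosome(s) ",
            paste(unique(snps$chrom[missing_chrom]), collapse = ", "),
            "; those SNPs match nothing", call. = FALSE)
  lv <- unique(c(genes$chrom, snps$chrom))
  gr_genes <- GRanges(factor(genes$chrom, lv),
                      IRanges(pmax(1L, genes$start + 1L - max_dist_bp),
                              genes$end + max_dist_bp))
  gr_snps <- GRanges(factor(snps$chrom, lv), IRanges(snps$pos, snps$pos))
  hits <- findOverlaps(gr_snps, gr_genes)
  pairs <- data.frame(gene_id = genes$gene_id[subjectHits(hits)],
                      rsid = snps$rsid[queryHits(hits)],
                      stringsAsFactors = FALSE)
  .candidates_from_pairs(pairs, "positional")
}

#' Map SNPs to genes through eQTL evidence
#'
#' A gene is an eQTL candidate if some record links an input SNP to it
#' in any tissue at FDR at or below `fdr_thresh` (boundary inclusive).
#'
#' @param snps SNP table; only records naming these rsids contribute.
#' @param eqtls data.frame with columns `rsid`, `gene_id`, `tissue`,
#'   `fdr`.
#' @param fdr_thresh Significance threshold on the record FDR.
#' @return A candidate-gene data.frame.
#' @export
map_eqtl <- function(snps, eqtls, fdr_thresh = 0.05) {
  .check_snps(snps)
  hit <- eqtls$rsid %in% snps$rsid & eqtls$fdr <= fdr_thresh
  .candidates_from_pairs(eqtls[hit, c("gene_id", "rsid")], "eqtl")
}

#' Map SNPs to genes through chromatin interactions with promoters
#'
#' A gene is a chromatin candidate if a significant interaction
#' (FDR <= `fdr_thresh`) has a SNP overlapping one end and the gene's
#' promoter overlapping the *other* end. The promoter is the closed
#' 1-based window from `promoter_up_bp` upstream to `promoter_down_bp`
#' downstream of the TSS; with `strand_aware = TRUE` (default) the
#' window is mirrored on the minus strand, otherwise plus-strand
#' coordinates are used for all genes.
#'
#' @param snps SNP table.
#' @param interactions data.frame with columns `chromA`, `startA`,
#'   `endA`, `chromB`, `startB`, `endB` (0-based half-open) and `fdr`.
#' @param genes Gene models.
#' @param fdr_thresh Interaction significance threshold (default 1e-6).
#' @param promoter_up_bp,promoter_down_bp Promoter window relative to
#'   the TSS, in bp.
#' @param strand_aware Mirror the promoter window on the minus strand.
#' @return A candidate-gene data.frame.
#' @export
map_chromatin <- function(snps, interactions, genes, fdr_thresh = 1e-6,
                          promoter_up_bp = 250, promoter_down_bp = 500,
                          strand_aware = TRUE) {
  .check_snps(snps)
  sig <- interactions[interactions$fdr <= fdr_thresh, , drop = FALSE]
  if (nrow(sig) == 0 || nrow(snps) == 0 || nrow(genes) == 0)
    return(.empty_candidates())

  up <- ifelse(strand_aware & genes$strand == "-",
               promoter_down_bp, promoter_up_bp)
  down <- ifelse(strand_aware & genes$strand == "-",
                 promoter_up_bp, promoter_down_bp)
  lv <- unique(c(genes$chrom, snps$chrom, sig$chromA, sig$chromB))
  gr_prom <- GRanges(factor(genes$chrom, lv),
                     IRanges(pmax(1L, genes$tss - up), genes$tss + down))
  gr_snps <- GRanges(factor(snps$chrom, lv), IRanges(snps$pos, snps$pos))
  gr_a <- GRanges(factor(sig$chromA, lv),
                  IRanges(sig$startA + 1L, pmax(sig$startA + 1L, sig$endA)))
  gr_b <- GRanges(factor(sig$chromB, lv),
                  IRanges(sig$startB + 1L, pmax(sig$startB + 1L, sig$endB)))

  pair_up <- function(snp_end, prom_end) {
    sh <- findOverlaps(gr_snps, snp_end)
    ph <- findOverlaps(gr_prom, prom_end)
    sh_df <- data.frame(k = subjectHits(sh), rsid = snps$rsid[queryHits(sh)])
    ph_df <- data.frame(k = subjectHits(ph),
                        gene_id = genes$gene_id[queryHits(ph)])
    merge(sh_df, ph_df, by = "k")[, c("gene_id", "rsid")]
  }
  pairs <- rbind(pair_up(gr_a, gr_b), pair_up(gr_b, gr_a))
  .candidates_from_pairs(pairs, "chromatin")
}

#' Combine candidate-gene sets from the three mapping strategies
#'
#' Union of genes with per-gene merged evidence flags and supporting
#' SNP lists.
#'
#' @param ... Candidate-gene data.frames as returned by
#'   [map_positional()], [map_eqtl()] and [map_chromatin()].
#' @return A single candidate-gene data.frame sorted by `gene_id`.
#' @export
combine_candidates <- function(...) {
  sets <- list(...)
  all <- do.call(rbind, sets)
  if (is.null(all) || nrow(all) == 0) return(.empty_candidates())
  genes <- sort(unique(all$gene_id))
  merge_support <- function(x) {
    s <- unique(unlist(strsplit(x[nzchar(x)], ",")))
    paste(sort(s), collapse = ",")
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    rows <- all[all$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g,
               positional = any(rows$positional),
               eqtl = any(rows$eqtl),
               chromatin = any(rows$chromatin),
               snps_positional = merge_support(rows$snps_positional),
               snps_eqtl = merge_support(rows$snps_eqtl),
               snps_chromatin = merge_support(rows$snps_chromatin),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
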