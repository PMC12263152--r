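#' Filter to ultra-rare variants
#'
#' Retains variants with gnomAD population-max allele frequency at or
#' below `af_max` (0.01% by default) AND cohort allele count at or
#' below `ac_max` (3 by default). A variant missing from gnomAD
#' (`popmax_af` NA) is treated as frequency 0 and a note is emitted.
#' If the `cohort_ac` column is absent or all-NA it is computed from
#' `genotypes` column sums.
#'
#' @param variants Annotation data.frame (see [gen_cohort()] for the
#'   column dialect).
#' @param af_max Maximum gnomAD popmax allele frequency (fraction).
#' @param ac_max Maximum cohort allele count.
#' @param genotypes Optional samples x variants allele-count matrix used
#'   to derive `cohort_ac` when absent.
#' @return The retained rows of `variants`, `popmax_af` NA replaced by 0.
#' @export
filter_ultra_rare <- function(variants, af_max = 1e-4, ac_max = 3,
                              genotypes = NULL) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0) return(variants)
  if (is.null(variants$cohort_ac) || all(is.na(variants$cohort_ac))) {
    if (is.null(genotypes))
      stop("filter_ultra_rare: cohort_ac absent and no genotypes supplied",
           call. = FALSE)
    variants$cohort_ac <-
      as.integer(Matrix::colSums(genotypes[, variants$variant_id,
                                           drop = FALSE]))
  }
  if (anyNA(variants$popmax_af)) {
    message("filter_ultra_rare: ", sum(is.na(variants$popmax_af)),
            " variant(s) missing popmax AF; treated as absent from gnomAD",
            " (AF = 0)")
    variants$popmax_af[is.na(variants$popmax_af)] <- 0
  }
  keep <- variants$popmax_af <= af_max & variants$cohort_ac <= ac_max
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign annotation-tier weights to ultra-rare variants
#'
#' Deterministic six-level ladder over consequence class and in-silico
#' scores, applied to variants that already passed the ultra-rare
#' filter:
#'
#' * **1.0** - canonical LoF (canonical splice, nonsense, frameshift,
#'   stop-gain, start-loss) rated high-confidence (`HC`) by LOFTEE;
#' * **0.8** - canonical LoF rated low-confidence or unlabeled by
#'   LOFTEE; noncanonical splice with SpliceAI > 0.5; missense with
#'   REVEL > 0.8;
#' * **0.6** - in-frame indel with CADD > 20; missense with
#'   0.6 < REVEL <= 0.8;
#' * **0.4** - in-frame indel with 10 < CADD <= 20; missense with
#'   0.4 < REVEL <= 0.6;
#' * **0.2** - remaining in-frame indels (CADD <= 10 or missing;
#'   configurable via `indel_low_cadd_weight`); missense with
#'   0.2 < REVEL <= 0.4;
#' * **0** - everything else (missense with REVEL <= 0.2 or missing,
#'   noncanonical splice with SpliceAI <= 0.5 or missing, class
#'   `other`).
#'
#' Missing scores are conservative: a missense variant without a REVEL
#' score gets weight 0; an in-frame indel without CADD falls to the
#' "remaining indel" tier.
#'
#' @param variants Annotation data.frame with columns `variant_id`,
#'   `gene_id`, `csq_class`, `loftee`, `spliceai`, `revel`, `cadd`.
#' @param indel_low_cadd_weight Weight for in-frame indels below the
#'   CADD > 10 tier (default 0.2).
#' @return data.frame with columns `variant_id`, `gene_id`, `weight`,
#'   `tier_reason`.
#' @examples
#' v <- data.frame(variant_id = "v1", gene_id = "G", csq_class = "missense",
#'                 loftee = NA, spliceai = NA, revel = 0.7, cadd = NA)
#' assign_weights(v)$weight  # 0.6
#' @export
assign_weights <- function(variants, indel_low_cadd_weight = 0.2) {
  stopifnot(is.data.frame(variants))
  n <- nrow(variants)
  cls <- as.character(variants$csq_class)
  bad <- !cls %in% .CSQ_CLASSES
  if (any(bad))
    stop("assign_weights: unknown csq_class: ",
         paste(unique(cls[bad]), collapse = ", "), call. = FALSE)
  num_or <- function(x, fill) {
    if (is.null(x)) return(rep(fill, n))
    x <- as.numeric(x); x[is.na(x)] <- fill; x
  }
  loftee <- as.character(if (is.null(variants$loftee)) rep(NA, n)
                         else variants$loftee)
  loftee[is.na(loftee) | loftee == ""] <- "missing"
  spliceai <- num_or(variants$spliceai, -Inf)
  revel <- num_or(variants$revel, -Inf)
  cadd <- num_or(variants$cadd, -Inf)

  w <- numeric(n)
  reason <- rep("no qualifying annotation", n)
  set <- function(cond, weight, why) {
    cond <- cond & !done
    w[cond] <<- weight
    reason[cond] <<- why
    done[cond] <<- TRUE
  }
  done <- rep(FALSE, n)
  lof <- cls == "lof_canonical"
  set(lof & loftee == "HC", 1.0, "canonical LoF, LOFTEE HC")
  set(lof, 0.8, "canonical LoF, LOFTEE LC/unlabeled")
  set(cls == "noncanonical_splice" & spliceai > 0.5, 0.8,
      "noncanonical splice, SpliceAI > 0.5")
  mis <- cls == "missense"
  set(mis & revel > 0.8, 0.8, "missense, REVEL > 0.8")
  ind <- cls == "inframe_indel"
  set(ind & cadd > 20, 0.6, "in-frame indel, CADD > 20")
  set(mis & revel > 0.6, 0.6, "missense, 0.6 < REVEL <= 0.8")
  set(ind & cadd > 10, 0.4, "in-frame indel, 10 < CADD <= 20")
  set(mis & revel > 0.4, 0.4, "missense, 0.4 < REVEL <= 0.6")
  set(ind, indel_low_cadd_weight, "remaining in-frame indel")
  set(mis & revel > 0.2, 0.2, "missense, 0.2 < REVEL <= 0.4")

  data.frame(variant_id = variants$variant_id,
             gene_id = variants$gene_id,
             weight = w,
             tier_reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-sample, per-gene maximum-weight burden
#'
#' The mutational burden of a gene in an individual is the maximum
#' ladder weight among the ultra-rare qualifying variants that
#' individual carries in the gene (carrier = allele count >= 1, het or
#' hom); non-carriers have burden 0, as do carriers of only weight-0
#' variants.
#'
#' @param genotypes Samples x variants allele-count matrix (0/1/2; dense
#'   or [Matrix::sparseMatrix()]), with dimnames.
#' @param weights Weighted variants from [assign_weights()]; every
#'   `variant_id` must be a column of `genotypes`.
#' @return A dense samples x genes burden matrix with values on the
#'   weight ladder.
#' @export
compute_gene_burden <- function(genotypes, weights) {
  stopifnot(is.data.frame(weights),
            all(c("variant_id", "gene_id", "weight") %in% names(weights)))
  missing <- setdiff(weights$variant_id, colnames(genotypes))
  if (length(missing))
    stop("compute_gene_burden: no genotype column for variant(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  genes <- sort(unique(weights$gene_id))
  burden <- matrix(0, nrow(genotypes), length(genes),
                   dimnames = list(rownames(genotypes), genes))
  if (nrow(weights) == 0 || nrow(genotypes) == 0) return(burden)
  G <- methods::as(genotypes[, weights$variant_id, drop = FALSE],
                   "TsparseMatrix")
  carried <- G@x >= 1
  i <- G@i[carried] + 1L
  j <- G@j[carried] + 1L
  wv <- weights$weight[j]
  gj <- match(weights$gene_id[j], genes)
  # assign ascending by weight so the last write per cell is the maximum
  o <- order(wv)
  burden[cbind(i[o], gj[o])] <- wv[o]
  burden
}
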