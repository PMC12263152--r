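#' Generate non-overlapping gene models on a toy chromosome
#'
#' Places `cfg$n_genes` genes on a single synthetic chromosome (`chr1`)
#' with random lengths (2-20 kb) separated by intergenic gaps of
#' 30-60 kb, so that the 10 kb positional-mapping window of one gene can
#' never reach a neighbour. Strand is random; the transcription start
#' site is the 5' end of the span on the assigned strand.
#'
#' Coordinates follow BED conventions internally: `start`/`end` are
#' 0-based half-open, `tss` is 1-based.
#'
#' @param cfg A [sim_config()] object.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @examples
#' genes <- gen_gene_models(sim_config(seed = 1, n_genes = 3))
#' @export
gen_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .seed_child(cfg, 1L)
  n <- cfg$n_genes
  len <- round(stats::runif(n, 2000, 20000))
  gap <- round(stats::runif(n, 30000, 60000))
  start <- cumsum(gap) + c(0, cumsum(len[-n]))
  end <- start + len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start + 1, end)
  data.frame(gene_id = sprintf("GENE%04d", seq_len(n)),
             chrom = "chr1",
             start = as.integer(start),
             end = as.integer(end),
             strand = strand,
             tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

#' Generate GWAS summary inputs: SNPs, LD, eQTLs and chromatin interactions
#'
#' Places SNPs in LD blocks of `cfg$ld_block_size` along the toy
#' chromosome. Within a block, pairwise r-squared is drawn uniform on
#' (0.5, 0.95) so both prune-away (r2 >= 0.6) and retain (r2 < 0.6)
#' cases occur; across blocks r-squared is 0 (absent from the table).
#' The first one or two SNPs of each block are genome-wide significant
#' (p < 5e-8). The first block is anchored just upstream of the causal
#' gene and linked to it by a planted significant eQTL record
#' (FDR = 0.01) and a planted chromatin interaction between the lead-SNP
#' region and the causal gene's promoter (FDR = 1e-8). Decoy records sit
#' above the respective significance thresholds, and one eQTL names a
#' SNP absent from the GWAS table, so the mapping stage's filters are
#' all exercised.
#'
#' @param cfg A [sim_config()] object.
#' @param genes Gene models from [gen_gene_models()].
#' @return A list with elements `snps` (rsid, chrom, pos, pvalue),
#'   `ld` (rsid1, rsid2, r2), `eqtls` (rsid, gene_id, tissue, fdr) and
#'   `interactions` (chromA, startA, endA, chromB, startB, endB, fdr).
#' @export
gen_gwas_inputs <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.data.frame(genes) || nrow(genes) == 0)
    stop("gen_gwas_inputs: genes must be a non-empty data.frame",
         call. = FALSE)
  .seed_child(cfg, 2L)
  causal <- genes[genes$gene_id == cfg$causal_gene, ]
  if (nrow(causal) != 1)
    stop("gen_gwas_inputs: causal gene not found in gene models",
         call. = FALSE)

  bs <- cfg$ld_block_size
  n_blocks <- ceiling(cfg$n_snps / bs)
  sizes <- rep(bs, n_blocks)
  sizes[n_blocks] <- cfg$n_snps - bs * (n_blocks - 1)

  chrom_end <- max(genes$end) + 50000
  anchors <- c(max(1, causal$start - 5000),
               round(stats::runif(n_blocks - 1, 1, chrom_end)))
  pos <- integer(0); block <- integer(0)
  for (b in seq_len(n_blocks)) {
    offs <- cumsum(round(stats::runif(sizes[b], 200, 1500)))
    pos <- c(pos, anchors[b] + offs - offs[1])
    block <- c(block, rep(b, sizes[b]))
  }
  rank_in_block <- unlist(lapply(sizes, seq_len))
  pval <- 10^-stats::runif(cfg$n_snps, 3, 7.25)     # non-significant
  pval[rank_in_block == 1] <- 10^-stats::runif(sum(rank_in_block == 1), 8.5, 12)
  pval[rank_in_block == 2] <- 10^-stats::runif(sum(rank_in_block == 2), 7.5, 9)
  snps <- data.frame(rsid = sprintf("rs%05d", seq_len(cfg$n_snps)),
                     chrom = "chr1",
                     pos = as.integer(pos),
                     pvalue = pval,
                     stringsAsFactors = FALSE)

  ld <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    ids <- snps$rsid[block == b]
    if (length(ids) < 2) return(NULL)
    pr <- t(utils::combn(ids, 2))
    data.frame(rsid1 = pr[, 1], rsid2 = pr[, 2],
               r2 = stats::runif(nrow(pr), 0.5, 0.95),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ld))
    ld <- data.frame(rsid1 = character(), rsid2 = character(),
                     r2 = numeric(), stringsAsFactors = FALSE)

  lead1 <- snps$rsid[block == 1][1]
  decoy_genes <- setdiff(genes$gene_id, cfg$causal_gene)
  if (length(decoy_genes) == 0) decoy_genes <- cfg$causal_gene
  eqtls <- data.frame(
    rsid = c(lead1,
             sample(snps$rsid, 3, replace = TRUE),
             "rs99999"),
    gene_id = c(cfg$causal_gene,
                sample(decoy_genes, 3, replace = TRUE),
                sample(decoy_genes, 1)),
    tissue = c("Muscle_Skeletal", "Whole_Blood", "Brain_Cortex",
               "Artery_Tibial", "Muscle_Skeletal"),
    fdr = c(0.01, stats::runif(3, 0.06, 0.5), 0.02),
    stringsAsFactors = FALSE)

  lead_pos <- snps$pos[snps$rsid == lead1]
  prom <- .promoter_span(causal)          # 1-based closed
  far <- chrom_end + 100000
  interactions <- data.frame(
    chromA = "chr1",
    startA = c(max(0, lead_pos - 2000), max(0, lead_pos - 2000), far),
    endA = c(lead_pos + 2000, lead_pos + 2000, far + 4000),
    chromB = "chr1",
    startB = c(prom[1] - 1001, prom[1] - 1001, far + 50000),
    endB = c(prom[2] + 1000, prom[2] + 1000, far + 54000),
    fdr = c(1e-8, 1e-3, 1e-8),
    stringsAsFactors = FALSE)

  list(snps = snps, ld = ld, eqtls = eqtls, interactions = interactions)
}

# promoter span, 1-based closed, strand-aware (-250/+500 around the TSS)
.promoter_span <- function(gene, up = 250, down = 500) {
  if (gene$strand == "+") c(gene$tss - up, gene$tss + down)
  else c(gene$tss - down, gene$tss + up)
}

#' Generate an annotated ultra-rare case-control cohort
#'
#' Carrier status at each gene is Bernoulli per individual: controls
#' carry a qualifying allele with probability
#' `cfg$baseline_carrier_rate`; at the causal gene, cases carry with the
#' probability implied by `cfg$target_or` on the odds scale (see
#' [case_rate_for_or()]); all other genes have equal rates in both arms.
#' Carriers are spread over variants with at most two carriers each, so
#' every qualifying variant respects the cohort allele count <= 3 and
#' gnomAD popmax allele frequency <= 0.01% filters, and each carried
#' variant is given annotation scores guaranteeing a positive ladder
#' weight. A configurable fraction of additional "noise" variants
#' deliberately violate the allele-frequency or allele-count filter, or
#' carry weight-0 annotations; their carriers are drawn independently of
#' phenotype so they exercise the filters without perturbing the planted
#' odds ratio.
#'
#' @param cfg A [sim_config()] object.
#' @param genes Gene models from [gen_gene_models()].
#' @return A list with elements `variants` (annotation data.frame with
#'   columns `variant_id`, `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `csq_class`, `loftee`, `spliceai`, `revel`, `cadd`, `popmax_af`,
#'   `cohort_ac`), `genotypes` (sparse samples x variants allele-count
#'   matrix) and `phenotype` (data.frame `sample`, `status`).
#' @export
gen_cohort <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.data.frame(genes) || nrow(genes) == 0)
    stop("gen_cohort: genes must be a non-empty data.frame", call. = FALSE)
  .seed_child(cfg, 3L)
  n_samp <- cfg$n_cases + cfg$n_controls
  samples <- sprintf("S%05d", seq_len(n_samp))
  status <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  p0 <- cfg$baseline_carrier_rate
  p1 <- case_rate_for_or(p0, cfg$target_or)

  n_genes <- nrow(genes)
  causal_j <- match(cfg$causal_gene, genes$gene_id)
  prob <- matrix(p0, n_samp, n_genes)
  if (!is.na(causal_j)) prob[status == "case", causal_j] <- p1
  carrier <- matrix(stats::rbinom(n_samp * n_genes, 1L, prob),
                    n_samp, n_genes)

  idx <- which(carrier == 1L, arr.ind = TRUE)
  # spread carriers over variants, <= 2 carriers per variant (AC <= 3 safe)
  ord <- order(idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  within <- stats::ave(seq_len(nrow(idx)), idx[, 2],
                       FUN = function(k) ceiling(seq_along(k) / 2))
  qual_vid <- sprintf("%s_v%03d", genes$gene_id[idx[, 2]], within)

  uq <- !duplicated(qual_vid)
  qual_tab <- data.frame(variant_id = qual_vid[uq],
                         gene_j = idx[uq, 2],
                         stringsAsFactors = FALSE)

  sp <- cfg$score_params
  qual_ann <- .draw_qualifying_annotations(qual_tab$variant_id,
                                           genes[qual_tab$gene_j, ],
                                           sp$af_zero_prob)

  n_noise <- max(2L, round(sp$noise_variant_frac * nrow(qual_ann)))
  noise <- .draw_noise_variants(n_noise, genes, n_samp)

  variants <- rbind(qual_ann, noise$variants)
  gi <- c(match(qual_vid, qual_tab$variant_id),
          nrow(qual_tab) + noise$geno$variant_k)
  geno_i <- c(idx[, 1], noise$geno$sample_i)
  geno_x <- c(rep(1L, nrow(idx)), noise$geno$ac)
  genotypes <- Matrix::sparseMatrix(
    i = geno_i, j = gi, x = geno_x,
    dims = c(n_samp, nrow(variants)),
    dimnames = list(samples, variants$variant_id))
  variants$cohort_ac <- as.integer(Matrix::colSums(genotypes))

  list(variants = variants,
       genotypes = genotypes,
       phenotype = data.frame(sample = samples, status = status,
                              stringsAsFactors = FALSE))
}

# qualifying variants: scores drawn so the ladder weight is always > 0
.draw_qualifying_annotations <- function(vids, gene_rows, af_zero_prob) {
  n <- length(vids)
  mix <- c(lof_canonical = 0.2, noncanonical_splice = 0.15,
           missense = 0.45, inframe_indel = 0.2)
  cls <- sample(names(mix), n, replace = TRUE, prob = mix)
  loftee <- ifelse(cls == "lof_canonical",
                   sample(c("HC", "LC"), n, replace = TRUE,
                          prob = c(0.8, 0.2)), NA)
  spliceai <- ifelse(cls == "noncanonical_splice",
                     stats::runif(n, 0.55, 1), NA)
  revel <- ifelse(cls == "missense", stats::runif(n, 0.45, 1), NA)
  cadd <- ifelse(cls == "inframe_indel", stats::runif(n, 11, 40), NA)
  af <- ifelse(stats::runif(n) < af_zero_prob, 0, stats::runif(n, 0, 1e-4))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(variant_id = vids,
             gene_id = gene_rows$gene_id,
             chrom = gene_rows$chrom,
             pos = as.integer(round(stats::runif(
               n, gene_rows$start + 1, gene_rows$end))),
             ref = ref, alt = unname(alt),
             csq_class = cls, loftee = loftee,
             spliceai = spliceai, revel = revel, cadd = cadd,
             popmax_af = af, cohort_ac = NA_integer_,
             stringsAsFactors = FALSE)
}

# noise variants: violate the AF or AC filter, or carry weight 0;
# carriers drawn uniformly over samples, independent of phenotype
.draw_noise_variants <- function(n, genes, n_samp) {
  kind <- rep_len(c("high_af", "high_ac", "weight0"), n)
  g <- genes[sample(nrow(genes), n, replace = TRUE), ]
  cls <- ifelse(kind == "weight0",
                sample(c("missense", "other"), n, replace = TRUE),
                "missense")
  revel <- ifelse(cls == "missense",
                  ifelse(kind == "weight0", stats::runif(n, 0, 0.15),
                         stats::runif(n, 0.45, 1)), NA)
  af <- ifelse(kind == "high_af", stats::runif(n, 2e-4, 5e-3), 0)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  variants <- data.frame(
    variant_id = sprintf("%s_noise%03d", g$gene_id, seq_len(n)),
    gene_id = g$gene_id, chrom = g$chrom,
    pos = as.integer(round(stats::runif(n, g$start + 1, g$end))),
    ref = ref, alt = unname(alt),
    csq_class = cls, loftee = NA_character_,
    spliceai = NA_real_, revel = revel, cadd = NA_real_,
    popmax_af = af, cohort_ac = NA_integer_,
    stringsAsFactors = FALSE)
  geno <- do.call(rbind, lapply(seq_len(n), function(k) {
    n_carr <- if (kind[k] == "high_ac") sample(4:6, 1) else sample(1:3, 1)
    ac <- rep(1L, n_carr)
    if (kind[k] == "weight0" && n_carr > 1) ac[1] <- 2L  # one hom carrier
    data.frame(variant_k = k,
               sample_i = sample.int(n_samp, n_carr),
               ac = ac)
  }))
  list(variants = variants, geno = geno)
}

#' Generate bilateral calcium fluorescence traces with known event times
#'
#' Left and right channels are baseline-plus-burst series: event counts
#' are Poisson at rates `f_left`/`f_right` (events/s), each event a
#' half-sine pulse of width `pulse_width_s`, with Gaussian noise added.
#' The right channel's event stream is phase-offset by half the mean
#' left inter-event interval, emulating alternating left-right
#' activation. Event times are thinned to a minimum separation of
#' pulse width + 0.6 s so that, without noise, threshold crossing
#' detection recovers them exactly; realised (post-thinning) times are
#' returned as ground truth.
#'
#' @param cfg A [sim_config()] object; see `trace_params`.
#' @return A list with `trace` (data.frame `time`, `left`, `right`),
#'   `events` (list of ground-truth event onset times per channel),
#'   `fps` and `duration_s`.
#' @export
gen_bilateral_traces <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .seed_child(cfg, 4L)
  tp <- cfg$trace_params
  n <- round(tp$fps * tp$duration_s)
  time <- (seq_len(n) - 1) / tp$fps
  min_gap <- tp$pulse_width_s + 0.6

  draw_events <- function(rate, offset) {
    k <- stats::rpois(1, rate * tp$duration_s)
    if (k == 0) return(numeric(0))
    t0 <- sort((stats::runif(k) * tp$duration_s + offset) %% tp$duration_s)
    t0 <- t0[t0 <= tp$duration_s - tp$pulse_width_s]
    keep <- numeric(0)
    last <- -Inf
    for (t in t0) {
      if (t - last >= min_gap) { keep <- c(keep, t); last <- t }
    }
    keep
  }
  offset_r <- if (tp$f_left > 0) 0.5 / tp$f_left else 0
  ev_l <- draw_events(tp$f_left, 0)
  ev_r <- draw_events(tp$f_right, offset_r)

  channel <- function(ev) {
    y <- rep(tp$baseline, n)
    for (t0 in ev) {
      in_pulse <- time >= t0 & time <= t0 + tp$pulse_width_s
      y[in_pulse] <- y[in_pulse] +
        tp$amplitude * sin(pi * (time[in_pulse] - t0) / tp$pulse_width_s)
    }
    pmax(y + stats::rnorm(n, 0, tp$noise_sd), 1e-6)
  }
  list(trace = data.frame(time = time,
                          left = channel(ev_l),
                          right = channel(ev_r)),
       events = list(left = ev_l, right = ev_r),
       fps = tp$fps, duration_s = tp$duration_s)
}

#' Generate a 2-D swim trajectory with a per-step turning bias
#'
#' A correlated random walk: each step turns by
#' `turn_bias_deg_per_step` plus Gaussian noise
#' (`traj_params$turn_noise_sd_deg`), with fixed step length and uniform
#' timestamps. Positive bias turns left (counter-clockwise).
#'
#' @param cfg A [sim_config()] object; see `traj_params`.
#' @param turn_bias_deg_per_step Mean signed heading change per step, in
#'   degrees (left positive).
#' @return A data.frame with columns `time` (s), `x`, `y` (mm);
#'   `n_steps + 1` rows.
#' @export
gen_trajectory <- function(cfg, turn_bias_deg_per_step = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  .seed_child(cfg, 5L)
  tp <- cfg$traj_params
  n <- tp$n_steps
  dturn <- turn_bias_deg_per_step +
    stats::rnorm(n - 1, 0, tp$turn_noise_sd_deg)
  heading <- cumsum(c(0, dturn)) * pi / 180
  data.frame(time = (0:n) * tp$dt_s,
             x = c(0, cumsum(cos(heading) * tp$step_mm)),
             y = c(0, cumsum(sin(heading) * tp$step_mm)))
}
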