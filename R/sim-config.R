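#' Simulation configuration for the synthetic gene-discovery pipeline
#'
#' Builds the single configuration object consumed by all generators
#' ([gen_gene_models()], [gen_gwas_inputs()], [gen_cohort()],
#' [gen_bilateral_traces()], [gen_trajectory()]). Defaults emulate the
#' study design the pipeline targets: 156 candidate genes, a cohort of
#' 411 cases and 3800 controls, a causal gene whose ultra-rare carrier
#' rate is enriched in cases at a planted odds ratio, and 1-minute
#' bilateral calcium recordings sampled at 10 frames per second.
#'
#' Reproducibility contract: identical configuration (including `seed`)
#' yields bit-identical generator output. Each generator draws from its
#' own child stream (a fixed offset of the root seed) so the components
#' are independently reproducible.
#'
#' @param seed Integer root seed (< 2^31 - 100).
#' @param n_genes Number of genes on the toy chromosome.
#' @param n_snps Number of GWAS SNPs to place.
#' @param ld_block_size SNPs per LD block; 1 means no LD at all.
#' @param n_cases,n_controls Cohort arm sizes.
#' @param causal_gene Gene identifier receiving planted carrier
#'   enrichment; defaults to the first generated gene (`"GENE0001"`).
#' @param target_or Planted carrier odds ratio (> 0); 1 is the null.
#' @param baseline_carrier_rate Probability that a control carries at
#'   least one qualifying ultra-rare allele in a given gene.
#' @param variant_class_mix Named proportions over consequence classes
#'   `lof_canonical`, `noncanonical_splice`, `missense`, `inframe_indel`,
#'   `other`; normalised to sum to 1.
#' @param score_params List of per-class score/AF distribution settings;
#'   see Details.
#' @param trace_params List controlling bilateral fluorescence traces:
#'   `fps`, `duration_s`, event rates `f_left`/`f_right` (events/s),
#'   `noise_sd`, `baseline`, `amplitude` (arbitrary fluorescence units)
#'   and `pulse_width_s` (half-sine event width).
#' @param traj_params List controlling swim trajectories: `n_steps`,
#'   `dt_s`, `step_mm`, `turn_noise_sd_deg`.
#'
#' @details `score_params` fields: `af_zero_prob` is the probability a
#'   qualifying variant is absent from gnomAD (popmax AF 0), otherwise
#'   popmax AF is uniform on (0, 1e-4]; `noise_variant_frac` is the
#'   fraction of extra variants planted to deliberately violate the
#'   ultra-rare filter or carry weight 0, exercising the downstream
#'   filtering logic without biasing case-control carrier rates.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5, n_cases = 50, n_controls = 50)
#' cfg$causal_gene
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 156L,
                       n_snps = 60L,
                       ld_block_size = 4L,
                       n_cases = 411L,
                       n_controls = 3800L,
                       causal_gene = NULL,
                       target_or = 4,
                       baseline_carrier_rate = 0.02,
                       variant_class_mix = c(lof_canonical = 0.15,
                                             noncanonical_splice = 0.10,
                                             missense = 0.50,
                                             inframe_indel = 0.15,
                                             other = 0.10),
                       score_params = list(),
                       trace_params = list(),
                       traj_params = list()) {
  score_defaults <- list(af_zero_prob = 0.7, noise_variant_frac = 0.15)
  trace_defaults <- list(fps = 10, duration_s = 60, f_left = 0.5,
                         f_right = 0.5, noise_sd = 2, baseline = 100,
                         amplitude = 100, pulse_width_s = 0.5)
  traj_defaults <- list(n_steps = 200L, dt_s = 0.1, step_mm = 2,
                        turn_noise_sd_deg = 10)
  score_params <- utils::modifyList(score_defaults, score_params)
  trace_params <- utils::modifyList(trace_defaults, trace_params)
  traj_params <- utils::modifyList(traj_defaults, traj_params)

  counts <- c(seed = seed, n_genes = n_genes, n_snps = n_snps,
              ld_block_size = ld_block_size, n_cases = n_cases,
              n_controls = n_controls)
  if (any(!is.finite(counts)) || any(counts != round(counts)))
    stop("sim_config: seed and counts must be whole numbers", call. = FALSE)
  if (any(counts[-1] < 1))
    stop("sim_config: all counts must be positive", call. = FALSE)
  if (seed < 0 || seed > 2^31 - 100)
    stop("sim_config: seed must be in [0, 2^31 - 100]", call. = FALSE)
  if (!is.finite(target_or) || target_or <= 0)
    stop("sim_config: target_or must be > 0", call. = FALSE)
  if (baseline_carrier_rate <= 0 || baseline_carrier_rate >= 1)
    stop("sim_config: baseline_carrier_rate must be in (0, 1)", call. = FALSE)
  required_classes <- c("lof_canonical", "noncanonical_splice", "missense",
                        "inframe_indel", "other")
  if (!all(required_classes %in% names(variant_class_mix)) ||
      any(variant_class_mix < 0) || sum(variant_class_mix) <= 0)
    stop("sim_config: variant_class_mix must name all five consequence ",
         "classes with non-negative proportions", call. = FALSE)
  variant_class_mix <- variant_class_mix[required_classes] /
    sum(variant_class_mix[required_classes])
  # fail early if the planted case rate is not a probability
  p1 <- case_rate_for_or(baseline_carrier_rate, target_or)
  if (!is.finite(p1) || p1 >= 1)
    stop("sim_config: implied case carrier rate is not < 1", call. = FALSE)
  with(trace_params, {
    if (fps <= 0 || duration_s <= 0 || f_left < 0 || f_right < 0 ||
        noise_sd < 0 || pulse_width_s <= 0)
      stop("sim_config: invalid trace_params", call. = FALSE)
  })
  if (traj_params$n_steps < 2 || traj_params$dt_s <= 0 ||
      traj_params$step_mm <= 0)
    stop("sim_config: invalid traj_params", call. = FALSE)

  if (is.null(causal_gene)) causal_gene <- sprintf("GENE%04d", 1L)

  structure(list(seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 n_snps = as.integer(n_snps),
                 ld_block_size = as.integer(ld_block_size),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal_gene = causal_gene,
                 target_or = target_or,
                 baseline_carrier_rate = baseline_carrier_rate,
                 variant_class_mix = variant_class_mix,
                 score_params = score_params,
                 trace_params = trace_params,
                 traj_params = traj_params),
            class = "sim_config")
}

#' Case carrier rate implied by a control rate and a target odds ratio
#'
#' Inverts the odds: with control carrier probability `p0` and odds ratio
#' `or`, the case probability is `q / (1 + q)` where
#' `q = or * p0 / (1 - p0)`.
#'
#' @param p0 Control carrier probability in (0, 1).
#' @param or Odds ratio (> 0).
#' @return Case carrier probability.
#' @examples
#' case_rate_for_or(0.01, 4) # ~0.0388
#' @export
case_rate_for_or <- function(p0, or) {
  stopifnot(p0 > 0, p0 < 1, or > 0)
  q <- or * p0 / (1 - p0)
  q / (1 + q)
}

# Child RNG stream: each generator seeds from the root with a fixed offset
# so components are reproducible independently of call order.
.seed_child <- function(cfg, offset) set.seed(cfg$seed + offset)

.CSQ_CLASSES <- c("lof_canonical", "noncanonical_splice", "missense",
                  "inframe_indel", "other")
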