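test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(seed = 1, n_genes = 2), "sim_config")
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(target_or = -1), "target_or")
  expect_error(sim_config(baseline_carrier_rate = 1.2), "carrier_rate")
  expect_error(sim_config(variant_class_mix = c(missense = 1)), "class")
  expect_error(sim_config(trace_params = list(fps = 0)), "trace_params")
})

test_that("generators are deterministic given the same config", {
  cfg <- sim_config(seed = 42, n_genes = 8, n_snps = 9, ld_block_size = 3,
                    n_cases = 30, n_controls = 60)
  expect_identical(gen_gene_models(cfg), gen_gene_models(cfg))
  genes <- gen_gene_models(cfg)
  expect_identical(gen_gwas_inputs(cfg, genes), gen_gwas_inputs(cfg, genes))
  expect_identical(gen_cohort(cfg, genes), gen_cohort(cfg, genes))
  expect_identical(gen_bilateral_traces(cfg), gen_bilateral_traces(cfg))
  expect_identical(gen_trajectory(cfg, 5), gen_trajectory(cfg, 5))
})

test_that("gene models are non-overlapping with valid spans and TSS", {
  genes <- gen_gene_models(sim_config(seed = 1, n_genes = 50))
  expect_equal(nrow(genes), 50)
  expect_true(all(genes$end > genes$start))
  # brute-force pairwise interval sweep
  for (i in seq_len(nrow(genes) - 1)) {
    for (j in (i + 1):nrow(genes)) {
      expect_true(genes$end[i] <= genes$start[j] ||
                    genes$end[j] <= genes$start[i])
    }
  }
  expect_true(all(genes$tss >= genes$start + 1 & genes$tss <= genes$end))
  g1 <- gen_gene_models(sim_config(seed = 2, n_genes = 1))
  expect_equal(nrow(g1), 1)
  expect_gt(g1$end - g1$start, 0)
})

test_that("GWAS inputs carry planted and decoy mapping evidence", {
  cfg <- sim_config(seed = 5, n_genes = 12, n_snps = 12, ld_block_size = 4)
  genes <- gen_gene_models(cfg)
  gw <- gen_gwas_inputs(cfg, genes)
  expect_true(any(gw$snps$pvalue < 5e-8))
  expect_true(all(gw$ld$r2 >= 0.5 & gw$ld$r2 <= 0.95))
  sig <- gw$snps[gw$snps$pvalue < 5e-8, ]
  indep <- prune_independent(sig, gw$ld)
  mapped <- expand_to_blocks(indep, gw$snps, gw$ld)
  # planted eQTL recovers the causal gene; decoy FDRs stay above threshold
  cand_e <- map_eqtl(mapped, gw$eqtls)
  expect_true(cfg$causal_gene %in% cand_e$gene_id)
  cand_c <- map_chromatin(mapped, gw$interactions, genes)
  expect_true(cfg$causal_gene %in% cand_c$gene_id)
  decoy <- gw$interactions[gw$interactions$fdr > 1e-6, , drop = FALSE]
  expect_equal(nrow(map_chromatin(mapped, decoy, genes)), 0)
})

test_that("block size 1 yields no LD and pruning keeps all significant SNPs", {
  cfg <- sim_config(seed = 6, n_genes = 4, n_snps = 6, ld_block_size = 1)
  genes <- gen_gene_models(cfg)
  gw <- gen_gwas_inputs(cfg, genes)
  expect_equal(nrow(gw$ld), 0)
  sig <- gw$snps[gw$snps$pvalue < 5e-8, ]
  expect_equal(sort(prune_independent(sig, gw$ld)$rsid), sort(sig$rsid))
})

test_that("planted carrier enrichment matches the odds-ratio closed form", {
  # closed-form odds inversion
  expect_equal(case_rate_for_or(0.01, 4), (4 * 0.01 / 0.99) / (1 + 4 * 0.01 / 0.99))
  expect_equal(case_rate_for_or(0.01, 4), 0.0388, tolerance = 1e-2)
  expect_equal(case_rate_for_or(0.3, 1), 0.3)
  # brute-force frequency estimate at n = 1e5 cases
  cfg <- sim_config(seed = 9, n_genes = 1, n_snps = 2, n_cases = 100000,
                    n_controls = 1000, target_or = 4,
                    baseline_carrier_rate = 0.01)
  genes <- gen_gene_models(cfg)
  coh <- gen_cohort(cfg, genes)
  w <- assign_weights(filter_ultra_rare(coh$variants))
  burden <- compute_gene_burden(coh$genotypes, w)
  is_case <- coh$phenotype$status == "case"
  p1_hat <- mean(burden[is_case, 1] > 0)
  p1 <- case_rate_for_or(0.01, 4)
  expect_lt(abs(p1_hat - p1), 3 * sqrt(p1 * (1 - p1) / sum(is_case)))
})

test_that("null target odds ratio gives equal carrier rates in both arms", {
  cfg <- sim_config(seed = 10, n_genes = 1, n_snps = 2, n_cases = 20000,
                    n_controls = 20000, target_or = 1,
                    baseline_carrier_rate = 0.05)
  coh <- gen_cohort(cfg, gen_gene_models(cfg))
  w <- assign_weights(filter_ultra_rare(coh$variants))
  burden <- compute_gene_burden(coh$genotypes, w)
  is_case <- coh$phenotype$status == "case"
  p_case <- mean(burden[is_case, 1] > 0)
  p_ctrl <- mean(burden[!is_case, 1] > 0)
  se <- sqrt(2 * 0.05 * 0.95 / 20000)
  expect_lt(abs(p_case - p_ctrl), 3 * se)
})

test_that("the cohort plants filter-violating variants that get removed", {
  cfg <- sim_config(seed = 11, n_genes = 6, n_snps = 4, n_cases = 150,
                    n_controls = 300)
  coh <- gen_cohort(cfg, gen_gene_models(cfg))
  v <- coh$variants
  expect_true(any(v$popmax_af > 1e-4))       # AF violators present
  expect_true(any(v$cohort_ac > 3))          # AC violators present
  ur <- filter_ultra_rare(v)
  expect_true(all(ur$popmax_af <= 1e-4 & ur$cohort_ac <= 3))
  expect_false(any(v$variant_id[v$popmax_af > 1e-4] %in% ur$variant_id))
  # genotypes are 0/1/2 allele counts
  expect_true(all(coh$genotypes@x %in% c(1, 2)))
})

test_that("bilateral traces have the configured geometry and ground truth", {
  cfg <- sim_config(seed = 12, trace_params = list(duration_s = 60,
                                                   fps = 10, noise_sd = 0))
  tr <- gen_bilateral_traces(cfg)
  expect_equal(nrow(tr$trace), 600)
  expect_true(all(tr$trace$left > 0 & tr$trace$right > 0))
  # noiseless traces: detector recovers ground-truth event counts exactly
  ev <- detect_events(normalize_trace(tr$trace))
  expect_equal(length(ev$left), length(tr$events$left))
  expect_equal(length(ev$right), length(tr$events$right))
})

test_that("asymmetric event rates propagate to the detected log-ratio", {
  cfg <- sim_config(seed = 13, trace_params = list(
    duration_s = 120, f_left = 0.5, f_right = 0.25, noise_sd = 0))
  tr <- gen_bilateral_traces(cfg)
  ev <- detect_events(normalize_trace(tr$trace))
  # detector is exact, so the ratio reflects the realised event counts
  expect_equal(lr_frequency_ratio(ev),
               log(length(tr$events$left) / length(tr$events$right)))
  expect_gt(lr_frequency_ratio(ev), 0)
})

test_that("trajectory bias appears as the mean per-step turning angle", {
  cfg0 <- sim_config(seed = 14, traj_params = list(n_steps = 4,
                                                   turn_noise_sd_deg = 0))
  straight <- gen_trajectory(cfg0, 0)
  st <- turning_statistics(straight)
  expect_equal(st$relative_angle_deg, 0)
  expect_equal(st$mean_abs_angle_deg, 0)

  cfg_sq <- sim_config(seed = 15, traj_params = list(n_steps = 5,
                                                     turn_noise_sd_deg = 0))
  square <- gen_trajectory(cfg_sq, 90)   # four left 90-degree turns
  expect_equal(turning_statistics(square)$relative_angle_deg, 360)

  cfg_b <- sim_config(seed = 16, traj_params = list(n_steps = 1000,
                                                    turn_noise_sd_deg = 1))
  biased <- gen_trajectory(cfg_b, 5)
  st_b <- turning_statistics(biased)
  mean_turn <- st_b$relative_angle_deg / st_b$n_turns
  expect_lt(abs(mean_turn - 5), 3 * 1 / sqrt(st_b$n_turns))
})
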