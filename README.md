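# scoligene

Gene discovery for idiopathic scoliosis, as a reusable and fully tested
R pipeline. The package implements the three analysis stages such a
study chains together, plus the zebrafish left–right coordination
metrics used to validate candidates in vivo, and a synthetic-data
module that generates every input with the statistical structure the
analysis assumes — so the whole workflow runs end to end without
restricted cohort data.

1. **Locus-to-gene mapping.** Genome-wide-significant SNPs
   (p < 5×10⁻⁸) are LD-clumped (independent at r² < 0.6), expanded to
   their LD blocks (r² ≥ 0.6), and mapped to genes three ways:
   positionally (within the gene span or 10 kb of an edge), through
   eQTL records (FDR ≤ 0.05, any tissue), and through chromatin
   interactions (FDR ≤ 10⁻⁶) linking a SNP-bearing region to a gene
   promoter (−250/+500 bp around the TSS, strand-aware).
2. **Ultra-rare variant weighting and burden.** Variants passing the
   ultra-rare gate (gnomAD popmax AF ≤ 0.01% and cohort allele count
   ≤ 3) get a six-level weight *w* ∈ {0, 0.2, 0.4, 0.6, 0.8, 1.0} from
   consequence class and LOFTEE / SpliceAI / REVEL / CADD annotations
   (e.g. LOFTEE-HC canonical LoF → 1.0; missense with
   0.6 < REVEL ≤ 0.8 → 0.6). The burden of gene *g* in individual *i*
   is the **maximum** weight among the qualifying variants *i* carries
   in *g*.
3. **Case–control association.** Per gene, carriers (burden > τ,
   default τ = 0) are collapsed to a 2×2 table tested exactly
   (odds ratio ad/bc with Haldane–Anscombe correction where needed);
   a logistic score test with covariates and Firth/permutation
   fallbacks, and a label-permutation test, are available through the
   same scan interface, with Benjamini–Hochberg q-values.
4. **Coordination metrics.** Bilateral calcium traces are normalised
   to F/F_min per channel, events detected by threshold crossing with
   a refractory period, and asymmetry summarised as
   log(f_left / f_right); swim trajectories yield distance, velocity,
   signed relative turning angle (left positive), mean absolute
   turning angle and angular velocity.

See `vignettes/gene-discovery-methods.Rmd` for the model, the
parameter choices and their rationale, and known limitations.

## Worked example

Simulate a small study with a causal gene planted at carrier odds
ratio 6, map SNPs to candidate genes, and scan the panel:

```r
library(scoligene)

cfg <- sim_config(seed = 7, n_genes = 10, n_snps = 12, ld_block_size = 3,
                  n_cases = 200, n_controls = 400, target_or = 6,
                  baseline_carrier_rate = 0.05)
genes <- gen_gene_models(cfg)
gw <- gen_gwas_inputs(cfg, genes)

sig <- gw$snps[gw$snps$pvalue < 5e-8, ]
indep <- prune_independent(sig, gw$ld)
mapped <- expand_to_blocks(indep, gw$snps, gw$ld)
combine_candidates(map_positional(indep, genes),
                   map_eqtl(mapped, gw$eqtls),
                   map_chromatin(mapped, gw$interactions, genes))
#>    gene_id positional  eqtl chromatin snps_positional snps_eqtl          snps_chromatin
#> 1 GENE0001       TRUE  TRUE      TRUE         rs00001   rs00001 rs00001,rs00002,rs00003
#> 2 GENE0003       TRUE FALSE     FALSE         rs00004                                  

cohort <- gen_cohort(cfg, genes)
weights <- assign_weights(filter_ultra_rare(cohort$variants))
burden <- compute_gene_burden(cohort$genotypes, weights)
head(run_gene_scan(burden, cohort$phenotype,
                   methods = c("fisher", "logistic")), 3)
#>    gene_id n_case_carriers n_control_carriers odds_ratio or_corrected     p_fisher      p_score p_perm         q_bh
#> 1 GENE0001              41                 26  3.7092404        FALSE 8.075648e-07 1.561950e-07     NA 8.075648e-06
#> 2 GENE0003              12                 13  1.9001637        FALSE 1.301128e-01 2.705185e-01     NA 6.505640e-01
#> 3 GENE0006               6                 20  0.5876289        FALSE 2.947944e-01 6.343549e-02     NA 7.988102e-01
```

The planted gene `GENE0001` is recovered by all three mapping
strategies (supported by the lead SNP `rs00001` and its LD block) and
ranks first in the burden scan: 41/200 case carriers vs 26/400 control
carriers, odds ratio 3.7, exact p ≈ 8×10⁻⁷ — the other genes sit at
their null carrier rates.

Coordination metrics on a noiseless synthetic recording (60 s at
10 fps) and a left-biased trajectory:

```r
tr <- gen_bilateral_traces(sim_config(seed = 3,
                                      trace_params = list(noise_sd = 0)))
ev <- detect_events(normalize_trace(tr$trace))
c(f_left = ev$f_left, f_right = ev$f_right,
  log_ratio = lr_frequency_ratio(ev))
#>      f_left     f_right   log_ratio 
#>  0.40000000  0.43333333 -0.08004271

unlist(turning_statistics(gen_trajectory(cfg, 5)))
#>               total_distance_mm              mean_velocity_mm_s 
#>                      400.000000                       20.000000 
#>              relative_angle_deg              mean_abs_angle_deg 
#>                      982.213551                        8.438544 
#> mean_abs_angular_velocity_deg_s                         n_turns 
#>                       84.385439                      199.000000
```

A +5°/step bias over 199 turns accumulates a relative angle of ≈ 982°
(≈ 4.9°/turn, the bias recovered through the turning noise), and the
event detector recovers the exact Poisson event counts, giving a
log-ratio near 0 for symmetric left/right rates.

A thin command-line front end over the same functions is installed at
`inst/cli/scoligene.R` (subcommands `simulate`, `map-genes`, `weight`,
`burden`, `calcium`, `kinematics`).

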