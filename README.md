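# sbhbm — hierarchical Bayesian analysis of social brain morphology

`sbhbm` is an R package for population-level analysis of gray-matter (GM)
volume across the **social brain atlas**: 36 meta-analytically defined
regions organized into four networks (visual-sensory, limbic, intermediate,
higher-associative). It is aimed at population-neuroscience studies that
relate regional brain morphology to social phenotypes (social support
frequency, household size, friendship satisfaction) in large epidemiological
cohorts, where participants are stratified into sex-by-trait groups by
median splits of questionnaire items.

The package covers the full pipeline:

1. **Atlas** — load/validate the 36-region, 4-network atlas
   (`load_atlas()`; a synthetic-coordinate default is packaged).
2. **ROI extraction** — 5 mm FWHM Gaussian smoothing of MNI-space NIfTI GM
   maps, then mean GM volume in 5 mm-diameter spheres around each region
   center (`gaussian_smooth()`, `sphere_mask()`, `extract_cohort()`),
   z-scored per region (`zscore_columns()`).
3. **Cohort preparation** — cleaning of non-answers, median-split
   dichotomization, sex-by-trait group assignment, design assembly
   (`clean_responses()`, `median_split()`, `build_design()`).
4. **Hierarchical model** — the core contribution (below), fit by blocked
   Gibbs sampling (`sample_posterior()`), summarized by posterior means and
   95% highest-posterior-density intervals (`summarize_posterior()`,
   `hpdi()`), with split-R̂/ESS diagnostics
   (`convergence_diagnostics()`).
5. **Synthetic data** — a generator that emulates the target cohort
   (n = 10 129, 52.4% female, age 40–70, BMI 26.7 ± 4.3) with known
   ground-truth coefficients, so every stage is testable without
   access-restricted data (`generate_cohort()`, `generate_volume_images()`,
   `recovery_experiment()`).
6. **Pipeline driver** — `run_pipeline()` chains
   simulate → prepare → fit → report and writes reproducible summary CSVs
   plus a manifest; `render_network_report()` draws per-network interval
   plots.

## The model

For participant *i* in sex-by-trait group *g(i)*, with z-scored age target
*y*, z-scored region volumes *x₁…x₃₆*, and z-scored confounds *c* (body
mass, head-size scaling):

    y_i     ~ Normal( Σⱼ x_ij β_j[g(i)]  +  Σₚ c_ip γ_p ,  σ )
    β_j[g]  ~ Normal( b_net(j)[g], τ_net(j)[g] )        region level
    b_k[g]  ~ Normal( 0, s_g )                          network level
    τ_k[g]  ~ Half-Cauchy(0, 1)
    s_g     ~ Half-Cauchy(0, 1)
    σ       ~ Half-Cauchy(0, 1)
    γ_p     ~ Normal(0, 1)

Region coefficients are partially pooled toward their network-level
coefficient, so estimates borrow strength across the regions of a network —
stabilizing the 144 region-by-group estimates and shrinking noise at weak
sample sizes. All full conditionals are conjugate once each Half-Cauchy
scale is written as an inverse-gamma scale mixture, which is how the Gibbs
sampler draws them; region betas are updated jointly per group from their
multivariate Gaussian conditional.

## Worked example

```r
library(sbhbm)

cohort <- generate_cohort(simulation_config(n = 2000, seed = 1))
design <- build_design(cohort$volumes, cohort$records, "support")
draws  <- sample_posterior(design,
            sampler = sampler_config(n_draws = 1500, burn_in = 500,
                                     chains = 2, seed = 1))
summ   <- summarize_posterior(draws)
head(subset(summ, parameter_type == "region_beta" & network == "limbic"), 4)
```

```
   parameter_type region network             group posterior_mean hpdi_lower hpdi_upper prob
7     region_beta   AM_L  limbic male_less_support        0.04896     0.0161     0.0794 0.95
8     region_beta   AM_R  limbic male_less_support        0.05538     0.0240     0.0869 0.95
9     region_beta   HC_L  limbic male_less_support        0.00536    -0.0256     0.0388 0.95
10    region_beta   HC_R  limbic male_less_support        0.00922    -0.0202     0.0404 0.95
```

Each row is one region-by-group coefficient: the posterior mean association
between that region's z-scored GM volume and z-scored age within the group,
with its 95% HPDI (e.g. the left amygdala in men with less social support:
0.049, HPDI 0.016/0.079 — an interval excluding zero). Because the cohort
is synthetic, the truth is known and recovery can be quantified:

```r
recovery_experiment(simulation_config(n = 2000, seed = 1),
                    sampler_config(n_draws = 1500, burn_in = 500,
                                   chains = 2, seed = 1))
#> sb_recovery: correlation(truth, posterior mean) = 0.984 ; HPDI coverage = 0.938
```

Convergence for the same fit: maximum split-R̂ 1.007 across all 183
parameters, minimum effective sample size 80 (scale hyperparameters mix
slowest; all coefficient ESS are far higher).

The full three-index pipeline, with per-network plots:

```r
run_pipeline(list(simulation = list(n = 2000, seed = 1),
                  sampler = list(n_draws = 1500, burn_in = 500,
                                 chains = 2, seed = 1)),
             out_dir = "run1")
summ <- read.csv("run1/summary_support.csv")
render_network_report(summ, "limbic")$plot
```

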