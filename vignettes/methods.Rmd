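---
title: "Methods: hierarchical Bayesian modeling of social brain morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian modeling of social brain morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sbhbm)
```

## Scientific setting

The package analyzes population variability of gray-matter (GM) volume in
the social brain — 36 regions grouped into four networks that span the
processing hierarchy from visual-sensory (pSTS, FG, MT-V5) through limbic
(amygdala, hippocampus, nucleus accumbens, vmPFC, rACC) and intermediate
(insula, cingulate, IFG, SMA, SMG, cerebellum) to higher-associative
(temporal pole, dmPFC, MTG, pMCC, FP, TPJ, PCC, precuneus) levels. The
scientific question is how regional volume relates to age differently
across sex-by-social-trait strata of a large epidemiological cohort: for
each of three social indices (social support frequency, household size,
friendship satisfaction), participants are split into four groups — male
or female crossed with a dichotomized trait — and one model per index
estimates group-specific region coefficients jointly.

## The probability model

With z-scored age $y$, z-scored region volumes $x_1 \dots x_{36}$,
z-scored confounds $c$ (body mass, head-size scaling) and group labels
$g \in \{0,\dots,3\}$:

$$y_i \sim \mathcal N\!\Big(\textstyle\sum_j x_{ij}\,
\beta_{j[g_i]} + \sum_p c_{ip}\gamma_p,\ \sigma\Big)$$

$$\beta_{j[g]} \sim \mathcal N\!\big(b_{\mathrm{net}(j)[g]},\
\tau_{\mathrm{net}(j)[g]}\big), \qquad
b_{k[g]} \sim \mathcal N(0, s_g)$$

$$\tau_{k[g]},\ s_g,\ \sigma \sim \mathrm{HalfCauchy}(0,1), \qquad
\gamma_p \sim \mathcal N(0,1)$$

Assumptions worth making explicit:

* **Partial pooling.** Region coefficients are exchangeable within a
  (network, group) cell and shrink toward the network coefficient. This is
  the model's answer to estimating 144 coefficients jointly: strength is
  borrowed across the regions of a network instead of correcting 144
  independent tests.
* **Shared residual scale.** A single $\sigma$ serves all groups (the
  likelihood has one noise line); confound coefficients $\gamma$ are also
  shared across groups (they carry no group subscript).
* **Half-Cauchy scales.** Weakly-informative on z-scored data: median 1,
  heavy right tail. Note a consequence: the *prior marginal* of a network
  coefficient, $\mathcal N(0, s)$ with $s \sim \mathrm{HC}(0,1)$, has
  Cauchy-like tails and no finite mean — prior-predictive draw *means* are
  not a stable summary (their medians and the noise-scale quartiles are,
  and the test suite checks those analytic values).
* **Open choices resolved.** The region-level spread is one
  $\tau$ per (network, group), matching the per-group betas with minimal
  structure. The network-coefficient scale $s$ is shared across the four
  networks within a group (`network_scale_mode = "per_group"`); a
  per-(network, group) alternative is selectable in `prior_config()`
  because the sharing granularity is genuinely underdetermined.

## Posterior computation

The model is conditionally conjugate once each Half-Cauchy scale is
represented as an inverse-gamma scale mixture
($x^2 \mid a \sim \mathrm{IG}(1/2, 1/a)$,
$a \sim \mathrm{IG}(1/2, 1/A^2)$ $\Rightarrow$
$x \sim \mathrm{HC}(0, A)$). `sample_posterior()` therefore runs a blocked
Gibbs sampler:

1. region coefficients, **jointly per group** from the exact multivariate
   Gaussian conditional (Cholesky draw) — this is what keeps mixing good
   with correlated volume columns;
2. confound coefficients jointly;
3. network coefficients; 4. region spreads; 5. network scale;
6. noise scale — each from conjugate normal/inverse-gamma conditionals.

The auxiliary variables are internal; the marginal law of the reported
parameters is exactly the model above. The scheme is validated three
independent ways in the tests: a term-by-term log-posterior oracle (to
1e-10), the closed-form Gaussian posterior in a degenerate configuration
(fixed scales, no hierarchy — the conditional *is* the posterior, so draws
are i.i.d. and agreement is within Monte-Carlo error), and truth recovery
on synthetic cohorts.

Protocol defaults follow the reference convention — 5000 draws with the first
4000 discarded — run as 2 chains so split-$\hat R$ is defined
(`sampler_config(chains = 1)` restores the single-chain protocol). Chains
are seeded `seed + chain - 1` and start from dispersed coefficient values;
the seed fully determines the output. Degenerate inputs (empty groups,
zero-variance columns, non-finite values) are rejected up front;
non-finite draws abort with a diagnostic rather than propagate.

With zero observations the same machinery samples the prior; this is used
for prior-recovery checks (noise-scale quartiles at the analytic
Half-Cauchy values $\tan\pi/8,\ 1,\ \tan 3\pi/8$).

**HPDI.** `hpdi()` returns the shortest contiguous window of the sorted
draws containing $\lceil p S \rceil$ samples, earliest window on ties —
checked exactly against an exhaustive window search. For multimodal draw
sets a single interval is a simplification; for the unimodal posteriors
here it is the standard summary.

**Diagnostics.** Split-$\hat R$ and a Geyer initial-monotone-sequence ESS
per scalar parameter; $\hat R > 1.05$ warns. Scale hyperparameters mix
slowest (heavy-tailed targets); coefficient ESS is typically near the
retained draw count.

## ROI extraction choices

* Smoothing before masking, never after; separable Gaussian kernel with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units,
  sampled to $4\sigma$, unit-normalized, zero padding at the grid edge.
* A voxel belongs to a sphere iff its **center** lies within the radius —
  the simplest unambiguous rule; "5 mm diameter" is a diameter
  (radius 2.5 mm), giving 81 voxels on a 1 mm grid.
* Spheres clipped by the grid are an error by default
  (`allow_clipped = TRUE` averages over the in-grid part); an empty mask
  names the offending region.
* z-scoring uses the population SD (divisor $n$) — immaterial at
  $n \approx 10^4$ but fixed so tests are exact. Region columns are
  z-scored independently of the confounds.
* Hemisphere is carried by the atlas label, never inferred from the sign
  of $x$; coordinates move through the NIfTI affine with no implicit
  flips.

The packaged atlas file ships **synthetic approximate coordinates** (the
file name says so): the region list, networks and block structure
(6/8/11/11, regions 1–6 visual-sensory, 7–14 limbic, 15–25 intermediate,
26–36 higher-associative) are exact, but analyses of real data should
supply the deposited coordinates via `load_atlas(path)`. The within-block
ordering of regions is a package convention — only the block membership is
determined by the model structure.

## The synthetic cohort generator

`generate_cohort()` emulates the target cohort's marginals: n = 10 129,
52.4% female, age mapped to 40–70 years (mean 55, SD 7.5), BMI
26.7 ± 4.3, head-size scaling 1 ± 0.1, ordinal social items with explicit
non-answer mass, and region volumes drawn multivariate-normal with
within-network correlation 0.3 / between-network 0.1. True coefficients
are drawn per group (network means $\mathcal N(0, 0.2)$, region offsets
$\mathcal N(0, 0.1)$), and the age target is generated **from the model
itself**, so the cohort carries an exact recovery oracle.

Choices that deserve justification:

* **Item distributions are invented.** The source demographics table
  reports no response frequencies. The shipped distributions are chosen so
  the sample median is stable and each sex-by-trait cell holds 15–35% of
  the cohort — in particular the lives-alone fraction (0.35 among valid
  responses) is higher than typical population values precisely so that
  all four strata remain usable for group-stratified fitting. Everything
  is configurable.
* **Group truth uses the same split rule as the analysis.** The generator
  dichotomizes its own items with the package's `median_split()` /
  `dichotomize_household()` over valid responders, so generator and
  downstream grouping agree for every realized sample, including small
  ones where the sample median can flip.
* **Age scale.** The linear predictor over 36 correlated regions has
  variance well above 1, so the raw target is standardized before mapping
  to years; ground-truth coefficients are recorded on that analysis scale
  (per SD of the age target — the same scale on which such coefficients
  are conventionally reported), with generative-scale values kept
  alongside. Truncation to 40–70 then clips only the ~5% of participants
  beyond 2 SD. This truncation is a realism feature, not part of the
  oracle: it perturbs least-squares identification at the few-percent
  level, which is why the exact noiseless-identifiability tests disable it
  while the default-protocol recovery test runs with it.
* **Fixture images.** `generate_volume_images()` paints each region's
  value in a 21 mm ball. The ball exists only so that 5 mm FWHM smoothing
  leaves the 5 mm extraction sphere essentially constant: 21 mm leaves
  8 mm ≈ 3.8 kernel sigmas of clearance (sphere-mean attenuation
  < 0.1%), whereas a 15 mm ball leaves 2.4σ, where the curvature of the
  ball boundary already costs ~2% of the sphere mean — measurably outside
  a 1% round-trip. Balls must not overlap and must fit the grid with
  ≥ 8 mm margin; violations are errors naming the regions.

What the generator does **not** emulate: real cortical anatomy or partial
volume structure in images; non-Gaussian volume distributions;
item-nonresponse that correlates with phenotype; socioeconomic covariates;
any dependence of volumes on the social items themselves beyond the
modeled age association. Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the model's assumptions —
not that the model is adequate for any particular real dataset.

## Cohort preparation conventions

* Non-answers (`do_not_know`, `prefer_not_to_answer`, empty) and missing
  sex/age/confounds remove a participant for that index only; removal
  counts are logged.
* Median split: strictly-greater-than-median is "high"; ties go low
  (deterministic and auditable — the tie mass is attached to the result).
  With ties sent low the group imbalance is bounded by twice the tie mass;
  with an interpolated median the split is exactly balanced.
* Household size uses the explicit lives-alone (= 1) vs lives-with-others
  (≥ 2) rule, matching the trait's semantics, rather than a literal median
  split; `household_rule = "median"` restores the literal split.
* Ordinal codings are oriented so larger = more support / happier.
* Rows are canonicalized by participant id, so shuffled inputs produce
  identical designs; the three indices are fit as three independent
  models.

## Problem sizes and runtime

The test suite runs the full recovery protocol at n = 2000 with
2 × 1500 draws (500 burn-in) — enough for stable posterior means of 144
coefficients while keeping the whole suite under a minute on one core —
and the shrinkage comparison at n = 100, where per-group designs are
underdetermined (≈25 observations, 38 predictors) and the non-hierarchical
comparator is therefore the minimum-norm least-squares solution. The
end-to-end determinism check reruns the three-index pipeline at n = 1000
and compares output files byte for byte.

## Known limitations

* The sampler is single-threaded R; at the full cohort size with the full
  5000-draw protocol a fit takes a few minutes per index.
* The HPDI is contiguous-interval only.
* Coefficients are reported exactly as what they are — associations
  between z-scored region volume and z-scored age within group — and no
  causal or directional "volume effect" reading is implied.
* The recovery oracle's coverage is evaluated against truths defined on
  the generator's analysis scale; the age-range truncation introduces a
  small (few-percent) scale distortion that the interval calibration test
  absorbs within its stated band.
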