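test_that("cohort generation is bit-reproducible and matches target demographics", {
  cfg <- simulation_config(n = 3000L, seed = 5L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$volumes$raw, c2$volumes$raw)
  expect_identical(c1$truth$region_betas, c2$truth$region_betas)

  rec <- c1$records
  expect_equal(mean(rec$sex == "female"), 0.524, tolerance = 0.03)
  expect_true(all(rec$age >= 40 & rec$age <= 70))
  expect_equal(mean(rec$body_mass), 26.7, tolerance = 0.3)
  expect_equal(sd(rec$body_mass), 4.3, tolerance = 0.3)
  expect_equal(mean(rec$head_size_scaling), 1, tolerance = 0.02)
})

test_that("volume correlations reproduce the configured network-block structure", {
  cfg <- simulation_config(seed = 2L)  # default n = 10129
  cohort <- generate_cohort(cfg)
  z <- cohort$volumes$zscored
  cors <- cor(z)
  atlas <- load_atlas("default")
  net <- network_index(atlas)
  same <- outer(net, net, "==") & !diag(36)
  expect_equal(mean(cors[same]), 0.3, tolerance = 0.05)
  expect_equal(mean(cors[!same & !diag(36)]), 0.1, tolerance = 0.05)
})

test_that("noiseless large-sample least squares identifies the true coefficients", {
  # age-range truncation disabled and no non-answer mass (so no rows are
  # dropped and the design's z-scoring coincides with the generator's):
  # the target is then an exact affine image of the linear predictor and
  # least squares must recover the stored truth to numerical precision
  cfg <- simulation_config(n = 20000L, noise_sd = 0, seed = 6L,
                           age_range = c(-1000, 1000),
                           support_probs = c(
                             "1" = 0.06, "2" = 0.05, "3" = 0.07,
                             "4" = 0.12, "5" = 0.22, "6" = 0.18,
                             "7" = 0.30))
  cohort <- generate_cohort(cfg)
  d <- build_design(cohort$volumes, cohort$records, "support",
                    quiet = TRUE)
  truth <- cohort$truth$region_betas
  keep <- match(d$participant_id, cohort$records$participant_id)
  expect_equal(d$g, cohort$truth$group[keep])  # grouping agrees
  for (gr in 0:3) {
    ii <- which(d$g == gr)
    # intercept soaks up the finite-sample group mean of the predictors
    Z <- cbind(1, d$X[ii, ], d$C[ii, ])
    est <- qr.solve(Z, d$y[ii])[2:37]
    expect_lt(max(abs(est - truth[, gr + 1])), 1e-6)
  }

  # with the default 40-70 truncation the ~5% of clipped ages distort the
  # coefficients only mildly
  cfg2 <- simulation_config(n = 20000L, noise_sd = 0, seed = 6L)
  cohort2 <- generate_cohort(cfg2)
  d2 <- build_design(cohort2$volumes, cohort2$records, "support",
                     quiet = TRUE)
  err <- sapply(0:3, function(gr) {
    ii <- which(d2$g == gr)
    Z <- cbind(1, d2$X[ii, ], d2$C[ii, ])
    max(abs(qr.solve(Z, d2$y[ii])[2:37] -
              cohort2$truth$region_betas[, gr + 1]))
  })
  expect_lt(max(err), 0.05)
})

test_that("ground-truth state has higher generative density than a zeroed state", {
  atlas <- load_atlas("default")
  cfg <- simulation_config(n = 600L, seed = 12L)
  cohort <- generate_cohort(cfg, atlas)
  d <- build_design(cohort$volumes, cohort$records, "support",
                    quiet = TRUE)
  tr <- cohort$truth
  K <- 4L
  st_true <- parameter_state(tr$region_betas, tr$network_betas,
                             matrix(0.1, K, 4L), rep(0.2, 4L),
                             tr$confound_betas, tr$noise_sd,
                             network = d$network)
  st_zero <- parameter_state(matrix(0, 36, 4), matrix(0, K, 4),
                             matrix(0.1, K, 4L), rep(0.2, 4L),
                             c(0, 0), tr$noise_sd, network = d$network)
  lp_true <- log_posterior(st_true, d)
  lp_zero <- log_posterior(st_zero, d)
  expect_true(is.finite(lp_true))
  expect_gt(lp_true, lp_zero)
})

test_that("painted images refuse overlapping regions", {
  tab <- data.frame(region_id = 1:2, name = c("A", "B"),
                    hemisphere = c("L", "R"),
                    network = c("limbic", "limbic"),
                    x = c(0, 10), y = c(0, 0), z = c(0, 0))
  atlas <- validate_atlas(tab, strict = FALSE)
  cohort <- generate_cohort(simulation_config(n = 8L, seed = 3L), atlas)
  expect_error(generate_volume_images(cohort, atlas, tempfile()),
               "overlap")
})

test_that("cross-diameter extractions agree on smooth fixture images", {
  atlas <- lattice_atlas(6L)
  cohort <- generate_cohort(simulation_config(n = 8L, seed = 14L), atlas)
  dir <- withr::local_tempdir()
  paths <- generate_volume_images(cohort, atlas, dir)
  ex <- lapply(c(2.5, 5, 7.5), function(diam) {
    t(sapply(paths, function(p) {
      extract_region_means(read_volume(p), atlas, diameter_mm = diam,
                           smooth_fwhm_mm = 5)
    }))
  })
  for (r in seq_len(nrow(atlas))) {
    expect_gt(cor(ex[[1]][, r], ex[[2]][, r]), 0.95)
    expect_gt(cor(ex[[2]][, r], ex[[3]][, r]), 0.95)
  }
})

test_that("recovery experiment recovers truth and is seed-stable", {
  rec <- recovery_experiment(
    simulation_config(n = 800L, seed = 18L),
    sampler_config(n_draws = 800L, burn_in = 300L, chains = 2L,
                   seed = 18L))
  expect_gt(rec$correlation, 0.9)
  expect_gte(rec$coverage, 0.85)
  rec2 <- recovery_experiment(
    simulation_config(n = 800L, seed = 18L),
    sampler_config(n_draws = 800L, burn_in = 300L, chains = 2L,
                   seed = 18L))
  expect_identical(rec$table, rec2$table)
})

test_that("recovery improves monotonically as noise vanishes", {
  # truncation disabled so the noise -> 0 limit is exactly corr -> 1
  cors <- vapply(c(1.6, 0.8, 0.1), function(ns) {
    recovery_experiment(
      simulation_config(n = 800L, noise_sd = ns, seed = 20L,
                        age_range = c(-1000, 1000)),
      sampler_config(n_draws = 600L, burn_in = 200L, chains = 1L,
                     seed = 20L))$correlation
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.995)
})
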