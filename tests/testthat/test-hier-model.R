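test_that("log-likelihood matches closed forms at reference points", {
  J <- 2L
  d <- new_design(matrix(0, 3, J), rep(0, 3), matrix(numeric(0), 3, 0),
                  rep(0L, 3), network = 1:2, n_groups = 1L)
  st <- parameter_state(matrix(0, J, 1), matrix(0, 2, 1),
                        matrix(1, 2, 1), 1, numeric(0), 1, network = 1:2)
  expect_equal(log_likelihood(st, d), -1.5 * log(2 * pi))

  d1 <- new_design(matrix(1, 1, J), 0.7, matrix(numeric(0), 1, 0), 0L,
                   network = 1:2, n_groups = 1L)
  # mu = 0.7 via betas (0.7, 0): exact fit, unit noise
  st1 <- parameter_state(matrix(c(0.7, 0), J, 1), matrix(0, 2, 1),
                         matrix(1, 2, 1), 1, numeric(0), 1, network = 1:2)
  expect_equal(log_likelihood(st1, d1), -0.5 * log(2 * pi))
  st_bad <- st1; st_bad$noise_scale <- -1
  expect_error(log_likelihood(st_bad, d1), "noise")
})

test_that("Half-Cauchy log-density has the stated closed form", {
  expect_equal(dhalfcauchy_log(1, 1), -log(pi))
  x <- c(0, 0.3, 2, 10)
  expect_equal(dhalfcauchy_log(x, 2),
               log(2 / (pi * 2 * (1 + (x / 2)^2))))
  expect_identical(dhalfcauchy_log(-1, 1), -Inf)
})

test_that("log-prior and log-posterior match the term-by-term oracle", {
  priors <- prior_config()
  for (seed in 1:5) {
    J <- sample(2:6, 1)
    d <- random_design(n = 10L, J = J, G = 2L, P = 2L, seed = seed)
    st <- random_state(J = J, G = 2L, K = 2L, P = 2L, seed = seed + 100L,
                       network = d$network)
    expect_equal(log_posterior(st, d, priors),
                 log_posterior_oracle(st, d, priors), tolerance = 1e-10)
    expect_equal(log_posterior(st, d, priors),
                 log_likelihood(st, d) + log_prior(st, priors))
  }
})

test_that("adding a perfectly-fit unit-noise observation shifts the log-posterior by -log(2*pi)/2", {
  J <- 2L
  st <- parameter_state(matrix(0, J, 1), matrix(0, 2, 1),
                        matrix(1, 2, 1), 1, numeric(0), 1, network = 1:2)
  d_n <- new_design(matrix(rnorm(6), 3, J), rnorm(3),
                    matrix(numeric(0), 3, 0), rep(0L, 3),
                    network = 1:2, n_groups = 1L)
  d_n1 <- new_design(rbind(d_n$X, 0), c(d_n$y, 0),
                     matrix(numeric(0), 4, 0), rep(0L, 4),
                     network = 1:2, n_groups = 1L)
  expect_equal(log_posterior(st, d_n1) - log_posterior(st, d_n),
               -0.5 * log(2 * pi))
})

test_that("hpdi matches its definition on reference cases", {
  expect_equal(hpdi(c(0.5, 0.5, 0.5)), c(0.5, 0.5))
  expect_equal(hpdi(1:100, 0.95), c(1, 95))
  # dense symmetric grid of normal quantiles -> central interval
  q <- qnorm(seq(1e-4, 1 - 1e-4, length.out = 10001))
  h <- hpdi(q, 0.95)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.01)
  expect_error(hpdi(1), "at least 2")
  expect_error(hpdi(1:10, 1.2), "between 0 and 1")
})

test_that("hpdi equals the exhaustive shortest-window oracle on random vectors", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(2:200, 1)
    x <- switch(sample(3, 1), rnorm(n), rexp(n),
                sample(round(rnorm(n), 1), n, replace = TRUE))
    prob <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_identical(hpdi(x, prob), hpdi_oracle(x, prob))
  }
})

test_that("sampling is a deterministic function of the seed", {
  d <- random_design(n = 40L, J = 4L, G = 2L, P = 1L, seed = 17L,
                     networks = rep_len(1:2, 4L))
  smp <- sampler_config(n_draws = 120L, burn_in = 40L, chains = 2L,
                        seed = 99L)
  dr1 <- sample_posterior(d, sampler = smp)
  dr2 <- sample_posterior(d, sampler = smp)
  expect_identical(dr1$draws, dr2$draws)
  dr3 <- sample_posterior(d, sampler = sampler_config(
    n_draws = 120L, burn_in = 40L, chains = 2L, seed = 100L))
  expect_false(identical(dr1$draws, dr3$draws))
})

test_that("degenerate non-hierarchical sampler reproduces the conjugate Gaussian posterior", {
  set.seed(42)
  n <- 80L; J <- 6L
  X <- matrix(rnorm(n * J), n, J)
  y <- rnorm(n)
  d <- new_design(X, y, matrix(numeric(0), n, 0), rep(0L, n),
                  network = rep_len(1:4, J), n_groups = 1L)
  dr <- sample_posterior(d, sampler = sampler_config(
    n_draws = 2000L, burn_in = 500L, chains = 2L, seed = 2L),
    hierarchy = FALSE, fix_noise_scale = 1, fix_region_spread = 1)
  analytic <- as.vector(solve(crossprod(X) + diag(J), crossprod(X, y)))
  cols <- startsWith(colnames(dr$draws), "beta[")
  est <- unname(colMeans(dr$draws[, cols]))
  mc_se <- apply(dr$draws[, cols], 2, sd) / sqrt(nrow(dr$draws))
  expect_true(all(abs(est - analytic) < 3 * mc_se))
})

test_that("prior-only sampling recovers analytic Half-Cauchy quartiles of the noise scale", {
  dr <- sample_posterior(empty_design(), sampler = sampler_config(
    n_draws = 3000L, burn_in = 1000L, chains = 2L, seed = 11L))
  sigma <- dr$draws[, "sigma"]
  # Half-Cauchy(0,1) quartiles: tan(pi/8), 1, tan(3*pi/8)
  q <- unname(quantile(sigma, c(0.25, 0.5, 0.75)))
  expect_equal(q[2], 1, tolerance = 0.1)
  expect_equal(q[1], tan(pi / 8), tolerance = 0.15)
  expect_equal(q[3], tan(3 * pi / 8), tolerance = 0.2)
  # network betas are symmetric about zero (heavy-tailed: medians, not means)
  nb <- dr$draws[, startsWith(colnames(dr$draws), "netbeta")]
  expect_true(all(abs(apply(nb, 2, median)) < 1))
})

test_that("summaries agree with a streaming-mean oracle and the bookkeeping row count", {
  d <- random_design(n = 60L, J = 4L, G = 4L, P = 2L, seed = 3L,
                     networks = rep_len(1:2, 4L))
  dr <- sample_posterior(d, sampler = sampler_config(
    n_draws = 150L, burn_in = 50L, chains = 2L, seed = 8L))
  summ <- summarize_posterior(dr)
  # 4 regions x 4 groups + 2 networks x 4 groups + 2 confounds + 1 noise
  expect_equal(nrow(summ), 4L * 4L + 2L * 4L + 2L + 1L)
  expect_true(all(summ$hpdi_lower <= summ$hpdi_upper))

  streaming_mean <- function(x) {
    m <- 0
    for (i in seq_along(x)) m <- m + (x[i] - m) / i
    m
  }
  sel <- summ$parameter_type == "region_beta"
  names <- dr$param_info$name[dr$param_info$type == "region_beta"]
  oracle <- vapply(names, function(nm) streaming_mean(dr$draws[, nm]),
                   numeric(1))
  expect_equal(unname(summ$posterior_mean[sel]), unname(oracle),
               tolerance = 1e-12)
})

test_that("constant draws summarize to degenerate mean and interval", {
  d <- random_design(n = 30L, J = 2L, G = 2L, P = 1L, seed = 5L)
  dr <- sample_posterior(d, sampler = sampler_config(
    n_draws = 60L, burn_in = 20L, chains = 1L, seed = 1L))
  dr$draws[, 1] <- 0.25
  summ <- summarize_posterior(dr)
  expect_equal(summ$posterior_mean[1], 0.25)
  expect_equal(summ$hpdi_lower[1], 0.25)
  expect_equal(summ$hpdi_upper[1], 0.25)
})

test_that("convergence diagnostics separate well-mixed from disjoint chains", {
  fake_draws <- function(mat, chains) {
    n_retain <- nrow(mat) / chains
    structure(list(draws = mat, chain = rep(seq_len(chains),
                                            each = n_retain),
                   param_info = data.frame(name = colnames(mat),
                                           type = "region_beta",
                                           region = colnames(mat),
                                           network = NA, group = 0L),
                   n_draws = n_retain, burn_in = 0L, chains = chains,
                   seed = 0L, n_obs = 0L, social_index = "support",
                   group_labels_n = 1L, hierarchy = TRUE),
              class = "sb_draws")
  }
  set.seed(44)
  S <- 1000L
  white <- matrix(rnorm(2 * S), ncol = 1,
                  dimnames = list(NULL, "p1"))
  diag1 <- convergence_diagnostics(fake_draws(white, 2L), warn = FALSE)
  expect_lt(abs(diag1$rhat - 1), 0.01)
  expect_gt(diag1$ess, 0.8 * 2 * S)
  expect_lt(diag1$ess, 1.2 * 2 * S)

  shifted <- matrix(c(rnorm(S), rnorm(S) + 10), ncol = 1,
                    dimnames = list(NULL, "p1"))
  expect_warning(diag2 <- convergence_diagnostics(fake_draws(shifted, 2L)),
                 "R-hat")
  expect_gt(diag2$rhat, 1.05)
})

test_that("sampler rejects invalid configurations", {
  expect_error(sampler_config(n_draws = 100L, burn_in = 100L), "burn_in")
  expect_error(prior_config(noise_scale_prior = -1), "positive")
  d <- random_design(n = 20L, J = 2L, G = 2L, P = 1L, seed = 1L)
  expect_error(new_design(d$X, d$y, d$C, rep(0L, 20L), network = 1:2,
                          n_groups = 2L), "empty group")
})
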