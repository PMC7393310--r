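#' Prior configuration for the hierarchical model
#'
#' The generative model regresses z-scored age on the z-scored region
#' volumes, with one coefficient per region and participant group. Region
#' coefficients are partially pooled toward a network-level coefficient:
#'
#' \preformatted{
#'   y_i            ~ Normal(sum_j X_ij beta[j, g_i] + sum_p C_ip gamma_p,
#'                           sigma)
#'   beta[j, g]     ~ Normal(b[net(j), g], tau[net(j), g])
#'   b[k, g]        ~ Normal(0, s_g)
#'   tau[k, g]      ~ Half-Cauchy(0, region_spread_prior)
#'   s_g            ~ Half-Cauchy(0, network_beta_scale_prior)
#'   sigma          ~ Half-Cauchy(0, noise_scale_prior)
#'   gamma_p        ~ Normal(0, confound_beta_prior_sd)
#' }
#'
#' The network-beta scale `s` is shared across the four networks within
#' each group by default (`network_scale_mode = "per_group"`); set
#' `"per_network_group"` for one scale per network and group.
#'
#' @param network_beta_scale_prior Half-Cauchy scale of the network-beta
#'   hyperprior (default 1).
#' @param region_spread_prior Half-Cauchy scale of the region-around-network
#'   spread prior (default 1).
#' @param noise_scale_prior Half-Cauchy scale of the residual-noise prior
#'   (default 1).
#' @param confound_beta_prior_sd Normal prior SD of confound coefficients
#'   (default 1; weakly informative on z-scored covariates).
#' @param network_scale_mode `"per_group"` (default) or
#'   `"per_network_group"`.
#' @return List of class `sb_priors`.
#' @export
prior_config <- function(network_beta_scale_prior = 1,
                         region_spread_prior = 1,
                         noise_scale_prior = 1,
                         confound_beta_prior_sd = 1,
                         network_scale_mode = c("per_group",
                                                "per_network_group")) {
  scales <- c(network_beta_scale_prior, region_spread_prior,
              noise_scale_prior, confound_beta_prior_sd)
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop("all prior scales must be strictly positive", call. = FALSE)
  }
  structure(list(network_beta_scale_prior = network_beta_scale_prior,
                 region_spread_prior = region_spread_prior,
                 noise_scale_prior = noise_scale_prior,
                 confound_beta_prior_sd = confound_beta_prior_sd,
                 network_scale_mode = match.arg(network_scale_mode)),
            class = "sb_priors")
}

#' Half-Cauchy log-density
#'
#' Density `2 / (pi * s * (1 + (x/s)^2))` on `x >= 0`; the median equals
#' the scale `s`.
#'
#' @param x Non-negative quantiles.
#' @param scale Positive scale.
#' @return Log-density values (`-Inf` for negative `x`).
#' @export
dhalfcauchy_log <- function(x, scale = 1) {
  stopifnot(scale > 0)
  out <- log(2) - log(pi) - log(scale) - log1p((x / scale)^2)
  out[x < 0] <- -Inf
  out
}

#' Construct one joint setting of the model unknowns
#'
#' @param region_betas J x G matrix of region coefficients.
#' @param network_betas K x G matrix of network coefficients.
#' @param network_spreads K x G matrix of positive region-around-network
#'   spreads.
#' @param network_scale Positive scale(s) of the network-beta prior: a
#'   length-G vector (per-group mode) or a K x G matrix.
#' @param confound_betas Length-P confound coefficients (may be empty).
#' @param noise_scale Positive residual noise SD.
#' @param network Integer vector of length J mapping regions to networks
#'   (1..K).
#' @return List of class `sb_state`.
#' @export
parameter_state <- function(region_betas, network_betas, network_spreads,
                            network_scale, confound_betas, noise_scale,
                            network) {
  region_betas <- as.matrix(region_betas)
  network_betas <- as.matrix(network_betas)
  network_spreads <- as.matrix(network_spreads)
  stopifnot(length(network) == nrow(region_betas),
            ncol(region_betas) == ncol(network_betas),
            all(dim(network_spreads) == dim(network_betas)))
  if (any(network_spreads <= 0) || noise_scale <= 0 ||
      any(network_scale <= 0)) {
    stop("spreads, network scale and noise scale must be strictly positive",
         call. = FALSE)
  }
  structure(list(region_betas = region_betas,
                 network_betas = network_betas,
                 network_spreads = network_spreads,
                 network_scale = network_scale,
                 confound_betas = as.numeric(confound_betas),
                 noise_scale = noise_scale,
                 network = as.integer(network)),
            class = "sb_state")
}

#' Log-likelihood of a parameter state
#'
#' `sum_i log Normal(y_i | mu_i, noise_scale)` with
#' `mu_i = sum_j X_ij * region_betas[j, g_i] + sum_p C_ip *
#' confound_betas[p]`.
#'
#' @param state `sb_state` object.
#' @param design `sb_design` object.
#' @return Scalar log-likelihood (0 for an empty design).
#' @export
log_likelihood <- function(state, design) {
  stopifnot(inherits(state, "sb_state"), inherits(design, "sb_design"))
  if (state$noise_scale <= 0) stop("non-positive noise scale",
                                   call. = FALSE)
  n <- nrow(design$X)
  if (n == 0L) return(0)
  if (anyNA(design$X) || anyNA(design$y)) {
    stop("NaN in design inputs", call. = FALSE)
  }
  mu <- rowSums(design$X * t(state$region_betas)[design$g + 1L, ,
                                                 drop = FALSE])
  if (length(state$confound_betas) > 0) {
    mu <- mu + as.vector(design$C %*% state$confound_betas)
  }
  sum(stats::dnorm(design$y, mu, state$noise_scale, log = TRUE))
}

#' Log-prior of a parameter state
#'
#' Sum of Half-Cauchy terms for the noise scale, region spreads and
#' network-beta scale(s), Normal terms for network betas around zero,
#' region betas around their network beta, and confound betas around zero.
#'
#' @param state `sb_state` object.
#' @param priors `sb_priors` configuration.
#' @return Scalar log-prior density.
#' @export
log_prior <- function(state, priors = prior_config()) {
  stopifnot(inherits(state, "sb_state"), inherits(priors, "sb_priors"))
  K <- nrow(state$network_betas)
  G <- ncol(state$network_betas)
  if (any(state$network_spreads <= 0) || state$noise_scale <= 0 ||
      any(state$network_scale <= 0)) {
    stop("non-positive scale in state", call. = FALSE)
  }
  lp <- dhalfcauchy_log(state$noise_scale, priors$noise_scale_prior)
  lp <- lp + sum(dhalfcauchy_log(state$network_spreads,
                                 priors$region_spread_prior))
  lp <- lp + sum(dhalfcauchy_log(as.numeric(state$network_scale),
                                 priors$network_beta_scale_prior))
  scale_mat <- if (is.matrix(state$network_scale)) {
    state$network_scale
  } else {
    matrix(rep(state$network_scale, each = K), K, G)
  }
  lp <- lp + sum(stats::dnorm(state$network_betas, 0, scale_mat,
                              log = TRUE))
  parent_mean <- state$network_betas[state$network, , drop = FALSE]
  parent_sd <- state$network_spreads[state$network, , drop = FALSE]
  lp <- lp + sum(stats::dnorm(state$region_betas, parent_mean, parent_sd,
                              log = TRUE))
  if (length(state$confound_betas) > 0) {
    lp <- lp + sum(stats::dnorm(state$confound_betas, 0,
                                priors$confound_beta_prior_sd, log = TRUE))
  }
  lp
}

#' Log-posterior (unnormalized): log-likelihood plus log-prior
#'
#' @inheritParams log_likelihood
#' @param priors `sb_priors` configuration.
#' @return Scalar.
#' @export
log_posterior <- function(state, design, priors = prior_config()) {
  log_likelihood(state, design) + log_prior(state, priors)
}

#' MCMC sampler configuration
#'
#' Defaults follow the reference protocol scaled to two chains: 5000 draws
#' per chain of which the first 4000 are discarded as burn-in.
#'
#' @param n_draws Total draws per chain (default 5000).
#' @param burn_in Initial draws discarded per chain (default 4000).
#' @param chains Number of chains (default 2; use 1 for the single-chain
#'   protocol).
#' @param seed Integer RNG seed; fully determines the output.
#' @return List of class `sb_sampler_config`.
#' @export
sampler_config <- function(n_draws = 5000L, burn_in = 4000L, chains = 2L,
                           seed = 1L) {
  stopifnot(n_draws >= 1, burn_in >= 0, burn_in < n_draws, chains >= 1)
  structure(list(n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in),
                 chains = as.integer(chains), seed = as.integer(seed)),
            class = "sb_sampler_config")
}

rinvgamma1 <- function(shape, rate) {
  # inverse-gamma with density prop. to x^-(shape+1) exp(-rate/x)
  rate / stats::rgamma(1L, shape = shape, rate = 1)
}

#' Draw from the posterior by blocked Gibbs sampling
#'
#' All full conditionals of the model are conjugate once each Half-Cauchy
#' scale is represented as a scale mixture of inverse-gamma distributions
#' (`x^2 | a ~ InvGamma(1/2, 1/a)`, `a ~ InvGamma(1/2, 1/scale^2)` implies
#' `x ~ Half-Cauchy(0, scale)`). Region betas are updated jointly per group
#' from their multivariate Gaussian conditional (Cholesky draw), which
#' gives good mixing even with correlated volume columns. The auxiliary
#' variables are internal; the marginal law of the reported parameters is
#' exactly the model of [prior_config()].
#'
#' With an empty design (zero rows) the same scheme samples the prior.
#'
#' @param design `sb_design` object (4 non-empty groups, or 0 rows for
#'   prior-only sampling).
#' @param priors `sb_priors` configuration.
#' @param sampler `sb_sampler_config`.
#' @param hierarchy If `FALSE`, the network level is removed: region betas
#'   get independent `Normal(0, spread)` priors (used for closed-form
#'   validation).
#' @param fix_noise_scale Optional positive value freezing the noise SD.
#' @param fix_region_spread Optional positive value freezing all region
#'   spreads.
#' @return Object of class `sb_draws`: retained draws (matrix of
#'   `chains * (n_draws - burn_in)` rows), chain ids, parameter metadata
#'   and sampler settings.
#' @export
sample_posterior <- function(design, priors = prior_config(),
                             sampler = sampler_config(),
                             hierarchy = TRUE,
                             fix_noise_scale = NULL,
                             fix_region_spread = NULL) {
  stopifnot(inherits(design, "sb_design"),
            inherits(priors, "sb_priors"),
            inherits(sampler, "sb_sampler_config"))
  X <- design$X; y <- design$y; C <- design$C; g <- design$g
  n <- nrow(X); J <- ncol(X); P <- ncol(C); G <- design$n_groups
  net <- design$network
  K <- max(net)
  region_names <- colnames(X)
  if (is.null(region_names)) region_names <- paste0("region", seq_len(J))
  confound_names <- colnames(C)
  if (P > 0 && is.null(confound_names)) {
    confound_names <- paste0("confound", seq_len(P))
  }
  per_net_scale <- priors$network_scale_mode == "per_network_group"

  idx_g <- lapply(seq_len(G) - 1L, function(gr) which(g == gr))
  XtX <- lapply(idx_g, function(ii) {
    crossprod(X[ii, , drop = FALSE])
  })
  CtC <- if (P > 0) crossprod(C) else NULL
  block_sizes <- tabulate(net, nbins = K)

  n_retain <- sampler$n_draws - sampler$burn_in
  par_names <- c(
    as.vector(outer(region_names, seq_len(G) - 1L,
                    function(r, gg) sprintf("beta[%s,g%d]", r, gg))),
    as.vector(outer(SB_NETWORKS[seq_len(K)], seq_len(G) - 1L,
                    function(k, gg) sprintf("netbeta[%s,g%d]", k, gg))),
    as.vector(outer(SB_NETWORKS[seq_len(K)], seq_len(G) - 1L,
                    function(k, gg) sprintf("netspread[%s,g%d]", k, gg))),
    if (per_net_scale) {
      as.vector(outer(SB_NETWORKS[seq_len(K)], seq_len(G) - 1L,
                      function(k, gg) sprintf("netscale[%s,g%d]", k, gg)))
    } else {
      sprintf("netscale[g%d]", seq_len(G) - 1L)
    },
    if (P > 0) sprintf("gamma[%s]", confound_names),
    "sigma")
  n_par <- length(par_names)
  draws <- matrix(NA_real_, n_retain * sampler$chains, n_par,
                  dimnames = list(NULL, par_names))
  chain_id <- rep(seq_len(sampler$chains), each = n_retain)

  A_tau2 <- priors$region_spread_prior^2
  A_s2 <- priors$network_beta_scale_prior^2
  A_sig2 <- priors$noise_scale_prior^2
  c_prec0 <- 1 / priors$confound_beta_prior_sd^2

  for (ch in seq_len(sampler$chains)) {
    set.seed(sampler$seed + ch - 1L)
    beta <- matrix(stats::rnorm(J * G, 0, 0.1), J, G)
    b <- matrix(0, K, G)
    tau2 <- matrix(1, K, G)
    a_tau <- matrix(1, K, G)
    s2 <- if (per_net_scale) matrix(1, K, G) else rep(1, G)
    a_s <- s2
    gamma <- rep(0, P)
    sig2 <- 1
    a_sig <- 1
    if (!is.null(fix_noise_scale)) {
      stopifnot(fix_noise_scale > 0)
      sig2 <- fix_noise_scale^2
    }
    if (!is.null(fix_region_spread)) {
      stopifnot(fix_region_spread > 0)
      tau2 <- matrix(fix_region_spread^2, K, G)
    }

    for (it in seq_len(sampler$n_draws)) {
      ## region betas, jointly per group
      for (gr in seq_len(G)) {
        ii <- idx_g[[gr]]
        prior_prec <- 1 / tau2[net, gr]
        prior_mean <- if (hierarchy) b[net, gr] else rep(0, J)
        if (length(ii) > 0) {
          resid <- y[ii]
          if (P > 0) resid <- resid - as.vector(C[ii, , drop = FALSE] %*%
                                                  gamma)
          prec <- XtX[[gr]] / sig2
          diag(prec) <- diag(prec) + prior_prec
          rhs <- as.vector(crossprod(X[ii, , drop = FALSE], resid)) / sig2 +
            prior_prec * prior_mean
        } else {
          prec <- diag(prior_prec, J)
          rhs <- prior_prec * prior_mean
        }
        R <- chol(prec)
        mu <- backsolve(R, forwardsolve(t(R), rhs))
        beta[, gr] <- mu + backsolve(R, stats::rnorm(J))
      }

      ## confound betas (shared across groups)
      if (P > 0 && n > 0) {
        fitted_beta <- rowSums(X * t(beta)[g + 1L, , drop = FALSE])
        prec <- CtC / sig2 + diag(c_prec0, P)
        rhs <- as.vector(crossprod(C, y - fitted_beta)) / sig2
        R <- chol(prec)
        mu <- backsolve(R, forwardsolve(t(R), rhs))
        gamma <- mu + backsolve(R, stats::rnorm(P))
      } else if (P > 0) {
        gamma <- stats::rnorm(P, 0, priors$confound_beta_prior_sd)
      }

      ## network betas
      if (hierarchy) {
        for (gr in seq_len(G)) {
          s2_k <- if (per_net_scale) s2[, gr] else rep(s2[gr], K)
          for (k in seq_len(K)) {
            prec_k <- block_sizes[k] / tau2[k, gr] + 1 / s2_k[k]
            mean_k <- sum(beta[net == k, gr]) / tau2[k, gr] / prec_k
            b[k, gr] <- stats::rnorm(1L, mean_k, sqrt(1 / prec_k))
          }
        }
      }

      ## region spreads (Half-Cauchy via inverse-gamma mixture)
      if (is.null(fix_region_spread)) {
        for (gr in seq_len(G)) {
          dev2 <- (beta[, gr] - (if (hierarchy) b[net, gr] else 0))^2
          for (k in seq_len(K)) {
            ss <- sum(dev2[net == k])
            tau2[k, gr] <- rinvgamma1((1 + block_sizes[k]) / 2,
                                      1 / a_tau[k, gr] + ss / 2)
            a_tau[k, gr] <- rinvgamma1(1, 1 / A_tau2 + 1 / tau2[k, gr])
          }
        }
      }

      ## network-beta scale
      if (hierarchy) {
        if (per_net_scale) {
          for (gr in seq_len(G)) for (k in seq_len(K)) {
            s2[k, gr] <- rinvgamma1(1, 1 / a_s[k, gr] + b[k, gr]^2 / 2)
            a_s[k, gr] <- rinvgamma1(1, 1 / A_s2 + 1 / s2[k, gr])
          }
        } else {
          for (gr in seq_len(G)) {
            s2[gr] <- rinvgamma1((1 + K) / 2,
                                 1 / a_s[gr] + sum(b[, gr]^2) / 2)
            a_s[gr] <- rinvgamma1(1, 1 / A_s2 + 1 / s2[gr])
          }
        }
      }

      ## noise scale
      if (is.null(fix_noise_scale)) {
        if (n > 0) {
          fitted <- rowSums(X * t(beta)[g + 1L, , drop = FALSE])
          if (P > 0) fitted <- fitted + as.vector(C %*% gamma)
          ssr <- sum((y - fitted)^2)
        } else {
          ssr <- 0
        }
        sig2 <- rinvgamma1((1 + n) / 2, 1 / a_sig + ssr / 2)
        a_sig <- rinvgamma1(1, 1 / A_sig2 + 1 / sig2)
      }

      if (it > sampler$burn_in) {
        row <- (ch - 1L) * n_retain + (it - sampler$burn_in)
        draws[row, ] <- c(beta, b, sqrt(tau2),
                          if (per_net_scale) sqrt(s2) else sqrt(s2),
                          gamma, sqrt(sig2))
      }
    }
  }
  if (!all(is.finite(draws))) {
    stop("sampler produced non-finite draws; check the design for ",
         "degenerate columns", call. = FALSE)
  }

  param_info <- data.frame(
    name = par_names,
    type = c(rep("region_beta", J * G), rep("network_beta", K * G),
             rep("network_spread", K * G),
             rep("network_scale", if (per_net_scale) K * G else G),
             rep("confound_beta", P), "noise_scale"),
    region = c(rep(region_names, G), rep(NA_character_, n_par - J * G)),
    network = c(SB_NETWORKS[net][rep(seq_len(J), G)],
                rep(SB_NETWORKS[seq_len(K)], G),
                rep(SB_NETWORKS[seq_len(K)], G),
                if (per_net_scale) rep(SB_NETWORKS[seq_len(K)], G)
                else rep(NA_character_, G),
                rep(NA_character_, P), NA_character_),
    group = c(rep(seq_len(G) - 1L, each = J), rep(seq_len(G) - 1L, each = K),
              rep(seq_len(G) - 1L, each = K),
              if (per_net_scale) rep(seq_len(G) - 1L, each = K)
              else seq_len(G) - 1L,
              rep(NA_integer_, P), NA_integer_),
    stringsAsFactors = FALSE)

  structure(list(draws = draws, chain = chain_id, param_info = param_info,
                 n_draws = sampler$n_draws, burn_in = sampler$burn_in,
                 chains = sampler$chains, seed = sampler$seed,
                 n_obs = n, social_index = design$social_index,
                 group_labels_n = G, hierarchy = hierarchy),
            class = "sb_draws")
}

#' @export
print.sb_draws <- function(x, ...) {
  cat("sb_draws:", nrow(x$draws), "retained draws (", x$chains,
      "chain(s) x", x$n_draws - x$burn_in, "),", ncol(x$draws),
      "parameters, seed", x$seed, "\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted samples containing
#' `ceiling(prob * S)` of the `S` samples; ties in width are broken toward
#' the smallest lower bound.
#'
#' @param samples Numeric vector, at least 2 values.
#' @param prob Probability mass in (0, 1) (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
hpdi <- function(samples, prob = 0.95) {
  if (length(samples) < 2L) stop("hpdi needs at least 2 samples",
                                 call. = FALSE)
  if (!is.numeric(prob) || prob <= 0 || prob >= 1) {
    stop("prob must lie strictly between 0 and 1", call. = FALSE)
  }
  s <- sort(samples)
  S <- length(s)
  m <- ceiling(prob * S)
  if (m >= S) return(c(s[1], s[S]))
  widths <- s[seq.int(m, S)] - s[seq.int(1L, S - m + 1L)]
  i <- which.min(widths)  # which.min takes the earliest minimum
  c(s[i], s[i + m - 1L])
}

#' Summarize posterior draws
#'
#' Posterior mean and HPDI for every region-by-group coefficient, network
#' coefficient, confound coefficient and the noise scale, keyed by region
#' name, network and group label.
#'
#' @param draws `sb_draws` object.
#' @param prob HPDI probability mass (default 0.95).
#' @param social_index Index whose group labels annotate the table;
#'   defaults to the index recorded in `draws`.
#' @return Data frame with columns `parameter_type, region, network, group,
#'   posterior_mean, hpdi_lower, hpdi_upper, prob`.
#' @export
summarize_posterior <- function(draws, prob = 0.95,
                                social_index = draws$social_index) {
  stopifnot(inherits(draws, "sb_draws"))
  keep <- draws$param_info$type %in%
    c("region_beta", "network_beta", "confound_beta", "noise_scale")
  info <- draws$param_info[keep, , drop = FALSE]
  mat <- draws$draws[, info$name, drop = FALSE]
  hp <- apply(mat, 2, hpdi, prob = prob)
  labels <- if (!is.null(social_index) && social_index %in% SB_INDICES &&
                draws$group_labels_n == 4L) {
    group_labels(social_index)
  } else {
    paste0("g", seq_len(draws$group_labels_n) - 1L)
  }
  data.frame(parameter_type = info$type,
             region = info$region,
             network = info$network,
             group = ifelse(is.na(info$group), NA_character_,
                            labels[info$group + 1L]),
             posterior_mean = colMeans(mat),
             hpdi_lower = hp[1, ],
             hpdi_upper = hp[2, ],
             prob = prob,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Posterior means of the region-by-group coefficients as a matrix
#'
#' @param draws `sb_draws` object.
#' @return J x G matrix (regions x groups).
#' @export
region_beta_means <- function(draws) {
  info <- draws$param_info
  sel <- info$type == "region_beta"
  J <- length(unique(info$region[sel]))
  G <- draws$group_labels_n
  matrix(colMeans(draws$draws[, info$name[sel], drop = FALSE]), J, G,
         dimnames = list(unique(info$region[sel]),
                         paste0("g", seq_len(G) - 1L)))
}

geyer_ess <- function(chains_mat) {
  # chains_mat: iterations x chains for one parameter
  m <- ncol(chains_mat)
  n <- nrow(chains_mat)
  W <- mean(apply(chains_mat, 2, stats::var))
  if (W == 0) return(NA_real_)
  B_over_n <- if (m > 1) stats::var(colMeans(chains_mat)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  max_lag <- min(n - 1L, 400L)
  rho_chain <- sapply(seq_len(m), function(j) {
    stats::acf(chains_mat[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1] * stats::var(chains_mat[, j]) *
      (n - 1) / n
  })
  rho_chain <- matrix(rho_chain, nrow = max_lag)
  rho <- 1 - (W - rowMeans(rho_chain)) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  n_pairs <- floor(max_lag / 2)
  tail_sum <- 0
  prev <- Inf
  for (p in seq_len(n_pairs)) {
    pair <- rho[2 * p - 1] + rho[2 * p]
    if (pair < 0) break
    pair <- min(pair, prev)
    tail_sum <- tail_sum + pair
    prev <- pair
  }
  ess <- m * n / (1 + 2 * tail_sum)
  min(ess, m * n)
}

#' Split-R-hat and effective sample size per parameter
#'
#' Each chain is split in half; R-hat compares between- and within-half
#' variances, and the effective sample size uses the Geyer initial
#' monotone positive sequence estimator on chain autocorrelations.
#' Parameters with `R-hat > 1.05` trigger a warning.
#'
#' @param draws `sb_draws` object.
#' @param warn Emit a warning for parameters with R-hat above 1.05.
#' @return Data frame with columns `name, rhat, ess`.
#' @export
convergence_diagnostics <- function(draws, warn = TRUE) {
  stopifnot(inherits(draws, "sb_draws"))
  n_retain <- draws$n_draws - draws$burn_in
  half <- floor(n_retain / 2)
  if (half < 2L) stop("too few retained draws for diagnostics",
                      call. = FALSE)
  out <- data.frame(name = colnames(draws$draws),
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(ncol(draws$draws))) {
    halves <- list()
    full <- list()
    for (ch in seq_len(draws$chains)) {
      x <- draws$draws[draws$chain == ch, p]
      halves <- c(halves, list(x[seq_len(half)]),
                  list(x[seq.int(n_retain - half + 1L, n_retain)]))
      full <- c(full, list(x))
    }
    hm <- do.call(cbind, halves)
    W <- mean(apply(hm, 2, stats::var))
    if (W == 0) {
      out$rhat[p] <- 1
      out$ess[p] <- NA_real_
      next
    }
    B_over_n <- stats::var(colMeans(hm))
    var_plus <- (half - 1) / half * W + B_over_n
    out$rhat[p] <- sqrt(var_plus / W)
    out$ess[p] <- geyer_ess(do.call(cbind, full))
  }
  if (warn && any(out$rhat > 1.05, na.rm = TRUE)) {
    bad <- out$name[which(out$rhat > 1.05)]
    warning("R-hat > 1.05 for: ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  out
}

#' Zero-observation design for prior-only sampling
#'
#' @param atlas Atlas supplying region names and the network map.
#' @param n_groups Number of groups (default 4).
#' @param n_confounds Number of confound columns (default 2).
#' @return `sb_design` with 0 rows.
#' @export
empty_design <- function(atlas = load_atlas("default"), n_groups = 4L,
                         n_confounds = 2L) {
  J <- nrow(atlas)
  X <- matrix(numeric(0), 0, J, dimnames = list(NULL, atlas$name))
  C <- matrix(numeric(0), 0, n_confounds)
  new_design(X, numeric(0), C, integer(0), network = network_index(atlas),
             social_index = "support", n_groups = n_groups)
}
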