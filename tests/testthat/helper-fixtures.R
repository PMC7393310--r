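# Shared fixtures built in code.

# A reduced atlas on a regular lattice: regions spaced `spacing` mm apart,
# far from each other and usable for image painting.
lattice_atlas <- function(n_regions = 6L, spacing = 24, strict = FALSE) {
  per_net <- ceiling(n_regions / 4)
  nets <- rep(sbhbm::SB_NETWORKS, each = per_net)[seq_len(n_regions)]
  grid <- expand.grid(x = seq_len(3), y = seq_len(3), z = seq_len(4))
  coords <- as.matrix(grid[seq_len(n_regions), ]) * spacing
  tab <- data.frame(region_id = seq_len(n_regions),
                    name = paste0("R", seq_len(n_regions)),
                    hemisphere = rep(c("L", "R"),
                                     length.out = n_regions),
                    network = nets,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  validate_atlas(tab, strict = strict, source = "test-lattice")
}

# Full-size 36-region atlas with lattice geometry (valid for painting).
lattice_atlas36 <- function(spacing = 22) {
  nets <- rep(sbhbm::SB_NETWORKS, times = c(6L, 8L, 11L, 11L))
  grid <- expand.grid(x = seq_len(4), y = seq_len(3), z = seq_len(3))
  coords <- as.matrix(grid) * spacing
  tab <- data.frame(region_id = 1:36,
                    name = paste0("R", 1:36),
                    hemisphere = rep(c("L", "R"), 18),
                    network = nets,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  validate_atlas(tab, strict = TRUE, source = "test-lattice36")
}

# Simple 1 mm isotropic volume centered near the origin.
unit_volume <- function(dims = c(21L, 21L, 21L), value = 0,
                        origin = -(dims - 1) / 2) {
  affine <- diag(4)
  affine[1:3, 4] <- origin
  sb_volume(array(value, dims), affine)
}

# Small random design with arbitrary region/group structure.
random_design <- function(n = 10L, J = 2L, G = 2L, P = 1L, seed = 99L,
                          networks = NULL) {
  set.seed(seed)
  if (is.null(networks)) networks <- rep_len(1:2, J)
  X <- matrix(rnorm(n * J), n, J,
              dimnames = list(NULL, paste0("r", seq_len(J))))
  C <- matrix(rnorm(n * P), n, P)
  g <- rep_len(seq_len(G) - 1L, n)
  y <- rnorm(n)
  new_design(X, y, C, g, network = networks, n_groups = G)
}

# Random parameter state matching a design's shape.
random_state <- function(J = 2L, G = 2L, K = 2L, P = 1L, seed = 7L,
                         network = rep_len(1:K, J)) {
  set.seed(seed)
  parameter_state(
    region_betas = matrix(rnorm(J * G), J, G),
    network_betas = matrix(rnorm(K * G), K, G),
    network_spreads = matrix(abs(rnorm(K * G)) + 0.3, K, G),
    network_scale = abs(rnorm(G)) + 0.5,
    confound_betas = rnorm(P),
    noise_scale = abs(rnorm(1)) + 0.5,
    network = network)
}

# Independent oracle: exhaustive shortest-window HPDI search.
hpdi_oracle <- function(samples, prob = 0.95) {
  s <- sort(samples)
  S <- length(s)
  m <- ceiling(prob * S)
  if (m >= S) return(c(s[1], s[S]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(S - m + 1L)) {
    w <- s[i + m - 1L] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + m - 1L])
  }
  c(best[2], best[3])
}

# Independent oracle: term-by-term log-posterior summation with plain loops.
log_posterior_oracle <- function(state, design, priors) {
  ll <- 0
  n <- nrow(design$X)
  for (i in seq_len(n)) {
    mu <- 0
    for (j in seq_len(ncol(design$X))) {
      mu <- mu + design$X[i, j] * state$region_betas[j, design$g[i] + 1L]
    }
    for (p in seq_len(ncol(design$C))) {
      mu <- mu + design$C[i, p] * state$confound_betas[p]
    }
    ll <- ll + dnorm(design$y[i], mu, state$noise_scale, log = TRUE)
  }
  lp <- 0
  hc <- function(x, s) log(2 / (pi * s * (1 + (x / s)^2)))
  lp <- lp + hc(state$noise_scale, priors$noise_scale_prior)
  K <- nrow(state$network_betas); G <- ncol(state$network_betas)
  for (k in seq_len(K)) for (g in seq_len(G)) {
    lp <- lp + hc(state$network_spreads[k, g], priors$region_spread_prior)
  }
  for (g in seq_len(G)) {
    lp <- lp + hc(state$network_scale[g], priors$network_beta_scale_prior)
    for (k in seq_len(K)) {
      lp <- lp + dnorm(state$network_betas[k, g], 0,
                       state$network_scale[g], log = TRUE)
    }
  }
  for (j in seq_len(nrow(state$region_betas))) for (g in seq_len(G)) {
    k <- state$network[j]
    lp <- lp + dnorm(state$region_betas[j, g], state$network_betas[k, g],
                     state$network_spreads[k, g], log = TRUE)
  }
  for (p in seq_along(state$confound_betas)) {
    lp <- lp + dnorm(state$confound_betas[p], 0,
                     priors$confound_beta_prior_sd, log = TRUE)
  }
  ll + lp
}
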