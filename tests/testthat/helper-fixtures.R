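# Shared fixtures and independent oracles.

# Exhaustive enumeration of all set partitions of n items (restricted-growth
# strings); the brute-force oracle for the map-equation optimiser.
setparts <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in setparts(n - 1L)) {
    k <- max(p)
    for (m in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

# Independent two-level codelength evaluation, written from the published
# formula with an eigenvector stationary distribution (not power iteration)
# and explicit entropy loops — deliberately a second route.
codelength_ref <- function(W, tau, partition) {
  n <- nrow(W)
  rs <- rowSums(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, ] <- if (rs[i] > 0) (1 - tau) * W[i, ] / rs[i] + tau / n
              else rep(1 / n, n)
  }
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  p <- Re(ev$vectors[, k]); p <- p / sum(p)
  H <- function(probs) {
    probs <- probs[probs > 0]
    -sum(probs * log(probs)) / log(2)
  }
  mods <- sort(unique(partition))
  q_m <- numeric(length(mods))
  total <- 0
  for (mi in seq_along(mods)) {
    inm <- partition == mods[mi]
    for (i in which(inm)) for (j in which(!inm)) q_m[mi] <- q_m[mi] + p[i] * P[i, j]
  }
  q <- sum(q_m)
  if (q > 0) total <- total + q * H(q_m / q)
  for (mi in seq_along(mods)) {
    inm <- partition == mods[mi]
    pm <- q_m[mi] + sum(p[inm])
    if (pm > 0) total <- total + pm * H(c(q_m[mi], p[inm]) / pm)
  }
  total
}

# Closed-form constant-coefficient solution of the fate system from an
# arbitrary initial state: the analytic oracle for the propagator and the
# settling-integral quadrature.
fate_closed_form <- function(t, L10, L20, alpha, mu, beta, mu_s, fr) {
  a <- alpha + mu
  g <- beta + mu + mu_s * fr
  L1 <- L10 * exp(-a * t)
  L2 <- if (abs(g - a) > 1e-12) {
    L20 * exp(-g * t) + alpha * L10 * (exp(-a * t) - exp(-g * t)) / (g - a)
  } else {
    L20 * exp(-g * t) + alpha * L10 * t * exp(-a * t)
  }
  list(L1 = L1, L2 = L2)
}

# Small ocean fixtures --------------------------------------------------

fix_grid <- function(n = 20, L = 100e3) {
  regular_grid(c(0, L), c(0, L), n, n)
}

# one-reef-cell grid for stationary-particle tests
fix_point_reef <- function(grid = fix_grid(), where = c(20e3, 50e3),
                           seed = 1) {
  make_reef_grid(grid, rbind(where), 1, seed = seed)
}

# small double-gyre pipeline configuration used across modules; scaled-down
# run sizes, same structure as default_config()
fix_config <- function(seed = 1, perturbation = 0) {
  cfg <- default_config(seed)
  cfg$ocean$perturbation <- perturbation
  cfg$ocean$nx <- 60; cfg$ocean$ny <- 30
  cfg$reefs$cells_per_cluster <- 6L
  cfg$calendar$sample_dates <- 6L
  cfg$advection$n_per_cell <- 2L
  cfg$advection$dt <- 0.05
  cfg$larvae$T_max <- 20
  cfg$connectivity$n_rep <- 20L
  cfg$partitioning$n_restarts <- 3L
  cfg
}
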