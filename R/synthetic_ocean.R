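# Synthetic inputs: analytic velocity fields, reef grids, spawning calendars
# and planted-structure gene-flow matrices. Every generator is a pure
# function of its parameters and seed, so fixture suites reproduce exactly.

#' Construct a gridded velocity field
#'
#' Holds u/v surface velocities (m s^-1) per time slice on a rectangular
#' grid, plus a land mask. Velocities over land are forced to zero.
#'
#' @param grid a [grid_spec()].
#' @param times numeric vector of days (since an arbitrary epoch), strictly
#'   increasing with uniform step, or a single time for a steady field.
#' @param u,v numeric arrays of dim `(n_times, ny, nx)` in m s^-1.
#' @param land optional `ny x nx` logical land mask.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(grid, times, u, v, land = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1L)
    stop("field times must be strictly increasing", call. = FALSE)
  if (length(times) > 2L) {
    dtv <- diff(times)
    if (max(abs(dtv - dtv[1])) > 1e-9 * dtv[1])
      stop("field time step must be uniform", call. = FALSE)
  }
  dims <- c(length(times), grid$ny, grid$nx)
  u <- array(u, dims); v <- array(v, dims)
  if (is.null(land)) land <- matrix(FALSE, grid$ny, grid$nx)
  stopifnot(identical(dim(land), c(grid$ny, grid$nx)))
  if (any(land)) {
    for (k in seq_along(times)) {
      uk <- u[k, , ]; vk <- v[k, , ]
      uk[land] <- 0; vk[land] <- 0
      u[k, , ] <- uk; v[k, , ] <- vk
    }
  }
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("velocity field contains non-finite values", call. = FALSE)
  structure(list(grid = grid, times = times, u = u, v = v, land = land),
            class = "velocity_field")
}

#' Spatially and temporally uniform velocity field
#'
#' @param speed current speed in m s^-1 (>= 0).
#' @param bearing direction of flow in compass degrees (0 = north, 90 = east).
#' @param grid a [grid_spec()].
#' @param times time axis in days (default a steady two-slice field).
#' @param land optional land mask (velocities zeroed there).
#' @return A `velocity_field`.
#' @export
make_uniform_field <- function(speed, bearing = 90, grid,
                               times = c(0, 1), land = NULL) {
  if (speed < 0) stop("speed must be >= 0", call. = FALSE)
  th <- bearing * pi / 180
  u0 <- speed * sin(th)
  v0 <- speed * cos(th)
  nt <- length(times)
  velocity_field(grid, times,
                 u = array(u0, c(nt, grid$ny, grid$nx)),
                 v = array(v0, c(nt, grid$ny, grid$nx)),
                 land = land)
}

#' Solid-body rotation field
#'
#' Rigid rotation about `centre` at angular speed `omega` (radians per day):
#' u = -omega (y - yc), v = omega (x - xc), converted to m s^-1. Linear in
#' space, so bilinear sampling reproduces it exactly — the standard analytic
#' oracle for integrator convergence on circular orbits.
#'
#' @param omega angular velocity, rad d^-1.
#' @param centre numeric length-2 rotation centre (grid units).
#' @param grid a [grid_spec()].
#' @param times time axis in days.
#' @return A `velocity_field`.
#' @export
make_solid_body_field <- function(omega, centre, grid, times = c(0, 1)) {
  xy <- expand.grid(y = grid$y_centres, x = grid$x_centres)
  u0 <- matrix(-omega * (xy$y - centre[2]) / 86400, grid$ny, grid$nx)
  v0 <- matrix(omega * (xy$x - centre[1]) / 86400, grid$ny, grid$nx)
  nt <- length(times)
  velocity_field(grid, times,
                 u = aperm(array(u0, c(grid$ny, grid$nx, nt)), c(3, 1, 2)),
                 v = aperm(array(v0, c(grid$ny, grid$nx, nt)), c(3, 1, 2)))
}

#' Double-gyre streamfunction
#'
#' The classic two-cell analytic test flow: two counter-rotating gyres on a
#' `2L x L` box separated by a separatrix that is impermeable when
#' `perturbation = 0` and oscillates (allowing weak inter-gyre exchange) when
#' `perturbation > 0`.
#'
#' @param x,y positions in metres.
#' @param t time in days.
#' @param amplitude peak speed U0, m s^-1.
#' @param perturbation dimensionless separatrix oscillation strength
#'   (`eps`); 0 gives a steady flow.
#' @param L gyre length scale in metres (domain is `[0, 2L] x [0, L]`).
#' @param period oscillation period in days.
#' @return Streamfunction value(s) in m^2 s^-1.
#' @export
double_gyre_psi <- function(x, y, t, amplitude, perturbation, L,
                            period = 10) {
  X <- x / L; Y <- y / L
  a <- perturbation * sin(2 * pi * t / period)
  b <- 1 - 2 * a
  f <- a * X^2 + b * X
  (amplitude * L / pi) * sin(pi * f) * sin(pi * Y)
}

#' Double-gyre velocity field
#'
#' Velocities derived from [double_gyre_psi()] (hence numerically
#' divergence-free in the interior), sampled at cell centres on each time
#' slice.
#'
#' @inheritParams double_gyre_psi
#' @param grid a [grid_spec()]; its domain should be `[0, 2L] x [0, L]`.
#' @param times time axis in days.
#' @return A `velocity_field`.
#' @export
make_double_gyre <- function(amplitude, perturbation, grid,
                             times = c(0, 1), L = diff(range(grid$y_edges)),
                             period = 10) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  nt <- length(times)
  u <- array(0, c(nt, grid$ny, grid$nx))
  v <- array(0, c(nt, grid$ny, grid$nx))
  X <- grid$x_centres / L
  Y <- grid$y_centres / L
  for (k in seq_len(nt)) {
    a <- perturbation * sin(2 * pi * times[k] / period)
    b <- 1 - 2 * a
    f <- a * X^2 + b * X       # length nx
    fp <- 2 * a * X + b
    # u = -dpsi/dy, v = dpsi/dx
    u[k, , ] <- outer(-amplitude * cos(pi * Y), sin(pi * f))
    v[k, , ] <- outer(amplitude * sin(pi * Y), fp * cos(pi * f))
  }
  velocity_field(grid, times, u, v)
}

#' Synthetic reef grid with clustered reef cells
#'
#' Places `cells_per_cluster` reef cells around each cluster centre (the
#' nearest grid cells to the centre), labels each cluster as one reef group,
#' and draws reef fractions F_r from a Beta distribution. Clusters that claim
#' the same cell are merged into one group, with a warning.
#'
#' @param grid a [grid_spec()].
#' @param cluster_centres numeric matrix `k x 2` of centre coordinates.
#' @param cells_per_cluster integer, reef cells per cluster.
#' @param seed integer seed for the F_r draws.
#' @param fr_beta length-2 Beta shape parameters for F_r (default
#'   `c(2, 2)`); a stand-in for unavailable satellite-derived fractions.
#' @param land optional `ny x nx` logical land mask; reef cells are always
#'   placed on ocean cells.
#' @return An object of class `reef_grid` with `reef_fraction`, `cell_area`
#'   and `group_id` matrices (group -1 = non-reef) plus a `cells` data frame
#'   (one row per reef cell: cell index, ix, iy, x, y, fr, area, group).
#' @export
make_reef_grid <- function(grid, cluster_centres, cells_per_cluster, seed,
                           fr_beta = c(2, 2), land = NULL) {
  if (is.null(dim(cluster_centres)))
    cluster_centres <- matrix(cluster_centres, ncol = 2, byrow = TRUE)
  k <- nrow(cluster_centres)
  if (k < 1L) stop("at least one reef cluster is required", call. = FALSE)
  if (any(cluster_centres[, 1] < grid$x_edges[1]) ||
      any(cluster_centres[, 1] > grid$x_edges[grid$nx + 1L]) ||
      any(cluster_centres[, 2] < grid$y_edges[1]) ||
      any(cluster_centres[, 2] > grid$y_edges[grid$ny + 1L]))
    stop("cluster centres must lie inside the grid domain", call. = FALSE)
  if (is.null(land)) land <- matrix(FALSE, grid$ny, grid$nx)

  xy <- expand.grid(y = grid$y_centres, x = grid$x_centres) # column-major
  ocean <- which(!land)
  group_id <- matrix(-1L, grid$ny, grid$nx)
  merged <- FALSE
  for (g in seq_len(k)) {
    d2 <- (xy$x[ocean] - cluster_centres[g, 1])^2 +
          (xy$y[ocean] - cluster_centres[g, 2])^2
    pick <- ocean[order(d2, ocean)[seq_len(cells_per_cluster)]]
    if (any(group_id[pick] != -1L)) merged <- TRUE
    group_id[pick] <- g
  }
  if (merged) {
    warning("overlapping reef clusters: shared cells keep the later group; ",
            "groups re-labelled contiguously", call. = FALSE)
  }
  # re-label contiguously in case a cluster was fully absorbed
  present <- sort(unique(group_id[group_id > 0L]))
  group_id[group_id > 0L] <- match(group_id[group_id > 0L], present)

  reef_cells <- which(group_id != -1L)
  reef_fraction <- matrix(0, grid$ny, grid$nx)
  withr::with_seed(seed, {
    reef_fraction[reef_cells] <-
      stats::rbeta(length(reef_cells), fr_beta[1], fr_beta[2])
  })
  # F_r must be strictly positive on reef cells
  reef_fraction[reef_cells] <- pmax(reef_fraction[reef_cells], 1e-6)
  area <- cell_areas(grid)

  cells <- data.frame(
    cell = reef_cells,
    iy = ((reef_cells - 1L) %% grid$ny) + 1L,
    ix = ((reef_cells - 1L) %/% grid$ny) + 1L
  )
  cells$x <- grid$x_centres[cells$ix]
  cells$y <- grid$y_centres[cells$iy]
  cells$fr <- reef_fraction[reef_cells]
  cells$area <- area[reef_cells]
  cells$group <- group_id[reef_cells]
  cells <- cells[order(cells$cell), , drop = FALSE]
  rownames(cells) <- NULL

  structure(list(grid = grid, reef_fraction = reef_fraction,
                 cell_area = area, group_id = group_id, land = land,
                 cells = cells, n_groups = length(present)),
            class = "reef_grid")
}

#' Daily spawning calendar restricted to given months
#'
#' Emulates daily virtual spawning with a seasonal window; the default
#' window (October through March) matches austral-summer coral spawning.
#'
#' @param start,end inclusive date range (`Date` or parseable strings).
#' @param months_allowed integer months (1-12) in which spawning occurs.
#' @return An object of class `spawning_calendar`: `dates` (Date, strictly
#'   increasing) and `months_allowed`.
#' @export
make_spawning_calendar <- function(start, end,
                                   months_allowed = c(10:12, 1:3)) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date precedes start date", call. = FALSE)
  months_allowed <- sort(unique(as.integer(months_allowed)))
  stopifnot(all(months_allowed %in% 1:12))
  dates <- seq(start, end, by = "day")
  dates <- dates[as.integer(format(dates, "%m")) %in% months_allowed]
  if (length(dates) == 0L)
    stop("no spawning dates fall in the allowed months", call. = FALSE)
  structure(list(dates = dates, months_allowed = months_allowed),
            class = "spawning_calendar")
}

#' Synthetic gene-flow (migration-rate) matrix with planted structure
#'
#' Builds a BayesAss-style site-by-site migration matrix `m` where `m[i, j]`
#' is the fraction of population `i` derived from population `j` per
#' generation. The diagonal (self-recruitment) is set near
#' `self_recruitment`; off-diagonal mass is biased toward within-partition
#' site pairs and each row is renormalised to sum to 1.
#'
#' @param n_sites number of sites.
#' @param self_recruitment target diagonal value, in (0, 1). The default
#'   0.8 sits in the empirically typical 0.77-0.84 range for reef corals.
#' @param structure integer vector of length `n_sites` giving the planted
#'   partition (default: one block, i.e. uniform exchange).
#' @param noise non-negative multiplicative log-normal noise scale on the
#'   off-diagonal weights (0 = deterministic closed form).
#' @param seed integer seed.
#' @param within_bias how much heavier within-block pairs are weighted than
#'   between-block pairs (weight `1 + within_bias` vs 1).
#' @param site_names optional character site labels.
#' @return A `gene_flow_matrix`: numeric matrix with site dimnames, rows
#'   summing to 1.
#' @export
make_synthetic_geneflow <- function(n_sites, self_recruitment = 0.8,
                                    structure = rep(1L, n_sites),
                                    noise = 0, seed = 1L, within_bias = 4,
                                    site_names = NULL) {
  if (self_recruitment <= 0 || self_recruitment >= 1)
    stop("self_recruitment must be in (0, 1)", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  stopifnot(length(structure) == n_sites, n_sites >= 2L)
  if (is.null(site_names))
    site_names <- sprintf("site_%02d", seq_len(n_sites))

  w <- 1 + within_bias * outer(structure, structure, "==")
  diag(w) <- 0
  if (noise > 0) {
    withr::with_seed(seed, {
      w <- w * exp(noise * matrix(stats::rnorm(n_sites^2), n_sites))
    })
    diag(w) <- 0
  }
  m <- w / rowSums(w) * (1 - self_recruitment)
  diag(m) <- self_recruitment
  dimnames(m) <- list(site_names, site_names)
  class(m) <- c("gene_flow_matrix", class(m))
  m
}

#' Validate a gene-flow matrix
#'
#' Checks entries in \[0, 1\] and rows summing to 1 within `tol`.
#'
#' @param m a square migration-rate matrix.
#' @param tol row-sum tolerance.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_geneflow <- function(m, tol = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m < 0) || any(m > 1))
    stop("gene-flow entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(m) - 1) > tol))
    stop("gene-flow rows must sum to 1", call. = FALSE)
  invisible(m)
}
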