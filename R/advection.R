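# Lagrangian advection of passive surface particles through a gridded
# velocity field: fixed-step RK4 with bilinear interpolation in space and
# linear interpolation in time.

#' Build a release set from a reef grid
#'
#' Releases `n_per_cell` particles from every reef cell (F_r > 0), at cell
#' centres by default or with seeded uniform jitter inside the cell.
#'
#' @param reef a [make_reef_grid()] object.
#' @param n_per_cell particles per reef cell, N (default 4).
#' @param date release date (`Date` or numeric day).
#' @param jitter fraction of the cell size (0-1) for uniform positional
#'   jitter; 0 places all particles at the cell centre.
#' @param seed seed for the jitter draws.
#' @return A `release_set` data frame: particle, source_cell, x, y, area,
#'   fr_source, group, with attributes `date` and `n_per_cell`.
#' @export
make_release <- function(reef, n_per_cell = 4L, date = 0, jitter = 0,
                         seed = 1L) {
  stopifnot(inherits(reef, "reef_grid"), n_per_cell >= 1L)
  cells <- reef$cells
  n <- nrow(cells) * n_per_cell
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  rel <- data.frame(
    particle = seq_len(n),
    source_cell = cells$cell[idx],
    x = cells$x[idx], y = cells$y[idx],
    area = cells$area[idx], fr_source = cells$fr[idx],
    group = cells$group[idx]
  )
  if (jitter > 0) {
    g <- reef$grid
    dx <- diff(g$x_edges)[cells$ix[idx]]
    dy <- diff(g$y_edges)[cells$iy[idx]]
    withr::with_seed(seed, {
      rel$x <- rel$x + (stats::runif(n) - 0.5) * jitter * dx
      rel$y <- rel$y + (stats::runif(n) - 0.5) * jitter * dy
    })
  }
  attr(rel, "date") <- date
  attr(rel, "n_per_cell") <- as.integer(n_per_cell)
  class(rel) <- c("release_set", class(rel))
  rel
}

# Bilinear (space) / linear (time) velocity sampling at particle positions.
# Outside the cell-centre hull the field is clamped to the nearest edge
# value. Returns list(u, v) in m s^-1.
interp_velocity <- function(field, x, y, t) {
  g <- field$grid
  nt <- length(field$times)
  if (nt == 1L) {
    k0 <- rep(1L, length(x)); wt <- 0; k1 <- k0
  } else {
    k0 <- findInterval(t, field$times)
    k0 <- pmin(pmax(k0, 1L), nt - 1L)
    k1 <- k0 + 1L
    wt <- (t - field$times[k0]) / (field$times[k1] - field$times[k0])
    wt <- pmin(pmax(wt, 0), 1)
  }
  bil <- function(arr) {
    xc <- g$x_centres; yc <- g$y_centres
    jx <- pmin(pmax(findInterval(x, xc), 1L), max(g$nx - 1L, 1L))
    jy <- pmin(pmax(findInterval(y, yc), 1L), max(g$ny - 1L, 1L))
    jx1 <- pmin(jx + 1L, g$nx); jy1 <- pmin(jy + 1L, g$ny)
    wx <- if (g$nx > 1L) (x - xc[jx]) / (xc[jx1] - xc[jx] + (jx1 == jx)) else 0
    wy <- if (g$ny > 1L) (y - yc[jy]) / (yc[jy1] - yc[jy] + (jy1 == jy)) else 0
    wx <- pmin(pmax(wx, 0), 1); wy <- pmin(pmax(wy, 0), 1)
    val <- function(arr, kk, iy, ix) arr[cbind(kk, iy, ix)]
    q <- function(arr, kk) {
      (1 - wx) * (1 - wy) * val(arr, kk, jy,  jx)  +
        wx * (1 - wy)     * val(arr, kk, jy,  jx1) +
        (1 - wx) * wy     * val(arr, kk, jy1, jx)  +
        wx * wy           * val(arr, kk, jy1, jx1)
    }
    (1 - wt) * q(arr, k0) + wt * q(arr, k1)
  }
  list(u = bil(field$u), v = bil(field$v))
}

#' Advect particles through a velocity field
#'
#' Fixed-step 4th-order Runge-Kutta integration of passive surface drifters.
#' Particles whose position falls in a land cell stick there (zero velocity,
#' state dynamics continue); particles leaving the open boundary are frozen
#' at their last inside position and flagged, and their trajectory is
#' treated as ended for reef sampling.
#'
#' @param field a [velocity_field()].
#' @param release a [make_release()] set (or data frame with x, y columns).
#' @param dt time step in days (default 0.02).
#' @param T_max maximum advection time in days (default 120, the standard
#'   pelagic-duration cap for broadcast-spawning corals).
#' @return A `trajectories` object: `times` (days since release), `x`, `y`
#'   (particle-by-step matrices), `end_step` (last valid step per particle;
#'   `n_steps + 1` if never exited), `exited` flag, plus the release.
#' @export
advect <- function(field, release, dt = 0.02, T_max = 120) {
  stopifnot(inherits(field, "velocity_field"), dt > 0, T_max > 0)
  g <- field$grid
  x <- release$x; y <- release$y
  np <- length(x)
  inside <- x >= g$x_edges[1] & x < g$x_edges[g$nx + 1L] &
            y >= g$y_edges[1] & y < g$y_edges[g$ny + 1L]
  if (!all(inside))
    stop("release positions outside the field domain: particles ",
         paste(which(!inside), collapse = ", "), call. = FALSE)

  date0 <- as.numeric(attr(release, "date") %||% 0)
  n_steps <- ceiling(T_max / dt - 1e-9)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  X <- matrix(NA_real_, np, n_steps + 1L)
  Y <- matrix(NA_real_, np, n_steps + 1L)
  X[, 1] <- x; Y[, 1] <- y
  end_step <- rep(n_steps + 1L, np)
  exited <- rep(FALSE, np)
  active <- rep(TRUE, np)
  # degrees mode: m s^-1 -> degrees day^-1 with cos(latitude) metric
  to_disp <- function(u, v, ylat) {
    if (g$coords == "degrees") {
      list(dx = u * 86400 / (111320 * cos(ylat * pi / 180)),
           dy = v * 86400 / 111320)
    } else {
      list(dx = u * 86400, dy = v * 86400)
    }
  }
  vel <- function(px, py, tt) {
    uv <- interp_velocity(field, px, py, tt)
    if (anyNA(uv$u) || anyNA(uv$v)) {
      bad <- which(is.na(uv$u) | is.na(uv$v))[1]
      stop(sprintf("NaN velocity at position (%g, %g)", px[bad], py[bad]),
           call. = FALSE)
    }
    to_disp(uv$u, uv$v, py)
  }
  on_land <- function(px, py) {
    cc <- locate_cells(g, px, py)
    ok <- !is.na(cc$ix)
    out <- rep(FALSE, length(px))
    out[ok] <- field$land[cbind(cc$iy[ok], cc$ix[ok])]
    out
  }

  for (s in seq_len(n_steps)) {
    t0 <- date0 + times[s]
    ia <- which(active)
    if (length(ia) == 0L) {
      X[, s + 1L] <- X[, s]; Y[, s + 1L] <- Y[, s]
      next
    }
    px <- X[ia, s]; py <- Y[ia, s]
    k1 <- vel(px, py, t0)
    k2 <- vel(px + dt / 2 * k1$dx, py + dt / 2 * k1$dy, t0 + dt / 2)
    k3 <- vel(px + dt / 2 * k2$dx, py + dt / 2 * k2$dy, t0 + dt / 2)
    k4 <- vel(px + dt * k3$dx, py + dt * k3$dy, t0 + dt)
    nx_ <- px + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
    ny_ <- py + dt / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)

    out <- nx_ < g$x_edges[1] | nx_ >= g$x_edges[g$nx + 1L] |
           ny_ < g$y_edges[1] | ny_ >= g$y_edges[g$ny + 1L]
    if (any(out)) {
      ids <- ia[out]
      exited[ids] <- TRUE
      end_step[ids] <- s
      active[ids] <- FALSE
      nx_[out] <- px[out]; ny_[out] <- py[out]
    }
    stuck <- !out & on_land(nx_, ny_)
    if (any(stuck)) active[ia[stuck]] <- FALSE
    X[, s + 1L] <- X[, s]; Y[, s + 1L] <- Y[, s]
    X[ia, s + 1L] <- nx_; Y[ia, s + 1L] <- ny_
  }

  structure(list(times = times, x = X, y = Y, end_step = end_step,
                 exited = exited, release = release, dt = dt, T_max = T_max,
                 release_date = attr(release, "date") %||% 0),
            class = "trajectories")
}

#' Occupied-cell indices along trajectories
#'
#' @param traj a [advect()] result.
#' @param grid a [grid_spec()] (usually the reef grid's).
#' @return Integer matrix (particle x step) of linear cell indices; NA
#'   outside the domain or beyond a particle's exit step.
#' @export
occupied_cells <- function(traj, grid) {
  cc <- locate_cells(grid, as.vector(traj$x), as.vector(traj$y))
  idx <- cc$iy + (cc$ix - 1L) * grid$ny
  m <- matrix(idx, nrow = nrow(traj$x))
  ns <- ncol(m)
  for (p in which(traj$exited)) {
    if (traj$end_step[p] < ns) m[p, (traj$end_step[p] + 1L):ns] <- NA_integer_
  }
  m
}

#' Reef fraction of the occupied cell along trajectories
#'
#' Samples F_r of the grid cell each particle occupies at each step, using
#' half-open cell intervals. Off-reef, off-domain and post-exit steps give 0.
#'
#' @param traj a [advect()] result.
#' @param reef a [make_reef_grid()] object.
#' @return Numeric matrix (particle x step) of F_r values in \[0, 1\].
#' @export
sample_reef_fraction <- function(traj, reef) {
  cells <- occupied_cells(traj, reef$grid)
  fr <- matrix(0, nrow(cells), ncol(cells))
  ok <- !is.na(cells)
  fr[ok] <- reef$reef_fraction[cells[ok]]
  fr
}
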