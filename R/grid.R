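#' Define a rectangular grid
#'
#' Cells are delimited by monotone increasing edge vectors; cell `(ix, iy)`
#' covers the half-open box `[x_edges[ix], x_edges[ix+1]) x
#' [y_edges[iy], y_edges[iy+1])`. Coordinates are flat Cartesian metres by
#' default; `coords = "degrees"` marks longitude/latitude axes, in which case
#' velocity-to-displacement conversion applies the cos(latitude) metric.
#'
#' @param x_edges,y_edges numeric vectors of cell edges, strictly increasing.
#' @param coords `"metres"` (default) or `"degrees"`.
#' @return An object of class `grid_spec` with edges, centres and cell counts.
#' @export
grid_spec <- function(x_edges, y_edges, coords = c("metres", "degrees")) {
  coords <- match.arg(coords)
  if (length(x_edges) < 2L || length(y_edges) < 2L)
    stop("grid axes need at least two edges", call. = FALSE)
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0))
    stop("grid axes must be strictly increasing", call. = FALSE)
  structure(list(
    x_edges = as.numeric(x_edges), y_edges = as.numeric(y_edges),
    x_centres = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
    y_centres = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
    nx = length(x_edges) - 1L, ny = length(y_edges) - 1L,
    coords = coords
  ), class = "grid_spec")
}

#' Regular grid over a rectangular domain
#'
#' @param xlim,ylim numeric length-2 domain bounds.
#' @param nx,ny number of cells per axis.
#' @inheritParams grid_spec
#' @return A `grid_spec`.
#' @export
regular_grid <- function(xlim, ylim, nx, ny, coords = "metres") {
  grid_spec(seq(xlim[1], xlim[2], length.out = nx + 1L),
            seq(ylim[1], ylim[2], length.out = ny + 1L),
            coords = coords)
}

# Locate points in the grid. Returns integer ix, iy (NA outside the domain)
# using the half-open convention [edge_k, edge_{k+1}); the last upper edge is
# exclusive too, so a point exactly on it counts as outside.
locate_cells <- function(grid, x, y) {
  ix <- findInterval(x, grid$x_edges, rightmost.closed = FALSE)
  iy <- findInterval(y, grid$y_edges, rightmost.closed = FALSE)
  ix[ix < 1L | ix > grid$nx] <- NA_integer_
  iy[iy < 1L | iy > grid$ny] <- NA_integer_
  ix[is.na(iy)] <- NA_integer_
  iy[is.na(ix)] <- NA_integer_
  list(ix = ix, iy = iy)
}

# Areas of all cells (ny x nx matrix), in m^2. In degrees mode the metric
# 111320 m/deg with cos(latitude) on the x axis is applied.
cell_areas <- function(grid) {
  dx <- diff(grid$x_edges)
  dy <- diff(grid$y_edges)
  if (grid$coords == "degrees") {
    m <- 111320
    outer(dy * m, dx * m) * cos(grid$y_centres * pi / 180)
  } else {
    outer(dy, dx)
  }
}
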