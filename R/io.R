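# Plain-text persistence: JSON (full precision) for gridded objects and
# ensembles, CSV for matrices. Every writer has a reader that reproduces
# the in-memory values exactly.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = FALSE)
}

#' Write / read a velocity field as JSON
#'
#' @param field a [velocity_field()].
#' @param path output file.
#' @return `read_velocity_field` returns the reconstructed
#'   `velocity_field`; the writer returns `path` invisibly.
#' @export
write_velocity_field <- function(field, path) {
  .write_json(list(
    format = "reefconn_velocity_field", version = 1L,
    x_edges = field$grid$x_edges, y_edges = field$grid$y_edges,
    coords = field$grid$coords, times = field$times,
    u = as.vector(field$u), v = as.vector(field$v),
    land = as.vector(field$land)
  ), path)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "reefconn_velocity_field"))
    stop("not a velocity-field file: ", path, call. = FALSE)
  g <- grid_spec(j$x_edges, j$y_edges, coords = j$coords)
  dims <- c(length(j$times), g$ny, g$nx)
  velocity_field(g, j$times, array(j$u, dims), array(j$v, dims),
                 land = matrix(j$land, g$ny, g$nx))
}

# Rebuild the reef-grid object (incl. its cells table) from raw matrices.
.reef_grid_from_matrices <- function(grid, reef_fraction, group_id, land) {
  area <- cell_areas(grid)
  reef_cells <- which(group_id != -1L)
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
                 cells = cells,
                 n_groups = length(unique(cells$group))),
            class = "reef_grid")
}

#' Write / read a reef grid as JSON
#'
#' @param reef a [make_reef_grid()] object.
#' @param path output file.
#' @return `read_reef_grid` returns the reconstructed `reef_grid`; the
#'   writer returns `path` invisibly.
#' @export
write_reef_grid <- function(reef, path) {
  .write_json(list(
    format = "reefconn_reef_grid", version = 1L,
    x_edges = reef$grid$x_edges, y_edges = reef$grid$y_edges,
    coords = reef$grid$coords,
    reef_fraction = as.vector(reef$reef_fraction),
    group_id = as.vector(reef$group_id),
    land = as.vector(reef$land)
  ), path)
  invisible(path)
}

#' @rdname write_reef_grid
#' @export
read_reef_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "reefconn_reef_grid"))
    stop("not a reef-grid file: ", path, call. = FALSE)
  g <- grid_spec(j$x_edges, j$y_edges, coords = j$coords)
  .reef_grid_from_matrices(g,
                           matrix(j$reef_fraction, g$ny, g$nx),
                           matrix(as.integer(j$group_id), g$ny, g$nx),
                           matrix(j$land, g$ny, g$nx))
}

#' Write / read a connectivity matrix as CSV
#'
#' Values are written with 17 significant digits so the round trip is
#' exact; the spawning date, unit level and axis orientation go in `#`
#' header comments.
#'
#' @param C a `connectivity_matrix`.
#' @param path output file.
#' @return `read_connectivity_csv` returns the matrix with its attributes;
#'   the writer returns `path` invisibly.
#' @export
write_connectivity_csv <- function(C, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- attr(C, "date")
  writeLines(c(
    paste0("# date=", if (is.null(d)) "" else as.character(d)),
    paste0("# level=", attr(C, "level") %||% ""),
    "# axis=source x destination",
    paste(c("source", colnames(C)), collapse = ",")
  ), con)
  for (i in seq_len(nrow(C))) {
    writeLines(paste(c(rownames(C)[i],
                       sprintf("%.17g", unclass(C)[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    v <- sub(paste0("# ", key, "="), "",
             hdr[startsWith(hdr, paste0("# ", key, "="))])
    if (length(v) == 0L || v == "") NULL else v
  }
  body <- lines[!startsWith(lines, "# ")]
  cn <- strsplit(body[1], ",")[[1]][-1]
  rows <- strsplit(body[-1], ",")
  C <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cn))))
  dimnames(C) <- list(vapply(rows, `[[`, "", 1L), cn)
  d <- get("date")
  structure(C, date = if (is.null(d)) NULL else as.Date(d),
            level = get("level"), axis = "source x destination",
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Write / read a gene-flow matrix as CSV
#'
#' Site names form the header row and first column, BayesAss-style.
#'
#' @param m a `gene_flow_matrix`.
#' @param path output file.
#' @return `read_geneflow_csv` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_geneflow_csv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("site", colnames(m)), collapse = ","), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", unclass(m)[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_geneflow_csv
#' @export
read_geneflow_csv <- function(path) {
  lines <- readLines(path)
  cn <- strsplit(lines[1], ",")[[1]][-1]
  rows <- strsplit(lines[-1], ",")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cn))))
  dimnames(m) <- list(vapply(rows, `[[`, "", 1L), cn)
  class(m) <- c("gene_flow_matrix", class(m))
  validate_geneflow(unclass(m))
  m
}

#' Write / read a bootstrap ensemble as JSON
#'
#' @param ensemble a [bootstrap_ensemble()].
#' @param path output file.
#' @return `read_ensemble` returns the reconstructed ensemble; the writer
#'   returns `path` invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  .write_json(list(
    format = "reefconn_bootstrap_ensemble", version = 1L,
    n_rep = ensemble$n_rep, k = ensemble$k, seed = ensemble$seed,
    replace = ensemble$replace, unit_names = ensemble$unit_names,
    dim = dim(ensemble$matrices),
    matrices = as.vector(ensemble$matrices),
    member_dates = lapply(ensemble$member_dates,
                          function(d) vapply(d, as.character, ""))
  ), path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "reefconn_bootstrap_ensemble"))
    stop("not an ensemble file: ", path, call. = FALSE)
  md <- j$member_dates
  if (is.matrix(md)) md <- lapply(seq_len(nrow(md)), function(i) md[i, ])
  structure(list(matrices = array(j$matrices, j$dim),
                 member_dates = lapply(md, as.list),
                 unit_names = j$unit_names, n_rep = j$n_rep, k = j$k,
                 seed = j$seed, replace = j$replace),
            class = "bootstrap_ensemble")
}
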