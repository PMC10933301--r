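# Potential-connectivity matrices: accumulation of settling events per
# spawning date, seasonal subsetting, bootstrap ensembles over random
# spawning dates, and derived summaries (distance decay, generations to a
# common ancestor).

#' Accumulate settling events into a potential-connectivity matrix
#'
#' `C[i, j]` is the probability that a larva produced at source reef unit
#' `i` (cell or group) during one spawning event settles at destination
#' `j`: summed settled larvae divided by larvae released at the source
#' (`rho * A_i` per cell).
#'
#' @param events a [settle_events()] table (one spawning date).
#' @param reef a [make_reef_grid()] object.
#' @param params the [larval_params()] used (provides rho).
#' @param level `"cell"` or `"group"`.
#' @param date spawning date attached as an attribute.
#' @return A `connectivity_matrix`: numeric source-by-destination matrix
#'   (orientation `C[source, destination]`, recorded in the `axis`
#'   attribute), with `date` and `level` attributes.
#' @export
accumulate_connectivity <- function(events, reef, params,
                                    level = c("cell", "group"),
                                    date = NULL) {
  level <- match.arg(level)
  cells <- reef$cells
  if (level == "cell") {
    ids <- cells$cell
    n <- length(ids)
    C <- matrix(0, n, n, dimnames = list(as.character(ids),
                                         as.character(ids)))
    if (nrow(events) > 0L) {
      si <- match(events$source_cell, ids)
      di <- match(events$dest_cell, ids)
      released <- params$rho * cells$area[si]
      for (r in seq_len(nrow(events)))
        C[si[r], di[r]] <- C[si[r], di[r]] + events$settled[r] / released[r]
    }
  } else {
    n <- reef$n_groups
    gnames <- sprintf("group_%02d", seq_len(n))
    C <- matrix(0, n, n, dimnames = list(gnames, gnames))
    released_g <- params$rho *
      tapply(cells$area, factor(cells$group, levels = seq_len(n)), sum)
    released_g[is.na(released_g)] <- 0
    if (nrow(events) > 0L) {
      for (r in seq_len(nrow(events))) {
        I <- events$source_group[r]; J <- events$dest_group[r]
        C[I, J] <- C[I, J] + events$settled[r] / released_g[I]
      }
    }
  }
  structure(C, date = date, level = level, axis = "source x destination",
            class = c("connectivity_matrix", class(C)))
}

#' Aggregate a cell-level connectivity matrix to reef groups
#'
#' Area-weighted aggregation: group rows are weighted means of their cells'
#' rows (weights `rho * A_i`, i.e. larvae released), columns are summed.
#' This conserves row totals, so it agrees exactly with accumulating at
#' group level directly.
#'
#' @param C_cell cell-level [accumulate_connectivity()] matrix.
#' @param reef a [make_reef_grid()] object.
#' @return Group-level `connectivity_matrix`.
#' @export
aggregate_to_groups <- function(C_cell, reef) {
  stopifnot(attr(C_cell, "level") == "cell")
  cells <- reef$cells
  ids <- as.character(cells$cell)
  stopifnot(identical(rownames(C_cell), ids))
  n <- reef$n_groups
  gnames <- sprintf("group_%02d", seq_len(n))
  G <- matrix(0, n, n, dimnames = list(gnames, gnames))
  w <- cells$area
  for (I in seq_len(n)) {
    ri <- cells$group == I
    if (!any(ri)) next
    row_sum <- colSums(C_cell[ri, , drop = FALSE] * w[ri]) / sum(w[ri])
    for (J in seq_len(n)) {
      cj <- cells$group == J
      G[I, J] <- sum(row_sum[cj])
    }
  }
  structure(G, date = attr(C_cell, "date"), level = "group",
            axis = "source x destination",
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Restrict dated connectivity matrices to a spawning season
#'
#' @param matrices named list of `connectivity_matrix` objects, each with a
#'   `date` attribute.
#' @param months integer months kept (default October-March).
#' @return The subset, in input order. Errors if nothing survives (a
#'   miscalibrated spawning calendar).
#' @export
seasonal_subset <- function(matrices, months = c(10:12, 1:3)) {
  keep <- vapply(matrices, function(m) {
    d <- attr(m, "date")
    if (is.null(d)) stop("connectivity matrix without a date", call. = FALSE)
    as.integer(format(as.Date(d), "%m")) %in% months
  }, logical(1))
  if (!any(keep))
    stop("no connectivity matrices fall in the spawning season; ",
         "check the spawning calendar", call. = FALSE)
  matrices[keep]
}

#' Bootstrap ensemble of short-term connectivity matrices
#'
#' Each replicate is the arithmetic mean of `k` matrices drawn (with
#' replacement by default) from the dated pool, emulating the connectivity
#' realised over `k` random spawning events.
#'
#' @param matrices list of same-shape `connectivity_matrix` objects.
#' @param n_rep number of replicates (default 1000).
#' @param k spawning events averaged per replicate (default 10).
#' @param seed integer seed.
#' @param replace sample with replacement (default TRUE).
#' @return A `bootstrap_ensemble`: `matrices` array (replicate x source x
#'   destination), `member_dates` (list of the k dates per replicate),
#'   `unit_names`, and the sampling settings.
#' @export
bootstrap_ensemble <- function(matrices, n_rep = 1000L, k = 10L, seed = 1L,
                               replace = TRUE) {
  np <- length(matrices)
  if (np == 0L) stop("empty matrix pool", call. = FALSE)
  if (!replace && np < k)
    stop("pool smaller than k with replacement disabled", call. = FALSE)
  n <- nrow(matrices[[1]])
  unit_names <- rownames(matrices[[1]])
  arr <- array(0, c(n_rep, n, n))
  member_dates <- vector("list", n_rep)
  withr::with_seed(seed, {
    for (r in seq_len(n_rep)) {
      pick <- sample.int(np, k, replace = replace)
      acc <- matrix(0, n, n)
      for (p in pick) acc <- acc + unclass(matrices[[p]])
      arr[r, , ] <- acc / k
      member_dates[[r]] <- lapply(matrices[pick], attr, "date")
    }
  })
  structure(list(matrices = arr, member_dates = member_dates,
                 unit_names = unit_names, n_rep = n_rep, k = k,
                 seed = seed, replace = replace),
            class = "bootstrap_ensemble")
}

#' Area-weighted reef-group centroids
#'
#' @param reef a [make_reef_grid()] object.
#' @return Data frame: group, x, y (centroid coordinates).
#' @export
group_centroids <- function(reef) {
  cells <- reef$cells
  out <- do.call(rbind, lapply(seq_len(reef$n_groups), function(g) {
    ci <- cells[cells$group == g, ]
    data.frame(group = g,
               x = sum(ci$x * ci$area) / sum(ci$area),
               y = sum(ci$y * ci$area) / sum(ci$area))
  }))
  out
}

#' Connectivity versus pairwise distance
#'
#' Long-format table of directed between-group connectivity against the
#' (symmetric) distance between group centroids — the standard way to show
#' the distance decay of larval exchange.
#'
#' @param C group-level `connectivity_matrix`.
#' @param reef a [make_reef_grid()] object.
#' @return Data frame: source, dest, distance (m, or great-circle m in
#'   degrees mode), connectivity; off-diagonal pairs only.
#' @export
distance_decay <- function(C, reef) {
  stopifnot(attr(C, "level") == "group")
  cen <- group_centroids(reef)
  n <- nrow(cen)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (reef$grid$coords == "degrees") {
      m <- 111320
      dx <- (cen$x[i] - cen$x[j]) * m *
        cos((cen$y[i] + cen$y[j]) / 2 * pi / 180)
      dy <- (cen$y[i] - cen$y[j]) * m
    } else {
      dx <- cen$x[i] - cen$x[j]; dy <- cen$y[i] - cen$y[j]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source = i, dest = j, distance = sqrt(dx^2 + dy^2),
      connectivity = unclass(C)[i, j])
  }
  do.call(rbind, rows)
}

#' Generations to a shared ancestor under threshold colonisation
#'
#' Treats the connectivity matrix as a per-generation colonisation graph
#' with an edge from source `j` to destination `i` whenever
#' `C[j, i] >= eps`, and asks after how many generations two reef groups
#' can first share an ancestor: `g(i, j) = min over sources k of
#' max(steps k to i, steps k to j)` by breadth-first search. A group counts
#' as its own 0-generation ancestor only if it self-recruits at `>= eps`;
#' otherwise its self-distance is its shortest directed return cycle.
#' Unreachable pairs are `Inf`.
#'
#' @param C group-level `connectivity_matrix` (source x destination).
#' @param eps colonisation threshold (> 0). A natural default is
#'   `1 / (rho * total reef area)` — at least one expected larva.
#' @return Symmetric numeric matrix of generation counts (Inf = never).
#' @export
generations_to_common_ancestor <- function(C, eps) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  A <- unclass(C) >= eps           # A[k, i]: k colonises i in one step
  n <- nrow(A)
  # D[k, i]: generations for a lineage from k to first occupy i
  D <- matrix(Inf, n, n)
  for (k in seq_len(n)) {
    dist <- rep(Inf, n)
    frontier <- which(A[k, ])
    dist[frontier] <- 1
    d <- 1
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ]))))
      nxt <- nxt[dist[nxt] > d + 1]
      dist[nxt] <- d + 1
      frontier <- nxt
      d <- d + 1
    }
    if (A[k, k]) dist[k] <- 0     # persists in place
    D[k, ] <- dist
  }
  G <- matrix(Inf, n, n, dimnames = dimnames(C))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- min(pmax(D[, i], D[, j]))
  }
  G
}
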