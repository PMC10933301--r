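# Flow-based community detection by the two-level map equation with uniform
# node teleportation, and the consistency analysis of module membership
# across a bootstrap ensemble.

#' Directed flow graph from a connectivity matrix
#'
#' @param C non-negative weight matrix (source x destination); self-loops
#'   allowed.
#' @param teleport teleportation probability in `[0, 1)` (default 0.01,
#'   i.e. 1%): the random walker jumps to a uniformly chosen node with this
#'   probability, which regularises the stationary distribution. Nodes with
#'   no out-weight teleport with probability 1.
#' @return A `flow_graph`: weights, teleportation rate, node names.
#' @export
flow_graph <- function(C, teleport = 0.01) {
  w <- unclass(C)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0)) stop("negative edge weights", call. = FALSE)
  if (all(w == 0)) stop("graph needs at least one edge", call. = FALSE)
  if (teleport < 0 || teleport >= 1)
    stop("teleport must be in [0, 1)", call. = FALSE)
  nm <- rownames(w) %||% as.character(seq_len(nrow(w)))
  structure(list(w = w, teleport = teleport, names = nm,
                 n = nrow(w)), class = "flow_graph")
}

# Full transition matrix including teleportation; dangling rows are pure
# teleportation.
.transition_matrix <- function(graph) {
  w <- graph$w; n <- graph$n; tau <- graph$teleport
  rs <- rowSums(w)
  P <- matrix(1 / n, n, n)
  live <- rs > 0
  P[live, ] <- (1 - tau) * w[live, , drop = FALSE] / rs[live] + tau / n
  P
}

#' Stationary visit rates of the teleportation-adjusted random walk
#'
#' Power iteration on the row-normalised transition matrix mixed with
#' uniform teleportation, to an L1 tolerance of 1e-12.
#'
#' @param graph a [flow_graph()].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap (error if exceeded).
#' @return Numeric visit-rate vector summing to 1, with the full transition
#'   matrix in attribute `"transition"`.
#' @export
stationary_distribution <- function(graph, tol = 1e-12, max_iter = 100000L) {
  P <- .transition_matrix(graph)
  n <- graph$n
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- as.vector(p %*% P)
    p_new <- p_new / sum(p_new)
    if (sum(abs(p_new - p)) < tol) {
      names(p_new) <- graph$names
      attr(p_new, "transition") <- P
      return(p_new)
    }
    p <- p_new
  }
  stop("stationary distribution did not converge after ", max_iter,
       " iterations", call. = FALSE)
}

#' Two-level map-equation codelength
#'
#' Average per-step description length, in bits, of the teleportation-
#' adjusted random walk under a two-level coding with one index codebook
#' over modules and one codebook per module:
#' `L(M) = q * H(Q) + sum_m p_m * H(P_m)`, with module exit rates and
#' visit rates computed from the stationary flows; entropies are base-2
#' with `0 log 0 = 0`.
#'
#' @param graph a [flow_graph()].
#' @param partition integer module id per node (modules non-empty).
#' @param p optional precomputed [stationary_distribution()] (with its
#'   transition-matrix attribute); recomputed if missing.
#' @return Codelength in bits.
#' @export
map_equation <- function(graph, partition, p = NULL) {
  n <- graph$n
  stopifnot(length(partition) == n)
  mods <- sort(unique(partition))
  if (!all(seq_len(max(partition)) %in% mods))
    stop("empty module in partition", call. = FALSE)
  if (is.null(p)) p <- stationary_distribution(graph)
  P <- attr(p, "transition")
  flow <- as.vector(p) * P                # flow[i, j] = p_i P_ij
  .codelength_from_flow(as.vector(p), flow, partition)
}

# Core codelength computation from node visit rates and the flow matrix.
.codelength_from_flow <- function(p, flow, partition) {
  mods <- sort(unique(partition))
  q_m <- vapply(mods, function(m) {
    inm <- partition == m
    sum(flow[inm, !inm, drop = FALSE])
  }, numeric(1))
  p_m <- vapply(mods, function(m) sum(p[partition == m]), numeric(1))
  q <- sum(q_m)
  # index codebook term
  idx <- if (q > 0) q * (-sum(.plog2p(q_m / q))) else 0
  # module codebook terms
  mod <- 0
  for (mi in seq_along(mods)) {
    tot <- q_m[mi] + p_m[mi]
    if (tot <= 0) next
    probs <- c(q_m[mi], p[partition == mods[mi]]) / tot
    mod <- mod + tot * (-sum(.plog2p(probs)))
  }
  idx + mod
}

# Relabel a partition contiguously from 1 by order of first appearance.
.relabel <- function(m) match(m, unique(m))

#' Optimise a partition by minimising the map equation
#'
#' Greedy node-moving (each node tried in the modules of its graph
#' neighbours and in a fresh singleton; the best codelength decrease is
#' accepted, ties broken by lowest module id), alternated with pairwise
#' module merges, repeated to a local minimum; the best of `n_restarts`
#' seeded restarts (differing in node visit order) is returned, and is
#' never worse than the all-in-one-module partition.
#'
#' @param graph a [flow_graph()].
#' @param seed integer seed (node visit order).
#' @param n_restarts number of restarts (default 10).
#' @return A `partition`: list with `modules` (integer id per node,
#'   contiguous from 1), `codelength` (bits), `n_modules`.
#' @export
optimize_partition <- function(graph, seed = 1L, n_restarts = 10L) {
  p <- stationary_distribution(graph)
  P <- attr(p, "transition")
  pv <- as.vector(p)
  flow <- pv * P
  n <- graph$n
  nbr <- lapply(seq_len(n), function(v) {
    which((graph$w[v, ] > 0 | graph$w[, v] > 0) & seq_len(n) != v)
  })
  cl <- function(m) .codelength_from_flow(pv, flow, .relabel(m))

  refine <- function(m, order_fun) {
    best <- cl(m)
    repeat {
      improved <- FALSE
      # node-moving pass
      for (v in order_fun()) {
        cand <- sort(unique(c(m[nbr[[v]]], m[v], max(m) + 1L)))
        cur <- m[v]
        for (cm in cand) {
          if (cm == cur) next
          m2 <- m; m2[v] <- cm
          val <- cl(m2)
          if (val < best - 1e-13) {
            best <- val; m <- m2; cur <- cm; improved <- TRUE
          }
        }
      }
      # pairwise module merges
      repeat {
        mods <- sort(unique(m))
        if (length(mods) < 2L) break
        gain <- FALSE
        for (a in seq_along(mods)[-length(mods)]) {
          for (b in seq((a + 1), length(mods))) {
            m2 <- m; m2[m2 == mods[b]] <- mods[a]
            val <- cl(m2)
            if (val < best - 1e-13) {
              best <- val; m <- m2; gain <- TRUE
            }
          }
          if (gain) break
        }
        if (!gain) break
      }
      if (!improved) break
    }
    list(m = .relabel(m), codelength = best)
  }

  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      res <- refine(seq_len(n), function() sample.int(n))
      if (is.null(best) || res$codelength < best$codelength - 1e-13)
        best <- res
    }
  })
  one <- cl(rep(1L, n))
  if (one < best$codelength - 1e-13)
    best <- list(m = rep(1L, n), codelength = one)
  structure(list(modules = best$m, codelength = best$codelength,
                 n_modules = max(best$m), names = graph$names),
            class = "partition")
}

#' Partition every replicate of a bootstrap ensemble
#'
#' @param ensemble a [bootstrap_ensemble()].
#' @param teleport teleportation probability (default 0.01).
#' @param n_restarts optimiser restarts per replicate.
#' @param seed master seed; each replicate gets a deterministic child seed.
#' @return List with `partitions` (list of [optimize_partition()] results)
#'   and `flows` (list of stationary visit-rate vectors).
#' @export
partition_ensemble <- function(ensemble, teleport = 0.01, n_restarts = 10L,
                               seed = 1L) {
  n_rep <- ensemble$n_rep
  partitions <- vector("list", n_rep)
  flows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    g <- flow_graph(ensemble$matrices[r, , ], teleport = teleport)
    partitions[[r]] <- optimize_partition(
      g, seed = split_seed(seed, paste0("replicate_", r)),
      n_restarts = n_restarts)
    flows[[r]] <- as.vector(stationary_distribution(g))
  }
  list(partitions = partitions, flows = flows,
       unit_names = ensemble$unit_names)
}

#' Canonicalise module labels across replicates
#'
#' Module ids from independent optimiser runs are arbitrary; within each
#' replicate, modules are renumbered 1..K in decreasing total stationary
#' flow (ties to the lowest original id), which makes the ids comparable
#' across replicates while preserving co-assignment structure exactly.
#'
#' @param partitions list of [optimize_partition()] results (or integer
#'   vectors), all over the same node set.
#' @param flows list of stationary visit-rate vectors, one per replicate.
#' @return A `membership_matrix`: integer matrix (groups x replicates) of
#'   canonical module ids.
#' @export
canonicalise_labels <- function(partitions, flows) {
  n_rep <- length(partitions)
  stopifnot(n_rep >= 1L, length(flows) == n_rep)
  get_mod <- function(p) if (is.list(p)) p$modules else p
  n <- length(get_mod(partitions[[1]]))
  M <- matrix(NA_integer_, n, n_rep)
  for (r in seq_len(n_rep)) {
    m <- get_mod(partitions[[r]])
    ids <- sort(unique(m))
    fl <- vapply(ids, function(k) sum(flows[[r]][m == k]), numeric(1))
    rank <- ids[order(-fl, ids)]
    M[, r] <- match(m, rank)
  }
  rownames(M) <- if (is.list(partitions[[1]]) &&
                     !is.null(partitions[[1]]$names))
    partitions[[1]]$names else NULL
  class(M) <- c("membership_matrix", class(M))
  M
}

#' Consistency PCA of module membership
#'
#' Centred (not scaled) principal component analysis of the canonical
#' module-id matrix, with reef groups as observations and replicates as
#' variables. The first component captures the dominant axis of clustering
#' variability: groups far apart on PC1 are consistently placed in
#' different modules across the stochastic ensemble, so PC1 separation is a
#' proxy for a persistent dispersal barrier.
#'
#' @param membership a [canonicalise_labels()] matrix (groups x
#'   replicates), needing at least 2 replicates.
#' @return A `consistency_pca`: `explained_variance_ratio` (non-increasing,
#'   in `[0, 1]`, summing to 1), `scores` (groups x PCs), and
#'   `zero_variance` flag (TRUE when all replicates agree on a single
#'   module, in which case ratios/scores are NA rather than NaN).
#' @export
consistency_pca <- function(membership) {
  X <- unclass(membership)
  stopifnot(ncol(X) >= 2L)
  storage.mode(X) <- "double"
  if (all(apply(X, 2, stats::var) == 0)) {
    return(structure(list(explained_variance_ratio = NA_real_,
                          scores = NULL, zero_variance = TRUE),
                     class = "consistency_pca"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(explained_variance_ratio = evr, scores = pc$x,
                 zero_variance = FALSE),
            class = "consistency_pca")
}
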