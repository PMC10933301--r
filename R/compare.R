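# Comparison of modelled larval flow against an observed gene-flow
# (migration-rate) matrix across the stochastic connectivity ensemble.

#' Align gene-flow sites with reef groups
#'
#' Validates a user-supplied site-to-group mapping as a bijection onto a
#' subset of reef groups.
#'
#' @param geneflow a gene-flow matrix with site dimnames.
#' @param reef a [make_reef_grid()] object.
#' @param mapping named integer vector: `mapping[site] = group id`. By
#'   default, sites named `group_k` map to group `k`.
#' @return Named integer vector (one group per site), validated.
#' @export
align_sites <- function(geneflow, reef, mapping = NULL) {
  sites <- rownames(geneflow)
  if (is.null(mapping)) {
    mapping <- stats::setNames(match(sites,
                                     sprintf("group_%02d",
                                             seq_len(reef$n_groups))),
                               sites)
  }
  missing <- sites[!sites %in% names(mapping) | is.na(mapping[sites])]
  if (length(missing) > 0L)
    stop("unmapped gene-flow sites: ", paste(missing, collapse = ", "),
         call. = FALSE)
  mapping <- mapping[sites]
  if (anyDuplicated(mapping))
    stop("duplicate target reef groups in site mapping", call. = FALSE)
  if (any(mapping < 1L | mapping > reef$n_groups))
    stop("mapped group ids outside 1..", reef$n_groups, call. = FALSE)
  mapping
}

#' Compare modelled larval flow with observed gene flow, per site pair
#'
#' For every ordered pair of sampled sites, summarises the full ensemble of
#' modelled connectivity values (min/max and 2.5/97.5% quantiles — the
#' feasible range under stochastic oceanographic variability), the observed
#' migration rate, their log10 ratio, the pairwise distance, and whether
#' the observation exceeds the ensemble maximum. Gene flow is taken as-is
#' (per-generation migration proportions); no demographic conversion is
#' attempted, so the comparison is about orders of magnitude and ranges.
#'
#' @param ensemble a [bootstrap_ensemble()] at group level.
#' @param geneflow observed site-by-site migration-rate matrix.
#' @param reef a [make_reef_grid()] object (for distances).
#' @param mapping site-to-group mapping (see [align_sites()]).
#' @return A `pair_comparison` data frame: site_from, site_to, observed,
#'   model_median, model_min, model_max, model_q025, model_q975,
#'   log10_ratio (observed / ensemble median), distance,
#'   exceeds_ensemble_max. Ordered off-diagonal pairs only.
#' @export
compare_pairs <- function(ensemble, geneflow, reef, mapping = NULL) {
  validate_geneflow(unclass(geneflow))
  mapping <- align_sites(geneflow, reef, mapping)
  sites <- names(mapping)
  cen <- group_centroids(reef)
  rows <- list()
  for (a in seq_along(sites)) for (b in seq_along(sites)) {
    if (a == b) next
    ga <- mapping[a]; gb <- mapping[b]
    vals <- ensemble$matrices[, ga, gb]
    qs <- stats::quantile(vals, c(0.025, 0.5, 0.975), names = FALSE,
                          type = 7)
    obs <- unclass(geneflow)[a, b]
    dx <- cen$x[cen$group == ga] - cen$x[cen$group == gb]
    dy <- cen$y[cen$group == ga] - cen$y[cen$group == gb]
    rows[[length(rows) + 1L]] <- data.frame(
      site_from = sites[a], site_to = sites[b],
      observed = obs,
      model_median = qs[2], model_min = min(vals), model_max = max(vals),
      model_q025 = qs[1], model_q975 = qs[3],
      log10_ratio = if (qs[2] > 0 && obs > 0) log10(obs / qs[2]) else NA_real_,
      distance = sqrt(dx^2 + dy^2),
      exceeds_ensemble_max = obs > max(vals)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pair_comparison", class(out))
  out
}

#' Gene-flow matrix simulated from a connectivity ensemble
#'
#' Closed-loop fixture: builds an "observed" migration matrix whose
#' off-diagonal entries equal the ensemble-mean modelled connectivity for
#' each site pair and whose diagonal is the residual (self-recruitment as
#' the remainder to a row sum of 1). Useful for verifying that when the
#' observations truly come from the model, they fall inside the modelled
#' feasible range.
#'
#' @param ensemble a [bootstrap_ensemble()].
#' @param mapping named integer vector `site -> group` (defaults to all
#'   groups, named `group_k`).
#' @return A `gene_flow_matrix`.
#' @export
geneflow_from_ensemble <- function(ensemble, mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- stats::setNames(seq_along(ensemble$unit_names),
                               ensemble$unit_names)
  }
  n <- length(mapping)
  m <- matrix(0, n, n, dimnames = list(names(mapping), names(mapping)))
  mean_C <- apply(ensemble$matrices, c(2, 3), mean)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b) m[a, b] <- mean_C[mapping[a], mapping[b]]
  }
  diag(m) <- 1 - rowSums(m)
  if (any(diag(m) <= 0))
    stop("off-diagonal connectivity too large for a residual diagonal",
         call. = FALSE)
  class(m) <- c("gene_flow_matrix", class(m))
  m
}
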