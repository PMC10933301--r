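# End-to-end pipeline: synthetic inputs -> advection -> larval fate ->
# connectivity matrices -> seasonal subset -> bootstrap ensemble ->
# map-equation partitioning -> consistency PCA -> (optional) gene-flow
# comparison, with a manifest recording seeds and artifact hashes.

#' Default pipeline configuration
#'
#' A complete, runnable demo configuration: a double-gyre ocean with two
#' planted reef clusters (three reef groups on one orbit per gyre), a
#' 30-day pelagic window and a modest ensemble. All constants with a
#' scientific default (120-day cap, 60-event cap, October-March season,
#' 1000x10 bootstrap, 1% teleportation) live here; the demo scales the run
#' sizes down, not the biology.
#'
#' @param seed master seed; every stage derives a child seed from it.
#' @return Nested configuration list (YAML-compatible).
#' @export
default_config <- function(seed = 1L) {
  L <- 100e3
  orbit <- function(x0, r, angles) {
    cbind(x0 + r * cos(angles), L / 2 + r * sin(angles))
  }
  centres <- rbind(
    orbit(L / 2, 0.3 * L, c(0, 2, 4) * pi / 3),
    orbit(3 * L / 2, 0.3 * L, c(1, 3, 5) * pi / 3)
  )
  list(
    seed = seed,
    ocean = list(type = "double_gyre", amplitude = 0.3, perturbation = 0,
                 period = 10, L = L, nx = 80, ny = 40,
                 time_step_days = 1.25),
    reefs = list(cluster_centres = centres, cells_per_cluster = 10L),
    calendar = list(start = "2018-10-01", end = "2019-03-31",
                    months_allowed = c(10:12, 1:3), sample_dates = 12L),
    larvae = list(alpha = 0.5, t_c = 1, beta = 0.02, mu_s = 0.2,
                  mortality = list(type = "constant", rate = 0.05),
                  rho = 1, T_max = 30, max_events = 60L),
    advection = list(dt = 0.05, n_per_cell = 3L, jitter = 1),
    connectivity = list(n_rep = 100L, k = 10L, replace = TRUE),
    partitioning = list(teleport = 0.01, n_restarts = 5L),
    compare = list(geneflow = NULL)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields missing from the file fall back to
#'   [default_config()] values.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(user$seed %||% 1L)
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_lists(base, user)
  if (!is.null(cfg$reefs$cluster_centres) &&
      is.list(cfg$reefs$cluster_centres))
    cfg$reefs$cluster_centres <-
      do.call(rbind, lapply(cfg$reefs$cluster_centres, unlist))
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Build the synthetic inputs a configuration describes
#'
#' @param config a [default_config()]-style list.
#' @return List: `field`, `reef`, `calendar`, `params`, `dates` (the
#'   possibly thinned spawning dates actually simulated).
#' @export
build_inputs <- function(config) {
  oc <- config$ocean
  cal <- .stage("calendar", make_spawning_calendar(
    config$calendar$start, config$calendar$end,
    months_allowed = config$calendar$months_allowed))
  dates <- cal$dates
  ns <- config$calendar$sample_dates
  if (!is.null(ns) && ns < length(dates))
    dates <- dates[round(seq(1, length(dates), length.out = ns))]
  t0 <- as.numeric(min(dates))
  t1 <- as.numeric(max(dates)) + config$larvae$T_max
  field <- .stage("ocean", {
    grid <- regular_grid(c(0, 2 * oc$L), c(0, oc$L), oc$nx, oc$ny)
    times <- seq(t0, t1 + oc$time_step_days, by = oc$time_step_days)
    switch(oc$type,
      double_gyre = make_double_gyre(oc$amplitude, oc$perturbation, grid,
                                     times = times, L = oc$L,
                                     period = oc$period),
      uniform = make_uniform_field(oc$amplitude, oc$bearing %||% 90, grid,
                                   times = times),
      stop("unknown ocean type: ", oc$type))
  })
  reef <- .stage("reefs", make_reef_grid(
    field$grid, config$reefs$cluster_centres,
    config$reefs$cells_per_cluster,
    seed = split_seed(config$seed, "reef_grid")))
  params <- .stage("larvae", do.call(larval_params, config$larvae))
  list(field = field, reef = reef, calendar = cal, params = params,
       dates = dates)
}

#' Simulate dated connectivity matrices
#'
#' Advects a release from every reef cell on each spawning date, integrates
#' larval fate, extracts settling events and accumulates one group-level
#' connectivity matrix per date.
#'
#' @param inputs a [build_inputs()] result.
#' @param config the configuration.
#' @return Named list of group-level `connectivity_matrix`, one per date.
#' @export
simulate_connectivity <- function(inputs, config) {
  adv <- config$advection
  lapply(stats::setNames(seq_along(inputs$dates),
                         as.character(inputs$dates)), function(i) {
    date <- inputs$dates[i]
    rel <- make_release(inputs$reef, n_per_cell = adv$n_per_cell,
                        date = date, jitter = adv$jitter %||% 0,
                        seed = split_seed(config$seed,
                                          paste0("release_", i)))
    traj <- advect(inputs$field, rel, dt = adv$dt,
                   T_max = inputs$params$T_max)
    fr <- sample_reef_fraction(traj, inputs$reef)
    fate <- integrate_fate(fr, traj$times, inputs$params)
    ev <- settle_events(traj, fate, inputs$reef, inputs$params)
    accumulate_connectivity(ev, inputs$reef, inputs$params,
                            level = "group", date = date)
  })
}

#' Run the full pipeline
#'
#' Chains input generation, simulation, seasonal subsetting, bootstrap
#' ensemble construction, map-equation partitioning with consistency PCA,
#' and (when a gene-flow matrix is configured) the model-vs-gene-flow
#' comparison. All artifacts are written under `out_dir` as plain text,
#' and `manifest.json` records the configuration, the seeds, and an md5
#' hash of every artifact, so byte-identical reruns are verifiable.
#'
#' @param config configuration list (see [default_config()]) or a path to
#'   a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all in-memory results (`inputs`,
#'   `matrices`, `ensemble`, `partitions`, `membership`, `pca`,
#'   `comparison`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- build_inputs(config)
  matrices <- .stage("simulate", simulate_connectivity(inputs, config))
  matrices <- .stage("seasonal_subset",
                     seasonal_subset(matrices,
                                     months = config$calendar$months_allowed))
  ensemble <- .stage("bootstrap", bootstrap_ensemble(
    matrices, n_rep = config$connectivity$n_rep,
    k = config$connectivity$k,
    seed = split_seed(config$seed, "bootstrap"),
    replace = config$connectivity$replace %||% TRUE))
  part <- .stage("cluster", partition_ensemble(
    ensemble, teleport = config$partitioning$teleport,
    n_restarts = config$partitioning$n_restarts,
    seed = split_seed(config$seed, "partition")))
  membership <- canonicalise_labels(part$partitions, part$flows)
  rownames(membership) <- ensemble$unit_names
  pca <- consistency_pca(membership)

  comparison <- NULL
  gf_cfg <- config$compare$geneflow
  if (!is.null(gf_cfg)) {
    comparison <- .stage("compare", {
      gf <- if (is.character(gf_cfg)) read_geneflow_csv(gf_cfg)
            else gf_cfg
      compare_pairs(ensemble, gf, inputs$reef)
    })
  }

  # artifacts
  paths <- c(
    field = file.path(out_dir, "field.json"),
    reef = file.path(out_dir, "reef.json"),
    ensemble = file.path(out_dir, "ensemble.json"),
    membership = file.path(out_dir, "membership.csv"),
    pca = file.path(out_dir, "pca_summary.json")
  )
  write_velocity_field(inputs$field, paths["field"])
  write_reef_grid(inputs$reef, paths["reef"])
  dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE)
  for (nm in names(matrices)) {
    p <- file.path(out_dir, "matrices", paste0(nm, ".csv"))
    write_connectivity_csv(matrices[[nm]], p)
    paths[paste0("matrix_", nm)] <- p
  }
  write_ensemble(ensemble, paths["ensemble"])
  utils::write.csv(as.data.frame(unclass(membership)), paths["membership"])
  .write_json(list(
    explained_variance_ratio = pca$explained_variance_ratio,
    zero_variance = pca$zero_variance,
    pc1_scores = if (!is.null(pca$scores))
      stats::setNames(as.list(pca$scores[, 1]), rownames(membership))
  ), paths["pca"])
  if (!is.null(comparison)) {
    paths["comparison"] <- file.path(out_dir, "comparison.csv")
    utils::write.csv(comparison, paths["comparison"], row.names = FALSE)
  }

  manifest <- list(
    package = "reefconn",
    version = as.character(utils::packageVersion("reefconn")),
    seed = config$seed,
    derived_seeds = list(
      reef_grid = split_seed(config$seed, "reef_grid"),
      bootstrap = split_seed(config$seed, "bootstrap"),
      partition = split_seed(config$seed, "partition")
    ),
    config = config,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(unname(paths))), names(paths)))
  )
  .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(inputs = inputs, matrices = matrices, ensemble = ensemble,
                 partitions = part, membership = membership, pca = pca,
                 comparison = comparison, manifest = manifest,
                 out_dir = out_dir))
}
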