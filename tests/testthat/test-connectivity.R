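test_that("connectivity accumulation is exact arithmetic and conserves mass", {
  g <- fix_grid()
  reef <- make_reef_grid(g, rbind(c(25e3, 25e3), c(75e3, 75e3)), 2,
                         seed = 21)
  p <- larval_params(0.5, 0, 0.05, 0.2)

  # no events: zero matrix
  empty <- data.frame(particle = integer(), source_cell = integer(),
                      source_group = integer(), event = integer(),
                      dest_cell = integer(), dest_group = integer(),
                      tau0 = numeric(), dtau = numeric(),
                      fr_dest = numeric(), settled = numeric())
  C0 <- accumulate_connectivity(empty, reef, p, level = "cell")
  expect_true(all(C0 == 0))

  # single event with S = 0.25 * rho * A_i (N = 1): C[i, j] = 0.25
  i <- reef$cells$cell[1]; j <- reef$cells$cell[3]
  ev <- data.frame(particle = 1L, source_cell = i,
                   source_group = reef$cells$group[1], event = 1L,
                   dest_cell = j, dest_group = reef$cells$group[3],
                   tau0 = 1, dtau = 2, fr_dest = reef$cells$fr[3],
                   settled = 0.25 * p$rho * reef$cells$area[1])
  C1 <- accumulate_connectivity(ev, reef, p, level = "cell")
  expect_equal(unclass(C1)[as.character(i), as.character(j)], 0.25)
  expect_equal(sum(C1), 0.25)
})

test_that("group aggregation is area-weighted and agrees with direct accumulation", {
  cfg <- fix_config(seed = 3)
  inputs <- build_inputs(cfg)
  rel <- make_release(inputs$reef, n_per_cell = 2, date = inputs$dates[1],
                      jitter = 1, seed = 8)
  tr <- advect(inputs$field, rel, dt = 0.05, T_max = inputs$params$T_max)
  fr <- sample_reef_fraction(tr, inputs$reef)
  fate <- integrate_fate(fr, tr$times, inputs$params)
  ev <- settle_events(tr, fate, inputs$reef, inputs$params)
  expect_gt(nrow(ev), 0)

  Cc <- accumulate_connectivity(ev, inputs$reef, inputs$params, "cell",
                                date = inputs$dates[1])
  Cg <- accumulate_connectivity(ev, inputs$reef, inputs$params, "group",
                                date = inputs$dates[1])
  Cagg <- aggregate_to_groups(Cc, inputs$reef)
  expect_equal(unclass(Cagg), unclass(Cg), tolerance = 1e-12)

  # settled proportion cannot exceed released
  expect_true(all(rowSums(Cc) <= 1 + 1e-12))
  expect_true(all(rowSums(Cg) <= 1 + 1e-12))
  expect_true(all(unclass(Cg) >= 0))
})

test_that("seasonal subsetting keeps only the spawning months", {
  mk <- function(date) {
    m <- matrix(1, 2, 2)
    structure(m, date = as.Date(date), level = "group",
              class = c("connectivity_matrix", class(m)))
  }
  pool <- lapply(c("2018-07-01", "2018-07-15"), mk)
  expect_error(seasonal_subset(pool), "spawning season")

  dates <- c("2018-10-05", "2018-11-05", "2018-12-05", "2019-01-05",
             "2019-02-05", "2019-03-05", "2019-06-05", "2019-08-05")
  pool2 <- lapply(dates, mk)
  kept <- seasonal_subset(pool2)
  expect_equal(length(kept), 6L)
  # invariant to input ordering
  kept_rev <- seasonal_subset(rev(pool2))
  expect_setequal(vapply(kept, function(m) as.character(attr(m, "date")), ""),
                  vapply(kept_rev, function(m) as.character(attr(m, "date")), ""))
})

test_that("bootstrap ensembles resample the pool correctly", {
  mk <- function(v, date) {
    m <- matrix(v, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
    structure(m, date = as.Date(date), level = "group",
              class = c("connectivity_matrix", class(m)))
  }
  # identical pool: every replicate equals the common matrix
  pool_same <- lapply(1:5, function(i) mk(0.1, "2018-10-01"))
  ens <- bootstrap_ensemble(pool_same, n_rep = 10, k = 4, seed = 1)
  expect_true(all(ens$matrices == 0.1))

  # k = 1: replicates are single resampled dates
  withr::with_seed(99, vals <- runif(6))
  pool <- lapply(seq_along(vals),
                 function(i) mk(vals[i], sprintf("2018-10-%02d", i)))
  ens1 <- bootstrap_ensemble(pool, n_rep = 50, k = 1, seed = 2)
  expect_true(all(ens1$matrices[, 1, 1] %in% vals))

  # same seed, same ensemble; no replacement with tiny pool errors
  ens1b <- bootstrap_ensemble(pool, n_rep = 50, k = 1, seed = 2)
  expect_identical(ens1$matrices, ens1b$matrices)
  expect_error(bootstrap_ensemble(pool, n_rep = 5, k = 10, seed = 1,
                                  replace = FALSE), "pool smaller")

  # law of large numbers: mean of replicate means matches the pool mean
  ens10 <- bootstrap_ensemble(pool, n_rep = 400, k = 10, seed = 3)
  reps <- ens10$matrices[, 1, 1]
  expect_lt(abs(mean(reps) - mean(vals)), 3 * sd(reps) / sqrt(400))
})

test_that("distance decay tables carry hand-computed distances", {
  g <- fix_grid()
  reef <- make_reef_grid(g, rbind(c(20e3, 20e3), c(80e3, 20e3),
                                  c(20e3, 80e3)), 1, seed = 7)
  cen <- group_centroids(reef)
  C <- matrix(0.1, 3, 3, dimnames = list(sprintf("group_%02d", 1:3),
                                         sprintf("group_%02d", 1:3)))
  C <- structure(C, level = "group",
                 class = c("connectivity_matrix", class(C)))
  dd <- distance_decay(C, reef)
  expect_equal(nrow(dd), 6L)               # 3 groups, directed off-diagonal
  d12 <- dd$distance[dd$source == 1 & dd$dest == 2]
  expect_equal(d12, sqrt((cen$x[1] - cen$x[2])^2 + (cen$y[1] - cen$y[2])^2))
  # symmetric distances
  expect_equal(d12, dd$distance[dd$source == 2 & dd$dest == 1])

  # diffusive decay: connectivity falls with distance (rank test)
  reef6 <- make_reef_grid(g, cbind(seq(15e3, 85e3, length.out = 5), 50e3),
                          1, seed = 8)
  cen6 <- group_centroids(reef6)
  D <- as.matrix(dist(cen6[, c("x", "y")]))
  Cd <- exp(-D / 30e3) * 0.05
  dimnames(Cd) <- list(sprintf("group_%02d", 1:5),
                       sprintf("group_%02d", 1:5))
  Cd <- structure(Cd, level = "group",
                  class = c("connectivity_matrix", class(Cd)))
  dd6 <- distance_decay(Cd, reef6)
  expect_lt(suppressWarnings(
    cor(dd6$distance, dd6$connectivity, method = "spearman")), 0)
})

test_that("generations-to-common-ancestor follows the colonisation graph", {
  nm <- c("a", "b", "c")
  C <- matrix(0, 3, 3, dimnames = list(nm, nm))
  C[1, 2] <- 0.1; C[2, 3] <- 0.1           # chain a -> b -> c
  diag(C)[1] <- 0.5                        # a self-recruits
  G <- generations_to_common_ancestor(C, eps = 0.01)
  expect_equal(G["a", "a"], 0)             # self-recruitment >= eps
  expect_equal(G["b", "c"], 2)             # common ancestor a, two steps
  expect_equal(G["a", "b"], 1)

  # disconnected components never share an ancestor
  C2 <- diag(c(0.5, 0.5, 0.5, 0.5))
  C2[1, 2] <- C2[2, 1] <- 0.2
  C2[3, 4] <- C2[4, 3] <- 0.2
  G2 <- generations_to_common_ancestor(C2, eps = 0.01)
  expect_true(is.infinite(G2[1, 3]) && is.infinite(G2[2, 4]))
  expect_true(is.finite(G2[1, 2]) && is.finite(G2[3, 4]))

  expect_error(generations_to_common_ancestor(C, eps = 0), "eps")
})
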