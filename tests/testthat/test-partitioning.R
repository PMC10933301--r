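test_that("stationary visit rates match symmetry and a dense linear solve", {
  # symmetric 2-node graph, no teleportation: (0.5, 0.5)
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  p <- stationary_distribution(flow_graph(W, teleport = 0))
  expect_equal(as.vector(p), c(0.5, 0.5))

  # star graph with 1% teleportation vs direct linear solve
  n <- 6
  Ws <- matrix(0, n, n)
  Ws[1, 2:n] <- 1; Ws[2:n, 1] <- 1
  g <- flow_graph(Ws, teleport = 0.01)
  p2 <- stationary_distribution(g)
  P <- attr(p2, "transition")
  # solve p (P - I) = 0 with sum(p) = 1
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  p_ref <- qr.solve(A, b)
  expect_equal(as.vector(p2), p_ref, tolerance = 1e-10)

  # all-dangling graph (self-loops only count as out-flow, so zero all):
  # pure teleportation gives the uniform distribution
  Wd <- matrix(0, 4, 4); Wd[1, 1] <- 1   # one self-loop, rest dangling
  pd <- stationary_distribution(flow_graph(Wd, teleport = 0.01))
  expect_true(all(pd > 0))
  expect_equal(sum(pd), 1)

  expect_error(flow_graph(matrix(0, 3, 3)), "at least one edge")
  expect_error(flow_graph(matrix(-1, 2, 2)), "negative")
})

test_that("the codelength matches hand values and an independent evaluation", {
  # uniform 4-cycle, one module, no teleportation: exactly 2 bits
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 3] <- W[3, 4] <- W[4, 1] <- 1
  g <- flow_graph(W, teleport = 0)
  expect_equal(map_equation(g, rep(1L, 4)), 2)

  expect_error(map_equation(g, c(1L, 1L, 3L, 3L)), "empty module")

  # independent second implementation agrees to 1e-12 bits across random
  # graphs and random partitions
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(3:8, 1)
      Wr <- matrix(rexp(n * n) * (matrix(runif(n * n), n) < 0.6), n)
      diag(Wr) <- diag(Wr) * (runif(n) < 0.5)
      if (all(Wr == 0)) Wr[1, 2] <- 1
      gr <- flow_graph(Wr, teleport = 0.01)
      part <- sample(1:2, n, replace = TRUE)
      part <- match(part, unique(part))
      expect_equal(map_equation(gr, part),
                   codelength_ref(Wr, 0.01, part), tolerance = 1e-12)
    }
  })

  # with zero flow between two cliques, the separated partition codes the
  # walk at least as cheaply as the merged one (no exit terms to pay)
  Wc <- matrix(0, 8, 8)
  Wc[1:4, 1:4] <- 1; Wc[5:8, 5:8] <- 1; diag(Wc) <- 0
  gc <- flow_graph(Wc, teleport = 0)
  expect_lte(map_equation(gc, rep(1:2, each = 4L)),
             map_equation(gc, rep(1L, 8)))
})

test_that("the optimiser matches exhaustive enumeration on small graphs", {
  graphs <- list(
    two_cliques = {
      W <- matrix(0, 8, 8); W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
      diag(W) <- 0; W
    },
    weak_join = {
      W <- matrix(0, 8, 8); W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
      diag(W) <- 0; W[4, 5] <- W[5, 4] <- 0.1; W
    },
    complete_uniform = { W <- matrix(1, 6, 6); diag(W) <- 0; W },
    cycle6 = { W <- matrix(0, 6, 6)
               for (i in 1:6) W[i, i %% 6 + 1] <- 1; W },
    two_triangles_bridge = {
      W <- matrix(0, 6, 6); W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
      diag(W) <- 0; W[3, 4] <- 0.2; W[4, 3] <- 0.2; W
    }
  )
  withr::with_seed(11, {
    for (n in 5:8) {
      blocks <- rep(1:2, length.out = n)
      W <- matrix(rexp(n * n), n) *
        ifelse(outer(blocks, blocks, "==") , 0.9, 0.08)
      diag(W) <- 0
      graphs[[paste0("planted", n)]] <- W
    }
  })
  for (nm in names(graphs)) {
    g <- flow_graph(graphs[[nm]], teleport = 0.01)
    p <- stationary_distribution(g)
    best <- min(vapply(setparts(g$n),
                       function(m) map_equation(g, m, p = p), numeric(1)))
    opt <- optimize_partition(g, seed = 13)
    expect_equal(opt$codelength, best, tolerance = 1e-12,
                 label = paste("codelength on", nm))
    expect_lte(opt$codelength, map_equation(g, rep(1L, g$n)))
  }

  # recovers the planted two-clique split
  gcl <- flow_graph(graphs$two_cliques, teleport = 0.01)
  opt <- optimize_partition(gcl, seed = 1)
  expect_equal(opt$modules, rep(1:2, each = 4L))

  # determinism
  expect_identical(optimize_partition(gcl, seed = 5),
                   optimize_partition(gcl, seed = 5))
})

test_that("label canonicalisation orders modules by flow and preserves co-assignment", {
  flows <- list(c(0.1, 0.1, 0.1, 0.25, 0.25, 0.2))
  # module B carries more flow than A: canonical ids must swap
  part <- list(c(2L, 2L, 2L, 1L, 1L, 1L))
  M <- canonicalise_labels(part, flows)
  expect_equal(as.vector(M[, 1]), c(2L, 2L, 2L, 1L, 1L, 1L))

  # identical partitions under permuted labels give identical rows
  part2 <- list(c(1L, 1L, 2L, 2L, 3L, 3L), c(3L, 3L, 1L, 1L, 2L, 2L))
  flows2 <- rep(list(c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1)), 2)
  M2 <- canonicalise_labels(part2, flows2)
  expect_equal(M2[, 1], M2[, 2])

  # co-membership structure is exactly preserved
  co <- function(v) outer(v, v, "==")
  for (r in 1:2) expect_equal(co(M2[, r]), co(part2[[r]]))
})

test_that("consistency PCA separates stable blocks and flags degeneracy", {
  # perfectly stable two-block membership: PC1 explains everything and
  # separates the blocks into two distinct score values
  M <- matrix(rep(c(1L, 1L, 1L, 2L, 2L, 2L), 40), ncol = 40)
  pca <- consistency_pca(M)
  expect_false(pca$zero_variance)
  expect_equal(pca$explained_variance_ratio[1], 1)
  s <- pca$scores[, 1]
  expect_equal(length(unique(round(s, 9))), 2L)
  expect_true(max(s[1:3]) < min(s[4:6]) || max(s[4:6]) < min(s[1:3]))

  # one noisy replicate: PC1 < 1 but block ordering preserved
  Mn <- M; Mn[, 40] <- c(1L, 2L, 1L, 2L, 1L, 2L)
  pcan <- consistency_pca(Mn)
  expect_lt(pcan$explained_variance_ratio[1], 1)
  sn <- pcan$scores[, 1]
  expect_true(max(sn[1:3]) < min(sn[4:6]) || max(sn[4:6]) < min(sn[1:3]))

  # column permutation leaves explained variance unchanged
  perm <- c(40:1)
  expect_equal(consistency_pca(Mn[, perm])$explained_variance_ratio,
               pcan$explained_variance_ratio)

  # all-identical single-module membership: flagged, not NaN
  expect_true(consistency_pca(matrix(1L, 4, 10))$zero_variance)
})
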