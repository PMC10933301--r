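test_that("mortality hazard modes agree with their closed forms", {
  pc <- larval_params(0.5, 0, 0.05, 0.2,
                      mortality = list(type = "constant", rate = 0.1))
  expect_equal(mortality_rate(c(0, 3, 77), pc), rep(0.1, 3))

  # weibull shape 1 reduces to a constant hazard
  pw1 <- larval_params(0.5, 0, 0.05, 0.2,
                       mortality = list(type = "weibull", scale = 0.07,
                                        shape = 1))
  expect_equal(mortality_rate(c(0.5, 10, 100), pw1), rep(0.07, 3))

  # numerically integrated hazard equals the closed-form cumulative hazard
  pw <- larval_params(0.5, 0, 0.05, 0.2,
                      mortality = list(type = "weibull", scale = 0.05,
                                       shape = 2))
  for (t in c(1, 10, 60, 120)) {
    num <- stats::integrate(function(s) mortality_rate(s, pw), 0, t,
                            rel.tol = 1e-10)$value
    expect_equal(num, (0.05 * t)^2, tolerance = 1e-8)
  }

  # decreasing hazard (shape < 1) is capped at t = 0, not infinite
  pw5 <- larval_params(0.5, 0, 0.05, 0.2,
                       mortality = list(type = "weibull", scale = 0.05,
                                        shape = 0.5))
  expect_message(h0 <- mortality_rate(0, pw5), "capped")
  expect_true(is.finite(h0))

  expect_error(larval_params(-1, 0, 0, 0.1), ">= 0")
  expect_error(larval_params(0.5, 119, 0.05, 0.2, T_max = 119), "T_max")
})

test_that("fate propagator matches the constant-coefficient closed form", {
  times <- seq(0, 120, by = 0.05)

  # nothing happens when competency never switches on and mortality is zero
  p0 <- larval_params(0.5, 200, 0.05, 0.2, T_max = 300)
  f0 <- integrate_fate(rep(0.5, length(times)), times, p0)
  expect_true(all(f0$L1 == 1) && all(f0$L2 == 0))

  # t_c = 0, constant rates: exact linear-ODE solution
  p <- larval_params(0.5, 0, 0.05, 0.2,
                     mortality = list(type = "constant", rate = 0.1))
  f <- integrate_fate(rep(0.5, length(times)), times, p)
  cf <- fate_closed_form(times, 1, 0, 0.5, 0.1, 0.05, 0.2, 0.5)
  expect_lt(max(abs(f$L1[1, ] - cf$L1)), 1e-9)
  expect_lt(max(abs(f$L2[1, ] - cf$L2)), 1e-9)
  # spec-level spot value
  expect_equal(f$L2[1, which(times == 5)], 0.33816818, tolerance = 1e-6)

  # degenerate case g -> a: L2 = alpha t exp(-a t)
  # alpha 0.5, mu 0.1 -> a = 0.6; choose beta + mu_s*Fr = 0.5 + 1e-9
  pd <- larval_params(0.5, 0, 0.25 + 1e-9, 0.5,
                      mortality = list(type = "constant", rate = 0.1))
  fd <- integrate_fate(rep(0.5, length(times)), times, pd)
  expect_lt(max(abs(fd$L2[1, ] - 0.5 * times * exp(-0.6 * times))), 1e-9)
})

test_that("fate invariants hold across random parameter sets", {
  times <- seq(0, 60, by = 0.1)
  withr::with_seed(42, {
    for (rep in 1:20) {
      p <- larval_params(
        alpha = runif(1, 0, 1), t_c = runif(1, 0, 10),
        beta = runif(1, 0, 0.2), mu_s = runif(1, 0, 1),
        mortality = if (runif(1) < 0.5)
          list(type = "constant", rate = runif(1, 0, 0.3))
        else list(type = "weibull", scale = runif(1, 0.01, 0.1),
                  shape = runif(1, 0.4, 2)))
      fr <- pmax(0, round(runif(length(times)), 2) - 0.4)  # patchy reef
      f <- integrate_fate(fr, times, p)
      expect_true(all(f$L1 >= 0) && all(f$L2 >= 0))
      expect_true(all(diff(f$L1[1, ]) <= 1e-15))           # non-increasing
      expect_true(all(f$L1 + f$L2 <= 1 + 1e-12))
      expect_true(all(f$L2[1, times < p$t_c] == 0))
      expect_lt(max(mass_balance(f)), 1e-8)                # mass conserved
    }
  })
})

test_that("settling events capture S_j with the exact integral", {
  g <- fix_grid()
  reef <- fix_point_reef(g, where = c(52.5e3, 52.5e3), seed = 9)
  fr_reef <- reef$cells$fr[1]
  A <- reef$cells$area[1]
  rel <- make_release(reef, n_per_cell = 1, date = 0)
  still <- make_uniform_field(0, 90, g)
  tr <- advect(still, rel, dt = 0.05, T_max = 30)

  p <- larval_params(0.5, 0, 0.05, 0.2,
                     mortality = list(type = "constant", rate = 0.1))
  fr <- sample_reef_fraction(tr, reef)
  fate <- integrate_fate(fr, tr$times, p)
  ev <- settle_events(tr, fate, reef, p)

  expect_equal(nrow(ev), 1L)                 # one uninterrupted event
  expect_equal(ev$tau0, 0)
  expect_equal(ev$dtau, 30)
  expect_equal(ev$fr_dest, fr_reef)

  # quadrature oracle on the closed-form L2
  quad <- stats::integrate(function(t)
    fate_closed_form(t, 1, 0, 0.5, 0.1, 0.05, 0.2, fr_reef)$L2,
    0, 30, rel.tol = 1e-10)$value
  S_expected <- p$rho * A * p$mu_s * fr_reef * quad
  expect_equal(ev$settled, S_expected, tolerance = 1e-6)

  # S_j is linear in rho and area
  p2 <- larval_params(0.5, 0, 0.05, 0.2, rho = 3,
                      mortality = list(type = "constant", rate = 0.1))
  ev2 <- settle_events(tr, integrate_fate(fr, tr$times, p2), reef, p2)
  expect_equal(ev2$settled, 3 * ev$settled)

  # no reef after t_c: empty result
  p_late <- larval_params(0.5, 40, 0.05, 0.2, T_max = 41)
  tr41 <- advect(still, rel, dt = 0.05, T_max = 30)
  fate_late <- integrate_fate(fr, tr41$times, p_late)
  expect_equal(nrow(settle_events(tr41, fate_late, reef, p_late)), 0L)
})

test_that("event splitting, the 60-event cap and mu_m monotonicity behave", {
  # flow east across a row of separate reef cells: one event per cell
  g <- fix_grid()
  centres <- cbind(seq(22.5e3, 72.5e3, by = 10e3), 52.5e3)
  reef <- make_reef_grid(g, centres, 1, seed = 5)
  rel <- make_release(reef, n_per_cell = 1, date = 0)
  rel <- rel[rel$source_cell == reef$cells$cell[1], ]
  attr(rel, "date") <- 0; attr(rel, "n_per_cell") <- 1L
  f <- make_uniform_field(0.5, 90, g)      # 43.2 km/day
  tr <- advect(f, rel, dt = 0.01, T_max = 2)
  p <- larval_params(2, 0, 0.01, 0.3,
                     mortality = list(type = "constant", rate = 0.05))
  fr <- sample_reef_fraction(tr, reef)
  fate <- integrate_fate(fr, tr$times, p)
  ev <- settle_events(tr, fate, reef, p)
  expect_equal(nrow(ev), 6L)               # source cell plus five downstream
  expect_equal(length(unique(ev$dest_cell)), 6L)
  expect_true(all(diff(ev$tau0) > 0))      # time-ordered

  # cap: keep only the earliest max_events
  p2 <- larval_params(2, 0, 0.01, 0.3, max_events = 3L,
                      mortality = list(type = "constant", rate = 0.05))
  ev3 <- settle_events(tr, integrate_fate(fr, tr$times, p2), reef, p2)
  expect_equal(nrow(ev3), 3L)
  expect_equal(ev3$dest_cell, ev$dest_cell[1:3])

  # raising mortality never increases any S_j
  p_hi <- larval_params(2, 0, 0.01, 0.3,
                        mortality = list(type = "constant", rate = 0.3))
  ev_hi <- settle_events(tr, integrate_fate(fr, tr$times, p_hi), reef, p_hi)
  expect_true(all(ev_hi$settled <= ev$settled + 1e-15))
})
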