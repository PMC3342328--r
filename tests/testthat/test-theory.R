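test_that("stationarity of the undamaged class fixes the mean repair rate", {
  expect_equal(as.numeric(steady_state_mean_repair(
    model_params(100, 0.9, 0.05, 1))), 0.9)   # a = 1: every failure lethal
  expect_equal(as.numeric(steady_state_mean_repair(
    model_params(100, 1, 0.05, 0.5))), 1)     # r0 = 1
  r <- steady_state_mean_repair(canonical_params())
  expect_equal(as.numeric(r), 0.8)
  expect_true(attr(r, "valid_regime"))
  # below the a > 1 - r0 threshold the state is flagged, not extrapolated
  r2 <- steady_state_mean_repair(model_params(100, 0.5, 0.1, 0.3))
  expect_false(attr(r2, "valid_regime"))
  expect_error(steady_state_mean_repair(model_params(100, 0.9, 0.05, 0)),
               "apoptosis_prob")
})

test_that("the occupancy recurrence reproduces hand-computed values", {
  p <- canonical_params()
  expect_equal(occupancy_recurrence(1250, 1, p), 1250)    # 1250*0.5*0.1/0.05
  expect_equal(occupancy_recurrence(1250, 2, p), 937.5)   # 1250*0.5*0.15/0.10
  pa1 <- model_params(100, 0.9, 0.05, 1)
  expect_equal(occupancy_recurrence(50, 3, pa1), 0)       # factor (1 - a) = 0
  expect_error(occupancy_recurrence(10, 1, model_params(100, 0.9, 0, 0.5)),
               "delta")
  expect_error(occupancy_recurrence(10, 0, p), "positive")
})

test_that("closed form equals recurrence iteration over a parameter grid", {
  # includes non-integer beta = (1 - r0)/delta
  grid <- expand.grid(r0 = c(0.5, 0.8, 0.93), a = c(0.55, 0.7, 0.95),
                      delta = c(0.03, 0.11, 0.25))
  for (k in seq_len(nrow(grid))) {
    p <- model_params(1000, grid$r0[k], grid$delta[k], grid$a[k])
    th <- occupancy_distribution(p, tail_tol = 1e-15)
    n <- min(length(th$occupancy), 50)
    iter <- numeric(n)
    iter[1] <- th$n0_star
    for (i in seq_len(n - 1)) iter[i + 1] <- occupancy_recurrence(iter[i], i, p)
    expect_lt(max(abs(th$occupancy[1:n] - iter) / pmax(iter, 1e-300)), 1e-10)
  }
})

test_that("the steady-state occupancy is the negative binomial law", {
  # independent oracle: stats::dnbinom with size = beta, prob = a
  for (r0 in c(0.6, 0.9)) for (a in c(0.5, 0.8)) {
    p <- model_params(5000, r0, 0.07, a)
    th <- occupancy_distribution(p)
    i <- seq_along(th$occupancy) - 1
    expect_equal(th$occupancy,
                 5000 * stats::dnbinom(i, size = th$beta, prob = a),
                 tolerance = 1e-12)
  }
})

test_that("occupancy normalises to N with n0* = N a^beta and the stated mean", {
  p <- canonical_params()
  th <- occupancy_distribution(p)
  expect_equal(th$beta, 2)
  expect_equal(th$n0_star, 1250)
  expect_equal(th$occupancy[1], th$n0_star)
  expect_equal(th$occupancy[1:3], c(1250, 1250, 937.5), tolerance = 1e-12)
  expect_equal(sum(th$occupancy), 5000, tolerance = 1e-9)
  # mean of the distribution reproduces rbar* (unclamped rates)
  i <- seq_along(th$occupancy) - 1
  rbar <- sum(th$occupancy * (0.9 - 0.05 * i)) / 5000
  expect_equal(rbar, 0.8, tolerance = 1e-9)

  # r0 = 1: beta = 0, all mass at level 0
  th1 <- occupancy_distribution(model_params(300, 1, 0.05, 0.5))
  expect_equal(th1$occupancy, 300)
  expect_equal(th1$n0_star, 300)
})

test_that("n0* increases with a, r0 and delta", {
  base <- function(r0 = 0.7, a = 0.6, delta = 0.1)
    occupancy_distribution(model_params(1000, r0, delta, a))$n0_star
  expect_true(all(diff(sapply(c(0.5, 0.7, 0.9), function(a) base(a = a))) > 0))
  expect_true(all(diff(sapply(c(0.5, 0.7, 0.9), function(r) base(r0 = r))) > 0))
  expect_true(all(diff(sapply(c(0.05, 0.1, 0.3),
                              function(d) base(delta = d))) > 0))
})

test_that("expected lifetime is geometric in the failure rate and a-independent", {
  expect_equal(expected_lifetime(model_params(100, 0.9, 0.05, 0.5))$events, 10)
  expect_equal(expected_lifetime(model_params(100, 0.5, 0.05, 0.5))$events, 2)
  expect_identical(
    expected_lifetime(model_params(100, 0.5, 0.1, 0.3))$events,
    expected_lifetime(model_params(100, 0.5, 0.1, 0.9))$events)
  inf <- expected_lifetime(model_params(100, 1, 0.05, 0.5))
  expect_true(inf$infinite)
})

test_that("the mean-field RHS vanishes at the fixed point and conserves cells", {
  p <- canonical_params()
  th <- occupancy_distribution(p)
  rhs <- mean_field_rhs(th$occupancy, p)
  expect_lt(max(abs(rhs)), 1e-8 * 5000)
  expect_equal(sum(rhs), 0, tolerance = 1e-10)

  # all cells undamaged: dn0/dt = (1 - r0)(a - 1) < 0
  y <- c(5000, 0, 0)
  rhs0 <- mean_field_rhs(y, p)
  expect_equal(rhs0[1], (1 - 0.9) * (0.5 - 1), tolerance = 1e-12)
  expect_lt(rhs0[1], 0)

  # conservation for arbitrary states
  set.seed(8)
  for (k in 1:5) {
    y <- stats::runif(12)
    y <- y / sum(y) * 5000
    expect_equal(sum(mean_field_rhs(y, p)), 0, tolerance = 1e-9)
  }
})

test_that("mean-field integration is conservative and attracted to the fixed point", {
  p <- canonical_params()
  th <- occupancy_distribution(p)

  # starting at the fixed point the trajectory stays there
  mf0 <- integrate_mean_field(p, t_end = 2e5, initial = th$occupancy,
                              n_out = 5)
  expect_lt(max(abs(mf0$occupancy[5, seq_along(th$occupancy)] -
                      th$occupancy)), 1e-4 * 5000)

  # from all-undamaged the stationarity residual goes below 1e-4 and the
  # distribution converges to the closed form
  mf <- integrate_mean_field(p, t_end = 3e6)
  expect_true(all(abs(rowSums(mf$occupancy) - 5000) < 1e-6 * 5000))
  resid <- abs(0.5 * (1 - mf$rbar[length(mf$rbar)]) - 0.1)
  expect_lt(resid, 1e-4)
  L <- length(th$occupancy)
  final <- mf$occupancy[nrow(mf$occupancy), 1:L]
  expect_lt(max(abs(final - th$occupancy) / pmax(th$occupancy, 1)), 0.02)

  expect_error(integrate_mean_field(p, 100, initial = c(10, 10)), "sum")
})

test_that("damaged classes relax at -i*delta/N while class 0 is marginal", {
  p <- canonical_params()
  expect_identical(perturbation_decay_rate(0, p), 0)
  expect_equal(perturbation_decay_rate(2, p), -2e-5)
  expect_equal(perturbation_decay_rate(0:3, p), c(0, -1, -2, -3) * 1e-5)
  expect_error(perturbation_decay_rate(-1, p), "non-negative")

  # oracle: mean-field integration of a perturbation that conserves both
  # cell number and mean repair rate (pattern +1, 0, -3, +2 across levels)
  th <- occupancy_distribution(p)
  i <- 2
  y0 <- th$occupancy
  eps <- 0.01 * y0[i + 1]
  y0[i + 1] <- y0[i + 1] + eps
  y0[i + 3] <- y0[i + 3] - 3 * eps
  y0[i + 4] <- y0[i + 4] + 2 * eps
  rate <- perturbation_decay_rate(i, p)
  mf <- integrate_mean_field(p, t_end = 0.1 / abs(rate), initial = y0,
                             n_out = 11)
  delta <- mf$occupancy[, i + 1] - th$occupancy[i + 1]
  slope <- unname(stats::coef(stats::lm(log(delta) ~ mf$times))[2])
  expect_lt(abs(slope - rate) / abs(rate), 0.25)
})
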