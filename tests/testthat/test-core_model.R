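test_that("parameter validation enforces the model invariants", {
  expect_s3_class(canonical_params(), "ratchet_params")
  expect_error(model_params(1, 0.9, 0.05, 0.5), "n_cells")
  expect_error(model_params(100, 1.2, 0.05, 0.5), "r0")
  expect_error(model_params(100, 0.9, -0.1, 0.5), "delta")
  expect_error(model_params(100, 0.9, 0.05, 1.5), "apoptosis_prob")
  expect_error(model_params(100, 0.9, 0.05, 0.5, topology = "lattice_2d",
                            lattice_shape = c(10, 12)), "lattice_shape")
  expect_error(model_params(100, 0.9, 0.05, 0.5, lattice_shape = c(10, 10)),
               "lattice_shape")
})

test_that("repair probability declines by delta per mutation and clamps at 0", {
  p <- model_params(100, 0.9, 0.05, 0.5)
  expect_equal(repair_probability(0, p), 0.9)
  expect_equal(repair_probability(2, p), 0.8)
  expect_equal(repair_probability(30, p), 0)  # r0 - 30*delta = -0.6, clamped
  expect_equal(repair_probability(0:3, p), c(0.9, 0.85, 0.8, 0.75))
  expect_error(repair_probability(-1, p), "non-negative")
})

test_that("initial state is all-undamaged and has mean repair rate r0", {
  for (N in c(5, 5000)) {
    p <- canonical_params(n_cells = N)
    s <- init_state(p)
    expect_identical(s, as.integer(N))
    expect_equal(sum(s), N)
    expect_equal(mean_repair_rate(s, p), 0.9)
  }
})

test_that("mean repair rate is the occupancy-weighted clamped rate", {
  p <- canonical_params()
  state <- c(2500L, 0L, 2500L)  # levels 0 and 2
  expect_equal(mean_repair_rate(state, p), 0.85)
  p0 <- model_params(5000, 0.9, 0, 0.5)
  expect_equal(mean_repair_rate(state, p0), 0.9)  # delta = 0: no decay
  expect_error(mean_repair_rate(c(10L, 10L), p), "conserve")
})

test_that("single steps conserve N, keep counts non-negative, and respect edge regimes", {
  # r0 = 1: every step repairs and leaves the state untouched
  p1 <- model_params(50, 1, 0.05, 0.5, seed = 1)
  s <- init_state(p1)
  set.seed(1)
  for (k in 1:50) {
    out <- step_well_mixed(s, p1)
    expect_identical(out$event$kind, "repair")
    expect_identical(out$state, s)
  }

  # a = 1: mutation branch unreachable, counts stay at level 0
  p2 <- model_params(50, 0, 0.05, 1, seed = 1)
  s <- init_state(p2)
  set.seed(2)
  for (k in 1:50) {
    out <- step_well_mixed(s, p2)
    expect_identical(out$event$kind, "apoptosis")
    expect_identical(out$state, s)
  }

  # property: conservation and validity over many random steps and params
  set.seed(42)
  for (rep in 1:3) {
    p <- model_params(30, runif(1, 0.3, 0.95), runif(1, 0.01, 0.3),
                      runif(1, 0.2, 0.9), seed = rep)
    s <- init_state(p)
    kinds <- c(repair = 0, apoptosis = 0, mutation = 0)
    for (k in 1:3000) {
      out <- step_well_mixed(s, p)
      s <- out$state
      kinds[out$event$kind] <- kinds[out$event$kind] + 1
      expect_true(all(s >= 0))
    }
    expect_equal(sum(s), 30)
    expect_equal(sum(kinds), 3000)
    # apoptosis events carry the divider's level, others do not
    expect_true(kinds["apoptosis"] > 0)
  }
})

test_that("trajectories are deterministic given the seed and conserve event algebra", {
  p <- canonical_params(n_cells = 500, seed = 7)
  t1 <- run_well_mixed(p, max_sweeps = 50)
  t2 <- run_well_mixed(p, max_sweeps = 50)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$final_state, t2$final_state)
  # each apoptosis triggers exactly one division
  expect_identical(t1$samples$divisions, t1$samples$apoptoses)
  expect_equal(sum(t1$final_state), 500)
  # sampled mean repair rate recomputes from the final state
  expect_equal(t1$samples$mean_repair_rate[nrow(t1$samples)],
               mean_repair_rate(t1$final_state, p))
})

test_that("frozen and neutral regimes hold exactly along whole runs", {
  # r0 = 1: nothing ever happens
  p1 <- model_params(200, 1, 0.05, 0.5, seed = 3)
  tr <- run_well_mixed(p1, max_sweeps = 10)
  expect_true(all(tr$samples$mean_repair_rate == 1))
  expect_true(all(tr$samples$apoptoses == 0))
  expect_true(all(tr$samples$mutations == 0))

  # delta = 0: mutations occur but are neutral, rbar stays at r0 exactly
  p2 <- model_params(200, 0.7, 0, 0.4, seed = 3)
  tr2 <- run_well_mixed(p2, max_sweeps = 50)
  expect_true(all(tr2$samples$mean_repair_rate == 0.7))
  expect_gt(tr2$samples$mutations[nrow(tr2$samples)], 0)
})

test_that("event frequencies match the sampled mean repair rate", {
  # fraction of repair events over a long run ~ time-average of rbar
  p <- canonical_params(n_cells = 500, seed = 11)
  tr <- run_well_mixed(p, max_sweeps = 2000, sample_every = 1)
  s <- tr$samples
  n_steps <- 2000 * 500
  frac_repair <- s$repairs[nrow(s)] / n_steps
  rbar_avg <- mean(s$mean_repair_rate[-nrow(s)])  # left-aligned time average
  sigma <- sqrt(rbar_avg * (1 - rbar_avg) / n_steps)
  expect_lt(abs(frac_repair - rbar_avg), 3 * sigma + 1e-3)
})

test_that("long-run mean repair rate approaches the stationary value", {
  p <- canonical_params(n_cells = 2000, seed = 5)
  tr <- run_well_mixed(p, max_sweeps = 1200)
  s <- tr$samples
  avg <- mean(s$mean_repair_rate[s$time > 300])
  expect_lt(abs(avg - 0.8), 0.01)
})

test_that("run arguments are validated", {
  p <- canonical_params(n_cells = 100)
  expect_error(run_well_mixed(p, max_sweeps = 0), "max_sweeps")
  expect_error(run_well_mixed(p, max_sweeps = 10, sample_every = -1),
               "sample_every")
  pl <- model_params(16, 0.9, 0.05, 0.5, topology = "lattice_2d",
                     lattice_shape = c(4, 4))
  expect_error(run_well_mixed(pl, 10), "well_mixed")
})

test_that("per-cell lifetimes average 1/(1 - r0) damage events, independent of a", {
  p <- model_params(200, 0.9, 0.05, 0.5, seed = 4)
  lt <- run_agent_lifetimes(p, max_sweeps = 1500, burn_in_sweeps = 300)
  expect_gt(lt$n_lifetimes, 1000)
  expect_lt(abs(lt$mean_lifetime_events - 10), 0.6)

  # apoptosis probability does not change the lifetime (r0 = 0.5 -> 2
  # events); N large enough that the steady state outlives the run
  for (a in c(0.6, 0.9)) {
    p2 <- model_params(1000, 0.5, 0.1, a, seed = 4)
    lt2 <- run_agent_lifetimes(p2, max_sweeps = 600, burn_in_sweeps = 150)
    expect_lt(abs(lt2$mean_lifetime_events - 2), 0.1)
  }
})
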