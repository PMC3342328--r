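# Replicated in-silico studies: persistence time T*, parameter sweeps,
# system-size scaling, distribution comparison, apoptosis-rate invariance.
# Every study is a pure function of (params, base_seed); replicate r uses
# seed base_seed + r.

with_seed_params <- function(params, seed) {
  params$seed <- as.integer(seed)
  params
}

run_topology <- function(params, ...) {
  if (params$topology == "well_mixed") run_well_mixed(params, ...)
  else run_lattice(params, ...)
}

#' Estimate the persistence time T* of the temporary steady state
#'
#' T* is the first-passage time (in sweeps) at which random fluctuations
#' drive the undamaged class to extinction (`n0 == 0`); undamaged cells are
#' never recreated, so after this the mean repair rate collapses. Runs
#' `n_replicates` independent simulations (replicate `r` seeded
#' `base_seed + r`), each stopped at extinction or at `max_sweeps`.
#' Replicates that reach `max_sweeps` with `n0 > 0` are censored and enter
#' the median as lower bounds at `max_sweeps`; a median that itself falls on
#' a censored value is reported as a lower bound, never as an estimate.
#'
#' @param params a [model_params()] object (any topology).
#' @param n_replicates number of independent runs (>= 1).
#' @param max_sweeps censoring horizon in sweeps.
#' @param base_seed base for per-replicate seeds (default `params$seed`).
#' @return An object of class `ratchet_tstar`: `per_replicate` (data frame
#'   with `replicate`, `seed`, `tstar`, `censored`), `median_tstar`,
#'   `median_is_lower_bound`, `censored_count`, `n_replicates`,
#'   `max_sweeps`, `params`.
#' @export
estimate_tstar <- function(params, n_replicates = 20, max_sweeps = 10000,
                           base_seed = params$seed) {
  stopifnot(n_replicates >= 1)
  tstar <- numeric(n_replicates)
  censored <- logical(n_replicates)
  seeds <- base_seed + seq_len(n_replicates)
  for (r in seq_len(n_replicates)) {
    tr <- run_topology(with_seed_params(params, seeds[r]),
                       max_sweeps = max_sweeps,
                       sample_every = max_sweeps,
                       stop_on_undamaged_extinction = TRUE)
    if (is.na(tr$extinct_time)) {
      tstar[r] <- max_sweeps
      censored[r] <- TRUE
    } else {
      tstar[r] <- tr$extinct_time
    }
  }
  ord <- order(tstar)
  n <- n_replicates
  mid <- if (n %% 2 == 1) (n + 1) / 2 else c(n / 2, n / 2 + 1)
  structure(
    list(per_replicate = data.frame(replicate = seq_len(n), seed = seeds,
                                    tstar = tstar, censored = censored),
         median_tstar = stats::median(tstar),
         median_is_lower_bound = any(censored[ord][mid]),
         censored_count = sum(censored),
         n_replicates = n, max_sweeps = max_sweeps, params = params),
    class = "ratchet_tstar")
}

#' @export
print.ratchet_tstar <- function(x, ...) {
  cat(sprintf(
    "T* estimate (%s, N = %d): median %s%.4g sweeps over %d replicates (%d censored at %g)\n",
    x$params$topology, x$params$n_cells,
    if (x$median_is_lower_bound) ">= " else "",
    x$median_tstar, x$n_replicates, x$censored_count, x$max_sweeps))
  invisible(x)
}

# internal: rebuild params with one field changed, revalidating
modify_param <- function(params, name, value) {
  allowed <- c("r0", "apoptosis_prob", "delta", "n_cells")
  if (!name %in% allowed)
    stop("`vary` must be one of ", paste(allowed, collapse = ", "),
         call. = FALSE)
  shape <- params$lattice_shape
  if (name == "n_cells" && !is.null(shape)) {
    d <- length(shape)
    side <- round(value^(1 / d))
    if (side^d != value)
      stop(sprintf("n_cells = %g is not a %dD lattice size (need side^%d)",
                   value, d, d), call. = FALSE)
    shape <- rep(side, d)
  }
  fields <- list(n_cells = params$n_cells, r0 = params$r0,
                 delta = params$delta, apoptosis_prob = params$apoptosis_prob)
  fields[[name]] <- value
  model_params(fields$n_cells, fields$r0, fields$delta,
               fields$apoptosis_prob, topology = params$topology,
               lattice_shape = shape, seed = params$seed)
}

#' Sweep one model parameter and record the median persistence time
#'
#' Varies exactly one of `r0`, `apoptosis_prob`, `delta`, `n_cells` while
#' holding all other parameters fixed, estimating T* at each value with
#' [estimate_tstar()] (same seeds at every value, so a single-value sweep
#' reproduces `estimate_tstar` exactly). In the valid regime the median T*
#' is expected to increase with each of `r0`, `apoptosis_prob` and `delta`,
#' because the undamaged steady-state count `n0* = N * a^((1-r0)/delta)`
#' grows with each of them.
#'
#' @param params baseline [model_params()].
#' @param vary name of the varied parameter.
#' @param values numeric values for the varied parameter.
#' @inheritParams estimate_tstar
#' @return A `SweepTable`-style data frame: `parameter`, `value`,
#'   `median_tstar`, `median_is_lower_bound`, `censored_count`,
#'   `n_replicates`, `topology`; per-value `ratchet_tstar` objects in
#'   `attr(, "estimates")`.
#' @export
sweep_tstar <- function(params, vary, values, n_replicates = 20,
                        max_sweeps = 10000, base_seed = params$seed) {
  estimates <- lapply(values, function(v) {
    estimate_tstar(modify_param(params, vary, v), n_replicates = n_replicates,
                   max_sweeps = max_sweeps, base_seed = base_seed)
  })
  tab <- data.frame(
    parameter = vary, value = values,
    median_tstar = vapply(estimates, `[[`, 0, "median_tstar"),
    median_is_lower_bound = vapply(estimates, `[[`, NA, "median_is_lower_bound"),
    censored_count = vapply(estimates, `[[`, 0L, "censored_count"),
    n_replicates = n_replicates,
    topology = params$topology)
  attr(tab, "estimates") <- estimates
  tab
}

#' System-size scaling of the persistence time
#'
#' Estimates the median T* over a grid of system sizes for one or more
#' topologies and fits the log-log slope of median T* against N by least
#' squares. The well-mixed system shows a steep (faster than linear) growth
#' of T* with N; spatially structured systems grow roughly linearly (slope
#' near 1). Slopes are fitted only on points whose median is an actual
#' estimate, not a censoring bound.
#'
#' @param params baseline [model_params()] (its `n_cells`/topology are
#'   overridden per condition; lattice sizes must be perfect squares/cubes).
#' @param n_values integer vector of system sizes N.
#' @param topologies subset of `c("well_mixed", "lattice_2d", "lattice_3d")`.
#' @inheritParams estimate_tstar
#' @return List with `table` (one row per topology x N) and `slopes` (named
#'   per topology; `NA` if fewer than 2 uncensored medians).
#' @export
scaling_study <- function(params, n_values,
                          topologies = c("well_mixed", "lattice_2d"),
                          n_replicates = 20, max_sweeps = 10000,
                          base_seed = params$seed) {
  rows <- list()
  for (topo in topologies) {
    for (N in n_values) {
      shape <- NULL
      if (topo != "well_mixed") {
        d <- if (topo == "lattice_2d") 2L else 3L
        side <- round(N^(1 / d))
        if (side^d != N)
          stop(sprintf("N = %d is not representable as a %dD lattice", N, d),
               call. = FALSE)
        shape <- rep(side, d)
      }
      p <- model_params(N, params$r0, params$delta, params$apoptosis_prob,
                        topology = topo, lattice_shape = shape,
                        seed = params$seed)
      est <- estimate_tstar(p, n_replicates = n_replicates,
                            max_sweeps = max_sweeps, base_seed = base_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        topology = topo, n_cells = N, median_tstar = est$median_tstar,
        median_is_lower_bound = est$median_is_lower_bound,
        censored_count = est$censored_count, n_replicates = n_replicates)
    }
  }
  tab <- do.call(rbind, rows)
  slopes <- vapply(topologies, function(topo) {
    sub <- tab[tab$topology == topo & !tab$median_is_lower_bound, ]
    if (nrow(sub) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(median_tstar) ~ log(n_cells),
                                 data = sub))[2])
  }, 0)
  list(table = tab, slopes = slopes)
}

#' Compare the simulated steady-state occupancy with the theory
#'
#' Runs the well-mixed model, time-averages the full occupancy vector over
#' sampled states in `(burn_in, burn_in + window]` (conditioned on the
#' undamaged class surviving throughout; an extinction inside the window
#' truncates it and is flagged), and compares the empirical distribution
#' over mutation levels with the closed-form steady-state profile.
#'
#' @param params a well-mixed [model_params()] in the valid regime.
#' @param burn_in sweeps discarded before averaging; should be long enough
#'   that the time-averaged mean repair rate is within 0.01 of the
#'   steady-state value (a warning is issued otherwise).
#' @param window averaging window length in sweeps.
#' @param base_seed seed for the run (default `params$seed`).
#' @return List with `empirical` and `theory` (expected counts per level,
#'   equal length), `tv_distance` (total-variation distance between the two
#'   normalised distributions), `residuals` (per-class standardised
#'   residuals `(emp - theo) / sqrt(theo)` where the theory expects at
#'   least one cell), `rbar_window` (time-averaged mean repair rate over the
#'   window), `window_truncated`, `n_samples`.
#' @export
distribution_comparison <- function(params, burn_in = 500, window = 1500,
                                    base_seed = params$seed) {
  th <- occupancy_distribution(params)
  if (!th$valid_regime)
    stop("parameters outside the valid steady-state regime (need a > 1 - r0)",
         call. = FALSE)
  tr <- run_well_mixed(with_seed_params(params, base_seed),
                       max_sweeps = burn_in + window, sample_every = 1,
                       accumulate_window = c(burn_in, window))
  emp <- tr$occupancy_mean
  if (is.null(emp))
    stop("no samples in the averaging window (extinction before burn-in?)",
         call. = FALSE)
  s <- tr$samples
  in_win <- s$time > burn_in & s$time <= burn_in + window
  rbar_window <- mean(s$mean_repair_rate[in_win])
  if (abs(rbar_window - th$r_star) > 0.01)
    warning(sprintf(
      "window mean repair rate %.4f is more than 0.01 from steady state %.4f; increase burn_in",
      rbar_window, th$r_star))
  L <- max(length(emp), length(th$occupancy))
  pad <- function(v) c(v, numeric(L - length(v)))
  emp <- pad(emp); theo <- pad(th$occupancy)
  N <- params$n_cells
  tv <- 0.5 * sum(abs(emp / N - theo / N))
  resid <- ifelse(theo >= 1, (emp - theo) / sqrt(theo), NA_real_)
  list(empirical = emp, theory = theo, tv_distance = tv,
       residuals = resid, rbar_window = rbar_window,
       window_truncated = tr$window_truncated,
       n_samples = tr$occupancy_samples, theory_result = th)
}

#' Apoptosis-rate invariance across apoptosis probabilities
#'
#' In the temporary steady state the per-step apoptosis-event rate is
#' `a * (1 - rbar*) = 1 - r0` — independent of `a`: raising the apoptosis
#' probability raises the steady-state repair rate by exactly the amount
#' needed to keep the death (and hence division) rate unchanged, so tissue
#' turnover and the approach to the Hayflick limit do not accelerate.
#' Measures the steady-state apoptosis-event rate per step for each value of
#' `a` over replicated runs.
#'
#' @param params baseline well-mixed [model_params()].
#' @param a_values apoptosis probabilities, all `> 1 - r0` (others rejected).
#' @param n_replicates replicates per value.
#' @param burn_in,window sweeps discarded / measured.
#' @param base_seed base for per-replicate seeds.
#' @return Data frame: `apoptosis_prob`, `rate_per_step` (mean over
#'   replicates), `sd`, `se`, `ci_lo`, `ci_hi` (mean +/- 1.96 se),
#'   `theory_rate` (`1 - r0`), `n_replicates`.
#' @export
apoptosis_invariance_study <- function(params, a_values, n_replicates = 8,
                                       burn_in = 200, window = 800,
                                       base_seed = params$seed) {
  if (any(a_values <= 1 - params$r0))
    stop("all `a_values` must exceed 1 - r0 (valid steady-state regime)",
         call. = FALSE)
  N <- params$n_cells
  rows <- lapply(a_values, function(a) {
    p <- modify_param(params, "apoptosis_prob", a)
    rate <- vapply(seq_len(n_replicates), function(r) {
      tr <- run_well_mixed(with_seed_params(p, base_seed + r),
                           max_sweeps = burn_in + window, sample_every = 1)
      s <- tr$samples
      # apoptosis events in the window / steps in the window, from the
      # cumulative counter sampled at the burn-in boundary and at the end
      at_burn <- which.min(abs(s$time - burn_in))
      (s$apoptoses[nrow(s)] - s$apoptoses[at_burn]) / (window * N)
    }, 0)
    data.frame(apoptosis_prob = a, rate_per_step = mean(rate),
               sd = stats::sd(rate), se = stats::sd(rate) / sqrt(n_replicates),
               theory_rate = 1 - params$r0, n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  out$ci_lo <- out$rate_per_step - 1.96 * out$se
  out$ci_hi <- out$rate_per_step + 1.96 * out$se
  out
}

#' Median trajectory of the mean repair rate over replicates
#'
#' Convenience wrapper reproducing the protocol behind the model's
#' hallmark time course: runs `n_replicates` simulations and returns the
#' per-time median of the mean repair rate and of the undamaged count —
#' initial decline from r0, a long plateau near the steady-state value, and
#' a collapse after the undamaged class dies out.
#'
#' @param params a [model_params()] object.
#' @param n_replicates number of runs (replicate `r` seeded `base_seed + r`).
#' @param max_sweeps,sample_every run control, in sweeps.
#' @param base_seed base seed (default `params$seed`).
#' @return Data frame `time`, `median_rbar`, `median_n0`, plus
#'   `extinct_times` (per replicate, `NA` if none) in `attr(, "extinct_times")`.
#' @export
median_trajectory <- function(params, n_replicates = 20, max_sweeps = 1000,
                              sample_every = 1, base_seed = params$seed) {
  runs <- lapply(seq_len(n_replicates), function(r) {
    run_topology(with_seed_params(params, base_seed + r),
                 max_sweeps = max_sweeps, sample_every = sample_every)
  })
  rbar <- sapply(runs, function(tr) tr$samples$mean_repair_rate)
  n0 <- sapply(runs, function(tr) tr$samples$n0)
  out <- data.frame(time = runs[[1]]$samples$time,
                    median_rbar = apply(rbar, 1, stats::median),
                    median_n0 = apply(n0, 1, stats::median))
  attr(out, "extinct_times") <- vapply(runs, `[[`, 0, "extinct_time")
  out
}
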