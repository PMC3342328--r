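#' Steady-state mean repair rate of the well-mixed system
#'
#' In the temporary steady state the undamaged class is stationary: its
#' per-event loss rate `1 - r0` must balance its replacement gain
#' `a * (1 - rbar)`, giving `rbar* = 1 - (1 - r0) / a`. The state exists
#' (positive `rbar*` requires `a > 1 - r0`); outside that regime the value
#' is still returned but flagged.
#'
#' @param params a [model_params()] object with `apoptosis_prob > 0`.
#' @return `rbar*` with attribute `valid_regime` (`TRUE` iff
#'   `a > 1 - r0`).
#' @examples
#' p <- model_params(5000, 0.9, 0.05, 0.5)
#' steady_state_mean_repair(p)  # 0.8
#' @export
steady_state_mean_repair <- function(params) {
  a <- params$apoptosis_prob
  if (a == 0)
    stop("no steady state for apoptosis_prob = 0 (cells are never replaced)",
         call. = FALSE)
  r <- 1 - (1 - params$r0) / a
  attr(r, "valid_regime") <- r >= 0
  r
}

#' One step of the steady-state occupancy recurrence
#'
#' Stationarity of mutation class `i >= 1` links consecutive classes:
#' `n_i * i * delta = n_{i-1} * (1 - a) * (1 - r0 + (i - 1) * delta)`.
#' Returns `n_i` given `n_{i-1}`.
#'
#' @param n_prev expected occupancy of class `i - 1`.
#' @param i positive integer class index.
#' @param params a [model_params()] object with `delta > 0`.
#' @return Expected occupancy `n_i` (real).
#' @export
occupancy_recurrence <- function(n_prev, i, params) {
  if (params$delta <= 0)
    stop("recurrence degenerate for delta = 0", call. = FALSE)
  if (any(i < 1) || any(i != round(i)))
    stop("`i` must be a positive integer", call. = FALSE)
  n_prev * (1 - params$apoptosis_prob) *
    (1 - params$r0 + (i - 1) * params$delta) / (i * params$delta)
}

#' Closed-form steady-state occupancy distribution
#'
#' Solving the recurrence gives a negative-binomial-shaped profile over
#' mutation levels:
#' `n_i* = n0 * (1 - a)^i * choose(beta + i - 1, i)` with
#' `beta = (1 - r0) / delta` and normalisation `n0* = N * a^beta` (so that
#' the classes sum to N). The binomial coefficient is generalised to real
#' `beta` via log-gamma. The sequence is truncated at the smallest level
#' whose remaining tail mass is below `tail_tol * N`.
#'
#' @param params a [model_params()] object, `delta > 0`, `0 < a <= 1`
#'   (`r0 = 1` is allowed and gives all mass at level 0).
#' @param tail_tol relative tail mass tolerance for truncation.
#' @return An object of class `ratchet_theory`: a list with `r_star`,
#'   `beta`, `n0_star`, `occupancy` (expected counts for levels
#'   `0:(length - 1)`), `expected_lifetime_events`,
#'   `expected_lifetime_sweeps`, `valid_regime`, and `clamp_tail_mass`
#'   (expected fraction of cells past the level where the raw rate
#'   `r0 - i*delta` turns negative — the theory's sums run over all levels
#'   unclamped, and are trustworthy when this mass is negligible).
#' @examples
#' th <- occupancy_distribution(model_params(5000, 0.9, 0.05, 0.5))
#' th$n0_star          # 1250
#' head(th$occupancy)  # 1250, 1250, 937.5, ...
#' @export
occupancy_distribution <- function(params, tail_tol = 1e-12) {
  a <- params$apoptosis_prob
  if (params$delta <= 0 && params$r0 < 1)
    stop("occupancy distribution requires delta > 0 (or r0 = 1)",
         call. = FALSE)
  if (a <= 0 || a > 1)
    stop("requires 0 < apoptosis_prob <= 1", call. = FALSE)
  N <- params$n_cells
  r_star <- steady_state_mean_repair(params)
  valid <- isTRUE(attr(r_star, "valid_regime"))
  attributes(r_star) <- NULL

  if (params$r0 >= 1) {  # beta = 0: nothing ever mutates
    out <- list(r_star = 1, beta = 0, n0_star = N, occupancy = N,
                expected_lifetime_events = Inf,
                expected_lifetime_sweeps = Inf,
                infinite_lifetime = TRUE,
                valid_regime = TRUE, clamp_tail_mass = 0,
                params = params)
    class(out) <- "ratchet_theory"
    return(out)
  }

  beta <- ratchet_beta(params)
  n0_star <- N * a^beta
  # class probabilities p_i = a^beta (1-a)^i C(beta+i-1, i), computed in log
  # space; C generalised to real beta via lgamma
  log_coef <- function(i) lgamma(beta + i) - lgamma(beta) - lgamma(i + 1)
  log_p <- function(i) beta * log(a) + i * log1p(-a) + log_coef(i)

  if (a == 1) {
    occ <- N  # every failure is lethal; only level 0 occupied
  } else {
    # truncate where cumulative mass exceeds 1 - tail_tol (or where the
    # remaining terms underflow relative to it)
    i_max <- 10L
    repeat {
      p <- exp(log_p(0:i_max))
      if (sum(p) >= 1 - tail_tol || p[i_max + 1L] < tail_tol * 1e-6 ||
            i_max > 100000L) break
      i_max <- i_max * 2L
    }
    cut <- which(cumsum(p) >= 1 - tail_tol)[1]
    if (is.na(cut)) cut <- length(p)
    occ <- N * p[seq_len(cut)]
  }

  i_clamp <- floor(params$r0 / params$delta)  # last level with positive raw rate
  lev <- seq_along(occ) - 1L
  clamp_tail <- 1 - sum(occ[lev <= i_clamp]) / N

  lt <- expected_lifetime(params)
  out <- list(r_star = r_star, beta = beta, n0_star = n0_star,
              occupancy = occ,
              expected_lifetime_events = lt$events,
              expected_lifetime_sweeps = lt$sweeps,
              infinite_lifetime = lt$infinite,
              valid_regime = valid, clamp_tail_mass = clamp_tail,
              params = params)
  class(out) <- "ratchet_theory"
  out
}

#' @export
print.ratchet_theory <- function(x, ...) {
  cat("Mean-field temporary steady state\n")
  cat(sprintf("  rbar* = %.6g, beta = %.6g, n0* = %.6g (of N = %d)\n",
              x$r_star, x$beta, x$n0_star, x$params$n_cells))
  cat(sprintf("  expected cell lifetime: %s damage events\n",
              if (isTRUE(x$infinite_lifetime)) "infinite"
              else format(x$expected_lifetime_events)))
  cat(sprintf("  valid regime (a > 1 - r0): %s; mass past rate clamp: %.3g\n",
              x$valid_regime, x$clamp_tail_mass))
  k <- min(length(x$occupancy), 8L)
  cat("  occupancy (levels 0..):", paste(signif(x$occupancy[1:k], 5),
                                         collapse = ", "),
      if (length(x$occupancy) > k) "..." else "", "\n")
  invisible(x)
}

#' Expected cell lifetime in the temporary steady state
#'
#' In the steady state an average cell dies, per damage event, with
#' probability `a * (1 - rbar*) = 1 - r0`, so its lifetime is geometric with
#' mean `1 / (1 - r0)` damage events — independent of both `a` and `delta`.
#' Since each cell is damaged once per sweep on average, the same number
#' also measures lifetime in sweeps.
#'
#' @param params a [model_params()] object.
#' @return List with `events`, `sweeps` (both `1 / (1 - r0)`), and
#'   `infinite` (`TRUE` for `r0 = 1`, where the numeric values are `Inf`).
#' @export
expected_lifetime <- function(params) {
  if (params$r0 >= 1)
    return(list(events = Inf, sweeps = Inf, infinite = TRUE))
  lt <- 1 / (1 - params$r0)
  list(events = lt, sweeps = lt, infinite = FALSE)
}

#' Mean-field dynamical equations
#'
#' Right-hand side of the deterministic rate equations, time measured in
#' simulation steps. Class 0 obeys
#' `dn0/dt = (n0/N) * (a * (1 - rbar) - (1 - r0))` and class `i >= 1`
#' `dn_i/dt = (n_{i-1}/N) * (1-a) * (1-R_{i-1}) + (n_i/N) * (a*(1-rbar) - (1-R_i))`,
#' with `R_i` the clamped per-class rate and `rbar` the current mean. The
#' top class of the (finite) vector has its mutation outflow suppressed —
#' it loses cells only through apoptosis — so that `sum(dn/dt) == 0`
#' exactly for any state; this truncation closure is harmless whenever the
#' top-class occupancy is negligible.
#'
#' @param occupancy non-negative real vector of expected class occupancies
#'   (levels `0:(length - 1)`), summing to `n_cells`.
#' @param params a [model_params()] object.
#' @return Vector of time derivatives, same length as `occupancy`.
#' @export
mean_field_rhs <- function(occupancy, params) {
  N <- params$n_cells
  L <- length(occupancy)
  lev <- seq_len(L) - 1L
  R <- repair_probability(lev, params)
  rbar <- sum(occupancy * R) / N
  gain_birth <- (occupancy / N) * params$apoptosis_prob * (1 - rbar)
  loss <- (occupancy / N) * (1 - R)
  # top class: no level L to mutate into; only apoptosis removes cells
  loss[L] <- (occupancy[L] / N) * params$apoptosis_prob * (1 - R[L])
  gain_mut <- c(0, (occupancy[-L] / N) * (1 - params$apoptosis_prob) *
                  (1 - R[-L]))
  gain_birth + gain_mut - loss
}

#' Integrate the mean-field equations
#'
#' Deterministic integration of [mean_field_rhs()] with the classical
#' fixed-step fourth-order Runge-Kutta scheme (via deSolve). The step size
#' is validated internally: it is halved until the endpoint changes by less
#' than `1e-6` in relative terms. From the all-undamaged start the
#' trajectory relaxes towards the steady state where
#' `a * (1 - rbar) = 1 - r0`.
#'
#' @param params a [model_params()] object.
#' @param t_end integration horizon in steps.
#' @param initial initial occupancy vector (padded with zeros to
#'   `n_classes`); default all cells undamaged.
#' @param n_classes number of mutation classes carried (default: enough to
#'   hold the steady-state support, from [occupancy_distribution()]).
#' @param n_out number of output times.
#' @return List with `times` (steps), `occupancy` (matrix, rows = times),
#'   `rbar` (mean repair rate per output time), and `step_size` used.
#' @export
integrate_mean_field <- function(params, t_end, initial = NULL,
                                 n_classes = NULL, n_out = 101) {
  N <- params$n_cells
  if (is.null(n_classes)) {
    n_classes <- if (params$delta > 0 && params$r0 < 1)
      length(occupancy_distribution(params, tail_tol = 1e-12)$occupancy) + 5L
    else 2L
  }
  y0 <- numeric(n_classes)
  if (is.null(initial)) {
    y0[1] <- N
  } else {
    if (length(initial) > n_classes) n_classes <- length(initial)
    y0 <- numeric(n_classes)
    y0[seq_along(initial)] <- initial
  }
  if (abs(sum(y0) - N) > 1e-6 * N)
    stop("initial occupancy must sum to n_cells", call. = FALSE)
  rhs <- function(t, y, parms) list(mean_field_rhs(y, params))
  times <- seq(0, t_end, length.out = n_out)

  solve_h <- function(h) {
    deSolve::ode(y0, times, rhs, parms = NULL, method = "rk4", hini = h)
  }
  # start from a step resolving the fastest per-class relaxation ~ L*delta/N
  rate <- max(n_classes * params$delta, 1 - params$r0, 1e-12) / N
  h <- min(diff(times)[1], 0.05 / rate)
  sol <- solve_h(h)
  repeat {
    sol2 <- solve_h(h / 2)
    end1 <- sol[nrow(sol), -1]
    end2 <- sol2[nrow(sol2), -1]
    if (max(abs(end1 - end2)) / N < 1e-6 || h < 1e-6) break
    h <- h / 2
    sol <- sol2
  }
  occ <- unname(sol[, -1, drop = FALSE])
  if (any(occ < -1e-6 * N))
    stop("mean-field integration unstable: negative occupancy", call. = FALSE)
  R <- repair_probability(seq_len(ncol(occ)) - 1L, params)
  list(times = sol[, 1], occupancy = occ,
       rbar = as.numeric(occ %*% R) / N, step_size = h)
}

#' First-order self-relaxation rate of a mutation class
#'
#' Perturbing class `i` away from the fixed point while holding the mean
#' repair rate fixed, the perturbation decays at rate `-i * delta / N` per
#' step: damaged classes are attracted back, while the undamaged class
#' (`i = 0`) is marginally stable — its fluctuations are not restored, which
#' is why the undamaged count can random-walk to extinction.
#'
#' @param i non-negative integer class index (vectorised).
#' @param params a [model_params()] object.
#' @return Linear decay rate(s), per step (0 for `i = 0`).
#' @export
perturbation_decay_rate <- function(i, params) {
  if (any(i < 0) || any(i != round(i)))
    stop("`i` must be a non-negative integer", call. = FALSE)
  -i * params$delta / params$n_cells
}
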