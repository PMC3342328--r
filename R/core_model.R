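#' Per-event repair probability of a cell with i accumulated mutations
#'
#' Each unrepaired damage permanently lowers a cell's repair probability by
#' `delta`, so a cell carrying `i` mutations repairs a new damage with
#' probability `r0 - i * delta`, clamped into `[0, 1]` (deeply damaged cells
#' simply never repair; mutation counts may still grow past the clamp
#' point).
#'
#' @param i non-negative integer mutation count(s); vectorised.
#' @param params a [model_params()] object.
#' @return Repair probabilities in `[0, 1]`, same length as `i`.
#' @examples
#' p <- model_params(100, r0 = 0.9, delta = 0.05, apoptosis_prob = 0.5)
#' repair_probability(0:3, p)
#' @export
repair_probability <- function(i, params) {
  if (any(i < 0) || any(i != round(i)))
    stop("mutation count `i` must be a non-negative integer", call. = FALSE)
  pmin(pmax(params$r0 - i * params$delta, 0), 1)
}

#' Initial occupancy state: all cells undamaged
#'
#' The state of the well-mixed system is an occupancy vector: element `k`
#' holds the number of cells that have accumulated exactly `k - 1` mutations
#' (levels start at 0). All cells start undamaged at the full repair rate.
#'
#' @param params a [model_params()] object.
#' @return Integer occupancy vector of length 1, `c(n_cells)`.
#' @export
init_state <- function(params) {
  as.integer(params$n_cells)
}

#' Population mean repair rate of an occupancy state
#'
#' The tissue-level observable of the model: the average over cells of the
#' (clamped) per-cell repair probability, `sum_i n_i * max(r0 - i*delta, 0) / N`.
#'
#' @param state integer occupancy vector (levels 0, 1, ... in order).
#' @param params a [model_params()] object.
#' @return A single number in `[0, 1]`.
#' @export
mean_repair_rate <- function(state, params) {
  if (sum(state) != params$n_cells)
    stop("state does not conserve the cell number N", call. = FALSE)
  lev <- seq_along(state) - 1L
  sum(state * repair_probability(lev, params)) / params$n_cells
}

#' One stochastic step of the well-mixed dynamics
#'
#' A single damage event: a random cell (mutation level `i` with probability
#' `n_i / N`) is damaged. With probability `repair_probability(i)` the damage
#' is repaired and nothing changes. Otherwise, with probability
#' `apoptosis_prob` the cell dies and a dividing cell, drawn uniformly from
#' the `N - 1` survivors, replaces it with a daughter at the divider's level;
#' else the damage becomes a mutation and the cell moves to level `i + 1`.
#' The cell number is conserved by every branch.
#'
#' This is the reference single-step implementation used for testing the
#' dynamics; long runs use the compiled engine in [run_well_mixed()], which
#' implements the identical law and consumes the same R random number
#' stream.
#'
#' @param state integer occupancy vector.
#' @param params a [model_params()] object.
#' @return A list with `state` (the new occupancy vector) and `event`, a
#'   list with `kind` (`"repair"`, `"apoptosis"` or `"mutation"`),
#'   `damaged_level`, and (apoptosis only) `replaced_by_level`.
#' @export
step_well_mixed <- function(state, params) {
  N <- params$n_cells
  if (sum(state) != N)
    stop("state does not conserve the cell number N", call. = FALSE)
  lev <- seq_along(state) - 1L
  i <- sample(lev, 1L, prob = state)
  event <- list(kind = "repair", damaged_level = i, replaced_by_level = NULL)
  if (stats::runif(1) < repair_probability(i, params)) {
    return(list(state = state, event = event))
  }
  state[i + 1L] <- state[i + 1L] - 1L
  if (stats::runif(1) < params$apoptosis_prob) {
    j <- sample(lev, 1L, prob = state)  # post-removal counts, N - 1 cells
    state[j + 1L] <- state[j + 1L] + 1L
    event$kind <- "apoptosis"
    event$replaced_by_level <- j
  } else {
    if (i + 2L > length(state)) state <- c(state, 0L)
    state[i + 2L] <- state[i + 2L] + 1L
    event$kind <- "mutation"
  }
  list(state = state, event = event)
}

# internal: assemble a trajectory object from an engine result
build_trajectory <- function(res, params, max_sweeps, sample_every,
                             final_state, occupancy_mean = NULL,
                             occupancy_samples = NA_integer_,
                             window_truncated = FALSE) {
  N <- params$n_cells
  samples <- data.frame(
    time = res$time / N,
    mean_repair_rate = res$rbar,
    n0 = as.integer(res$n0),
    repairs = res$repairs,
    apoptoses = res$apoptoses,
    mutations = res$mutations,
    divisions = res$apoptoses  # each apoptosis triggers exactly one division
  )
  structure(
    list(samples = samples,
         final_state = final_state,
         extinct_time = if (res$extinct_step >= 0) res$extinct_step / N else NA_real_,
         occupancy_mean = occupancy_mean,
         occupancy_samples = occupancy_samples,
         window_truncated = window_truncated,
         max_sweeps = max_sweeps,
         sample_every = sample_every,
         params = params,
         seed = params$seed),
    class = "ratchet_trajectory")
}

#' @export
print.ratchet_trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf("Trajectory: %s, N = %d, %d samples over %g sweeps\n",
              x$params$topology, x$params$n_cells, nrow(s), max(s$time)))
  cat(sprintf("  final mean repair rate %.4f, n0 = %d\n",
              s$mean_repair_rate[nrow(s)], s$n0[nrow(s)]))
  cat(sprintf("  events: %d repairs, %d apoptoses (= divisions), %d mutations\n",
              s$repairs[nrow(s)], s$apoptoses[nrow(s)], s$mutations[nrow(s)]))
  if (!is.na(x$extinct_time))
    cat(sprintf("  undamaged class extinct at %.2f sweeps\n", x$extinct_time))
  invisible(x)
}

#' Run the well-mixed stochastic model
#'
#' Executes `max_sweeps * n_cells` damage events (one sweep = N steps, i.e.
#' one expected damage per cell) from the all-undamaged start, sampling the
#' mean repair rate, the undamaged count n0 and cumulative event counters
#' every `sample_every` sweeps. Deterministic given `(params, params$seed)`.
#'
#' @param params a [model_params()] object (topology `"well_mixed"`).
#' @param max_sweeps positive number of sweeps to simulate.
#' @param sample_every sampling interval in sweeps (positive).
#' @param stop_on_undamaged_extinction if `TRUE`, the run stops at the first
#'   step where no undamaged cell remains (the persistence-time event); the
#'   first-passage time is recorded in `$extinct_time` (sweeps) either way.
#' @param accumulate_window optional `c(from, length)` in sweeps: the full
#'   occupancy vector is time-averaged over samples in
#'   `(from, from + length]`, conditioned on the undamaged class surviving;
#'   result in `$occupancy_mean`.
#' @return A `ratchet_trajectory` object; `$samples` is a data frame with
#'   columns `time` (sweeps), `mean_repair_rate`, `n0`, and cumulative
#'   `repairs`, `apoptoses`, `mutations`, `divisions`.
#' @examples
#' p <- model_params(500, r0 = 0.9, delta = 0.05, apoptosis_prob = 0.5, seed = 7)
#' tr <- run_well_mixed(p, max_sweeps = 50)
#' tail(tr$samples, 3)
#' @export
run_well_mixed <- function(params, max_sweeps, sample_every = 1,
                           stop_on_undamaged_extinction = FALSE,
                           accumulate_window = NULL) {
  if (params$topology != "well_mixed")
    stop("params$topology must be \"well_mixed\"; see run_lattice()",
         call. = FALSE)
  if (!is.numeric(max_sweeps) || max_sweeps <= 0)
    stop("`max_sweeps` must be positive", call. = FALSE)
  if (!is.numeric(sample_every) || sample_every <= 0)
    stop("`sample_every` must be positive", call. = FALSE)
  N <- params$n_cells
  acc_from <- 0; acc_len <- 0
  if (!is.null(accumulate_window)) {
    stopifnot(length(accumulate_window) == 2, all(accumulate_window >= 0))
    acc_from <- accumulate_window[1] * N
    acc_len <- accumulate_window[2] * N
  }
  set.seed(params$seed)
  res <- run_well_mixed_cpp(init_state(params), params$r0, params$delta,
                            params$apoptosis_prob,
                            round(max_sweeps * N), round(sample_every * N),
                            stop_on_undamaged_extinction, acc_from, acc_len)
  occ_mean <- NULL
  if (acc_len > 0 && res$occ_n > 0) occ_mean <- res$occ_sum / res$occ_n
  build_trajectory(res, params, max_sweeps, sample_every,
                   final_state = res$final_counts,
                   occupancy_mean = occ_mean,
                   occupancy_samples = as.integer(res$occ_n),
                   window_truncated = isTRUE(res$acc_truncated))
}

#' Per-cell lifetimes from an agent-list simulation
#'
#' Runs the same well-mixed law on an explicit list of cells, each carrying
#' its mutation level and the number of damage events experienced since
#' birth. When a cell born after the burn-in goes apoptotic, its damage-event
#' count (including the fatal event) is recorded. In the temporary steady
#' state the per-event death probability is `a * (1 - rbar*) = 1 - r0`, so
#' the mean recorded lifetime approaches `1 / (1 - r0)` events.
#'
#' @param params a [model_params()] object.
#' @param max_sweeps total sweeps to simulate.
#' @param burn_in_sweeps lifetimes are recorded only for cells born after
#'   this many sweeps (steady-state conditioning).
#' @return A list with `lifetimes` (numeric vector, damage events per
#'   completed life), `mean_lifetime_events`, and event counters.
#' @export
run_agent_lifetimes <- function(params, max_sweeps, burn_in_sweeps = 0) {
  N <- params$n_cells
  set.seed(params$seed)
  res <- run_agents_cpp(N, params$r0, params$delta, params$apoptosis_prob,
                        round(max_sweeps * N), round(burn_in_sweeps * N))
  list(lifetimes = res$lifetimes,
       mean_lifetime_events = mean(res$lifetimes),
       n_lifetimes = length(res$lifetimes),
       repairs = res$repairs, apoptoses = res$apoptoses,
       mutations = res$mutations)
}
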