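#' Lattice grid state
#'
#' Spatially structured variant of the model: cells sit on a periodic square
#' (2D) or simple cubic (3D) lattice, every site always occupied, and an
#' apoptotic cell can only be replaced by a dividing lattice neighbour.
#'
#' @param params a [model_params()] object with a lattice topology.
#' @param levels optional integer vector of per-site mutation levels in
#'   column-major site order (default: all sites undamaged).
#' @return An object of class `ratchet_lattice` with fields `shape` and
#'   `levels` (array of per-site mutation counts).
#' @export
lattice_grid <- function(params, levels = NULL) {
  if (is.null(params$lattice_shape))
    stop("params must have a lattice topology", call. = FALSE)
  shape <- params$lattice_shape
  if (is.null(levels)) levels <- integer(prod(shape))
  if (length(levels) != prod(shape) || any(levels < 0))
    stop("`levels` must give one non-negative count per site", call. = FALSE)
  structure(list(shape = shape,
                 levels = array(as.integer(levels), dim = shape)),
            class = "ratchet_lattice")
}

#' @export
print.ratchet_lattice <- function(x, ...) {
  cat(sprintf("Lattice grid %s: %d sites, %d undamaged, max level %d\n",
              paste(x$shape, collapse = "x"), length(x$levels),
              sum(x$levels == 0), max(x$levels)))
  invisible(x)
}

#' Von Neumann neighbours of a lattice site
#'
#' Nearest neighbours along each axis (4 in 2D, 6 in 3D) with periodic
#' boundary wrap. Coordinates are 1-based, matching R array indexing.
#'
#' @param site integer coordinate vector (length 2 or 3, 1-based).
#' @param grid a [lattice_grid()] object.
#' @return Integer matrix, one neighbour coordinate per row.
#' @examples
#' p <- model_params(16, 0.9, 0.05, 0.5, topology = "lattice_2d",
#'                   lattice_shape = c(4, 4))
#' lattice_neighbors(c(1, 1), lattice_grid(p))
#' @export
lattice_neighbors <- function(site, grid) {
  shape <- grid$shape
  if (length(site) != length(shape) || any(site < 1) || any(site > shape))
    stop("`site` out of range for this grid", call. = FALSE)
  d <- length(shape)
  out <- matrix(rep(as.integer(site), each = 2 * d), nrow = 2 * d)
  for (ax in seq_len(d)) {
    # periodic wrap on 1-based coordinates
    out[2 * ax - 1, ax] <- ((site[ax] - 2) %% shape[ax]) + 1L
    out[2 * ax, ax] <- (site[ax] %% shape[ax]) + 1L
  }
  out
}

#' One stochastic step of the lattice dynamics
#'
#' As [step_well_mixed()], except the damaged site is uniform over sites and
#' the dividing cell on apoptosis is a uniformly chosen von Neumann
#' neighbour of the dead site, whose level is copied into the vacated site.
#' Reference single-step implementation; long runs use [run_lattice()].
#'
#' @param grid a [lattice_grid()] object.
#' @param params a [model_params()] object (lattice topology).
#' @return A list with `grid` and `event` (as in [step_well_mixed()]).
#' @export
step_lattice <- function(grid, params) {
  shape <- grid$shape
  nsite <- prod(shape)
  idx <- sample.int(nsite, 1L)
  coord <- arrayInd(idx, shape)[1, ]
  i <- grid$levels[idx]
  event <- list(kind = "repair", damaged_level = i, replaced_by_level = NULL)
  if (stats::runif(1) < repair_probability(i, params)) {
    return(list(grid = grid, event = event))
  }
  if (stats::runif(1) < params$apoptosis_prob) {
    nb <- lattice_neighbors(coord, grid)
    pick <- nb[sample.int(nrow(nb), 1L), , drop = FALSE]
    j <- grid$levels[pick]
    grid$levels[idx] <- j
    event$kind <- "apoptosis"
    event$replaced_by_level <- j
  } else {
    grid$levels[idx] <- i + 1L
    event$kind <- "mutation"
  }
  list(grid = grid, event = event)
}

#' Run the lattice stochastic model
#'
#' As [run_well_mixed()] but on a periodic von Neumann lattice: on apoptosis
#' only a neighbour of the dead site divides, so competition between
#' mutation levels is local. `neighborhood = "complete"` makes every site a
#' neighbour of every other, which reproduces the well-mixed law on the
#' lattice representation and serves as an equivalence check between the two
#' engines.
#'
#' @inheritParams run_well_mixed
#' @param neighborhood `"von_neumann"` (default) or `"complete"`.
#' @return A `ratchet_trajectory`; `$final_state` is the final grid.
#' @export
run_lattice <- function(params, max_sweeps, sample_every = 1,
                        stop_on_undamaged_extinction = FALSE,
                        neighborhood = c("von_neumann", "complete")) {
  neighborhood <- match.arg(neighborhood)
  if (is.null(params$lattice_shape))
    stop("params must have a lattice topology; see run_well_mixed()",
         call. = FALSE)
  if (!is.numeric(max_sweeps) || max_sweeps <= 0)
    stop("`max_sweeps` must be positive", call. = FALSE)
  if (!is.numeric(sample_every) || sample_every <= 0)
    stop("`sample_every` must be positive", call. = FALSE)
  N <- params$n_cells
  set.seed(params$seed)
  res <- run_lattice_cpp(integer(N), params$lattice_shape,
                         params$r0, params$delta, params$apoptosis_prob,
                         round(max_sweeps * N), round(sample_every * N),
                         stop_on_undamaged_extinction,
                         neighborhood == "complete")
  grid <- lattice_grid(params, levels = res$final_levels)
  build_trajectory(res, params, max_sweeps, sample_every, final_state = grid)
}
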