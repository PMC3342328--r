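#' Model parameters for the repair-decline tissue model
#'
#' Bundles the constants of the stochastic model: a homeostatic population of
#' `n_cells` cells, each starting with repair probability `r0`; every
#' unrepaired damage lowers a cell's repair probability by `delta` (the
#' fragility of the repair machinery); a cell that fails to repair dies by
#' apoptosis with probability `apoptosis_prob` and is replaced by a dividing
#' peer (well-mixed) or lattice neighbour (2D/3D), the daughter inheriting
#' the parent's repair rate; otherwise the damage is fixed as a mutation.
#'
#' @param n_cells integer, number of cells N (constant over time), >= 2.
#' @param r0 initial per-damage-event repair probability, in `[0, 1]`.
#' @param delta repair-rate penalty per accumulated mutation, >= 0.
#' @param apoptosis_prob conditional apoptosis probability given failed
#'   repair, in `[0, 1]`.
#' @param topology `"well_mixed"` (any cell may divide to replace a dead
#'   one), `"lattice_2d"` or `"lattice_3d"` (only lattice neighbours divide).
#' @param lattice_shape integer extents of the lattice (length 2 or 3);
#'   required for lattice topologies, and `prod(lattice_shape)` must equal
#'   `n_cells`.
#' @param seed non-negative integer seed; every run driven by these
#'   parameters is deterministic given the seed.
#'
#' @return An object of class `ratchet_params`.
#' @examples
#' p <- model_params(n_cells = 5000, r0 = 0.9, delta = 0.05, apoptosis_prob = 0.5)
#' p
#' @export
model_params <- function(n_cells, r0, delta, apoptosis_prob,
                         topology = c("well_mixed", "lattice_2d", "lattice_3d"),
                         lattice_shape = NULL, seed = 1L) {
  topology <- match.arg(topology)
  stop_field <- function(cond, field, msg) {
    if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  stop_field(is.numeric(n_cells) && length(n_cells) == 1 &&
               n_cells == round(n_cells) && n_cells >= 2,
             "n_cells", "must be a single integer >= 2")
  stop_field(is.numeric(r0) && length(r0) == 1 && r0 >= 0 && r0 <= 1,
             "r0", "must be a probability in [0, 1]")
  stop_field(is.numeric(delta) && length(delta) == 1 && delta >= 0,
             "delta", "must be a non-negative real")
  stop_field(is.numeric(apoptosis_prob) && length(apoptosis_prob) == 1 &&
               apoptosis_prob >= 0 && apoptosis_prob <= 1,
             "apoptosis_prob", "must be a probability in [0, 1]")
  stop_field(is.numeric(seed) && length(seed) == 1 && seed >= 0 &&
               seed == round(seed),
             "seed", "must be a single non-negative integer")

  if (topology == "well_mixed") {
    if (!is.null(lattice_shape))
      stop("`lattice_shape` is only meaningful for lattice topologies",
           call. = FALSE)
  } else {
    ndim <- if (topology == "lattice_2d") 2L else 3L
    stop_field(!is.null(lattice_shape) && length(lattice_shape) == ndim &&
                 all(lattice_shape == round(lattice_shape)) &&
                 all(lattice_shape >= 1),
               "lattice_shape",
               sprintf("must give %d positive integer extents", ndim))
    stop_field(prod(lattice_shape) == n_cells, "lattice_shape",
               sprintf("prod(lattice_shape) = %d must equal n_cells = %d",
                       prod(lattice_shape), n_cells))
    lattice_shape <- as.integer(lattice_shape)
  }

  structure(
    list(n_cells = as.integer(n_cells), r0 = as.numeric(r0),
         delta = as.numeric(delta),
         apoptosis_prob = as.numeric(apoptosis_prob),
         topology = topology, lattice_shape = lattice_shape,
         seed = as.integer(seed)),
    class = "ratchet_params")
}

#' @export
print.ratchet_params <- function(x, ...) {
  cat("Tissue repair-decline model parameters\n")
  cat(sprintf("  N = %d cells, topology = %s%s\n", x$n_cells, x$topology,
              if (!is.null(x$lattice_shape))
                paste0(" (", paste(x$lattice_shape, collapse = "x"), ")")
              else ""))
  cat(sprintf("  r0 = %g, delta = %g, apoptosis_prob = %g, seed = %d\n",
              x$r0, x$delta, x$apoptosis_prob, x$seed))
  invisible(x)
}

# internal: shape parameter beta = (1 - r0) / delta of the stationary
# occupancy distribution
ratchet_beta <- function(params) {
  if (params$delta <= 0) stop("beta undefined for delta = 0", call. = FALSE)
  (1 - params$r0) / params$delta
}
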