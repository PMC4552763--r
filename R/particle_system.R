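#' Particle state container
#'
#' Holds positions, velocities, force accumulators, species and bookkeeping
#' tags for every particle in a simulation: free fluid, frozen wall particles,
#' membrane vertices (which always carry a cell id), ghost images used to
#' close the generating region periodically, and slaved duplicate vertices.
#'
#' @param position numeric matrix (n x 3), DPD length units.
#' @param velocity numeric matrix (n x 3) or NULL for all-zero.
#' @param species character vector: "fluid", "wall" or "membrane".
#' @param cell_id integer vector; NA for fluid and wall particles. Every
#'   membrane vertex must have a valid cell id.
#' @param region character vector: "generating" or "main".
#' @return object of class `particle_system`.
#' @examples
#' ps <- particle_system(matrix(rnorm(30), 10, 3), species = "fluid")
#' nrow(ps$position)
#' @export
particle_system <- function(position, velocity = NULL,
                            species = "fluid", cell_id = NA_integer_,
                            region = "main") {
  position <- as.matrix(position)
  stopifnot(ncol(position) == 3)
  n <- nrow(position)
  if (is.null(velocity)) velocity <- matrix(0, n, 3)
  velocity <- as.matrix(velocity)
  species <- rep_len(species, n)
  cell_id <- rep_len(as.integer(cell_id), n)
  region <- rep_len(region, n)
  stopifnot(all(species %in% SPECIES_LEVELS), all(region %in% REGION_LEVELS))
  if (any(species == "membrane" & is.na(cell_id)))
    stop("every membrane vertex must have a valid cell_id")
  if (any(species %in% c("fluid", "wall") & !is.na(cell_id)))
    stop("fluid and wall particles must not carry a cell_id")
  if (any(species == "wall" & rowSums(velocity^2) > 0))
    stop("wall particles are frozen: velocities must be zero")
  structure(list(position = position, velocity = velocity,
                 force = matrix(0, n, 3), species = species,
                 cell_id = cell_id, region = region),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system> ", nrow(x$position), " particles (",
      paste(sprintf("%s: %d", names(table(x$species)), table(x$species)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Simulation clock
#'
#' Time step, step counter and master RNG seed. Identical seed and
#' configuration give a bitwise-identical trajectory (the reproducibility
#' contract); the master seed is split into independent subsystem streams
#' (fluid thermostat, membrane random force, outflow coin flips) so that
#' toggling one subsystem does not perturb another's draws.
#'
#' @param dt time step in DPD time units; default 0.005 is stable for the
#'   default fluid friction and membrane stiffness.
#' @param seed integer master seed.
#' @export
sim_clock <- function(dt = 0.005, seed = 1L) {
  stopifnot(dt > 0)
  structure(list(dt = dt, step = 0L, seed = as.integer(seed)),
            class = "sim_clock")
}
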