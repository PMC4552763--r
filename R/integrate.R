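#' One velocity-Verlet step
#'
#' Reference R implementation of the velocity-Verlet update used by the
#' compiled engine: half kick, drift, force re-evaluation, half kick.
#' Wall particles (and any index in `exclude`) are not integrated. Ghost
#' regeneration, bounce-back and the open-boundary hooks are engine-side
#' post-step hooks (see [simulation()]); this function is the bare
#' integrator, convenient for unit-scale dynamics.
#'
#' @param ps `particle_system` with `ps$force` holding forces at the current
#'   positions.
#' @param dt time step.
#' @param force_provider function(ps) -> n x 3 force matrix.
#' @param mass particle mass (DPD reduced units, default 1).
#' @param exclude integer indices never integrated (on top of wall particles).
#' @return updated `particle_system` (positions, velocities, forces).
#' @examples
#' ps <- particle_system(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3))
#' ps <- velocity_verlet_step(ps, 0.01, function(p) matrix(0, 1, 3))
#' ps$position[1, 1]  # 0.01: displacement is exactly v * dt under zero force
#' @export
velocity_verlet_step <- function(ps, dt, force_provider, mass = 1,
                                 exclude = integer(0)) {
  stopifnot(inherits(ps, "particle_system"), dt > 0)
  mob <- ps$species != "wall"
  mob[exclude] <- FALSE
  v <- ps$velocity
  v[mob, ] <- v[mob, ] + 0.5 * dt * ps$force[mob, , drop = FALSE] / mass
  ps$position[mob, ] <- ps$position[mob, , drop = FALSE] +
    dt * v[mob, , drop = FALSE]
  if (!all(is.finite(ps$position)) || !all(is.finite(v)))
    stop("non-finite position/velocity after drift (instability: reduce dt)")
  ps$velocity <- v
  f <- force_provider(ps)
  v[mob, ] <- v[mob, ] + 0.5 * dt * f[mob, , drop = FALSE] / mass
  ps$velocity <- v
  ps$force <- f
  ps
}
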