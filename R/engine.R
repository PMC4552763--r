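#' Compiled simulation engine
#'
#' Wraps the compiled DPD + membrane + OBC engine. `state` is a plain list
#' (positions, velocities, integer species/region codes, cell table) as
#' produced by [make_sim_state()] or [sim_state()]; `config` comes from
#' [engine_config()]. The engine owns three independent RNG streams (fluid
#' thermostat, membrane random force, outflow coin flips) derived from the
#' master seed; the trajectory is bitwise reproducible given (state, config)
#' and restartable from a checkpointed state (which carries the stream
#' states).
#'
#' Step structure: half kick, drift, periodic wrap (whole-cell along the flow
#' axis; copy-border crossings recorded), bounce-back, cell dissolution,
#' outflow membrane, controller update, duplication (fluid and slaved whole
#' cells), ghost regeneration, force evaluation, half kick.
#'
#' @param state simulation state list.
#' @param config engine configuration list from [engine_config()].
#' @return object of class `hemoflow_sim`.
#' @export
simulation <- function(state, config) {
  stopifnot(is.list(state), is.list(config))
  ptr <- cpp_sim_create(state, config)
  structure(list(ptr = ptr, config = config), class = "hemoflow_sim")
}

#' @export
print.hemoflow_sim <- function(x, ...) {
  st <- cpp_sim_state(x$ptr)
  cat("<hemoflow_sim> ", nrow(st$position), " particles, step ", st$step,
      if (isTRUE(x$config$obc$enabled)) " (open boundaries)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Advance the simulation
#'
#' @param sim `hemoflow_sim`.
#' @param steps number of velocity-Verlet steps.
#' @param sample_every accumulate observables every this many steps (0 =
#'   never).
#' @return the simulation, invisibly.
#' @export
sim_run <- function(sim, steps, sample_every = 0) {
  cpp_sim_run(sim$ptr, as.integer(steps), as.integer(sample_every))
  invisible(sim)
}

#' Snapshot the full simulation state
#'
#' Returns positions, velocities, species/region codes, the cell table and
#' the RNG stream states; the result can be passed back to [simulation()]
#' (with the same config) to restart bitwise-identically, or written with
#' [save_checkpoint()].
#'
#' @param sim `hemoflow_sim`.
#' @return state list.
#' @export
sim_state <- function(sim) cpp_sim_state(sim$ptr)

#' Retrieve accumulated observables
#'
#' Per-sample velocity-profile rows, pressure-slab rows, fluid temperature,
#' total momentum, main-domain counts, the per-step density and controller-P
#' logs, cumulative insertion/removal counters and the cell exit log.
#'
#' @param sim `hemoflow_sim`.
#' @return list of accumulators.
#' @export
sim_stats <- function(sim) cpp_sim_stats(sim$ptr)

#' Clear accumulated observables (e.g. after a burn-in)
#'
#' @param sim `hemoflow_sim`.
#' @export
sim_reset_stats <- function(sim) {
  cpp_sim_reset_stats(sim$ptr)
  invisible(sim)
}

#' Assemble an engine configuration
#'
#' @param dt time step.
#' @param seed master RNG seed (integer).
#' @param box simulation bounding box `c(xlo, xhi, ylo, yhi, zlo, zhi)`; must
#'   contain all particles including ghost images.
#' @param periodic logical length 3 (minimum-image periodicity per dimension;
#'   all FALSE for open-boundary runs, z TRUE for periodic pilot runs).
#' @param fluid [dpd_params()].
#' @param geometry a `wall_geometry` (or NULL for a pure periodic box).
#' @param membrane [membrane_params()] (required when cells are present).
#' @param templates list of mesh templates ([build_rbc_mesh()] objects).
#' @param obc [obc_layout()] or NULL; `main_volume` is required with OBC.
#' @param main_volume lumen volume of the main domain (density measurement).
#' @param thermostat logical; FALSE disables the random forces (conservative
#'   + dissipative only).
#' @param gfactors per-branch body-force factors `c(parent, daughter1,
#'   daughter2)` for imposing flow-rate ratios.
#' @param g_main_factor body-force factor applied on top in the main region;
#'   0 gives a pressure-driven main domain fed by the pilot piston (the
#'   setting under which the axial pressure profile is linear with slope
#'   `n g`).
#' @param limit_disp per-step displacement cap (packing relaxation only).
#' @param stats observable configuration from [stats_config()] or NULL.
#' @return config list for [simulation()].
#' @export
engine_config <- function(dt = 0.005, seed = 1L, box, periodic = c(FALSE, FALSE, FALSE),
                          fluid = dpd_params(), geometry = NULL,
                          membrane = NULL, templates = NULL, obc = NULL,
                          main_volume = NULL, thermostat = TRUE,
                          gfactors = c(1, 1, 1), g_main_factor = 1,
                          limit_disp = 0, stats = NULL) {
  cgeom <- if (is.null(geometry)) list(type = 0L) else geometry$cgeom
  ob <- NULL
  if (!is.null(obc)) {
    stopifnot(inherits(obc, "obc_layout"), !is.null(main_volume))
    outs <- lapply(obc$outlets, function(o)
      list(origin = as.numeric(o$origin), dir = as.numeric(o$dir),
           deletion_length = o$deletion_length, rho_target = o$rho_target,
           branch = as.integer(o$branch)))
    ob <- list(enabled = TRUE, generating_length = obc$generating_length,
               zone_width = obc$zone_width, h = obc$h, P0 = obc$P0,
               smooth_window = as.integer(obc$smooth_window),
               main_volume = main_volume, outlets = outs)
  }
  tmpl <- if (is.null(templates)) NULL else lapply(templates, mesh_as_list)
  list(dt = dt, seed = as.integer(seed), box = as.numeric(box),
       periodic = as.logical(periodic), fluid = unclass(fluid),
       geometry = cgeom,
       membrane = if (is.null(membrane)) NULL else unclass(membrane),
       templates = tmpl, obc = ob, thermostat = isTRUE(thermostat),
       gfactors = as.numeric(gfactors), g_main_factor = g_main_factor,
       limit_disp = limit_disp, stats = stats)
}

#' Observable accumulation settings
#'
#' @param vel_nbins radial velocity-profile bin count (0 disables).
#' @param vel_zlim z window for the velocity profile.
#' @param vel_rmax maximum radius (tube radius).
#' @param pres_nslabs axial pressure-slab count (0 disables).
#' @param pres_zlim z window for the pressure profile.
#' @param slab_volume lumen volume of one slab.
#' @return stats config list.
#' @export
stats_config <- function(vel_nbins = 0, vel_zlim = c(0, 0), vel_rmax = 1,
                         pres_nslabs = 0, pres_zlim = c(0, 0),
                         slab_volume = 1) {
  list(vel_nbins = as.integer(vel_nbins), vel_zmin = vel_zlim[1],
       vel_zmax = vel_zlim[2], vel_rmax = vel_rmax,
       pres_nslabs = as.integer(pres_nslabs), pres_zmin = pres_zlim[1],
       pres_zmax = pres_zlim[2], slab_volume = slab_volume)
}

#' Build a simulation state from components
#'
#' Particles are laid out as wall, then free fluid, then per-cell contiguous
#' vertex blocks (the engine requires cell vertices contiguous).
#'
#' @param wall wall particle positions (n x 3) or NULL.
#' @param wall_region integer region code per wall particle (0 generating,
#'   1 main) or a single value.
#' @param fluid_pos free fluid positions.
#' @param fluid_region region codes for the fluid.
#' @param fluid_vel fluid velocities (NULL = Maxwellian at `kBT`).
#' @param cells list of cell descriptors `list(vertices, template, region,
#'   A0, V0)` (template = index into the template list).
#' @param cell_vel list of vertex velocity matrices or NULL.
#' @param kBT thermal energy for Maxwellian initialization.
#' @return state list for [simulation()].
#' @export
make_sim_state <- function(wall = NULL, wall_region = 1L, fluid_pos,
                           fluid_region = 1L, fluid_vel = NULL,
                           cells = list(), cell_vel = NULL, kBT = 0.0945) {
  nw <- if (is.null(wall)) 0L else nrow(wall)
  nf <- nrow(fluid_pos)
  if (is.null(fluid_vel))
    fluid_vel <- matrix(rnorm(3 * nf, sd = sqrt(kBT)), nf, 3)
  pos <- rbind(if (nw) wall else NULL, fluid_pos)
  vel <- rbind(if (nw) matrix(0, nw, 3) else NULL, fluid_vel)
  species <- c(rep(1L, nw), rep(0L, nf))
  region <- c(rep_len(as.integer(wall_region), nw),
              rep_len(as.integer(fluid_region), nf))
  cell_id <- rep(NA_integer_, nw + nf)
  ctab <- list(first = integer(0), nv = integer(0), template = integer(0),
               region = integer(0), A0 = numeric(0), V0 = numeric(0),
               slaved = integer(0), master = integer(0), offz = numeric(0),
               alive = integer(0))
  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    v <- cl$vertices
    nv <- nrow(v)
    first <- nrow(pos) + 1L
    vv <- if (is.null(cell_vel)) matrix(rnorm(3 * nv, sd = sqrt(kBT)), nv, 3)
          else cell_vel[[k]]
    pos <- rbind(pos, v)
    vel <- rbind(vel, vv)
    species <- c(species, rep(2L, nv))
    region <- c(region, rep(as.integer(cl$region), nv))
    cell_id <- c(cell_id, rep(k, nv))
    ctab$first <- c(ctab$first, first)
    ctab$nv <- c(ctab$nv, nv)
    ctab$template <- c(ctab$template, as.integer(cl$template))
    ctab$region <- c(ctab$region, as.integer(cl$region))
    ctab$A0 <- c(ctab$A0, cl$A0)
    ctab$V0 <- c(ctab$V0, cl$V0)
    ctab$slaved <- c(ctab$slaved, 0L)
    ctab$master <- c(ctab$master, NA_integer_)
    ctab$offz <- c(ctab$offz, 0)
    ctab$alive <- c(ctab$alive, 1L)
  }
  list(position = pos, velocity = vel, species = species, region = region,
       cell_id = cell_id, cells = if (length(cells)) ctab else NULL)
}
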