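#' Scenario configuration
#'
#' Bundles geometry, fluid/membrane parameters, hematocrit, run lengths and
#' open-boundary settings for the end-to-end experiment families: straight
#' tube validation (single phase), OBC-vs-PBC suspension comparison, and
#' bifurcation sweeps (flow-rate ratio or bifurcation angle).
#'
#' @param kind one of "tube_validation", "obc_vs_pbc", "bifurcation".
#' @param d tube / parent diameter (DPD length units).
#' @param L_gen generating-region (pilot) length.
#' @param L_main main-domain length (tube kinds; integer multiple of `L_gen`
#'   is used for tiling the pilot state).
#' @param hematocrit RBC volume fraction in `[0, 0.6)`.
#' @param n_vertices vertices per cell mesh.
#' @param cell_radius nominal cell radius (mesh area = equal-area sphere).
#' @param fluid [dpd_params()].
#' @param membrane [membrane_params()].
#' @param bifurcation [bifurcation_spec()] (bifurcation kind only).
#' @param gfactors per-branch body-force factors (imposes the flow-rate
#'   ratio between daughters).
#' @param dt time step.
#' @param seed master seed.
#' @param equil_steps burn-in steps of the assembled open system.
#' @param production_steps sampled steps.
#' @param sample_every sampling stride.
#' @param deletion_length cell-deletion region length at each outlet.
#' @param P0,h,smooth_window outflow-controller settings.
#' @param rho_target main-domain density target (default fluid `n`).
#' @param pilot_chunk,pilot_tol,pilot_max_steps pilot convergence windows,
#'   relative tolerance and step budget (see [run_pilot()]; the attainable
#'   tolerance is bounded below by thermal flux noise at desk scales).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("tube_validation", "obc_vs_pbc",
                                     "bifurcation"),
                            d = 10, L_gen = 10, L_main = 10, hematocrit = 0,
                            n_vertices = 42, cell_radius = 2,
                            fluid = dpd_params(), membrane = membrane_params(),
                            bifurcation = NULL, gfactors = c(1, 1, 1),
                            dt = 0.005, seed = 1L, equil_steps = 2000,
                            production_steps = 4000, sample_every = 20,
                            deletion_length = 3, P0 = 0.5, h = 0.05,
                            smooth_window = 100, rho_target = NULL,
                            pilot_chunk = 2500, pilot_tol = 0.2,
                            pilot_max_steps = 30000) {
  kind <- match.arg(kind)
  stopifnot(hematocrit >= 0, hematocrit < 0.6)
  if (kind == "bifurcation" && is.null(bifurcation))
    stop("bifurcation kind requires a bifurcation_spec")
  if (is.null(rho_target)) rho_target <- fluid$n
  structure(as.list(environment()), class = "scenario_config")
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c3 <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c3^2 - d^2, 2 * (b * c3 - a * d), 2 * (b * d + a * c3),
           2 * (b * c3 + a * d), a^2 - b^2 + c3^2 - d^2, 2 * (c3 * d - a * b),
           2 * (b * d - a * c3), 2 * (c3 * d + a * b), a^2 - b^2 - c3^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Pack red blood cells into a region at a target hematocrit
#'
#' Random sequential insertion with rejection on mesh overlap: cell centers
#' and orientations are drawn uniformly, placements with any vertex outside
#' the lumen (margin `wall_margin`) or closer than `min_sep` to an already
#' placed cell are rejected. The achieved count is
#' `floor(hematocrit * V_lumen / V_cell)`; failure to reach it within
#' `max_attempts` attempts is an error reporting the achieved hematocrit.
#' A short soft relaxation (displacement-capped engine run) is applied by the
#' scenario builders, not here.
#'
#' @param geometry `wall_geometry`.
#' @param zlim axial placement window.
#' @param hematocrit target volume fraction.
#' @param template [build_rbc_mesh()] mesh (centered at the origin).
#' @param seed RNG seed.
#' @param lumen_vol lumen volume of the placement region (analytic for tubes;
#'   Monte-Carlo otherwise).
#' @param wall_margin minimum vertex clearance from the wall.
#' @param min_sep minimum vertex-vertex distance between different cells.
#' @param max_attempts rejection-sampling budget.
#' @param region region code for the placed cells (0 generating, 1 main).
#' @param periodic_z treat `zlim` as a periodic interval (pilot tubes):
#'   cells may straddle the seam and overlaps are checked minimum-image.
#' @return list `cells` (descriptors for [make_sim_state()]), `n_target`,
#'   `achieved_hematocrit`.
#' @export
pack_cells <- function(geometry, zlim, hematocrit, template, seed = 1,
                       lumen_vol = NULL, wall_margin = 0.25, min_sep = 0.55,
                       max_attempts = 30000, region = 0L, periodic_z = FALSE) {
  if (is.null(lumen_vol)) {
    if (!is.null(geometry$d))
      lumen_vol <- pi * (geometry$d / 2)^2 * diff(zlim)
    else
      lumen_vol <- lumen_volume(geometry, filter = function(p)
        p[, 3] >= zlim[1] & p[, 3] <= zlim[2])
  }
  n_target <- floor(hematocrit * lumen_vol / template$V0)
  if (n_target == 0)
    return(list(cells = list(), n_target = 0L, achieved_hematocrit = 0))
  set.seed(seed)
  ext <- max(sqrt(rowSums(template$vertices^2)))
  placed <- list()
  attempts <- 0
  bbox <- geometry$bbox
  Pz <- diff(zlim)
  shifts <- if (periodic_z) c(-Pz, 0, Pz) else 0
  while (length(placed) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1
    zr <- if (periodic_z) zlim else c(zlim[1] + ext, zlim[2] - ext)
    cen <- c(runif(1, bbox[1] + ext, bbox[2] - ext),
             runif(1, bbox[3] + ext, bbox[4] - ext),
             runif(1, zr[1], zr[2]))
    if (geometry$sdf(cen)[1] < ext * 0.35) next
    v <- template$vertices %*% t(random_rotation())
    v <- sweep(v, 2, cen, "+")
    if (any(cpp_sdf_many(geometry$cgeom, v) < wall_margin)) next
    ok <- TRUE
    for (q in placed) {
      for (sh in shifts) {
        qc <- attr(q, "center") + c(0, 0, sh)
        if (sqrt(sum((qc - cen)^2)) > 2 * ext + min_sep) next
        qs <- q
        qs[, 3] <- qs[, 3] + sh
        dmin <- min(as.matrix(stats::dist(rbind(v, qs)))[seq_len(nrow(v)),
                                                         nrow(v) + seq_len(nrow(qs))])
        if (dmin < min_sep) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    attr(v, "center") <- cen
    placed[[length(placed) + 1]] <- v
  }
  if (length(placed) < n_target)
    stop(sprintf(
      "hematocrit %.3f unreachable after %d attempts (achieved %.3f)",
      hematocrit, max_attempts,
      length(placed) * template$V0 / lumen_vol))
  cells <- lapply(placed, function(v)
    list(vertices = v[, , drop = FALSE], template = 1L, region = region,
         A0 = template$A0, V0 = template$V0))
  list(cells = cells, n_target = n_target,
       achieved_hematocrit = n_target * template$V0 / lumen_vol)
}

# split a full engine state into wall / free fluid / per-cell components
split_state <- function(st) {
  wall <- st$species == 1L
  fluid <- st$species == 0L
  cells <- list()
  if (!is.null(st$cells) && length(st$cells$first)) {
    for (k in seq_along(st$cells$first)) {
      if (!st$cells$alive[k]) next
      idx <- st$cells$first[k] + seq_len(st$cells$nv[k]) - 1L
      cells[[length(cells) + 1]] <- list(
        vertices = st$position[idx, , drop = FALSE],
        velocity = st$velocity[idx, , drop = FALSE],
        template = st$cells$template[k], A0 = st$cells$A0[k],
        V0 = st$cells$V0[k])
    }
  }
  list(wall_pos = st$position[wall, , drop = FALSE],
       fluid_pos = st$position[fluid, , drop = FALSE],
       fluid_vel = st$velocity[fluid, , drop = FALSE],
       cells = cells)
}

#' Run a periodic pilot simulation until the flow is fully developed
#'
#' Body-force-driven periodic tube flow (the generating-region physics run in
#' isolation). After packing and a displacement-capped relaxation, the run
#' proceeds in chunks until the window-to-window change of the binned
#' velocity profile drops below `tol` (relative to the profile maximum);
#' non-convergence within `max_steps` is an error carrying the profile
#' history.
#'
#' @param d tube diameter.
#' @param L tube (= generating region) length; the periodic box.
#' @param hematocrit cell volume fraction.
#' @param template cell mesh from [build_rbc_mesh()] (required if
#'   `hematocrit > 0`).
#' @param fluid,membrane parameter sets.
#' @param dt time step.
#' @param seed master seed.
#' @param relax_steps displacement-capped relaxation steps after packing.
#' @param chunk steps per convergence window.
#' @param max_steps convergence budget.
#' @param tol relative window-to-window profile change for convergence.
#' @param bins radial profile bins.
#' @param sample_every sampling stride within windows.
#' @return list `state` (checkpointable), `geometry`, `profile`
#'   (`flow_profile` of the last window), `converged`, `steps`, `history`.
#' @export
run_pilot <- function(d, L, hematocrit = 0, template = NULL,
                      fluid = dpd_params(), membrane = membrane_params(),
                      dt = 0.005, seed = 1L, relax_steps = 300, chunk = 1500,
                      max_steps = 30000, tol = 0.05, bins = 12,
                      sample_every = 25) {
  geom <- build_tube(d, L, fluid = fluid, seed = seed, wall_pad = 0)
  # periodic wall cloud: keep [0, L) only
  keep <- geom$wall[, 3] >= 0 & geom$wall[, 3] < L
  wall <- geom$wall[keep, , drop = FALSE]
  cells <- list()
  if (hematocrit > 0) {
    stopifnot(!is.null(template))
    pk <- pack_cells(geom, c(0, L), hematocrit, template, seed = seed + 1,
                     region = 1L, periodic_z = TRUE)
    cells <- pk$cells
  }
  set.seed(seed + 2)
  st <- make_sim_state(wall = wall, wall_region = 1L,
                       fluid_pos = geom$fluid, fluid_region = 1L,
                       cells = cells, kBT = fluid$kBT)
  R <- d / 2
  box <- c(geom$bbox[1:4], 0, L)
  statcfg <- stats_config(vel_nbins = bins, vel_zlim = c(0, L), vel_rmax = R)
  tpl <- if (is.null(template)) NULL else list(template)
  if (length(cells) && relax_steps > 0) {
    fl0 <- fluid; fl0$g <- 0
    cfg0 <- engine_config(dt = min(dt, 0.002), seed = seed, box = box,
                          periodic = c(FALSE, FALSE, TRUE), fluid = fl0,
                          geometry = geom, membrane = membrane,
                          templates = tpl, limit_disp = 0.02, stats = statcfg)
    sim0 <- simulation(st, cfg0)
    sim_run(sim0, relax_steps)
    st <- sim_state(sim0)
  }
  cfg <- engine_config(dt = dt, seed = seed, box = box,
                       periodic = c(FALSE, FALSE, TRUE), fluid = fluid,
                       geometry = geom, membrane = membrane,
                       templates = tpl, stats = statcfg)
  sim <- simulation(st, cfg)
  prev <- NULL
  history <- list()
  steps <- 0
  converged <- FALSE
  while (steps < max_steps) {
    sim_reset_stats(sim)
    sim_run(sim, chunk, sample_every)
    steps <- steps + chunk
    stt <- sim_stats(sim)
    m <- colMeans(stt$profile, na.rm = TRUE)
    cnt <- colMeans(stt$profile_counts)
    history[[length(history) + 1]] <- m
    if (!is.null(prev)) {
      # count-weighted RMS window-to-window change relative to the profile
      # scale (inner radial bins hold few particles and are noise-dominated)
      scale <- max(abs(m), na.rm = TRUE)
      ok <- is.finite(m) & is.finite(prev)
      drms <- sqrt(sum(cnt[ok] * (m - prev)[ok]^2) / sum(cnt[ok]))
      if (scale > 0 && drms / scale < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- m
  }
  if (!converged)
    stop(structure(class = c("pilot_not_converged", "error", "condition"),
                   list(message = sprintf(
                          "pilot flow not fully developed after %d steps", steps),
                        call = sys.call(), history = history)))
  stt <- sim_stats(sim)
  edges <- seq(0, R, length.out = bins + 1)
  prof <- profile_from_samples(stt$profile, edges)
  list(state = sim_state(sim), geometry = geom, profile = prof,
       converged = converged, steps = steps, history = history,
       d = d, L = L, fluid = fluid, membrane = membrane,
       template = template, dt = dt, seed = seed)
}

#' Assemble an open-boundary tube simulation from a pilot checkpoint
#'
#' The pilot state becomes the generating region (fluid, cells and periodic
#' wall structure, one-way coupled); the main domain is initialized by
#' tiling the pilot state downstream (`main_tiles` copies), giving a
#' near-developed initial flow. One outlet with the adaptive outflow
#' membrane sits at the far end.
#'
#' @param pilot result of [run_pilot()].
#' @param main_tiles number of pilot-length tiles forming the main domain.
#' @param deletion_length cell-deletion region length.
#' @param rho_target density target; a number, or `"auto"` to calibrate
#'   the sustainable density in place (a short pre-run with the membrane
#'   held half open measures the density the copy border actually delivers;
#'   the adaptive controller then holds that value). The default is the
#'   assembled main domain's initial number density (fluid plus membrane
#'   vertices per lumen volume). Targets above what the border can deliver
#'   pin the reflection probability at 1, which closes the outlet and
#'   chokes the flow -- a desk-scale artifact discussed in the vignette.
#' @param P0,h,smooth_window controller settings.
#' @param seed master seed for the assembled run.
#' @param include_cells copy pilot cells into the main-domain tiles.
#' @param dt time step for the open-boundary run; defaults to
#'   `min(pilot$dt, 0.003)` (the one-way coupled border tolerates a smaller
#'   step than the periodic pilot: local density pile-ups against the
#'   dissipative friction are stiffer there).
#' @param vel_zlim,vel_nbins velocity-profile window (default: interior of
#'   the main domain) and bins.
#' @param pres_nslabs axial pressure slabs over the main domain (0 = off).
#' @param g_main_factor main-region body-force factor: 1 drives the main
#'   domain like the pilot; 0 makes it pressure-driven by the inflow piston
#'   (the validation setting where `dP/dz = n g`).
#' @return `hemoflow_sim` with attributes `layout`, `geometry`.
#' @export
obc_tube_simulation <- function(pilot, main_tiles = 1, deletion_length = 3,
                                rho_target = NULL, P0 = 0.5, h = 0.05,
                                smooth_window = 100, seed = pilot$seed + 10,
                                include_cells = TRUE, vel_zlim = NULL,
                                vel_nbins = 12, pres_nslabs = 0, dt = NULL,
                                g_main_factor = 1) {
  if (is.null(dt)) dt <- min(pilot$dt, 0.003)
  fluid <- pilot$fluid
  d <- pilot$d
  R <- d / 2
  Lg <- pilot$L
  Lm <- main_tiles * Lg
  zend <- Lg + Lm
  sp <- split_state(pilot$state)

  # main-domain walls: independent density-matched shell over [Lg, zend + 2]
  mw <- build_tube(d, Lm + 2, fluid = fluid, seed = seed + 7, wall_pad = 0)
  mwall <- mw$wall
  mwall[, 3] <- mwall[, 3] + Lg
  wall <- rbind(sp$wall_pos, mwall)
  wall_region <- c(rep(0L, nrow(sp$wall_pos)), rep(1L, nrow(mwall)))

  fluid_pos <- sp$fluid_pos
  fluid_vel <- sp$fluid_vel
  fluid_region <- rep(0L, nrow(fluid_pos))
  cells <- list()
  cvel <- list()
  for (cl in sp$cells) {
    cells[[length(cells) + 1]] <- list(vertices = cl$vertices, template = 1L,
                                       region = 0L, A0 = cl$A0, V0 = cl$V0)
    cvel[[length(cvel) + 1]] <- cl$velocity
  }
  for (k in seq_len(main_tiles)) {
    fp <- sp$fluid_pos; fp[, 3] <- fp[, 3] + k * Lg
    fluid_pos <- rbind(fluid_pos, fp)
    fluid_vel <- rbind(fluid_vel, sp$fluid_vel)
    fluid_region <- c(fluid_region, rep(1L, nrow(fp)))
    if (include_cells) for (cl in sp$cells) {
      v <- cl$vertices; v[, 3] <- v[, 3] + k * Lg
      if (max(v[, 3]) > zend - 0.5) next  # keep clear of the outlet
      # a seam-straddling pilot cell already exists in the generating region
      # as the (wrapped) original: its tile copy would overlap it exactly
      if (min(v[, 3]) < Lg + 0.1) next
      cells[[length(cells) + 1]] <- list(vertices = v, template = 1L,
                                         region = 1L, A0 = cl$A0, V0 = cl$V0)
      cvel[[length(cvel) + 1]] <- cl$velocity
    }
  }
  st <- make_sim_state(wall = wall, wall_region = wall_region,
                       fluid_pos = fluid_pos, fluid_region = fluid_region,
                       fluid_vel = fluid_vel, cells = cells, cell_vel = cvel,
                       kBT = fluid$kBT)
  calibrate <- identical(rho_target, "auto")
  if (is.null(rho_target) || calibrate) {
    n_main <- sum(fluid_region == 1L) +
      sum(vapply(cells, function(cl)
        if (cl$region == 1L) nrow(cl$vertices) else 0L, 0L))
    rho_target <- n_main / (pi * R^2 * Lm)
  }
  layout <- obc_layout(Lg, zone_width = fluid$r_c,
                       outlets = list(list(origin = c(0, 0, zend),
                                           dir = c(0, 0, 1), branch = 0L)),
                       deletion_length = deletion_length, h = h, P0 = P0,
                       rho_target = rho_target,
                       smooth_window = smooth_window)
  if (is.null(vel_zlim)) vel_zlim <- c(Lg + 1.5, zend - max(deletion_length, 1.5))
  statcfg <- stats_config(vel_nbins = vel_nbins, vel_zlim = vel_zlim,
                          vel_rmax = R,
                          pres_nslabs = pres_nslabs,
                          pres_zlim = c(Lg + 1, zend - 1),
                          slab_volume = pi * R^2 * (zend - 2 - Lg) /
                            max(1, pres_nslabs))
  box <- c(pilot$geometry$bbox[1:4], -(fluid$r_c + 1.5), zend + 2.5)
  tpl <- if (is.null(pilot$template)) NULL else list(pilot$template)
  mkcfg <- function(lay, sd) {
    engine_config(dt = dt, seed = sd, box = box,
                  periodic = c(FALSE, FALSE, FALSE), fluid = fluid,
                  geometry = pilot$geometry, membrane = pilot$membrane,
                  templates = tpl, obc = lay,
                  main_volume = pi * R^2 * Lm,
                  g_main_factor = g_main_factor, stats = statcfg)
  }
  if (calibrate) {
    # hold the membrane half open (vanishing gain) and measure the density
    # the copy border sustains; that is the density an open steady flow can
    # actually run at, and becomes the adaptive controller's target
    lay0 <- layout
    lay0$h <- 1e-12
    sim0 <- simulation(st, mkcfg(lay0, seed))
    sim_run(sim0, 2500)
    rho_target <- mean(tail(sim_stats(sim0)$rho, 1200))
    layout <- obc_layout(Lg, zone_width = fluid$r_c,
                         outlets = list(list(origin = c(0, 0, zend),
                                             dir = c(0, 0, 1), branch = 0L)),
                         deletion_length = deletion_length, h = h, P0 = P0,
                         rho_target = rho_target,
                         smooth_window = smooth_window)
    st <- sim_state(sim0)
  }
  sim <- simulation(st, mkcfg(layout, seed))
  attr(sim, "layout") <- layout
  attr(sim, "zend") <- zend
  sim
}

#' Assemble an open-boundary bifurcation simulation
#'
#' The pilot (periodic parent-tube suspension) becomes the generating region
#' inside the parent branch; the main domain (rest of the parent plus both
#' daughters) starts cell free and fills with duplicated cells flowing in
#' through the copy border. Each daughter end carries an outflow membrane
#' and a deletion region logging cell exits for [recovery_efficiency()].
#'
#' @param pilot result of [run_pilot()] with `d` = parent diameter and
#'   `L` <= the parent length of `spec`.
#' @param spec [bifurcation_spec()]; the parent length must exceed the pilot
#'   length.
#' @param gfactors per-branch body-force factors (parent, daughter 1,
#'   daughter 2): unequal daughter factors impose a flow-rate ratio.
#' @param deletion_length cell-deletion region length along each daughter.
#' @param rho_target,P0,h,smooth_window controller settings; `rho_target`
#'   defaults to the fluid density `n` (the cell-free initial main
#'   filling): the incoming vertex-rich suspension then keeps the
#'   controller in its open, proportional regime.
#' @param seed master seed.
#' @param dt time step (defaults to `min(pilot$dt, 0.003)`).
#' @return `hemoflow_sim` with attribute `geometry` (the bifurcation).
#' @export
obc_bifurcation_simulation <- function(pilot, spec, gfactors = c(1, 1, 1),
                                       deletion_length = 4, rho_target = NULL,
                                       P0 = 0.5, h = 0.05,
                                       smooth_window = 100,
                                       seed = pilot$seed + 20, dt = NULL) {
  if (is.null(dt)) dt <- min(pilot$dt, 0.003)
  fluid <- pilot$fluid
  Lg <- pilot$L
  stopifnot(spec$parent_length > Lg + fluid$r_c)
  bif <- build_bifurcation(spec, fluid = fluid, seed = seed + 3)
  sp <- split_state(pilot$state)

  mwall <- bif$wall[bif$wall[, 3] >= Lg, , drop = FALSE]
  wall <- rbind(sp$wall_pos, mwall)
  wall_region <- c(rep(0L, nrow(sp$wall_pos)), rep(1L, nrow(mwall)))
  mfluid <- bif$fluid[bif$fluid[, 3] > Lg, , drop = FALSE]
  fluid_pos <- rbind(sp$fluid_pos, mfluid)
  fluid_region <- c(rep(0L, nrow(sp$fluid_pos)), rep(1L, nrow(mfluid)))
  set.seed(seed + 4)
  fluid_vel <- rbind(sp$fluid_vel,
                     matrix(rnorm(3 * nrow(mfluid), sd = sqrt(fluid$kBT)),
                            nrow(mfluid), 3))
  cells <- list(); cvel <- list()
  for (cl in sp$cells) {
    cells[[length(cells) + 1]] <- list(vertices = cl$vertices, template = 1L,
                                       region = 0L, A0 = cl$A0, V0 = cl$V0)
    cvel[[length(cvel) + 1]] <- cl$velocity
  }
  st <- make_sim_state(wall = wall, wall_region = wall_region,
                       fluid_pos = fluid_pos, fluid_region = fluid_region,
                       fluid_vel = fluid_vel, cells = cells, cell_vel = cvel,
                       kBT = fluid$kBT)
  # achievable density target: the cell-free initial main filling (the
  # controller then passes the vertex-rich incoming suspension freely)
  if (is.null(rho_target)) rho_target <- fluid$n
  outs <- lapply(bif$outlets, function(o)
    list(origin = o$origin, dir = o$dir, branch = o$branch))
  layout <- obc_layout(Lg, zone_width = fluid$r_c, outlets = outs,
                       deletion_length = deletion_length, h = h, P0 = P0,
                       rho_target = rho_target, smooth_window = smooth_window)
  Vmain <- lumen_volume(bif, seed = seed + 5, filter = function(p) {
    s1 <- (p[, 1] - bif$outlets[[1]]$origin[1]) * bif$outlets[[1]]$dir[1] +
      (p[, 3] - bif$outlets[[1]]$origin[3]) * bif$outlets[[1]]$dir[3]
    s2 <- (p[, 1] - bif$outlets[[2]]$origin[1]) * bif$outlets[[2]]$dir[1] +
      (p[, 3] - bif$outlets[[2]]$origin[3]) * bif$outlets[[2]]$dir[3]
    p[, 3] > Lg & s1 < 0 & s2 < 0
  })
  box <- bif$bbox
  box[5] <- -(fluid$r_c + 1.5)
  tpl <- if (is.null(pilot$template)) NULL else list(pilot$template)
  cfg <- engine_config(dt = dt, seed = seed, box = box,
                       periodic = c(FALSE, FALSE, FALSE), fluid = fluid,
                       geometry = bif, membrane = pilot$membrane,
                       templates = tpl, obc = layout, main_volume = Vmain,
                       gfactors = gfactors, stats = NULL)
  sim <- simulation(st, cfg)
  attr(sim, "layout") <- layout
  attr(sim, "geometry") <- bif
  sim
}

#' Run a configured scenario end to end
#'
#' Dispatches on `config$kind`:
#' \describe{
#'   \item{tube_validation}{single-phase pilot, OBC tube, burn-in, sampled
#'     production; returns OBC and pilot profiles, Poiseuille fit and the
#'     axial pressure profile.}
#'   \item{obc_vs_pbc}{suspension pilot; continued periodic sampling and an
#'     OBC run over the same geometry; returns both profiles.}
#'   \item{bifurcation}{suspension pilot in the parent, bifurcation main
#'     domain; returns the recovery record and controller/exit logs.}
#' }
#'
#' @param config [scenario_config()].
#' @return list of scenario outputs (same seed + config gives identical
#'   results).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  template <- NULL
  if (config$hematocrit > 0) {
    set.seed(config$seed)
    template <- build_rbc_mesh(config$n_vertices, radius = config$cell_radius)
  }
  pilot <- run_pilot(config$d, config$L_gen, config$hematocrit, template,
                     fluid = config$fluid, membrane = config$membrane,
                     dt = config$dt, seed = config$seed,
                     chunk = config$pilot_chunk, tol = config$pilot_tol,
                     max_steps = config$pilot_max_steps)
  if (config$kind == "bifurcation") {
    sim <- obc_bifurcation_simulation(pilot, config$bifurcation,
                                      gfactors = config$gfactors,
                                      deletion_length = config$deletion_length,
                                      rho_target = config$rho_target,
                                      P0 = config$P0, h = config$h,
                                      smooth_window = config$smooth_window)
    sim_run(sim, config$equil_steps)
    sim_reset_stats(sim)
    sim_run(sim, config$production_steps, config$sample_every)
    stt <- sim_stats(sim)
    rec <- recovery_efficiency(stt$exits, n_branches = 2,
                               fluid_removed = stt$removed_fluid)
    return(list(kind = config$kind, pilot = pilot, stats = stt,
                recovery = rec, config = config))
  }
  tiles <- max(1L, round(config$L_main / config$L_gen))
  sim <- obc_tube_simulation(pilot, main_tiles = tiles,
                             deletion_length = config$deletion_length,
                             rho_target = config$rho_target, P0 = config$P0,
                             h = config$h,
                             smooth_window = config$smooth_window,
                             pres_nslabs = if (config$kind ==
                                               "tube_validation") 8 else 0)
  sim_run(sim, config$equil_steps)
  sim_reset_stats(sim)
  sim_run(sim, config$production_steps, config$sample_every)
  stt <- sim_stats(sim)
  R <- config$d / 2
  edges <- seq(0, R, length.out = ncol(stt$profile) + 1)
  prof <- profile_from_samples(stt$profile, edges)
  out <- list(kind = config$kind, pilot = pilot, stats = stt,
              profile = prof, config = config)
  if (config$kind == "tube_validation") {
    ng <- config$fluid$n * config$fluid$g
    out$poiseuille <- fit_poiseuille(prof$centers, prof$mean, config$d, ng)
  }
  if (config$kind == "obc_vs_pbc") {
    out$reference_profile <- continue_pilot_sampling(
      pilot, steps = config$production_steps,
      sample_every = config$sample_every)
  }
  out
}

#' Continue a pilot run periodically and sample its velocity profile
#'
#' Rebuilds the periodic simulation from the pilot checkpoint (bitwise
#' restartable: the checkpoint carries the RNG stream states) and
#' accumulates the reference profile used for OBC-vs-PBC comparisons.
#'
#' @param pilot result of [run_pilot()].
#' @param steps sampled steps.
#' @param sample_every sampling stride.
#' @param bins radial bins (default: as in the pilot).
#' @return `flow_profile` with block standard errors.
#' @export
continue_pilot_sampling <- function(pilot, steps, sample_every = 25,
                                    bins = 12) {
  R <- pilot$d / 2
  box <- c(pilot$geometry$bbox[1:4], 0, pilot$L)
  statcfg <- stats_config(vel_nbins = bins, vel_zlim = c(0, pilot$L),
                          vel_rmax = R)
  tpl <- if (is.null(pilot$template)) NULL else list(pilot$template)
  cfg <- engine_config(dt = pilot$dt, seed = pilot$seed, box = box,
                       periodic = c(FALSE, FALSE, TRUE), fluid = pilot$fluid,
                       geometry = pilot$geometry, membrane = pilot$membrane,
                       templates = tpl, stats = statcfg)
  sim <- simulation(pilot$state, cfg)
  sim_run(sim, steps, sample_every)
  stt <- sim_stats(sim)
  profile_from_samples(stt$profile, seq(0, R, length.out = bins + 1))
}
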