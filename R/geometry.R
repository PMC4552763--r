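#' @title Wall geometries: frozen-particle shells with bounce-back
#' @description Solid walls are modeled by freezing layers of particles in a
#'   shell outside the wetted lumen, combined with bounce-back reflection of
#'   any fluid or membrane particle that crosses the lumen boundary (no-slip).
#'   Wall particles are frozen copies of an equilibrated fluid cloud
#'   (density-matched), which reduces near-wall density artifacts compared to
#'   lattice walls.
#' @name wall-geometry
NULL

# Equilibrate a homogeneous DPD fluid in a fully periodic box and return the
# particle positions: used to cut density-matched frozen walls and initial
# fluid fillings out of one relaxed point cloud.
equilibrated_cloud <- function(bbox, fluid = dpd_params(), seed = 1,
                               steps = 250, dt = 0.005) {
  vol <- prod(bbox[c(2, 4, 6)] - bbox[c(1, 3, 5)])
  n <- round(fluid$n * vol)
  set.seed(seed)
  pos <- cbind(runif(n, bbox[1], bbox[2]), runif(n, bbox[3], bbox[4]),
               runif(n, bbox[5], bbox[6]))
  vel <- matrix(rnorm(3 * n, sd = sqrt(fluid$kBT)), n, 3)
  fl <- unclass(fluid)
  fl$g <- 0
  cfg <- list(dt = dt, seed = seed, box = as.numeric(bbox),
              periodic = c(TRUE, TRUE, TRUE), fluid = fl,
              geometry = list(type = 0L), thermostat = TRUE,
              obc = NULL, stats = NULL, templates = NULL)
  st <- list(position = pos, velocity = vel,
             species = rep(0L, n), region = rep(1L, n),
             cell_id = rep(NA_integer_, n), cells = NULL)
  ptr <- cpp_sim_create(st, cfg)
  cpp_sim_run(ptr, as.integer(steps), 0L)
  cpp_sim_state(ptr)$position
}

new_wall_geometry <- function(cgeom, wall, fluid_fill, thickness, density,
                              bbox, extra = list()) {
  structure(c(list(cgeom = cgeom, wall = wall, fluid = fluid_fill,
                   thickness = thickness, density = density, bbox = bbox,
                   sdf = function(p) cpp_sdf_many(cgeom, rbind(p)),
                   branch = function(p) cpp_branch_many(cgeom, rbind(p))),
              extra),
            class = "wall_geometry")
}

#' Build a straight cylindrical tube
#'
#' Cylindrical lumen of diameter `d` along z, `z` in `[0, L]`. Frozen wall
#' particles fill a shell of thickness >= `r_c` outside the lumen at the
#' fluid number density; an equilibrated fluid filling of the lumen is
#' returned alongside (positions only).
#'
#' @param d tube diameter.
#' @param L tube length (walls and filling span `[0, L]`, with `wall_pad`
#'   extra wall length at each end for force coverage near open faces).
#' @param fluid [dpd_params()] (sets density, cutoff and temperature).
#' @param thickness wall shell thickness (default `r_c`).
#' @param seed RNG seed for the equilibrated cloud.
#' @param wall_pad extra wall length beyond `[0, L]`.
#' @return `wall_geometry` with `$wall` and `$fluid` position matrices,
#'   `$sdf` (inside-positive signed distance) and `$cgeom` (engine geometry).
#' @export
build_tube <- function(d, L, fluid = dpd_params(), thickness = fluid$r_c,
                       seed = 1, wall_pad = 2) {
  stopifnot(d > 0, L > 0)
  R <- d / 2
  pad <- R + thickness + 0.05
  bbox <- c(-pad, pad, -pad, pad, -wall_pad, L + wall_pad)
  cloud <- equilibrated_cloud(bbox, fluid, seed)
  cgeom <- list(type = 1L, radius = R)
  s <- cpp_sdf_many(cgeom, cloud)
  wall <- cloud[s < 0 & s >= -thickness, , drop = FALSE]
  fl <- cloud[s > 0 & cloud[, 3] >= 0 & cloud[, 3] < L, , drop = FALSE]
  new_wall_geometry(cgeom, wall, fl, thickness, fluid$n, bbox,
                    list(d = d, L = L, lumen_volume = pi * R^2 * L))
}

#' Bifurcation specification
#'
#' Geometry of a planar Y-bifurcation: a parent tube along z splitting at the
#' junction into two daughters in the x-z plane. `theta` is the bifurcation
#' angle between the daughter axes; by default it is split symmetrically, or
#' daughter 1 (the "main" branch) can be held at a fixed `tilt` from the
#' parent axis while daughter 2 (the "side" branch) takes `theta - tilt`.
#'
#' @param parent_diameter,daughter_diameters parent and daughter diameters
#'   (daughters as length-2 vector).
#' @param theta bifurcation angle between the daughters, degrees (0, 180).
#' @param tilt angle of daughter 1 from the parent axis, degrees; default
#'   `theta/2` (symmetric).
#' @param parent_length axial length of the parent branch (junction at
#'   `z = parent_length`).
#' @param daughter_length length of each daughter along its own axis
#'   (length-2 or scalar).
#' @param phi_d target flow-rate ratio between daughters (diagnostic).
#' @return object of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(parent_diameter, daughter_diameters, theta,
                             tilt = theta / 2, parent_length,
                             daughter_length, phi_d = 1) {
  daughter_diameters <- rep_len(daughter_diameters, 2)
  daughter_length <- rep_len(daughter_length, 2)
  stopifnot(parent_diameter > 0, all(daughter_diameters > 0),
            theta > 0, theta < 180, phi_d > 0)
  structure(list(parent_diameter = parent_diameter,
                 daughter_diameters = daughter_diameters, theta = theta,
                 tilt = tilt, parent_length = parent_length,
                 daughter_length = daughter_length, phi_d = phi_d),
            class = "bifurcation_spec")
}

#' Build a Y-bifurcation wall geometry
#'
#' The lumen is the sharp union of the parent and daughter capped cylinders
#' (signed distance = max over branches); each daughter end is registered as
#' an outlet plane (origin + outward normal) for the open-boundary module.
#'
#' @param spec a [bifurcation_spec()].
#' @inheritParams build_tube
#' @return `wall_geometry` with `$outlets` (list of origin/dir/branch),
#'   `$wall`, `$fluid`, `$sdf`, `$cgeom`.
#' @export
build_bifurcation <- function(spec, fluid = dpd_params(),
                              thickness = fluid$r_c, seed = 1, wall_pad = 2) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  a1 <- spec$tilt * pi / 180
  a2 <- (spec$theta - spec$tilt) * pi / 180
  dir1 <- c(sin(a1), 0, cos(a1))
  dir2 <- c(-sin(a2), 0, cos(a2))
  zj <- spec$parent_length
  Rd <- spec$daughter_diameters / 2
  Ld <- spec$daughter_length
  o1 <- c(0, 0, zj) + Ld[1] * dir1
  o2 <- c(0, 0, zj) + Ld[2] * dir2
  if (sqrt(sum((o1 - o2)^2)) < sum(Rd))
    stop("overlapping outlets: daughter end caps intersect")
  cgeom <- list(type = 2L, parent_radius = spec$parent_diameter / 2,
                junction_z = zj, dir1 = dir1, dir2 = dir2,
                daughter_radius = Rd, daughter_length = Ld)
  reach_x <- max(abs(o1[1]), abs(o2[1])) + max(Rd) + thickness + 0.05
  reach_x <- max(reach_x, spec$parent_diameter / 2 + thickness + 0.05)
  reach_z <- max(o1[3], o2[3]) + max(Rd) + wall_pad
  pad_y <- max(spec$parent_diameter / 2, max(Rd)) + thickness + 0.05
  bbox <- c(-reach_x, reach_x, -pad_y, pad_y, -wall_pad, reach_z)
  cloud <- equilibrated_cloud(bbox, fluid, seed)
  s <- cpp_sdf_many(cgeom, cloud)
  wall <- cloud[s < 0 & s >= -thickness & cloud[, 3] >= 0, , drop = FALSE]
  # fluid filling: inside the lumen and upstream of every outlet plane
  inside <- s > 0 & cloud[, 3] >= 0
  so1 <- (cloud[, 1] - o1[1]) * dir1[1] + (cloud[, 3] - o1[3]) * dir1[3]
  so2 <- (cloud[, 1] - o2[1]) * dir2[1] + (cloud[, 3] - o2[3]) * dir2[3]
  fl <- cloud[inside & so1 < 0 & so2 < 0, , drop = FALSE]
  outlets <- list(list(origin = o1, dir = dir1, branch = 1L),
                  list(origin = o2, dir = dir2, branch = 2L))
  new_wall_geometry(cgeom, wall, fl, thickness, fluid$n, bbox,
                    list(spec = spec, outlets = outlets))
}

#' Monte-Carlo lumen volume
#'
#' Uniform-sampling estimate of the wetted volume, optionally restricted by a
#' point filter (e.g. to the main simulation domain between the copy border
#' and the outlet planes).
#'
#' @param geometry a `wall_geometry`.
#' @param n_points sample count.
#' @param seed RNG seed.
#' @param filter optional function(points) -> logical, applied on top of the
#'   inside-lumen test.
#' @return volume estimate.
#' @export
lumen_volume <- function(geometry, n_points = 2e5, seed = 1, filter = NULL) {
  bbox <- geometry$bbox
  set.seed(seed)
  p <- cbind(runif(n_points, bbox[1], bbox[2]),
             runif(n_points, bbox[3], bbox[4]),
             runif(n_points, bbox[5], bbox[6]))
  inside <- cpp_sdf_many(geometry$cgeom, p) > 0 & p[, 3] >= 0
  if (!is.null(filter)) inside <- inside & filter(p)
  vol_box <- prod(bbox[c(2, 4, 6)] - bbox[c(1, 3, 5)])
  mean(inside) * vol_box
}

#' Bounce-back reflection at the walls
#'
#' For particles that crossed the lumen boundary during the last step, the
#' position is reflected across the crossing point along the incoming
#' trajectory and the full velocity vector is negated (bounce-back, not
#' specular: the tangential component reverses too, enforcing no-slip). A
#' particle found deeper than one step inside the wall is clamped to the
#' surface with a warning.
#'
#' @param pos_old,pos_new n x 3 positions before/after the drift.
#' @param vel n x 3 velocities.
#' @param geometry `wall_geometry`.
#' @return list `position`, `velocity`, `crossed` (logical), `clamped`
#'   (count).
#' @export
bounce_back <- function(pos_old, pos_new, vel, geometry) {
  pos_old <- unname(rbind(pos_old))
  pos_new <- unname(rbind(pos_new))
  vel <- unname(rbind(vel))
  sdf <- function(p) cpp_sdf_many(geometry$cgeom, p)
  out <- sdf(pos_new) < 0
  clamped <- 0L
  for (i in which(out)) {
    p0 <- pos_old[i, ]; p1 <- pos_new[i, ]
    if (sdf(rbind(p0))[1] < 0) { # deep penetration: clamp to surface
      base <- sdf(rbind(p1))[1]
      g <- vapply(1:3, function(c3) {
        pp <- p1; pp[c3] <- pp[c3] + 1e-4
        (sdf(rbind(pp))[1] - base) / 1e-4
      }, 0)
      gn <- sqrt(sum(g^2))
      if (gn > 0) pos_new[i, ] <- p1 + (-base + 0.01) * g / gn
      vel[i, ] <- -vel[i, ]
      clamped <- clamped + 1L
      warning("particle deeper than one step inside the wall: clamped")
      next
    }
    a <- 0; b <- 1
    for (it in 1:30) {
      m <- (a + b) / 2
      if (sdf(rbind(p0 + m * (p1 - p0)))[1] >= 0) a <- m else b <- m
    }
    q <- p0 + a * (p1 - p0)
    pos_new[i, ] <- 2 * q - p1
    vel[i, ] <- -vel[i, ]
    if (sdf(rbind(pos_new[i, ]))[1] < 0) {
      pos_new[i, ] <- q
      clamped <- clamped + 1L
    }
  }
  list(position = pos_new, velocity = vel, crossed = out, clamped = clamped)
}
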