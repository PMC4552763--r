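#' Open-boundary layout
#'
#' Geometric decomposition of an open system along the flow axis: a periodic
#' generating region `z` in `[0, Lg]` whose periodicity is implemented with
#' ghost particles (zones A2 = `[0, w)` and A3 = `(Lg - w, Lg]` are ghost
#' sources; their images are placed in A4 = `(Lg, Lg + w]` and
#' A1 = `[-w, 0)`), the copy border at the downstream face `z = Lg`, the main
#' simulation domain beyond it, and per-outlet deletion regions ending at the
#' outflow planes. Zone width `w` must equal the maximum interaction cutoff.
#'
#' @param generating_length length `Lg` of the generating region; must be at
#'   least twice the zone width.
#' @param zone_width ghost-zone width = maximum of all force cutoff radii.
#' @param outlets list of outlet descriptors `list(origin, dir, branch)`
#'   (outward unit normal `dir`); for a straight tube a single outlet at the
#'   far end.
#' @param deletion_length axial extent of the cell-deletion region upstream of
#'   each outflow plane (recycled across outlets).
#' @param h controller gain (weighting factor), default 0.05.
#' @param P0 initial removal probability.
#' @param rho_target target main-domain number density (defaults to the fluid
#'   density `n`; recycled across outlets).
#' @param smooth_window moving-average window (steps) for the measured
#'   density; 1 reproduces the bare per-step measurement.
#' @return object of class `obc_layout`.
#' @export
obc_layout <- function(generating_length, zone_width = 1.5, outlets,
                       deletion_length = 3, h = 0.05, P0 = 0.5,
                       rho_target = 2.96, smooth_window = 100) {
  if (generating_length < 2 * zone_width)
    stop("generating-region length must be at least twice the zone width")
  stopifnot(h > 0, P0 >= 0, P0 <= 1, all(rho_target > 0))
  deletion_length <- rep_len(deletion_length, length(outlets))
  rho_target <- rep_len(rho_target, length(outlets))
  for (k in seq_along(outlets)) {
    outlets[[k]]$deletion_length <- deletion_length[k]
    outlets[[k]]$rho_target <- rho_target[k]
    if (is.null(outlets[[k]]$branch)) outlets[[k]]$branch <- 0L
  }
  structure(list(generating_length = generating_length,
                 copy_border = generating_length, zone_width = zone_width,
                 outlets = outlets, h = h, P0 = P0,
                 smooth_window = smooth_window),
            class = "obc_layout")
}

#' Adaptive outflow controller state
#'
#' Per-outlet reflection-survival probability `P`: a particle crossing the
#' outflow plane is reflected back with probability `P` and removed with
#' probability `1 - P`. The density feedback raises `P` (keeps more
#' particles) while the measured density is below target and lowers it
#' otherwise, holding the main-domain density at `rho_target`.
#'
#' @param rho_target target number density (> 0).
#' @param h weighting factor (gain), default 0.05.
#' @param P initial reflection probability in `[0, 1]`.
#' @return object of class `outflow_controller`.
#' @export
outflow_controller <- function(rho_target, h = 0.05, P = 0.5) {
  if (rho_target <= 0) stop("rho_target must be positive")
  stopifnot(h > 0, P >= 0, P <= 1)
  structure(list(P = P, rho_target = rho_target, h = h,
                 rho_current = NA_real_),
            class = "outflow_controller")
}

#' Controller update
#'
#' `dP = h |rho_current - rho_target| / rho_target`; `P <- P + dP` when
#' `rho_current <= rho_target`, else `P <- P - dP`; clamped to `[0, 1]`.
#'
#' @param controller an [outflow_controller()].
#' @param rho_current measured main-domain number density.
#' @return updated controller.
#' @export
update_outflow_probability <- function(controller, rho_current) {
  stopifnot(inherits(controller, "outflow_controller"))
  dP <- controller$h * abs(rho_current - controller$rho_target) /
    controller$rho_target
  P <- if (rho_current <= controller$rho_target) controller$P + dP
       else controller$P - dP
  controller$P <- min(1, max(0, P))
  controller$rho_current <- rho_current
  controller
}

#' Probabilistic outflow membrane
#'
#' Particles beyond the outflow plane are removed with probability
#' `P_remove` and otherwise reflected back specularly (position mirrored
#' across the plane, normal velocity component negated). With the adaptive
#' controller, `P_remove = 1 - P` where `P` is the controller's
#' reflection-survival probability.
#'
#' @param position,velocity n x 3 state of the particles that crossed.
#' @param origin,dir plane origin and outward unit normal.
#' @param P_remove removal probability.
#' @param u optional vector of uniform draws (for reproducible testing);
#'   defaults to `runif(n)`.
#' @return list `position`, `velocity` (reflected states), `removed`
#'   (logical).
#' @export
outflow_membrane <- function(position, velocity, origin, dir, P_remove,
                             u = NULL) {
  position <- rbind(position); velocity <- rbind(velocity)
  n <- nrow(position)
  if (is.null(u)) u <- runif(n)
  s <- as.numeric((position - matrix(origin, n, 3, byrow = TRUE)) %*% dir)
  removed <- u < P_remove & s > 0
  refl <- !removed & s > 0
  if (any(refl)) {
    position[refl, ] <- position[refl, , drop = FALSE] -
      2 * s[refl] %o% dir
    vn <- as.numeric(velocity[refl, , drop = FALSE] %*% dir)
    velocity[refl, ] <- velocity[refl, , drop = FALSE] - 2 * vn %o% dir
  }
  list(position = position, velocity = velocity, removed = removed)
}

#' Ghost regeneration for the generating region
#'
#' Creates the ghost images that close the generating region periodically:
#' every generating-region particle with `z < w` gets a ghost at `z + Lg`
#' (zone A2 -> A4) and every particle with `z > Lg - w` a ghost at `z - Lg`
#' (zone A3 -> A1). Ghosts carry the source particle's velocity, species and
#' cell id, exert forces but are never integrated; bonded terms across the
#' periodic seam use the minimum-image convention (see
#' [min_image_spring_vector()]).
#'
#' @param ps `particle_system`.
#' @param layout [obc_layout()].
#' @return list `ghosts` (a `particle_system` with species `"ghost"`),
#'   `source` (indices into `ps`), `source_species`.
#' @export
regenerate_ghosts <- function(ps, layout) {
  gen <- which(ps$region == "generating" & ps$species != "ghost")
  Lg <- layout$generating_length
  w <- layout$zone_width
  z <- ps$position[gen, 3]
  lowz <- gen[z < w]
  hiz <- gen[z > Lg - w]
  src <- c(lowz, hiz)
  if (length(src) == 0)
    return(list(ghosts = NULL, source = integer(0),
                source_species = character(0)))
  gpos <- ps$position[src, , drop = FALSE]
  gpos[, 3] <- gpos[, 3] + c(rep(Lg, length(lowz)), rep(-Lg, length(hiz)))
  ghosts <- particle_system(gpos, ps$velocity[src, , drop = FALSE],
                            species = "ghost", cell_id = ps$cell_id[src],
                            region = "generating")
  list(ghosts = ghosts, source = src, source_species = ps$species[src])
}

#' Minimum-image spring vector across the periodic generating region
#'
#' @param p1,p2 endpoint positions (length 3).
#' @param Lg generating-region period along z.
#' @return displacement `p1 - p2` with z reduced to `(-Lg/2, Lg/2]`.
#' @export
min_image_spring_vector <- function(p1, p2, Lg) {
  d <- as.numeric(p1) - as.numeric(p2)
  d[3] <- d[3] - Lg * round(d[3] / Lg)
  d
}

#' One-way coupling mask
#'
#' Decides, per neighbor pair, which side actually receives the pair force:
#' for a pair crossing the copy border the force is applied only to the
#' main-domain particle (the generating-region particle's accumulator is
#' untouched), ghosts act only on generating-region particles, slaved
#' duplicates act only on main-domain particles, and wall/ghost/slaved
#' particles never receive forces.
#'
#' @param pairs two-column index matrix (as from [build_neighbor_pairs()]).
#' @param region character vector per particle: `"generating"` or `"main"`.
#' @param species character vector per particle (`"fluid"`, `"wall"`,
#'   `"membrane"`, `"ghost"`, `"slaved"`).
#' @return data.frame `i`, `j`, `apply_i`, `apply_j`.
#' @export
mask_one_way_coupling <- function(pairs, region, species) {
  cat_of <- function(k) {
    if (species[k] == "ghost") return("ghost")
    if (species[k] == "slaved") return("slaved")
    if (species[k] == "wall")
      return(if (region[k] == "generating") "wallgen" else "wallmain")
    if (region[k] == "generating") "gen" else "main"
  }
  receives <- function(tc, sc) {
    if (tc == "gen") return(sc %in% c("gen", "wallgen", "ghost"))
    if (tc == "main") return(sc != "ghost")
    FALSE
  }
  n <- nrow(pairs)
  ai <- logical(n); aj <- logical(n)
  for (r in seq_len(n)) {
    ci <- cat_of(pairs[r, 1]); cj <- cat_of(pairs[r, 2])
    ai[r] <- receives(ci, cj)
    aj[r] <- receives(cj, ci)
  }
  data.frame(i = pairs[, 1], j = pairs[, 2], apply_i = ai, apply_j = aj)
}

#' Duplicate fluid particles at the copy border
#'
#' Generating-region fluid particles whose z coordinate reached the copy
#' border are wrapped back periodically and a free main-domain duplicate is
#' inserted at the crossing position with the original's velocity.
#'
#' @param ps `particle_system`.
#' @param layout [obc_layout()].
#' @return list `ps` (updated system incl. inserted duplicates), `inserted`
#'   (indices of the new particles).
#' @export
duplicate_fluid_at_border <- function(ps, layout) {
  Lg <- layout$generating_length
  cross <- which(ps$species == "fluid" & ps$region == "generating" &
                   ps$position[, 3] >= Lg)
  up <- which(ps$species == "fluid" & ps$region == "generating" &
                ps$position[, 3] < 0)
  inserted <- integer(0)
  if (length(cross)) {
    dup <- particle_system(ps$position[cross, , drop = FALSE],
                           ps$velocity[cross, , drop = FALSE],
                           species = "fluid", region = "main")
    ps$position[cross, 3] <- ps$position[cross, 3] - Lg
    n0 <- nrow(ps$position)
    ps$position <- rbind(ps$position, dup$position)
    ps$velocity <- rbind(ps$velocity, dup$velocity)
    ps$force <- rbind(ps$force, matrix(0, length(cross), 3))
    ps$species <- c(ps$species, dup$species)
    ps$cell_id <- c(ps$cell_id, dup$cell_id)
    ps$region <- c(ps$region, dup$region)
    inserted <- n0 + seq_along(cross)
  }
  if (length(up)) ps$position[up, 3] <- ps$position[up, 3] + Lg
  list(ps = ps, inserted = inserted)
}

#' Slaved whole-cell duplicate at the copy border
#'
#' When a generating-region cell's center of mass crosses the copy border the
#' whole mesh is duplicated with a constant copy-border offset. While active,
#' the duplicate's vertex positions equal the original's plus the offset,
#' exactly, every step; it is released as an independent cell once every
#' duplicate vertex lies strictly inside the main domain.
#'
#' @param vertex_ids integer ids of the original cell's vertices.
#' @param offset copy-border translation (length 3, typically `c(0, 0, Lg)`).
#' @return object of class `slaved_duplicate`.
#' @export
slaved_duplicate <- function(vertex_ids, offset) {
  structure(list(vertex_ids = vertex_ids,
                 duplicate_ids = seq_along(vertex_ids),
                 offset = as.numeric(offset), active = TRUE),
            class = "slaved_duplicate")
}

#' Apply slaved motion
#'
#' @param dup `slaved_duplicate`.
#' @param orig_positions positions of the original cell's vertices.
#' @param copy_border z position of the copy border (release test).
#' @return list `positions` (duplicate vertices), `dup` (with `active`
#'   updated: released once fully inside the main domain).
#' @export
slave_update <- function(dup, orig_positions, copy_border) {
  stopifnot(inherits(dup, "slaved_duplicate"))
  if (!dup$active)
    stop("slave_update called on a released duplicate")
  p <- sweep(rbind(orig_positions), 2, dup$offset, "+")
  if (all(p[, 3] > copy_border)) dup$active <- FALSE
  list(positions = p, dup = dup)
}

#' Dissolve a cell at an outlet
#'
#' When the whole cell lies inside the deletion region, its topology is
#' destroyed: vertices are retagged as fluid particles in place (positions
#' and velocities unchanged, so the local density is unperturbed) and become
#' removable by the outflow membrane downstream. Partial containment leaves
#' the cell untouched.
#'
#' @param ps `particle_system`.
#' @param cell integer cell id.
#' @param in_deletion_region function(points) -> logical.
#' @return list `ps`, `dissolved` (logical).
#' @export
dissolve_cell_at_outlet <- function(ps, cell, in_deletion_region) {
  idx <- which(!is.na(ps$cell_id) & ps$cell_id == cell &
                 ps$species == "membrane")
  if (length(idx) == 0) return(list(ps = ps, dissolved = FALSE))
  if (!all(in_deletion_region(ps$position[idx, , drop = FALSE])))
    return(list(ps = ps, dissolved = FALSE))
  ps$species[idx] <- "fluid"
  ps$cell_id[idx] <- NA_integer_
  list(ps = ps, dissolved = TRUE)
}
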