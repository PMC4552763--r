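#' Write a particle snapshot as legacy VTK polydata (ASCII)
#'
#' Points plus `species` and `cell_id` point scalars; readable by ParaView
#' and pyvista.
#'
#' @param state engine state list (from [sim_state()]) or `particle_system`.
#' @param file output path.
#' @export
write_vtk <- function(state, file) {
  pos <- state$position
  n <- nrow(pos)
  species <- if (is.character(state$species))
    match(state$species, SPECIES_LEVELS) - 1L else state$species
  cid <- state$cell_id
  cid[is.na(cid)] <- -1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hemoflow snapshot", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(format(pos, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS species int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(species), con)
  writeLines(c("SCALARS cell_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(cid), con)
  invisible(file)
}

#' Write a snapshot in XYZ format
#'
#' @param state engine state list or `particle_system`.
#' @param file output path.
#' @export
write_xyz <- function(state, file) {
  pos <- state$position
  lab <- if (is.character(state$species)) substr(state$species, 1, 1)
         else c("F", "W", "M", "G", "S")[state$species + 1L]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), "hemoflow"), con)
  writeLines(paste(lab, apply(format(pos, trim = TRUE), 1, paste,
                              collapse = " ")), con)
  invisible(file)
}

#' Write a profile (or controller log) as CSV with header metadata
#'
#' @param x `flow_profile`, `pressure_profile` or a data.frame.
#' @param file output path.
#' @param meta named list written as `# key: value` header lines (window,
#'   bins, seed, ...).
#' @export
write_profile_csv <- function(x, file, meta = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  df <- if (inherits(x, "flow_profile")) {
    data.frame(center = x$centers, mean = x$mean, count = x$count,
               se = if (!is.null(x$se)) x$se else NA_real_)
  } else if (inherits(x, "pressure_profile")) {
    data.frame(center = x$centers, pressure = x$pressure, count = x$count)
  } else as.data.frame(x)
  write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Save / load a simulation checkpoint
#'
#' Plain R serialization of the full engine state (positions, velocities,
#' species, cell table and RNG stream states). Restarting from a checkpoint
#' with the original config reproduces the trajectory bitwise.
#'
#' @param state list from [sim_state()].
#' @param file path.
#' @export
save_checkpoint <- function(state, file) {
  saveRDS(state, file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(file) readRDS(file)

#' Read / write scenario configuration (JSON)
#'
#' The `fluid:` block uses the keys `a`, `gamma`, `r_c`, `kBT`, `s`, `n`,
#' `g` exactly.
#'
#' @param file path.
#' @export
read_scenario_json <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  args <- cfg
  if (!is.null(cfg$fluid)) args$fluid <- do.call(dpd_params, as.list(cfg$fluid))
  if (!is.null(cfg$membrane))
    args$membrane <- do.call(membrane_params, as.list(cfg$membrane))
  if (!is.null(cfg$bifurcation))
    args$bifurcation <- do.call(bifurcation_spec, as.list(cfg$bifurcation))
  do.call(scenario_config, args)
}

#' @rdname read_scenario_json
#' @param config a [scenario_config()].
#' @export
write_scenario_json <- function(config, file) {
  cfg <- unclass(config)
  cfg$fluid <- unclass(cfg$fluid)
  cfg$fluid$sigma <- NULL
  if (!is.null(cfg$membrane)) cfg$membrane <- unclass(cfg$membrane)
  if (!is.null(cfg$bifurcation)) cfg$bifurcation <- unclass(cfg$bifurcation)
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}
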