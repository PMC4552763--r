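test_that("cell packing hits the target count and rejects the impossible", {
  tb <- small_tube()
  tmpl <- suppressMessages(build_rbc_mesh(12, radius = 1.1))
  # H_t = 0: no cells, pure fluid at density n
  p0 <- pack_cells(tb, c(0, 6), 0, tmpl, seed = 1)
  expect_length(p0$cells, 0)
  # achieved cell count equals floor(H_t V / V_cell)
  p1 <- pack_cells(tb, c(0, 6), 0.08, tmpl, seed = 2)
  expect_length(p1$cells, floor(0.08 * pi * 9 * 6 / tmpl$V0))
  expect_equal(p1$achieved_hematocrit, 0.08, tolerance = 0.25)
  # unreachable hematocrit errors with the achieved value reported
  expect_error(pack_cells(tb, c(0, 6), 0.55, tmpl, seed = 3,
                          max_attempts = 200), "unreachable")
})

test_that("scenario_config validates inputs; JSON round trip preserves keys", {
  expect_error(scenario_config(hematocrit = 0.7), "hematocrit")
  expect_error(scenario_config("bifurcation"), "bifurcation_spec")
  cfg <- scenario_config("tube_validation", d = 8, seed = 5L,
                         fluid = dpd_params(g = 0.2))
  f <- tempfile(fileext = ".json")
  write_scenario_json(cfg, f)
  txt <- paste(readLines(f), collapse = "")
  # the fluid block uses the exact parameter names
  for (key in c("\"a\"", "\"gamma\"", "\"r_c\"", "\"kBT\"", "\"s\"", "\"n\"",
                "\"g\""))
    expect_match(txt, key, fixed = TRUE)
  cfg2 <- read_scenario_json(f)
  expect_equal(cfg2$fluid$g, 0.2)
  expect_equal(cfg2$d, 8)
  unlink(f)
})

test_that("pilot flow develops into a parabola and checkpoints bitwise", {
  pilot <- fast_pilot()
  expect_true(pilot$converged)
  fit <- fit_poiseuille(pilot$profile$centers, pilot$profile$mean, 7,
                        2.96 * 0.5)
  expect_gt(fit$r_squared, 0.97)
  expect_gt(fit$v_max, 0)
  # same config + seed reproduces the state bitwise (determinism contract)
  pilot2 <- run_pilot(d = 7, L = 7, fluid = dpd_params(g = 0.5), seed = 31,
                      chunk = 2000, max_steps = 20000, tol = 0.12, bins = 10)
  expect_identical(pilot$state$position, pilot2$state$position)
  expect_identical(pilot$state$velocity, pilot2$state$velocity)
})

test_that("suspension pilot: packing relaxes overlaps, profile is blunted", {
  # post-relaxation (pack + displacement-capped settle, before production)
  # minimum vertex-vertex cross-cell distance > 0.3 r_c
  fl <- dpd_params(g = 0.5)
  geom <- build_tube(7, 7, fluid = fl, seed = 32, wall_pad = 0)
  set.seed(32)
  tmpl <- build_rbc_mesh(42, radius = 1.55)
  pk <- pack_cells(geom, c(0, 7), 0.15, tmpl, seed = 33, region = 1L,
                   periodic_z = TRUE)
  set.seed(34)
  st <- make_sim_state(wall = geom$wall[geom$wall[, 3] >= 0 &
                                          geom$wall[, 3] < 7, ],
                       wall_region = 1L, fluid_pos = geom$fluid,
                       fluid_region = 1L, cells = pk$cells, kBT = fl$kBT)
  fl0 <- fl; fl0$g <- 0
  cfg <- engine_config(dt = 0.002, seed = 34, box = c(geom$bbox[1:4], 0, 7),
                       periodic = c(FALSE, FALSE, TRUE), fluid = fl0,
                       geometry = geom, membrane = membrane_params(),
                       templates = list(tmpl), limit_disp = 0.02)
  sim <- simulation(st, cfg)
  sim_run(sim, 300)
  st <- sim_state(sim)
  cells <- which(!is.na(st$cell_id))
  dmin <- Inf
  ids <- st$cell_id[cells]
  pos <- st$position[cells, , drop = FALSE]
  for (a in unique(ids)) for (b in unique(ids)) if (a < b) {
    pa <- pos[ids == a, , drop = FALSE]
    pb <- pos[ids == b, , drop = FALSE]
    # minimum-image along the periodic tube axis
    for (sh in c(-7, 0, 7)) {
      pbs <- pb
      pbs[, 3] <- pbs[, 3] + sh
      cd <- min(sqrt(outer(rowSums(pa^2), rowSums(pbs^2), "+") -
                       2 * pa %*% t(pbs)))
      dmin <- min(dmin, cd)
    }
  }
  expect_gt(dmin, 0.3 * 1.5)
  # blunted (plug-like) profile: the center-to-shoulder contrast of the
  # suspension is below the single-phase parabola's at matched bins
  sp <- suspension_pilot()$profile$mean
  fp <- fast_pilot()$profile$mean
  shoulder <- 7  # bin at r ~ 0.65 R
  expect_lt(sp[1] / sp[shoulder], fp[1] / fp[shoulder])
})

test_that("end-to-end scenario runs are deterministic in config + seed", {
  cfg <- scenario_config("tube_validation", d = 6, L_gen = 6, L_main = 6,
                         fluid = dpd_params(g = 0.5), seed = 77L,
                         equil_steps = 300, production_steps = 500,
                         sample_every = 25, deletion_length = 1.5,
                         pilot_chunk = 2000, pilot_tol = 0.3)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$profile$mean, r2$profile$mean)
  expect_identical(r1$stats$rho, r2$stats$rho)
  expect_type(r1$poiseuille, "list")
  expect_true(is.finite(r1$poiseuille$v_max))
})
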