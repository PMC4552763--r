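test_that("tube geometry: signed distance, wall shell, no lumen intrusion", {
  tb <- small_tube()  # d = 6, L = 6
  expect_equal(tb$sdf(c(0, 0, 3))[1], 3)          # axis point: distance d/2
  expect_equal(tb$sdf(c(2, 0, 1))[1], 1)
  # no wall particle inside the lumen; all within [-thickness, 0)
  s <- cpp_sdf_many(tb$cgeom, tb$wall)
  expect_true(all(s < 0 & s >= -tb$thickness))
  # wall count matches density x shell volume within 5%
  zspan <- diff(range(tb$wall[, 3])) + 0.1
  shell <- pi * ((3 + 1.5)^2 - 9) * zspan
  expect_equal(nrow(tb$wall) / (tb$density * shell), 1, tolerance = 0.05)
  # lumen filling at the fluid density
  expect_equal(nrow(tb$fluid) / (2.96 * pi * 9 * 6), 1, tolerance = 0.05)
})

test_that("Monte-Carlo lumen volume matches the analytic tube volume", {
  tb <- small_tube()
  v <- lumen_volume(tb, n_points = 2e5, seed = 3,
                    filter = function(p) p[, 3] <= 6)
  expect_equal(v, pi * 9 * 6, tolerance = 0.01)
})

test_that("bifurcation geometry: symmetry, junction, outlets, volume bracket", {
  spec <- bifurcation_spec(6, 5, theta = 70, parent_length = 7,
                           daughter_length = 7)
  bf <- build_bifurcation(spec, seed = 5)
  # symmetric daughters: signed distance symmetric under x -> -x
  set.seed(2)
  pts <- cbind(runif(200, -6, 6), runif(200, -2, 2), runif(200, 0, 13))
  s1 <- cpp_sdf_many(bf$cgeom, pts)
  s2 <- cpp_sdf_many(bf$cgeom, cbind(-pts[, 1], pts[, 2:3]))
  expect_equal(s1, s2, tolerance = 1e-12)
  # interior junction point lies inside the lumen of at least one branch
  expect_gt(bf$sdf(c(0, 0, 7.2))[1], 0)
  expect_gt(bf$sdf(c(0, 0, 6.8))[1], 0)
  # two registered outlet planes with outward normals
  expect_length(bf$outlets, 2)
  expect_equal(bf$outlets[[1]]$dir[3], cos(35 * pi / 180), tolerance = 1e-12)
  # lumen volume (restricted upstream of the outlet planes) bracketed by
  # the union bound and the parent + daughters sum
  ups <- function(p) {
    s1 <- (p[, 1] - bf$outlets[[1]]$origin[1]) * bf$outlets[[1]]$dir[1] +
      (p[, 3] - bf$outlets[[1]]$origin[3]) * bf$outlets[[1]]$dir[3]
    s2 <- (p[, 1] - bf$outlets[[2]]$origin[1]) * bf$outlets[[2]]$dir[1] +
      (p[, 3] - bf$outlets[[2]]$origin[3]) * bf$outlets[[2]]$dir[3]
    s1 < 0 & s2 < 0
  }
  v <- lumen_volume(bf, n_points = 2e5, seed = 7, filter = ups)
  vsum <- pi * 9 * 7 + 2 * pi * 2.5^2 * 7
  expect_lt(v, vsum * 1.02)
  expect_gt(v, vsum * 0.75)
  # overlapping outlets are rejected
  expect_error(build_bifurcation(
    bifurcation_spec(6, 5, theta = 8, parent_length = 7, daughter_length = 7)),
    "overlap")
})

test_that("bounce-back reverses the full velocity at the crossing point", {
  tb <- small_tube()
  # normal incidence at speed u: exits at speed u, reversed
  r <- bounce_back(pos_old = c(2.8, 0, 3), pos_new = c(3.1, 0, 3),
                   vel = c(0.5, 0, 0), geometry = tb)
  expect_true(r$crossed[1])
  expect_equal(r$velocity[1, ], c(-0.5, 0, 0))
  expect_equal(r$position[1, 1], 2.9, tolerance = 1e-6)  # reflected about 3.0
  # tangential component is also negated (bounce-back, not specular)
  r <- bounce_back(c(2.8, 0, 3), c(3.05, 0.1, 3.2), c(0.4, 0.2, 0.3), tb)
  expect_equal(r$velocity[1, ], c(-0.4, -0.2, -0.3))
  expect_gt(tb$sdf(r$position[1, ])[1], 0)
  # deep penetration: clamped to the surface with a warning
  expect_warning(
    r <- bounce_back(c(3.4, 0, 3), c(3.6, 0, 3), c(0.1, 0, 0), tb),
    "clamp")
  expect_gte(tb$sdf(r$position[1, ])[1], 0)
})

test_that("no particle penetrates the wall and near-wall density is sane", {
  tb <- small_tube()
  fl <- dpd_params()
  fl$g <- 0
  set.seed(51)
  st <- make_sim_state(wall = tb$wall, wall_region = 1L, fluid_pos = tb$fluid,
                       fluid_region = 1L, kBT = fl$kBT)
  cfg <- engine_config(dt = 0.005, seed = 51, box = c(tb$bbox[1:4], 0, 6),
                       periodic = c(FALSE, FALSE, TRUE), fluid = fl,
                       geometry = tb)
  sim <- simulation(st, cfg)
  sim_run(sim, 1500)
  vz_wall <- c(); nshell <- 0; nbulk <- 0; nsnap <- 0
  for (k in 1:10) {
    sim_run(sim, 100)
    s <- sim_state(sim)
    flid <- s$species == 0L
    sdf <- cpp_sdf_many(tb$cgeom, s$position[flid, , drop = FALSE])
    expect_gte(min(sdf), 0)  # bounce-back: nobody inside the wall
    vz_wall <- c(vz_wall, s$velocity[flid, 3][sdf < 0.5])
    nshell <- nshell + sum(sdf < 1.5)
    nbulk <- nbulk + sum(sdf >= 1.5)
    nsnap <- nsnap + 1
  }
  # no-slip: mean tangential velocity in the first wall bin is zero in noise
  expect_lt(abs(mean(vz_wall)), 3 * sd(vz_wall) / sqrt(length(vz_wall) / 5))
  # near-wall density within 15% of bulk (first r_c shell vs interior)
  vshell <- pi * (9 - 1.5^2) * 6
  vbulk <- pi * 1.5^2 * 6
  rho_shell <- nshell / nsnap / vshell
  rho_bulk <- nbulk / nsnap / vbulk
  expect_equal(rho_shell / rho_bulk, 1, tolerance = 0.15)
})
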