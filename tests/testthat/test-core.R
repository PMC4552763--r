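test_that("particle_system validates species, cell ids and frozen walls", {
  ps <- particle_system(matrix(rnorm(9), 3, 3), species = "fluid")
  expect_s3_class(ps, "particle_system")
  expect_error(particle_system(matrix(0, 1, 3), species = "membrane"),
               "cell_id")
  expect_error(particle_system(matrix(0, 1, 3), species = "fluid",
                               cell_id = 1L), "cell_id")
  expect_error(particle_system(matrix(0, 1, 3), matrix(1, 1, 3),
                               species = "wall"), "frozen")
  expect_error(sim_clock(dt = 0), "dt > 0")
})

test_that("neighbor search matches brute-force enumeration", {
  set.seed(5)
  pos <- matrix(runif(150, 0, 5), 50, 3)
  box <- c(0, 5, 0, 5, 0, 5)
  for (per in list(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE),
                   c(FALSE, FALSE, TRUE))) {
    got <- build_neighbor_pairs(pos, 1.2, box = box, periodic = per)
    want <- brute_pairs(pos, 1.2, box = box, periodic = per)
    sortp <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(sortp(got), sortp(unname(want)), ignore_attr = TRUE)
  }
})

test_that("neighbor search handles direct distance, images and edge cases", {
  p <- rbind(c(0.5, 2, 2), c(0.5 + 0.9, 2, 2))
  expect_equal(nrow(build_neighbor_pairs(p, 1)), 1)      # 0.9 * cutoff
  # image pair across the periodic face found iff image distance < cutoff
  q <- rbind(c(0.2, 2, 2), c(4.8, 2, 2))
  box <- c(0, 5, 0, 5, 0, 5)
  expect_equal(nrow(build_neighbor_pairs(q, 1, box, c(TRUE, FALSE, FALSE))), 1)
  expect_equal(nrow(build_neighbor_pairs(q, 0.3, box, c(TRUE, FALSE, FALSE))), 0)
  expect_equal(nrow(build_neighbor_pairs(matrix(0, 0, 3), 1)), 0)
  expect_error(build_neighbor_pairs(q, 2.6, box, c(TRUE, FALSE, FALSE)),
               "minimum image")
})

test_that("velocity-Verlet reproduces exact discrete trajectories", {
  # zero force: displacement exactly v * dt each step
  ps <- particle_system(matrix(0, 1, 3), matrix(c(0.3, 0, 0), 1, 3))
  ps <- velocity_verlet_step(ps, 0.01, function(p) matrix(0, 1, 3))
  expect_identical(ps$position[1, 1], 0.3 * 0.01)
  # constant force from rest: x_k = f (k dt)^2 / 2 exactly
  f <- 0.7; dt <- 0.02
  ps <- particle_system(matrix(0, 1, 3))
  ps$force <- matrix(c(f, 0, 0), 1, 3)
  for (k in 1:25)
    ps <- velocity_verlet_step(ps, dt, function(p) matrix(c(f, 0, 0), 1, 3))
  expect_equal(ps$position[1, 1], 0.5 * f * (25 * dt)^2, tolerance = 1e-12)
})

test_that("harmonic oscillator energy drift stays below 1e-4 over 1e4 steps", {
  k <- 1; dt <- 0.005
  ps <- particle_system(matrix(c(1, 0, 0), 1, 3))
  ps$force <- -k * ps$position
  e0 <- 0.5 * k
  emax <- 0
  for (s in 1:10000) {
    ps <- velocity_verlet_step(ps, dt, function(p) -k * p$position)
    e <- 0.5 * sum(ps$velocity^2) + 0.5 * k * sum(ps$position^2)
    emax <- max(emax, abs(e - e0) / e0)
  }
  expect_lt(emax, 1e-4)
})

test_that("non-finite state aborts with a diagnostic", {
  ps <- particle_system(matrix(0, 1, 3), matrix(c(Inf, 0, 0), 1, 3))
  expect_error(velocity_verlet_step(ps, 0.01, function(p) matrix(0, 1, 3)),
               "non-finite")
})

test_that("momentum is conserved under pairwise-antisymmetric forces", {
  bx <- periodic_fluid_box(L = 5, seed = 9)
  bx$config$fluid$gamma <- 0       # conservative only
  bx$config$thermostat <- FALSE
  sim <- simulation(bx$state, bx$config)
  p0 <- colSums(cpp_sim_state(sim$ptr)$velocity)
  sim_run(sim, 1000)
  p1 <- colSums(cpp_sim_state(sim$ptr)$velocity)
  expect_lt(max(abs(p1 - p0)), 1e-9)
})

test_that("trajectories are bitwise reproducible and restartable", {
  bx <- periodic_fluid_box(L = 5, seed = 13)
  s1 <- simulation(bx$state, bx$config)
  s2 <- simulation(bx$state, bx$config)
  sim_run(s1, 200)
  sim_run(s2, 200)
  expect_identical(sim_state(s1)$position, sim_state(s2)$position)
  # checkpoint restart: continue vs rebuild-from-checkpoint, bitwise equal
  ck <- sim_state(s1)
  sim_run(s1, 150)
  s3 <- simulation(ck, bx$config)
  sim_run(s3, 150)
  expect_identical(sim_state(s1)$position, sim_state(s3)$position)
  expect_identical(sim_state(s1)$velocity, sim_state(s3)$velocity)
})
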