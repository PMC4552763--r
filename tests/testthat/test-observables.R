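test_that("velocity profile bins recover synthetic fields", {
  set.seed(71)
  n <- 4000
  r <- sqrt(runif(n)) * 5
  phi <- runif(n, 0, 2 * pi)
  pos <- cbind(r * cos(phi), r * sin(phi), runif(n, 0, 10))
  # flat field
  snap <- list(position = pos, velocity = cbind(0, 0, rep(0.3, n)))
  pf <- velocity_profile(list(snap), bins = 10, rmax = 5)
  expect_true(all(abs(pf$mean - 0.3) < 1e-12))
  # parabolic field recovered bin-wise at the bin-mean level
  vz <- 0.1 * (1 - (r / 5)^2)
  snap2 <- list(position = pos, velocity = cbind(0, 0, vz))
  pf2 <- velocity_profile(list(snap2), bins = 10, rmax = 5)
  want <- vapply(seq_len(10), function(b) {
    i <- r >= pf2$edges[b] & r <= pf2$edges[b + 1]
    mean(vz[i])
  }, 0)
  expect_equal(pf2$mean, want, tolerance = 1e-6)
  # empty bins are missing, not zero
  snap3 <- list(position = pos[r > 2.5, ], velocity = snap2$velocity[r > 2.5, ])
  pf3 <- velocity_profile(list(snap3), bins = 10, rmax = 5)
  expect_true(all(is.na(pf3$mean[1:4])))
})

test_that("two half windows merge into the full window to roundoff", {
  set.seed(72)
  snaps <- lapply(1:6, function(k) {
    n <- 500 + 40 * k
    r <- sqrt(runif(n)) * 5
    phi <- runif(n, 0, 2 * pi)
    list(position = cbind(r * cos(phi), r * sin(phi), runif(n)),
         velocity = cbind(0, 0, rnorm(n, 0.05)))
  })
  full <- velocity_profile(snaps, bins = 8, rmax = 5)
  h1 <- velocity_profile(snaps[1:3], bins = 8, rmax = 5)
  h2 <- velocity_profile(snaps[4:6], bins = 8, rmax = 5)
  merged <- combine_profiles(h1, h2)
  expect_equal(merged$mean, full$mean, tolerance = 1e-12)
  expect_equal(merged$count, full$count)
  expect_equal(merged$window, full$window)
})

test_that("profile_from_samples averages rows and attaches block errors", {
  set.seed(73)
  sm <- matrix(rnorm(400, mean = 0.1, sd = 0.01), 40, 10)
  pf <- profile_from_samples(sm, edges = seq(0, 5, length.out = 11))
  expect_equal(pf$mean, colMeans(sm))
  expect_true(all(pf$se > 0))
  expect_equal(length(pf$se), 10)
})

test_that("ideal-gas pressure is n kBT per slab; thin slabs warn", {
  set.seed(74)
  kBT <- 0.0945; n_dens <- 2.96
  L <- 10; A <- 16
  snaps <- lapply(1:25, function(k) {
    n <- rpois(1, n_dens * L * A)
    list(position = cbind(runif(n, -2, 2), runif(n, -2, 2), runif(n, 0, L)),
         velocity = matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3))
  })
  pp <- pressure_profile(snaps, slabs = 4, zlim = c(0, L),
                         slab_volume = A * L / 4)
  # small downward bias ~ kBT/V from subtracting the per-slab mean velocity
  expect_equal(mean(pp$pressure), n_dens * kBT, tolerance = 0.03)
  expect_warning(
    pressure_profile(snaps[1:2], slabs = 12, zlim = c(0, L),
                     slab_volume = A * L / 12), "thinner")
})

test_that("recovery efficiency counts cell flux with binomial intervals", {
  # all cells exit branch 1
  ex <- cbind(step = 1:5, outlet = rep(1, 5), cell = 1:5, nv = 42)
  r <- recovery_efficiency(ex, n_branches = 2)
  expect_equal(r$fraction, c(1, 0))
  # 30 of 40 to branch 1: 75% with the Clopper-Pearson interval
  ex2 <- cbind(step = 1:40, outlet = c(rep(1, 30), rep(2, 10)), cell = 1:40,
               nv = 42)
  r2 <- recovery_efficiency(ex2, n_branches = 2)
  expect_equal(r2$fraction[1], 0.75)
  bt <- binom.test(30, 40)$conf.int  # independent oracle
  expect_equal(unname(r2$ci[, 1]), c(bt[1], bt[2]), tolerance = 1e-10)
  # fractions always sum to one over exited cells
  set.seed(75)
  ex3 <- cbind(step = 1:17, outlet = sample(1:2, 17, TRUE), cell = 1:17,
               nv = 12)
  expect_equal(sum(recovery_efficiency(ex3)$fraction), 1)
  # measured flow-rate ratio from per-branch fluid removals
  r4 <- recovery_efficiency(ex2, fluid_removed = c(300, 100))
  expect_equal(r4$phi_d, 3)
  expect_error(recovery_efficiency(cbind(step = 1, outlet = 3, cell = 1,
                                         nv = 42), n_branches = 2),
               "unregistered")
})
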