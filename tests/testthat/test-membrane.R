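test_that("mesh combinatorics: closed triangulation identities", {
  ico <- build_rbc_mesh(12)
  expect_equal(ico$nv, 12)
  expect_equal(nrow(ico$springs), 30)
  expect_equal(nrow(ico$triangles), 20)
  expect_equal(ico$nv - nrow(ico$springs) + nrow(ico$triangles), 2)  # Euler
  m <- build_rbc_mesh(42)
  expect_equal(nrow(m$springs), 3 * (42 - 2))
  expect_equal(nrow(m$triangles), 2 * (42 - 2))
  expect_message(build_rbc_mesh(500), "642")  # nearest achievable count
  expect_error(build_rbc_mesh(11))
})

test_that("mesh volume equals the divergence-theorem oracle", {
  m <- random_mesh(seed = 2, nv = 42)
  got <- mesh_area_volume(m)$volume
  # independent oracle: V = (1/3) sum_T A_T (c_T . n_T) over triangle
  # centroids and unit outward normals
  vol <- 0
  for (t in seq_len(nrow(m$triangles))) {
    tri <- m$vertices[m$triangles[t, ], ]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    vol <- vol + sum(colMeans(tri) * n) / 6
  }
  expect_equal(got, vol, tolerance = 1e-12)
})

test_that("mesh builder approaches requested area and reduced volume", {
  m <- build_rbc_mesh(162, radius = 2, reduced_volume = 0.64)
  expect_equal(m$A0, 4 * pi * 4, tolerance = 0.02)
  v_sphere <- 4 / 3 * pi * (sqrt(m$A0 / (4 * pi)))^3
  expect_equal(m$V0 / v_sphere, 0.64, tolerance = 0.05)
  expect_equal(m$lm, m$l0 / 0.45, tolerance = 1e-12)
})

test_that("membrane parameter invariants are enforced", {
  expect_error(membrane_params(gamma_T = 10, gamma_C = 3), "3\\*gamma_C")
  expect_silent(membrane_params(gamma_T = 10, gamma_C = 10 / 3))
  expect_error(membrane_params(p = 0))
})

test_that("analytic forces equal central-difference gradients to 1e-6", {
  m <- random_mesh(seed = 11)
  par <- membrane_params(theta0 = 0.25)
  cases <- list(
    list(f = function(p) elastic_forces(m, par, p),
         e = function(p) elastic_forces(m, par, p)$energy),
    list(f = function(p) bending_forces(m, par, p),
         e = function(p) bending_forces(m, par, p)$energy),
    list(f = function(p) area_volume_forces(m, par, p),
         e = function(p) {
           r <- area_volume_forces(m, par, p)
           r$energy_area + r$energy_volume
         }))
  for (cs in cases) {
    ana <- cs$f(m$vertices)$forces
    num <- -numeric_gradient(m, par, m$vertices, cs$e)
    expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-6)
  }
  # combined provider equals the sum of the four gradients
  all4 <- rbc_energy_forces(m, par)
  s3 <- cases[[1]]$f(m$vertices)$forces + cases[[2]]$f(m$vertices)$forces +
    cases[[3]]$f(m$vertices)$forces
  expect_equal(all4$forces, s3, tolerance = 1e-12)
  expect_equal(all4$total, all4$V_s + all4$V_b + all4$V_a + all4$V_v)
})

test_that("WLC term diverges monotonically as a spring approaches l_m", {
  m <- build_rbc_mesh(12)
  par <- membrane_params()
  stretch <- function(fac) {
    p <- m$vertices
    sp <- m$springs[1, ]
    dir <- p[sp[2], ] - p[sp[1], ]
    p[sp[2], ] <- p[sp[1], ] + dir * fac * m$lm / sqrt(sum(dir^2))
    elastic_forces(m, par, p)$energy
  }
  es <- vapply(c(0.8, 0.9, 0.95, 0.99), stretch, 0)
  expect_true(all(diff(es) > 0))
  expect_gt(es[4] - es[1], 10 * (es[2] - es[1]))
  expect_error(stretch(1.0), "overextended")
})

test_that("per-triangle repulsion scales as 1/A under uniform dilation", {
  m <- build_rbc_mesh(12)
  par <- membrane_params()
  # isolate the triangle term: WLC part subtracted via spring lengths
  tri_term <- function(scale) {
    p <- m$vertices * scale
    tot <- elastic_forces(m, par, p)$energy
    l <- sqrt(rowSums((p[m$springs[, 1], ] - p[m$springs[, 2], ])^2))
    x <- l / m$lm
    wlc <- sum(par$kBT * m$lm / (4 * par$p) * (3 * x^2 - 2 * x^3) / (1 - x))
    tot - wlc
  }
  r12 <- tri_term(1.2) / tri_term(1.0)
  expect_equal(r12, 1 / 1.2^2, tolerance = 1e-10)  # A scales as scale^2
})

test_that("bending energy is zero at the spontaneous angle, restoring off it", {
  # regular (spherical) icosahedron: all dihedral angles are congruent
  m <- build_rbc_mesh(12, reduced_volume = 1 - 1e-9)
  b0 <- bending_forces(m, membrane_params(theta0 = 0))
  expect_gt(b0$energy, 0)
  # flat two-triangle patch via a degenerate check is covered by gradients;
  # here: uniform sphere-like mesh has all dihedrals equal; setting theta0 to
  # that angle zeroes energy and forces
  p <- m$vertices
  sp <- m$dihedrals[1, ]
  n1 <- function(a, b, c3) {
    e1 <- p[b, ] - p[a, ]; e2 <- p[c3, ] - p[a, ]
    c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
      e1[1] * e2[2] - e1[2] * e2[1])
  }
  nn1 <- n1(sp[1], sp[2], sp[3]); nn2 <- n1(sp[2], sp[1], sp[4])
  th <- acos(sum(nn1 * nn2) / sqrt(sum(nn1^2) * sum(nn2^2)))
  bt <- bending_forces(m, membrane_params(theta0 = th))
  expect_equal(bt$energy, 0, tolerance = 1e-9)
  expect_lt(max(abs(bt$forces)), 1e-7)
  # convex mesh: the signed dihedral is positive (sign convention)
  expect_gt(th, 0)
})

test_that("area/volume constraints: zero at reference, quadratic growth", {
  m <- build_rbc_mesh(42)
  par <- membrane_params()
  at <- area_volume_forces(m, par)
  expect_equal(at$energy_area, 0, tolerance = 1e-20)
  expect_equal(at$energy_volume, 0, tolerance = 1e-20)
  expect_lt(max(abs(at$forces)), 1e-10)
  # V = V0 (1 + eps): V_v grows as eps^2
  ev <- vapply(c(1e-2, 1e-3), function(eps) {
    sc <- (1 + eps)^(1 / 3)
    m2 <- m
    m2$A0 <- mesh_area_volume(m, m$vertices * sc)$area  # isolate volume term
    area_volume_forces(m2, par, m$vertices * sc)$energy_volume
  }, 0)
  expect_equal(ev[1] / ev[2], 100, tolerance = 0.05)
  # inverted mesh (reversed orientation) is an error
  m3 <- m
  m3$triangles <- m$triangles[, c(1, 3, 2)]
  expect_error(area_volume_forces(m3, par), "inverted")
})

test_that("membrane viscous force follows the spring pair law", {
  m <- build_rbc_mesh(12)
  par <- membrane_params(gamma_T = 10, gamma_C = 5)
  v <- matrix(0, m$nv, 3)
  r0 <- membrane_viscous_forces(m, par, velocities = v, dt = 0.005)
  expect_equal(max(abs(r0$dissipative)), 0)
  # relative velocity parallel to the spring axis: |F| = (gT + gC) |v|
  sp <- m$springs[1, ]
  e <- m$vertices[sp[1], ] - m$vertices[sp[2], ]
  e <- e / sqrt(sum(e^2))
  v[sp[1], ] <- 0.3 * e
  # direct evaluation on an isolated spring: |F| = (gT + gC)|v| for v || e
  m2 <- m
  m2$springs <- m$springs[1, , drop = FALSE]
  r2 <- membrane_viscous_forces(m2, par, velocities = v, dt = 0.005)
  expect_equal(sqrt(sum(r2$dissipative[sp[1], ]^2)), (10 + 5) * 0.3,
               tolerance = 1e-12)
  expect_equal(r2$dissipative[sp[1], ], -r2$dissipative[sp[2], ])
})

test_that("Wiener increments decompose into traceless symmetric part + trace", {
  set.seed(21)
  W <- spring_wiener_increments(30, dt = 0.005)
  expect_equal(dim(W), c(30, 9))
  for (k in c(1, 17)) {
    d <- wiener_decompose(W[k, ])
    expect_equal(d$traceless_symmetric, t(d$traceless_symmetric))
    expect_equal(sum(diag(d$traceless_symmetric)), 0, tolerance = 1e-14)
    expect_equal(d$trace, sum(W[k, c(1, 5, 9)]))
  }
  # random force is momentum free (antisymmetric per spring)
  m <- build_rbc_mesh(12)
  rr <- membrane_viscous_forces(m, membrane_params(),
                                velocities = matrix(0, 12, 3), dt = 0.005,
                                dW = spring_wiener_increments(30, 0.005))
  expect_lt(max(abs(colSums(rr$random))), 1e-10)
})

test_that("membrane internal forces are momentum- and torque-free", {
  m <- random_mesh(seed = 33, nv = 42)
  r <- rbc_energy_forces(m, membrane_params(theta0 = 0.1))
  expect_lt(max(abs(colSums(r$forces))), 1e-9)
  trq <- colSums(cbind(
    m$vertices[, 2] * r$forces[, 3] - m$vertices[, 3] * r$forces[, 2],
    m$vertices[, 3] * r$forces[, 1] - m$vertices[, 1] * r$forces[, 3],
    m$vertices[, 1] * r$forces[, 2] - m$vertices[, 2] * r$forces[, 1]))
  expect_lt(max(abs(trq)), 1e-9)
})

test_that("regular flat network with springs at l0 is near equilibrium", {
  # the triangle-repulsion constant C is constructed so a flat equilateral
  # sheet with all springs at l0 is stress free: the interior vertex of a
  # regular hexagonal patch must feel (almost) no elastic force
  par <- membrane_params()
  l0 <- 0.8
  ang <- seq(0, 5) * pi / 3
  verts <- rbind(c(0, 0, 0), cbind(l0 * cos(ang), l0 * sin(ang), 0))
  tris <- cbind(1, 2:7, c(3:7, 2))
  springs <- unique(t(apply(rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)]),
                            1, sort)))
  mesh <- list(nv = 7L, vertices = verts, springs = springs,
               triangles = tris,
               dihedrals = matrix(integer(0), 0, 4),
               l0 = l0, lm = l0 / 0.45, A0 = 1, V0 = 1)
  class(mesh) <- "rbc_mesh"
  r <- elastic_forces(mesh, par)
  force_scale <- par$kBT / par$p
  expect_lt(sqrt(sum(r$forces[1, ]^2)) / force_scale, 1e-2)
})

test_that("isolated thermal membrane holds area/volume and temperature", {
  set.seed(44)
  m <- build_rbc_mesh(162, radius = 1.7)
  par <- membrane_params()
  st <- make_sim_state(fluid_pos = matrix(0, 0, 3),
                       cells = list(list(vertices = m$vertices, template = 1L,
                                         region = 1L, A0 = m$A0, V0 = m$V0)))
  fl <- dpd_params(); fl$g <- 0
  cfg <- engine_config(dt = 0.005, seed = 45, box = c(-3, 3, -3, 3, -3, 3),
                       fluid = fl, membrane = par, templates = list(m))
  sim <- simulation(st, cfg)
  sim_run(sim, 20000)  # equilibrate
  kes <- c(); A <- c(); V <- c()
  for (k in 1:100) {
    sim_run(sim, 800)
    s <- sim_state(sim)
    kes <- c(kes, mean(rowSums(s$velocity^2)) / 2)
    av <- mesh_area_volume(m, s$position)
    A <- c(A, av$area); V <- c(V, av$volume)
  }
  # fluctuation-dissipation of the membrane thermostat: kT within 5%
  expect_equal(equilibrium_temperature(kes), 0.0945, tolerance = 0.05)
  # area and volume within 1% of reference over 10^5 steps
  expect_lt(max(abs(A / m$A0 - 1)), 0.01)
  expect_lt(max(abs(V / m$V0 - 1)), 0.01)
})
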