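# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# brute-force O(N^2) neighbor enumeration: the independent oracle for the
# cell-list search
brute_pairs <- function(pos, cutoff, box = NULL, periodic = c(FALSE, FALSE, FALSE)) {
  n <- nrow(pos)
  out <- NULL
  L <- if (is.null(box)) c(0, 0, 0) else box[c(2, 4, 6)] - box[c(1, 3, 5)]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    for (c3 in 1:3) if (periodic[c3]) d[c3] <- d[c3] - L[c3] * round(d[c3] / L[c3])
    if (sum(d^2) < cutoff^2) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# perturbed icosahedron mesh with reference area/volume targets
random_mesh <- function(seed = 42, jitter = 0.03, nv = 12) {
  set.seed(seed)
  m <- suppressMessages(build_rbc_mesh(nv, radius = 1))
  m$vertices <- m$vertices + matrix(rnorm(3 * m$nv, sd = jitter), m$nv, 3)
  av <- mesh_area_volume(m)
  m$A0 <- av$area * 0.97
  m$V0 <- av$volume * 1.04
  m
}

# central-difference gradient of a membrane energy functional
numeric_gradient <- function(mesh, params, positions, energy_of, h = 1e-6) {
  g <- matrix(0, nrow(positions), 3)
  for (i in seq_len(nrow(positions))) for (c3 in 1:3) {
    pp <- positions; pp[i, c3] <- pp[i, c3] + h
    pm <- positions; pm[i, c3] <- pm[i, c3] - h
    g[i, c3] <- (energy_of(pp) - energy_of(pm)) / (2 * h)
  }
  g
}

# small equilibrated tube geometry (shared: walls + lumen filling)
small_tube <- function() fixture("small_tube", function() {
  build_tube(6, 6, seed = 101, wall_pad = 0)
})

# engine state/config for a periodic equilibrium box of DPD fluid
periodic_fluid_box <- function(L = 6, seed = 7, g = 0) {
  fl <- dpd_params()
  fl$g <- g
  n <- round(fl$n * L^3)
  set.seed(seed)
  st <- list(position = matrix(runif(3 * n, 0, L), n, 3),
             velocity = matrix(rnorm(3 * n, sd = sqrt(fl$kBT)), n, 3),
             species = rep(0L, n), region = rep(1L, n),
             cell_id = rep(NA_integer_, n), cells = NULL)
  cfg <- engine_config(dt = 0.005, seed = seed, box = c(0, L, 0, L, 0, L),
                       periodic = c(TRUE, TRUE, TRUE), fluid = fl)
  list(state = st, config = cfg, fluid = fl, n = n, L = L)
}

# single-phase pilot at a boosted driving force (strong signal, short runs)
fast_pilot <- function() fixture("fast_pilot", function() {
  run_pilot(d = 7, L = 7, fluid = dpd_params(g = 0.5), seed = 31,
            chunk = 2000, max_steps = 20000, tol = 0.12, bins = 10)
})

# small suspension pilot (4 cells at 15% hematocrit, boosted driving)
suspension_pilot <- function() fixture("suspension_pilot", function() {
  set.seed(32)
  tmpl <- build_rbc_mesh(42, radius = 1.55)
  run_pilot(d = 7, L = 7, hematocrit = 0.15, template = tmpl,
            fluid = dpd_params(g = 0.5), seed = 32, chunk = 2500,
            max_steps = 25000, tol = 0.2, bins = 10)
})
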