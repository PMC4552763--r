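#' Membrane model parameters
#'
#' Parameters of the coarse-grained red-blood-cell membrane: worm-like-chain
#' (WLC) spring elasticity with a per-triangle area repulsion making the
#' relaxed network stress free, dihedral bending resistance, global
#' area/volume constraint coefficients, and the membrane viscosity pair
#' (`gamma_T`, `gamma_C`). The random spring force conjugate to the membrane
#' viscosity requires `3 * gamma_C >= gamma_T` (the trace-term amplitude must
#' be real); this is enforced at construction.
#'
#' The defaults are the package's documented reference set for a stable
#' biconcave-like cell at coarse resolutions (the persistence length `p`
#' controls the shear stiffness scale `kBT/p`; `k_b` is about 80 kBT; `k_a`
#' and `k_v` are stiff global constraints, doubled from the classical
#' spectrin-network values so the coarse meshes used here hold area and
#' volume within 1 percent).
#'
#' @param p persistence length (DPD length units).
#' @param k_b bending modulus (energy units).
#' @param theta0 spontaneous dihedral angle (radians); scalar.
#' @param k_a,k_v area and volume constraint coefficients (dimensionless,
#'   scaled internally by `kBT/l0^2` and `kBT/l0^3`).
#' @param gamma_T,gamma_C membrane dissipative parameters (translational and
#'   central).
#' @param kBT thermal energy.
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(p = 0.004, k_b = 7.56, theta0 = 0, k_a = 9800,
                            k_v = 10000, gamma_T = 10, gamma_C = 5,
                            kBT = 0.0945) {
  stopifnot(p > 0, gamma_T > 0)
  if (3 * gamma_C < gamma_T)
    stop("membrane viscosity requires 3*gamma_C >= gamma_T ",
         "(random trace amplitude must be real)")
  structure(list(p = p, k_b = k_b, theta0 = theta0, k_a = k_a, k_v = k_v,
                 gamma_T = gamma_T, gamma_C = gamma_C, kBT = kBT),
            class = "membrane_params")
}

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v / sqrt(1 + t^2), faces = f)
}

subdivide_once <- function(v, f) {
  key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  mid <- new.env()
  verts <- v
  getmid <- function(i, j) {
    k <- key(i, j)
    if (!is.null(mid[[k]])) return(mid[[k]])
    m <- (verts[i, ] + verts[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    mid[[k]] <- nrow(verts)
    nrow(verts)
  }
  nf <- NULL
  for (r in seq_len(nrow(f))) {
    a <- f[r, 1]; b <- f[r, 2]; c3 <- f[r, 3]
    ab <- getmid(a, b); bc <- getmid(b, c3); ca <- getmid(c3, a)
    nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
  }
  list(vertices = verts, faces = nf)
}

orient_outward <- function(v, f) {
  cen <- colMeans(v)
  for (r in seq_len(nrow(f))) {
    a <- v[f[r, 1], ]; b <- v[f[r, 2], ]; c3 <- v[f[r, 3], ]
    e1 <- b - a; e2 <- c3 - a
    n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    if (sum(n * ((a + b + c3) / 3 - cen)) < 0) f[r, ] <- f[r, c(1, 3, 2)]
  }
  f
}

mesh_topology <- function(faces) {
  edges <- unique(t(apply(rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)]),
                          1, sort)))
  # map each directed edge to its triangle
  m <- nrow(faces)
  dir_edges <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  dir_tri <- rep(seq_len(m), 3)
  ekey <- function(i, j) paste0(i, "_", j)
  lookup <- new.env(hash = TRUE, size = 6 * m)
  for (r in seq_len(nrow(dir_edges)))
    lookup[[ekey(dir_edges[r, 1], dir_edges[r, 2])]] <- dir_tri[r]
  dih <- matrix(0L, nrow(edges), 4)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    t1 <- lookup[[ekey(i, j)]]   # triangle containing i -> j
    t2 <- lookup[[ekey(j, i)]]   # triangle containing j -> i
    if (is.null(t1) || is.null(t2))
      stop("mesh is not a closed orientable 2-manifold (open or doubled edge)")
    k <- setdiff(faces[t1, ], c(i, j))
    l <- setdiff(faces[t2, ], c(i, j))
    dih[e, ] <- c(i, j, k, l)
  }
  list(springs = edges, dihedrals = dih)
}

#' Build a triangulated red-blood-cell mesh
#'
#' Closed sphere-topology triangulation by icosahedral subdivision (achievable
#' vertex counts are 12, 42, 162, 642, 2562, ...; the nearest achievable count
#' is used and reported via a message). The sphere is flattened into an oblate
#' shape and rescaled iteratively toward the requested total area and volume;
#' spring rest length `l0` is the mean generated edge length, and the
#' reference `A0`, `V0` are recorded from the built mesh.
#'
#' @param n_vertices requested vertex count (>= 12).
#' @param area target total membrane area; default `4 * pi * radius^2`.
#' @param volume target enclosed volume; default `reduced_volume` times the
#'   volume of the sphere with the same area (0.64 is the classical reduced
#'   volume of a biconcave red cell).
#' @param radius nominal cell radius used when `area` is NULL.
#' @param reduced_volume volume fraction relative to the equal-area sphere.
#' @param center cell center (length 3).
#' @param orientation unit vector for the oblate (short) axis; default z.
#' @param x0 equilibrium-to-maximum spring length ratio `l0/lm` (0 < x0 < 1).
#' @return object of class `rbc_mesh`: `vertices`, `springs`, `triangles`,
#'   `dihedrals`, `nv`, `l0`, `lm`, `A0`, `V0`.
#' @examples
#' m <- build_rbc_mesh(12)         # icosahedron: 30 springs, 20 triangles
#' nrow(m$springs)
#' @export
build_rbc_mesh <- function(n_vertices, area = NULL, volume = NULL, radius = 1,
                           reduced_volume = 0.64, center = c(0, 0, 0),
                           orientation = c(0, 0, 1), x0 = 0.45) {
  stopifnot(n_vertices >= 12, x0 > 0, x0 < 1)
  counts <- 10 * 4^(0:5) + 2
  k <- which.min(abs(counts - n_vertices))
  if (counts[k] != n_vertices)
    message("n_vertices = ", n_vertices, " not achievable by subdivision; ",
            "using nearest achievable ", counts[k])
  ico <- icosahedron()
  v <- ico$vertices; f <- ico$faces
  if (k > 1) for (s in seq_len(k - 1)) {
    sub <- subdivide_once(v, f)
    v <- sub$vertices; f <- sub$faces
  }
  f <- orient_outward(v, f)

  if (is.null(area)) area <- 4 * pi * radius^2
  rA <- sqrt(area / (4 * pi))
  if (is.null(volume)) volume <- reduced_volume * 4 / 3 * pi * rA^3
  stopifnot(area > 0, volume > 0)

  # iterate oblate scaling toward the (area, volume) pair
  av <- function(vv) mesh_area_volume(list(triangles = f), vv)
  sq <- 1
  for (it in 1:60) {
    vv <- v %*% diag(c(1, 1, sq))
    cur <- av(vv)
    vv <- vv * sqrt(area / cur$area)
    cur <- av(vv)
    ratio <- volume / cur$volume
    if (abs(ratio - 1) < 1e-6) break
    # oblate flattening only: a coarse polyhedron cannot reach the reduced
    # volume of the smooth sphere, so targets above its maximum are clamped
    if (sq >= 1 && ratio >= 1) break
    sq <- min(1, sq * max(0.5, min(2, ratio^0.9)))
    if (sq < 0.05) { sq <- 0.05; break }
  }
  v <- v %*% diag(c(1, 1, sq))
  v <- v * sqrt(area / av(v)$area)

  # rotate short axis onto `orientation`, then translate
  o <- orientation / sqrt(sum(orientation^2))
  z <- c(0, 0, 1)
  if (sum((o - z)^2) > 1e-12) {
    ax <- c(z[2] * o[3] - z[3] * o[2], z[3] * o[1] - z[1] * o[3],
            z[1] * o[2] - z[2] * o[1])
    sa <- sqrt(sum(ax^2)); ca <- sum(z * o)
    if (sa > 1e-12) {
      ax <- ax / sa
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      Rm <- diag(3) + sa * K + (1 - ca) * K %*% K
      v <- v %*% t(Rm)
    } else if (ca < 0) v[, 3] <- -v[, 3]
  }
  v <- sweep(v, 2, center, "+")

  topo <- mesh_topology(f)
  l0 <- mean(sqrt(rowSums((v[topo$springs[, 1], ] - v[topo$springs[, 2], ])^2)))
  cur <- mesh_area_volume(list(triangles = f), v)
  structure(list(vertices = v, springs = topo$springs, triangles = f,
                 dihedrals = topo$dihedrals, nv = nrow(v), l0 = l0,
                 lm = l0 / x0, A0 = cur$area, V0 = cur$volume),
            class = "rbc_mesh")
}

#' Total area and signed volume of a closed triangulated mesh
#'
#' Area is the sum of triangle areas; volume is the sum of signed tetrahedron
#' volumes `(a . (b x c)) / 6`, positive for consistent outward orientation.
#'
#' @param mesh list with `triangles` (m x 3 vertex indices).
#' @param positions n x 3 vertex coordinates (defaults to `mesh$vertices`).
#' @return list `area`, `volume`.
#' @export
mesh_area_volume <- function(mesh, positions = mesh$vertices) {
  f <- mesh$triangles
  a <- positions[f[, 1], , drop = FALSE]
  b <- positions[f[, 2], , drop = FALSE]
  c3 <- positions[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  bc <- cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
              b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
              b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  volume <- sum(rowSums(a * bc)) / 6
  list(area = area, volume = volume)
}

mesh_as_list <- function(mesh) {
  list(nv = mesh$nv, springs = mesh$springs, triangles = mesh$triangles,
       dihedrals = mesh$dihedrals, l0 = mesh$l0, lm = mesh$lm)
}

#' Elastic (in-plane) membrane forces and energy
#'
#' WLC spring energy plus the per-triangle repulsion `C/A_alpha` whose
#' constant `C` makes a flat equilateral network with all springs at `l0`
#' stress free. Forces are the exact negative gradient of the energy; any
#' spring at or beyond its maximum extension (`l >= lm`) is an error.
#'
#' @param mesh an `rbc_mesh`.
#' @param params [membrane_params()].
#' @param positions vertex coordinates (defaults to `mesh$vertices`).
#' @return list `forces` (n x 3), `energy` (V_s).
#' @export
elastic_forces <- function(mesh, params = membrane_params(),
                           positions = mesh$vertices) {
  r <- cpp_membrane_forces(positions, mesh_as_list(mesh), unclass(params),
                           mesh$A0, mesh$V0, TRUE, FALSE, FALSE)
  list(forces = r$forces, energy = r$V_s)
}

#' Bending forces and energy
#'
#' Dihedral bending energy `sum k_b (1 - cos(theta - theta0))` over adjacent
#' triangle pairs, with exact analytic gradients (regular at flat
#' configurations).
#'
#' @inheritParams elastic_forces
#' @return list `forces`, `energy` (V_b).
#' @export
bending_forces <- function(mesh, params = membrane_params(),
                           positions = mesh$vertices) {
  r <- cpp_membrane_forces(positions, mesh_as_list(mesh), unclass(params),
                           mesh$A0, mesh$V0, FALSE, TRUE, FALSE)
  list(forces = r$forces, energy = r$V_b)
}

#' Global area and volume constraint forces
#'
#' `V_a = k_a kBT (A - A0)^2 / (2 l0^2 A0)` and
#' `V_v = k_v kBT (V - V0)^2 / (2 l0^3 V0)`, with forces from the exact
#' triangle-area and signed-tetrahedron-volume derivatives. An inverted mesh
#' (V <= 0) is an error.
#'
#' @inheritParams elastic_forces
#' @return list `forces`, `energy_area`, `energy_volume`, `area`, `volume`.
#' @export
area_volume_forces <- function(mesh, params = membrane_params(),
                               positions = mesh$vertices) {
  r <- cpp_membrane_forces(positions, mesh_as_list(mesh), unclass(params),
                           mesh$A0, mesh$V0, FALSE, FALSE, TRUE)
  list(forces = r$forces, energy_area = r$V_a, energy_volume = r$V_v,
       area = r$area, volume = r$volume)
}

#' All membrane bonded energies at once
#'
#' Total energy `V = V_s + V_b + V_a + V_v` and the combined force (sum of
#' the four negative gradients).
#'
#' @inheritParams elastic_forces
#' @return list `forces`, `V_s`, `V_b`, `V_a`, `V_v`, `total`, `area`,
#'   `volume`.
#' @export
rbc_energy_forces <- function(mesh, params = membrane_params(),
                              positions = mesh$vertices) {
  r <- cpp_membrane_forces(positions, mesh_as_list(mesh), unclass(params),
                           mesh$A0, mesh$V0, TRUE, TRUE, TRUE)
  r$total <- r$V_s + r$V_b + r$V_a + r$V_v
  r
}

#' Per-spring Wiener increments for the membrane random force
#'
#' One 3 x 3 matrix of independent Gaussian increments (variance `dt`) per
#' spring, stored as an `n_springs` x 9 matrix (row-major 3 x 3). Use
#' [wiener_decompose()] for the traceless symmetric part and the trace.
#'
#' @param n_springs number of springs.
#' @param dt time step.
#' @return matrix of class `spring_wiener_increment` with attribute `dt`.
#' @export
spring_wiener_increments <- function(n_springs, dt) {
  W <- matrix(rnorm(9 * n_springs, sd = sqrt(dt)), n_springs, 9)
  structure(W, dt = dt, class = c("spring_wiener_increment", "matrix"))
}

#' Decompose a Wiener increment matrix
#'
#' @param w length-9 numeric (row-major 3 x 3 increment).
#' @return list `symmetric` (3 x 3), `traceless_symmetric` (3 x 3, symmetric
#'   and zero-trace by construction) and `trace`.
#' @export
wiener_decompose <- function(w) {
  M <- matrix(as.numeric(w), 3, 3, byrow = TRUE)
  S <- (M + t(M)) / 2
  tr <- sum(diag(M))
  list(symmetric = S, traceless_symmetric = S - diag(3) * tr / 3, trace = tr)
}

#' Membrane viscous (dissipative) and random spring forces
#'
#' Per-spring dissipative force `F_D = -gamma_T v_ij - gamma_C (v_ij.e) e`
#' applied antisymmetrically to the endpoints, and its fluctuation-dissipation
#' counterpart built from the traceless symmetric part and trace of the
#' per-spring Wiener increments (amplitudes `sqrt(2 kBT) sqrt(2 gamma_T)` and
#' `sqrt(2 kBT) sqrt(3 gamma_C - gamma_T) / 3`).
#'
#' @inheritParams elastic_forces
#' @param velocities n x 3 vertex velocities.
#' @param dt time step.
#' @param dW optional [spring_wiener_increments()] matrix; NULL disables the
#'   random part.
#' @return list `dissipative`, `random` (n x 3 each).
#' @export
membrane_viscous_forces <- function(mesh, params = membrane_params(),
                                    positions = mesh$vertices, velocities,
                                    dt = 0.005, dW = NULL) {
  cpp_membrane_viscous(positions, velocities, mesh_as_list(mesh),
                       unclass(params), dt, dW)
}
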