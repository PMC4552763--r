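#' DPD fluid parameters
#'
#' Pair-force parameters of the plasma fluid (also used for fluid-wall and
#' fluid-membrane coupling). The random amplitude is derived from the
#' fluctuation-dissipation relation `sigma^2 = 2 * gamma * kBT` and cannot be
#' set independently. Defaults are the reference parameter set for plasma:
#' `a = 4.0`, `gamma = 30.0`, `r_c = 1.5`, `kBT = 0.0945`, `n = 2.96`, with
#' the generalized dissipative weight exponent `s = 0.5` (chosen to raise the
#' fluid viscosity relative to the classical `s = 2`) and per-particle body
#' force `g = 0.1` driving the flow.
#'
#' @param a conservative amplitude.
#' @param gamma dissipative coefficient.
#' @param r_c interaction cutoff.
#' @param kBT thermal energy.
#' @param s dissipative weight exponent in `w_D(r) = (1 - r/r_c)^s`;
#'   the random weight is `w_R = w_D^(1/2)`.
#' @param n target fluid number density.
#' @param g per-particle body-force magnitude along the local flow axis.
#' @return object of class `dpd_params` (with derived `sigma`).
#' @export
dpd_params <- function(a = 4.0, gamma = 30.0, r_c = 1.5, kBT = 0.0945,
                       s = 0.5, n = 2.96, g = 0.1) {
  stopifnot(r_c > 0, gamma >= 0, kBT >= 0, n > 0)
  structure(list(a = a, gamma = gamma, r_c = r_c, kBT = kBT, s = s, n = n,
                 g = g, sigma = sqrt(2 * gamma * kBT)),
            class = "dpd_params")
}

#' DPD pairwise force
#'
#' Standard Groot-Warren force on particle i from particle j:
#' `F = [a (1 - r/r_c) - gamma w_D (e.v_ij) + sigma w_R xi / sqrt(dt)] e`,
#' with `w_D = (1 - r/r_c)^s`, `w_R = sqrt(w_D)`, `e` the unit vector from j
#' to i and `v_ij = v_i - v_j`. All components vanish at and beyond the cutoff (`r_c`); forces
#' are equal and opposite. The per-pair standard normal `xi` is symmetric in
#' the pair order; pass `xi = 0` (default) to disable the random term.
#'
#' @param xi_pos,xj_pos positions (length 3).
#' @param vi,vj velocities (length 3).
#' @param params [dpd_params()].
#' @param dt time step (only used by the random term).
#' @param xi standard-normal draw for the random force (default 0).
#' @return list with `f_i`, `f_j` (= -f_i) and the scalar `conservative`,
#'   `dissipative`, `random` amplitudes along `e`.
#' @export
dpd_pair_force <- function(xi_pos, xj_pos, vi = c(0, 0, 0), vj = c(0, 0, 0),
                           params = dpd_params(), dt = 0.005, xi = 0) {
  d <- as.numeric(xi_pos) - as.numeric(xj_pos)
  r <- sqrt(sum(d^2))
  if (r == 0) stop("coincident particles: r = 0 in dpd_pair_force")
  if (r >= params$r_c)
    return(list(f_i = c(0, 0, 0), f_j = c(0, 0, 0), conservative = 0,
                dissipative = 0, random = 0))
  e <- d / r
  om <- 1 - r / params$r_c
  wD <- om^params$s
  fc <- params$a * om
  fd <- -params$gamma * wD * sum(e * (vi - vj))
  fr <- params$sigma * sqrt(wD) * xi / sqrt(dt)
  F <- (fc + fd + fr) * e
  list(f_i = F, f_j = -F, conservative = fc, dissipative = fd, random = fr)
}

#' Equilibrium kinetic temperature estimate
#'
#' `kBT` estimated as 2/3 of the mean kinetic energy per particle over a
#' window of velocity snapshots (unit mass).
#'
#' @param vel_samples list of n x 3 velocity matrices (>= 10 snapshots), or a
#'   numeric vector of per-snapshot mean kinetic energies per particle.
#' @return scalar `kBT` estimate.
#' @export
equilibrium_temperature <- function(vel_samples) {
  ke <- if (is.list(vel_samples)) {
    vapply(vel_samples, function(v) mean(rowSums(as.matrix(v)^2)) / 2, 0)
  } else as.numeric(vel_samples)
  if (length(ke) < 10)
    stop("temperature window must contain at least 10 samples")
  mean(ke) * 2 / 3
}

#' Fit a Poiseuille (parabolic) velocity profile
#'
#' Least-squares parabola `v(x) = v_max (1 - (2x/d)^2)` fitted as
#' `v ~ 1 + x^2` to a radial profile of mean axial velocities; returns the
#' centerline velocity, the apparent viscosity from the analytic relation
#' `dP/dz = 16 v_max eta / d^2 = n g`, and the fit R^2. Profiles whose R^2
#' falls below `r2_flag` are flagged non-parabolic (plug-like).
#'
#' @param r bin centers (radial or cross-flow coordinate, signed or not).
#' @param v mean axial velocity per bin.
#' @param d tube diameter.
#' @param ng product of number density and body force, the analytic pressure
#'   gradient; used for the viscosity estimate.
#' @param r2_flag threshold below which the profile is flagged non-parabolic.
#' @return list `v_max`, `eta`, `r_squared`, `parabolic`.
#' @export
fit_poiseuille <- function(r, v, d, ng, r2_flag = 0.9) {
  keep <- is.finite(r) & is.finite(v)
  r <- r[keep]; v <- v[keep]
  if (length(r) < 5) stop("need at least 5 radial bins to fit a parabola")
  fit <- lm(v ~ I(r^2))
  v_max <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  eta <- ng * d^2 / (16 * v_max)
  list(v_max = v_max, eta = eta, r_squared = r2, parabolic = r2 >= r2_flag)
}
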