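#' Radial velocity profile from snapshots
#'
#' Time- and azimuth-averaged axial velocity per radial bin (cylindrical
#' shells of equal width). Empty bins are recorded as missing, not zero.
#'
#' @param snapshots list of snapshots, each a list with `position` and
#'   `velocity` matrices (or `particle_system` objects).
#' @param bins number of radial bins.
#' @param rmax maximum radius (tube radius).
#' @param zlim optional axial window.
#' @param axis flow axis (only `"z"` supported).
#' @return object of class `flow_profile`: `edges`, `centers`, `mean`,
#'   `count`, `window` (number of snapshots).
#' @export
velocity_profile <- function(snapshots, bins = 20, rmax, zlim = NULL,
                             axis = "z") {
  stopifnot(axis == "z", bins >= 1, rmax > 0)
  edges <- seq(0, rmax, length.out = bins + 1)
  sums <- numeric(bins); cnts <- numeric(bins)
  for (sn in snapshots) {
    p <- sn$position; v <- sn$velocity
    keep <- rep(TRUE, nrow(p))
    if (!is.null(zlim)) keep <- p[, 3] >= zlim[1] & p[, 3] <= zlim[2]
    r <- sqrt(p[keep, 1]^2 + p[keep, 2]^2)
    vz <- v[keep, 3]
    b <- findInterval(r, edges, rightmost.closed = TRUE)
    ok <- b >= 1 & b <= bins
    sums <- sums + tabulate_weighted(b[ok], vz[ok], bins)
    cnts <- cnts + tabulate(b[ok], bins)
  }
  m <- ifelse(cnts > 0, sums / cnts, NA_real_)
  structure(list(edges = edges, centers = (edges[-1] + edges[-(bins + 1)]) / 2,
                 mean = m, count = cnts, window = length(snapshots)),
            class = "flow_profile")
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- tapply(w, factor(bin, levels = seq_len(nbins)), sum)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  out
}

#' Merge two profiles measured over disjoint windows
#'
#' Count-weighted mean; merging two half-length windows reproduces the full
#' window to roundoff (streaming-mean identity).
#'
#' @param p1,p2 `flow_profile` objects over identical bins.
#' @return merged `flow_profile`.
#' @export
combine_profiles <- function(p1, p2) {
  stopifnot(all(p1$edges == p2$edges))
  cnt <- p1$count + p2$count
  s1 <- ifelse(p1$count > 0, p1$mean * p1$count, 0)
  s2 <- ifelse(p2$count > 0, p2$mean * p2$count, 0)
  m <- ifelse(cnt > 0, (s1 + s2) / cnt, NA_real_)
  structure(list(edges = p1$edges, centers = p1$centers, mean = m,
                 count = cnt, window = p1$window + p2$window),
            class = "flow_profile")
}

#' Profile with block standard errors from engine sample rows
#'
#' Averages the per-sample bin means accumulated by the engine and estimates
#' per-bin standard errors by block averaging (reducing the bias from
#' autocorrelation between consecutive samples).
#'
#' @param sample_matrix samples x bins matrix of per-sample bin means.
#' @param edges bin edges.
#' @param blocks number of blocks for the error estimate.
#' @return `flow_profile` with `se` and `blocks` fields.
#' @export
profile_from_samples <- function(sample_matrix, edges, blocks = 10) {
  nb <- ncol(sample_matrix)
  ns <- nrow(sample_matrix)
  m <- colMeans(sample_matrix, na.rm = TRUE)
  bl <- pmin(blocks, ns)
  idx <- cut(seq_len(ns), bl, labels = FALSE)
  bm <- vapply(seq_len(nb), function(b)
    tapply(sample_matrix[, b], idx, mean, na.rm = TRUE), numeric(bl))
  se <- apply(bm, 2, function(x) sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
  cnt <- colSums(is.finite(sample_matrix))
  structure(list(edges = edges, centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 mean = m, se = se, count = cnt, window = ns, blocks = bl),
            class = "flow_profile")
}

#' Axial pressure profile from snapshots
#'
#' Per-slab virial pressure: peculiar-velocity kinetic part plus half the
#' pairwise r-dot-F virial assigned per particle (supplied per snapshot as
#' `virial`, the engine's per-particle accumulator; forces off gives the
#' ideal-gas limit `n kBT`). A slab thinner than the interaction cutoff
#' biases the virial assignment and triggers a warning.
#'
#' @param snapshots list of lists with `position`, `velocity` and optionally
#'   `virial` (per-particle, already divided by 6 per pair end).
#' @param slabs number of axial slabs.
#' @param zlim axial window.
#' @param slab_volume lumen volume of one slab.
#' @param r_c interaction cutoff (for the thin-slab warning).
#' @return object of class `pressure_profile`: `centers`, `pressure`,
#'   `count`.
#' @export
pressure_profile <- function(snapshots, slabs, zlim, slab_volume, r_c = 1.5) {
  dz <- diff(zlim) / slabs
  if (dz < r_c) warning("slab thinner than r_c: virial slab assignment biased")
  edges <- seq(zlim[1], zlim[2], length.out = slabs + 1)
  acc <- matrix(0, 0, slabs)
  for (sn in snapshots) {
    p <- sn$position; v <- sn$velocity
    keep <- p[, 3] >= zlim[1] & p[, 3] < zlim[2]
    b <- findInterval(p[keep, 3], edges, rightmost.closed = TRUE)
    vir <- if (!is.null(sn$virial)) sn$virial[keep] else numeric(sum(keep))
    vv <- v[keep, , drop = FALSE]
    row <- vapply(seq_len(slabs), function(s) {
      i <- b == s
      if (!any(i)) return(NA_real_)
      u <- colMeans(vv[i, , drop = FALSE])
      kin <- sum(sweep(vv[i, , drop = FALSE], 2, u)^2) / 3
      (kin + sum(vir[i])) / slab_volume
    }, 0)
    acc <- rbind(acc, row)
  }
  structure(list(centers = (edges[-1] + edges[-(slabs + 1)]) / 2,
                 pressure = colMeans(acc, na.rm = TRUE),
                 count = colSums(is.finite(acc))),
            class = "pressure_profile")
}

#' Red-blood-cell recovery efficiency at a bifurcation
#'
#' Fraction of the parent-branch RBC flux entering each daughter branch,
#' computed from counts of cells dissolved per outlet (cell flux, not
#' instantaneous positions), with Clopper-Pearson binomial confidence
#' intervals. The measured flow-rate ratio `phi_d` comes from the per-outlet
#' fluid removal rates when supplied.
#'
#' @param exits matrix/data.frame with an `outlet` column (1-based outlet
#'   index per dissolved cell), as in `sim_stats()$exits`.
#' @param n_branches number of outlets.
#' @param fluid_removed optional per-outlet cumulative fluid removal counts.
#' @param conf confidence level.
#' @return object of class `recovery_record`: `counts`, `fraction`, `ci`
#'   (2 x n matrix), `phi_d` (or NA), `n_cells`.
#' @export
recovery_efficiency <- function(exits, n_branches = 2, fluid_removed = NULL,
                                conf = 0.95) {
  outlet <- if (is.matrix(exits)) exits[, "outlet"] else exits$outlet
  if (length(outlet) > 0 &&
      any(outlet < 1 | outlet > n_branches))
    stop("cell exited an unregistered branch")
  counts <- tabulate(outlet, n_branches)
  n <- sum(counts)
  frac <- if (n > 0) counts / n else rep(NA_real_, n_branches)
  al <- (1 - conf) / 2
  ci <- vapply(counts, function(k) {
    if (n == 0) return(c(NA_real_, NA_real_))
    lo <- if (k == 0) 0 else qbeta(al, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - al, k + 1, n - k)
    c(lo, hi)
  }, numeric(2))
  phi <- NA_real_
  if (!is.null(fluid_removed) && length(fluid_removed) >= 2 &&
      all(fluid_removed[1:2] > 0))
    phi <- max(fluid_removed[1:2]) / min(fluid_removed[1:2])
  structure(list(counts = counts, fraction = frac, ci = ci, phi_d = phi,
                 n_cells = n),
            class = "recovery_record")
}

#' @export
print.recovery_record <- function(x, ...) {
  cat("<recovery_record> ", x$n_cells, " cells; fractions: ",
      paste(sprintf("%.3f", x$fraction), collapse = " / "),
      if (is.finite(x$phi_d)) sprintf("; measured phi_d = %.2f", x$phi_d),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom stats qbeta
NULL
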