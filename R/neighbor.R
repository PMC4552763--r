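#' Neighbor pair search
#'
#' Returns all unordered particle pairs with separation below `cutoff`, using
#' a uniform cell list (cell edge >= cutoff, rebuilt on every call). Minimum
#' image convention is honored only in dimensions flagged periodic.
#'
#' @param x a `particle_system` or an n x 3 position matrix.
#' @param cutoff interaction cutoff (> 0).
#' @param box length-6 numeric `c(xlo, xhi, ylo, yhi, zlo, zhi)`; if NULL, the
#'   tight bounding box of the positions (plus a small pad) is used, which is
#'   only valid for non-periodic searches.
#' @param periodic logical length 3; periodicity per dimension.
#' @return integer matrix with two columns (i, j), i < j, one row per pair.
#' @examples
#' p <- matrix(c(0, 0, 0, 0.5, 0, 0), 2, 3, byrow = TRUE)
#' build_neighbor_pairs(p, cutoff = 1)
#' @export
build_neighbor_pairs <- function(x, cutoff, box = NULL,
                                 periodic = c(FALSE, FALSE, FALSE)) {
  pos <- if (inherits(x, "particle_system")) x$position else as.matrix(x)
  stopifnot(cutoff > 0, length(periodic) == 3)
  if (nrow(pos) < 2)
    return(matrix(integer(0), 0, 2))
  if (is.null(box)) {
    if (any(periodic)) stop("periodic search requires an explicit box")
    pad <- 1e-9 + cutoff * 1e-6
    box <- c(min(pos[, 1]) - pad, max(pos[, 1]) + pad + cutoff,
             min(pos[, 2]) - pad, max(pos[, 2]) + pad + cutoff,
             min(pos[, 3]) - pad, max(pos[, 3]) + pad + cutoff)
  }
  cpp_neighbor_pairs(pos, cutoff, as.numeric(box), as.logical(periodic))
}
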