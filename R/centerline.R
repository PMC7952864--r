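#' Sample a smooth tract centerline through control points
#'
#' Interpolates ordered control points (mm coordinates, e.g. running
#' from the frontal toward the temporal terminations of an arching
#' bundle) with a natural cubic spline per coordinate, parameterized by
#' chord length, and samples it densely.
#'
#' @param control_points matrix or data frame with 3 columns (x, y, z in
#'   mm), at least 3 rows, no duplicated consecutive rows.
#' @param n_samples number of samples along the curve (>= 10).
#' @return A tibble with columns `x`, `y`, `z`, `arc_length` (cumulative
#'   polyline arc length in mm, starting at 0 and strictly increasing)
#'   and `t` (arc-length fraction in \[0, 1\]).
#' @export
make_centerline <- function(control_points, n_samples = 200L) {
  cp <- as.matrix(control_points)
  if (ncol(cp) != 3L) abort("`control_points` must have 3 columns (x, y, z).")
  if (nrow(cp) < 3L) abort("At least 3 control points are required.")
  if (!all(is.finite(cp))) abort("Control points must be finite.")
  n_samples <- as.integer(n_samples)
  if (n_samples < 10L) abort("`n_samples` must be at least 10.")
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  if (any(seg == 0)) abort("Duplicate consecutive control points.")
  u <- c(0, cumsum(seg))
  uu <- seq(0, u[length(u)], length.out = n_samples)
  pts <- vapply(
    1:3,
    function(a) stats::spline(u, cp[, a], xout = uu, method = "natural")$y,
    numeric(n_samples)
  )
  step <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n_samples, , drop = FALSE])^2))
  arc <- c(0, cumsum(step))
  tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    arc_length = arc, t = arc / arc[length(arc)]
  )
}
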