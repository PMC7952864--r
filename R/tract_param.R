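#' Threshold a tract density map at a fraction of its maximum
#'
#' Reduces false-positive streamline visitations by keeping only voxels
#' whose density reaches `fraction` of the global maximum (boundary
#' values are kept).
#'
#' @param density non-negative `scalar_volume`.
#' @param fraction threshold fraction in (0, 1); default 0.10.
#' @return binary `scalar_volume` mask.
#' @export
threshold_density <- function(density, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  dmax <- max(density, na.rm = TRUE)
  if (!is.finite(dmax) || dmax <= 0) abort("Empty tract: density map has no positive values.")
  if (min(density, na.rm = TRUE) < 0) abort("Density map must be non-negative.")
  mask <- array(0, dim(density))
  mask[!is.na(unclass(density)) & unclass(density) >= fraction * dmax] <- 1
  scalar_volume(mask, vol_affine(density))
}

#' Restrict a tract mask to its compact white-matter core
#'
#' Removes voxels beyond anatomical limits where a bundle fans out
#' toward the cortex: anterior frontal projections (mm y-coordinate
#' greater than `y_max_mm`) and inferior temporal projections (mm
#' z-coordinate less than `z_min_mm`). Either limit may be Inf/-Inf to
#' disable it.
#'
#' @param mask binary `scalar_volume`.
#' @param y_max_mm anterior limit (voxels with y > limit are dropped).
#' @param z_min_mm inferior limit (voxels with z < limit are dropped).
#' @return restricted binary `scalar_volume`.
#' @export
restrict_core <- function(mask, y_max_mm = Inf, z_min_mm = -Inf) {
  xyz <- voxel_grid_mm(mask)
  drop <- xyz[, 2] > y_max_mm | xyz[, 3] < z_min_mm
  out <- unclass(mask)
  attr(out, "affine") <- NULL
  out[drop] <- 0
  if (sum(out > 0, na.rm = TRUE) == 0) {
    abort(sprintf(
      "Core restriction emptied the mask (y_max = %g mm, z_min = %g mm).",
      y_max_mm, z_min_mm
    ))
  }
  scalar_volume(out, vol_affine(mask))
}

#' Build a rectangular ROI mask in world (mm) coordinates
#'
#' Voxels whose center lies inside the closed box
#' \[x0, x1\] x \[y0, y1\] x \[z0, z1\] are set to 1. For mirrored
#' hemisphere pairs, call once per hemisphere with signed x ranges.
#'
#' @param grid_shape voxel counts (3 ints).
#' @param affine 4x4 voxel-to-mm affine.
#' @param x_range_mm,y_range_mm,z_range_mm length-2 numeric (min, max).
#' @return binary `scalar_volume`; warns if the box misses the grid.
#' @export
make_box_roi <- function(grid_shape, affine, x_range_mm, y_range_mm, z_range_mm) {
  rng <- list(x_range_mm, y_range_mm, z_range_mm)
  for (r in rng) {
    if (length(r) != 2 || r[1] > r[2]) abort("Ranges must be ordered (min, max).")
  }
  vol <- scalar_volume(array(0, grid_shape), affine)
  xyz <- voxel_grid_mm(vol)
  inside <- xyz[, 1] >= rng[[1]][1] & xyz[, 1] <= rng[[1]][2] &
    xyz[, 2] >= rng[[2]][1] & xyz[, 2] <= rng[[2]][2] &
    xyz[, 3] >= rng[[3]][1] & xyz[, 3] <= rng[[3]][2]
  if (!any(inside)) warn("Box ROI lies outside the grid: empty mask.")
  out <- unclass(vol)
  attr(out, "affine") <- NULL
  out[inside] <- 1
  scalar_volume(out, affine)
}

neighborhood_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1,
    "18" = nz >= 1 & rowSums(abs(off) > 0) <= 2,
    "26" = nz >= 1,
    abort("`connectivity` must be 6, 18 or 26.")
  )
  off[keep, , drop = FALSE]
}

#' Build the voxel-adjacency graph of a binary mask
#'
#' Nodes are in-mask voxels; edges connect voxels whose index offsets
#' lie in the chosen 3-D neighborhood (6, 18 or 26 neighbors). This is
#' the discrete "mesh" whose Laplacian parameterizes the tract.
#'
#' @param mask binary `scalar_volume`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return An object of class `voxel_graph`: list with `voxels` (n x 3
#'   1-based indices), `mm` (n x 3 world coordinates), `adjacency`
#'   (sparse symmetric 0/1 Matrix, zero diagonal), `component`
#'   (integer component label per node) and `connectivity`.
#' @export
build_voxel_graph <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(unclass(mask) > 0)
  if (length(idx) == 0) abort("Mask is empty.")
  n <- length(idx)
  node_of <- array(0L, d)
  node_of[idx] <- seq_len(n)
  vox <- arrayInd(idx, d)
  off <- neighborhood_offsets(connectivity)
  # half the offsets suffice; symmetrize afterwards
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
    (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- vox + matrix(off[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- rep(0L, n)
    j[ok] <- node_of[nb[ok, , drop = FALSE]]
    hit <- j > 0L
    from <- c(from, which(hit))
    to <- c(to, j[hit])
  }
  adj <- Matrix::sparseMatrix(
    i = c(from, to), j = c(to, from), x = 1,
    dims = c(n, n)
  )
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  structure(
    list(
      voxels = vox,
      mm = voxel_to_world(vox, vol_affine(mask)),
      adjacency = adj,
      component = as.integer(comp),
      connectivity = connectivity,
      dim = d, affine = vol_affine(mask)
    ),
    class = "voxel_graph"
  )
}

#' @export
print.voxel_graph <- function(x, ...) {
  cat(sprintf(
    "<voxel_graph> %d voxels, %d edges, %d component(s), %d-connectivity\n",
    nrow(x$voxels), Matrix::nnzero(x$adjacency) / 2,
    max(x$component), x$connectivity
  ))
  invisible(x)
}

#' Reduce a voxel graph to its largest connected component
#'
#' Density thresholding can leave satellite islands; the along-tract
#' coordinate is defined on the main body only. Errors if the largest
#' component holds less than `min_fraction` of the mask voxels.
#'
#' @param graph a `voxel_graph`.
#' @param min_fraction minimum tolerated fraction in the largest
#'   component (default 0.5).
#' @return a connected `voxel_graph`; warns when voxels are discarded.
#' @export
reduce_to_largest_component <- function(graph, min_fraction = 0.5) {
  tab <- tabulate(graph$component)
  if (length(tab) == 1L) {
    return(graph)
  }
  big <- which.max(tab)
  frac <- tab[big] / sum(tab)
  if (frac < min_fraction) {
    abort(sprintf(
      "Largest connected component holds only %.0f%% of mask voxels.",
      100 * frac
    ))
  }
  warn(sprintf(
    "Mask is disconnected: keeping largest component (%.1f%% of voxels).",
    100 * frac
  ))
  keep <- graph$component == big
  adj <- graph$adjacency[keep, keep, drop = FALSE]
  structure(
    list(
      voxels = graph$voxels[keep, , drop = FALSE],
      mm = graph$mm[keep, , drop = FALSE],
      adjacency = adj,
      component = rep(1L, sum(keep)),
      connectivity = graph$connectivity,
      dim = graph$dim, affine = graph$affine
    ),
    class = "voxel_graph"
  )
}

#' Fiedler vector of a voxel graph
#'
#' Computes the eigenvector of the combinatorial graph Laplacian
#' L = D - A associated with its smallest non-zero eigenvalue. Along an
#' elongated tract this eigenvector varies smoothly from one end to the
#' other and serves as the along-tract coordinate. Small graphs use a
#' dense symmetric eigendecomposition; larger ones use shift-and-invert
#' power iteration on a sparse Cholesky factor with deflation of the
#' constant vector.
#'
#' @param graph a `voxel_graph` (must be connected).
#' @param dense_cutoff node count at or below which the dense solver is
#'   used.
#' @param tol relative eigen-residual tolerance `||Lv - lambda v|| <=
#'   tol * ||v||`.
#' @param max_iter iteration cap for the sparse path.
#' @return list with `vector` (unit norm, orthogonal to constant),
#'   `value` (the Fiedler eigenvalue) and `residual`.
#' @export
fiedler_vector <- function(graph, dense_cutoff = 1500L, tol = 1e-8,
                           max_iter = 5000L) {
  n <- nrow(graph$voxels)
  if (max(graph$component) > 1L) {
    abort("Graph is disconnected; reduce to one component first.")
  }
  if (n < 2L) abort("Graph must have at least 2 nodes.")
  A <- graph$adjacency
  deg <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(n, deg) - A
  if (n <= dense_cutoff) {
    e <- eigen(as.matrix(L), symmetric = TRUE)
    v <- e$vectors[, n - 1L]
    lam <- e$values[n - 1L]
  } else {
    sigma <- 1e-4 * mean(deg)
    ch <- Matrix::Cholesky(L + Matrix::Diagonal(n, sigma), LDL = FALSE)
    ones <- rep(1 / sqrt(n), n)
    v <- rnorm(n)
    v <- v - sum(v * ones) * ones
    v <- v / sqrt(sum(v^2))
    lam <- NA_real_
    for (it in seq_len(max_iter)) {
      w <- as.numeric(Matrix::solve(ch, v))
      w <- w - sum(w * ones) * ones
      w <- w / sqrt(sum(w^2))
      Lw <- as.numeric(L %*% w)
      lam_new <- sum(w * Lw)
      res <- sqrt(sum((Lw - lam_new * w)^2))
      v <- w
      lam <- lam_new
      if (res <= tol) break
    }
    if (is.na(lam)) abort("Eigensolver failed to start.")
  }
  v <- v / sqrt(sum(v^2))
  resid <- sqrt(sum((as.numeric(L %*% v) - lam * v)^2))
  if (resid > tol * 10) {
    abort(sprintf(
      "Eigensolver did not converge: residual %.2e after iteration cap.",
      resid
    ))
  }
  list(vector = v, value = lam, residual = resid)
}

#' Orient and normalize a raw spectral coordinate
#'
#' The Fiedler vector is defined only up to sign. The sign is fixed by
#' an anatomical anchor: with `anchor = "frontal"`, the decile of voxels
#' with the smallest coordinate must lie more anterior (greater mean
#' mm y) than the decile with the largest coordinate, so t = 0 sits at
#' the frontal end. The coordinate is then min-max rescaled to
#' \[0, 1\].
#'
#' @param raw numeric coordinate per graph node.
#' @param graph the `voxel_graph` the coordinate lives on.
#' @param anchor "frontal" (t = 0 anterior) or "temporal" (t = 0 at the
#'   inferior-posterior end).
#' @return numeric t in \[0, 1\] per node.
#' @export
orient_and_normalize <- function(raw, graph, anchor = c("frontal", "temporal")) {
  anchor <- match.arg(anchor)
  if (diff(range(raw)) == 0) abort("Raw coordinate is constant; cannot orient.")
  n <- length(raw)
  k <- max(1L, floor(n / 10))
  ord <- order(raw)
  y_low <- mean(graph$mm[head(ord, k), 2])
  y_high <- mean(graph$mm[tail(ord, k), 2])
  if (y_low == y_high) {
    abort("Anterior coordinate ties: sign undecidable; supply explicit anchor coordinates.")
  }
  flip <- if (anchor == "frontal") y_low < y_high else y_low > y_high
  if (flip) raw <- -raw
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Equal-width segment labels from a normalized coordinate
#'
#' @param t numeric in \[0, 1\].
#' @param K number of segments (>= 2), default 15.
#' @return integer labels in 1..K: label = floor(t K) + 1, with t = 1
#'   assigned to K. Warns if any label is empty.
#' @export
segment_labels <- function(t, K = 15L) {
  K <- as.integer(K)
  if (K < 2L) abort("`K` must be at least 2.")
  if (any(t < 0 | t > 1, na.rm = TRUE)) abort("`t` must lie in [0, 1].")
  lab <- pmin(floor(t * K) + 1L, K)
  miss <- setdiff(seq_len(K), unique(lab[!is.na(lab)]))
  if (length(miss) > 0) {
    warn(sprintf("Empty segment label(s): %s.", paste(miss, collapse = ", ")))
  }
  as.integer(lab)
}

#' Parameterize a tract density volume end to end
#'
#' threshold -> optional core restriction -> voxel graph -> largest
#' component -> Fiedler vector -> orientation -> K equal-width
#' segments.
#'
#' @param density tract density `scalar_volume`.
#' @param fraction density threshold fraction (default 0.10).
#' @param y_max_mm,z_min_mm core-restriction limits (defaults disable).
#' @param connectivity voxel neighborhood (default 26).
#' @param K number of segments (default 15).
#' @param anchor anatomical end assigned t = 0 (default "frontal").
#' @return list of class `tract_parameterization`: `t_volume` and
#'   `label_volume` (`scalar_volume`s, NA outside the tract), `graph`,
#'   `t`, `labels`, `eigenvalue`, and a tibble `voxels` (i, j, k, x, y,
#'   z, t, segment).
#' @export
parameterize_tract <- function(density, fraction = 0.10,
                               y_max_mm = Inf, z_min_mm = -Inf,
                               connectivity = 26, K = 15L,
                               anchor = "frontal") {
  mask <- threshold_density(density, fraction)
  mask <- restrict_core(mask, y_max_mm = y_max_mm, z_min_mm = z_min_mm)
  graph <- build_voxel_graph(mask, connectivity)
  graph <- reduce_to_largest_component(graph)
  eig <- fiedler_vector(graph)
  t <- orient_and_normalize(eig$vector, graph, anchor)
  labels <- segment_labels(t, K)
  t_vol <- array(NA_real_, dim(density))
  l_vol <- array(NA_real_, dim(density))
  lin <- graph$voxels[, 1] +
    (graph$voxels[, 2] - 1) * dim(density)[1] +
    (graph$voxels[, 3] - 1) * dim(density)[1] * dim(density)[2]
  t_vol[lin] <- t
  l_vol[lin] <- labels
  structure(
    list(
      t_volume = scalar_volume(t_vol, vol_affine(density)),
      label_volume = scalar_volume(l_vol, vol_affine(density)),
      graph = graph, t = t, labels = labels,
      eigenvalue = eig$value, K = K,
      voxels = tibble(
        i = graph$voxels[, 1], j = graph$voxels[, 2], k = graph$voxels[, 3],
        x = graph$mm[, 1], y = graph$mm[, 2], z = graph$mm[, 3],
        t = t, segment = labels
      )
    ),
    class = "tract_parameterization"
  )
}

#' @export
print.tract_parameterization <- function(x, ...) {
  cat(sprintf(
    "<tract_parameterization> %d voxels, K = %d segments, lambda_2 = %.3g\n",
    length(x$t), x$K, x$eigenvalue
  ))
  invisible(x)
}
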