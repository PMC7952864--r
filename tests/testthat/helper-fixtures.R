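# Small phantoms and graph fixtures shared across test files.

# straight tube along +y on a small grid
straight_spec <- function(grid = c(15L, 25L, 15L), voxel = 2, radius = 3,
                          n_segments = 5L) {
  half_y <- (grid[2] - 1) / 2 * voxel - radius - 1
  phantom_spec(
    grid_shape = grid, voxel_size_mm = voxel,
    curve_control_points = cbind(0, seq(half_y, -half_y, length.out = 4), 0),
    tube_radius_mm = radius, density_falloff = 2,
    n_segments = n_segments
  )
}

straight_tube <- function(...) {
  spec <- straight_spec(...)
  curve <- make_centerline(spec$curve_control_points, 200)
  c(rasterize_tube(curve, spec), list(spec = spec, curve = curve))
}

# voxel_graph for a straight line of n voxels (a path graph under
# 6-connectivity)
line_graph <- function(n) {
  arr <- array(0, dim = c(1L, n, 1L))
  arr[1, , 1] <- 1
  mask <- scalar_volume(arr, ras_affine(c(1L, n, 1L), 1))
  build_voxel_graph(mask, connectivity = 6)
}

# wrap an arbitrary symmetric adjacency matrix as a voxel_graph
adhoc_graph <- function(adj) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(
    methods::as(adj, "CsparseMatrix"),
    mode = "undirected"
  )
  structure(
    list(
      voxels = cbind(seq_len(n), 1L, 1L),
      mm = cbind(0, seq_len(n), 0),
      adjacency = methods::as(adj, "CsparseMatrix"),
      component = as.integer(igraph::components(g)$membership),
      connectivity = NA, dim = c(n, 1L, 1L), affine = diag(4)
    ),
    class = "voxel_graph"
  )
}

# random connected graph adjacency
random_connected_adj <- function(n, p = 0.15) {
  repeat {
    a <- matrix(stats::rbinom(n * n, 1, p), n, n)
    a[lower.tri(a, diag = TRUE)] <- 0
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::is_connected(g)) {
      return(Matrix::Matrix(a, sparse = TRUE))
    }
  }
}

# long HC profile tibble with Gaussian segment values around a profile
gaussian_hc_profiles <- function(n_subj = 32, K = 15, sigma = 0.02,
                                 base = NULL, parameter = "MD",
                                 hemisphere = "L") {
  if (is.null(base)) base <- 0.58 + 0.02 * sin(seq_len(K) / K * pi)
  purrr::map_dfr(seq_len(n_subj), function(s) {
    tibble::tibble(
      subject_id = sprintf("hc%03d", s), group = "HC",
      hemisphere = hemisphere, parameter = parameter,
      segment = seq_len(K),
      median = base + stats::rnorm(K, 0, sigma),
      n_voxels = 40L
    )
  })
}

# brute-force Mann-Whitney enumeration over all group assignments
mw_enumerate <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  w_all <- apply(sets, 2, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  list(
    U = w_obs - n1 * (n1 + 1) / 2,
    p = min(1, 2 * min(p_le, p_ge))
  )
}

# independent permutation enumerator (oracle for exact Spearman p)
perm_matrix <- function(n) {
  if (n == 1L) {
    return(matrix(1L))
  }
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- matrix(0L, nrow(sub), n)
    m[, 1] <- i
    rest <- setdiff(seq_len(n), i)
    m[, -1] <- matrix(rest[sub], nrow(sub))
    m
  }))
}

# classic step-up BH rejection set at level alpha
bh_reject_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
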