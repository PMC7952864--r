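test_that("density thresholding keeps boundary values and rejects bad input", {
  arr <- array(0, c(3, 1, 1))
  arr[, 1, 1] <- c(5, 20, 200)
  vol <- scalar_volume(arr, diag(4))
  mask <- threshold_density(vol, 0.10)
  expect_equal(as.vector(unclass(mask)), c(0, 1, 1))

  uni <- scalar_volume(array(7, c(2, 2, 2)), diag(4))
  expect_equal(sum(unclass(threshold_density(uni))), 8)

  expect_error(threshold_density(vol, 0), "fraction")
  expect_error(threshold_density(vol, 1), "fraction")
  expect_error(
    threshold_density(scalar_volume(array(0, c(2, 2, 2)), diag(4))),
    "Empty tract"
  )
})

test_that("core restriction removes exactly the voxels beyond the mm limits", {
  # straight tube along z from 0 to 80 mm on a 1-voxel-thick column
  arr <- array(1, c(1, 1, 81))
  aff <- diag(4) # voxel k (1-based) sits at z = k - 1 mm
  vol <- scalar_volume(arr, aff)
  kept <- restrict_core(vol, z_min_mm = 40)
  zz <- voxel_grid_mm(vol)[, 3]
  expect_equal(which(unclass(kept) > 0), which(zz >= 40))

  # limits beyond the bounding box: no-op
  same <- restrict_core(vol, y_max_mm = 100, z_min_mm = -100)
  expect_equal(unclass(same)[, , ], unclass(vol)[, , ])

  expect_error(restrict_core(vol, z_min_mm = 1000), "emptied")
})

test_that("core restriction agrees with a brute-force coordinate filter on the phantom", {
  tube <- straight_tube()
  mask <- threshold_density(tube$density)
  y_max <- 10
  z_min <- -4
  got <- restrict_core(mask, y_max_mm = y_max, z_min_mm = z_min)
  xyz <- voxel_grid_mm(mask)
  manual <- which(unclass(mask) > 0 & !(xyz[, 2] > y_max | xyz[, 3] < z_min))
  expect_equal(which(unclass(got) > 0), manual)
})

test_that("voxel graphs have the expected edges and components", {
  g3 <- line_graph(3)
  expect_equal(Matrix::nnzero(g3$adjacency) / 2, 2)
  expect_equal(max(g3$component), 1)

  # 2x2x2 solid block under 26-connectivity: complete graph on 8 nodes
  blk <- scalar_volume(array(1, c(2, 2, 2)), diag(4))
  g8 <- build_voxel_graph(blk, 26)
  expect_equal(Matrix::nnzero(g8$adjacency) / 2, 28)
  expect_true(all(Matrix::diag(g8$adjacency) == 0))
  expect_true(Matrix::isSymmetric(g8$adjacency))

  # two blocks separated by a gap: 2 components
  arr <- array(0, c(7, 2, 2))
  arr[1:2, , ] <- 1
  arr[6:7, , ] <- 1
  g2 <- build_voxel_graph(scalar_volume(arr, diag(4)), 26)
  expect_equal(max(g2$component), 2)

  # 6- vs 18- vs 26-connectivity neighbor counts around a center voxel
  ctr <- scalar_volume(array(1, c(3, 3, 3)), diag(4))
  for (conn in c(6, 18, 26)) {
    g <- build_voxel_graph(ctr, conn)
    ctr_node <- which(g$voxels[, 1] == 2 & g$voxels[, 2] == 2 & g$voxels[, 3] == 2)
    expect_equal(sum(g$adjacency[ctr_node, ]), conn)
  }
})

test_that("Fiedler pair matches closed forms on path graphs", {
  g3 <- line_graph(3)
  ev <- fiedler_vector(g3)
  expect_equal(ev$value, 1, tolerance = 1e-10)
  expect_equal(abs(ev$vector), abs(c(1, 0, -1) / sqrt(2)), tolerance = 1e-8)

  for (n in c(10, 57, 200)) {
    ev <- fiedler_vector(line_graph(n))
    i <- 0:(n - 1)
    ref <- cos(pi * (i + 0.5) / n)
    ref <- ref / sqrt(sum(ref^2))
    dev <- min(max(abs(ev$vector - ref)), max(abs(ev$vector + ref)))
    expect_lt(dev, 1e-6)
    expect_equal(ev$value, 2 - 2 * cos(pi / n), tolerance = 1e-10)
    expect_lt(abs(sum(ev$vector)), 1e-8) # orthogonal to constants
  }
})

test_that("sparse eigensolver path agrees with the dense solver", {
  set.seed(11)
  for (rep in 1:3) {
    adj <- random_connected_adj(40)
    g <- adhoc_graph(adj)
    dense <- fiedler_vector(g, dense_cutoff = 1500)
    sparse <- fiedler_vector(g, dense_cutoff = 0)
    expect_equal(sparse$value, dense$value, tolerance = 1e-7)
    dev <- min(
      max(abs(sparse$vector - dense$vector)),
      max(abs(sparse$vector + dense$vector))
    )
    expect_lt(dev, 1e-5)
    expect_lt(sparse$residual, 1e-7)
  }
})

test_that("disconnected graphs are reduced or rejected", {
  arr <- array(0, c(9, 2, 2))
  arr[1:6, , ] <- 1
  arr[9, , ] <- 1
  g <- build_voxel_graph(scalar_volume(arr, diag(4)), 26)
  expect_error(fiedler_vector(g), "disconnected")
  expect_warning(gr <- reduce_to_largest_component(g), "largest component")
  expect_equal(nrow(gr$voxels), 24)

  arr2 <- array(0, c(8, 2, 2))
  arr2[1:2, , ] <- 1
  arr2[4:5, , ] <- 1
  arr2[7:8, , ] <- 1
  g2 <- build_voxel_graph(scalar_volume(arr2, diag(4)), 26)
  expect_error(reduce_to_largest_component(g2), "connected component holds")
})

test_that("orientation puts t = 0 at the anterior end and is sign-invariant", {
  tube <- straight_tube()
  mask <- threshold_density(tube$density)
  g <- build_voxel_graph(mask)
  ev <- fiedler_vector(g)
  t1 <- orient_and_normalize(ev$vector, g, anchor = "frontal")
  t2 <- orient_and_normalize(-ev$vector, g, anchor = "frontal")
  expect_equal(t1, t2)
  expect_equal(range(t1), c(0, 1))
  # most anterior (max y) voxels carry the smallest t
  expect_lt(cor(t1, g$mm[, 2]), -0.9)
  t3 <- orient_and_normalize(ev$vector, g, anchor = "temporal")
  expect_gt(cor(t3, g$mm[, 2]), 0.9)
  expect_error(orient_and_normalize(rep(1, nrow(g$voxels)), g), "constant")
})

test_that("segment labels bin t into K equal-width intervals", {
  expect_equal(suppressWarnings(segment_labels(c(0, 0.5, 1), 15)), c(1L, 8L, 15L))
  expect_equal(suppressWarnings(segment_labels(1, 15)), 15L)
  expect_error(segment_labels(c(0, 0.5), 1), "at least 2")
  expect_error(segment_labels(c(-0.1, 0.5), 5), "\\[0, 1\\]")
  expect_warning(segment_labels(c(0.1, 0.9), 5), "Empty segment")
  # idempotence: labels depend on t only
  t <- seq(0, 1, length.out = 100)
  expect_equal(segment_labels(t, 15), segment_labels(t, 15))
})

test_that("uniform straight tube yields near-equal segment occupancy by truth t", {
  tube <- straight_tube()
  labs <- truth_segments(tube$truth_t, K = 5)
  counts <- table(unclass(labs))
  # equal within one cross-sectional column of voxels
  xyz <- voxel_grid_mm(tube$density)
  col_size <- max(table(xyz[which(!is.na(unclass(tube$truth_t))), 2]))
  expect_lt(max(counts) - min(counts), col_size + 1)
})

test_that("box ROIs count voxel centers inside closed mm intervals", {
  # 1 mm grid with integer voxel centers
  grid <- c(101L, 101L, 101L)
  aff <- ras_affine(grid, 1)
  roi <- make_box_roi(grid, aff, c(-42, -30), c(-38, -37), c(20, 34))
  expect_equal(sum(unclass(roi)), 13 * 2 * 15)

  # zero extent on all axes: one voxel
  roi1 <- make_box_roi(grid, aff, c(0, 0), c(0, 0), c(0, 0))
  expect_equal(sum(unclass(roi1)), 1)

  # 2 mm grid vs brute-force center-in-box oracle
  grid2 <- c(40L, 40L, 40L)
  aff2 <- ras_affine(grid2, 2)
  roi2 <- make_box_roi(grid2, aff2, c(-42, -30), c(-38, -37), c(20, 34))
  xyz <- voxel_grid_mm(scalar_volume(array(0, grid2), aff2))
  oracle <- sum(
    xyz[, 1] >= -42 & xyz[, 1] <= -30 &
      xyz[, 2] >= -38 & xyz[, 2] <= -37 &
      xyz[, 3] >= 20 & xyz[, 3] <= 34
  )
  expect_equal(sum(unclass(roi2)), oracle)

  expect_warning(
    make_box_roi(grid2, aff2, c(500, 510), c(0, 1), c(0, 1)),
    "outside the grid"
  )
  expect_error(make_box_roi(grid2, aff2, c(2, -2), c(0, 1), c(0, 1)), "ordered")
})

test_that("parameterization is invariant to voxel storage order", {
  # same mask, grid axes permuted: t as a field over space is unchanged
  tube <- straight_tube()
  mask <- threshold_density(tube$density)
  p1 <- parameterize_tract(tube$density, K = 5)
  arr_t <- aperm(unclass(tube$density), c(3, 2, 1))
  attr(arr_t, "affine") <- NULL
  aff <- vol_affine(tube$density)[, c(3, 2, 1, 4)]
  p2 <- parameterize_tract(scalar_volume(arr_t, aff), K = 5)
  t2_back <- aperm(unclass(p2$t_volume), c(3, 2, 1))
  expect_equal(unclass(p1$t_volume)[, , ], t2_back, tolerance = 1e-6)
})
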