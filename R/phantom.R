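#' Specification of a synthetic tract phantom
#'
#' Collects the geometry and generative parameters of the synthetic
#' phantom: a curved tube standing in for a probabilistic-tractography
#' visitation map of the arcuate fasciculus, plus the DTI baselines and
#' between-subject variability used to draw cohorts. Diffusivities (MD,
#' AD, RD) are in units of 1e-3 mm^2/s throughout; FA is dimensionless.
#'
#' The default centerline is a C-shaped arch lying in a sagittal plane
#' (constant x), running anterior (frontal), up and over, then down and
#' posterior-inferior (temporal), mimicking the arcuate arch. The
#' default baselines sit near healthy-control along-tract medians for
#' the arcuate fasciculus (FA 0.43, AD 0.88, MD 0.58, RD 0.44). MD is
#' always derived as (AD + 2 RD) / 3 so generated maps satisfy the
#' tensor identity; the FA baseline is free.
#'
#' @param grid_shape voxels per axis (3 positive integers).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param curve_control_points matrix of mm coordinates (>= 3 rows)
#'   defining the centerline, frontal end first.
#' @param tube_radius_mm tube support radius (mm); density is exactly 0
#'   beyond it.
#' @param density_falloff Gaussian decay scale (mm) of visitation
#'   density away from the centerline.
#' @param dti_baselines named list/vector with FA, MD, AD, RD. MD must
#'   equal (AD + 2 RD) / 3 (it is rederived; a mismatch errors).
#' @param subject_sd named per-parameter between-subject SD of segment
#'   values (MD derived from AD and RD draws).
#' @param lesion_segments integer segment indices (1..K) carrying the
#'   focal lesion in patient volumes.
#' @param lesion_deltas named additive offsets applied inside lesion
#'   segments of patient maps (FA, AD, RD; MD offset follows as
#'   (AD + 2 RD)/3 to preserve the tensor identity).
#' @param n_segments number of along-tract segments K the truth labels
#'   refer to.
#' @param rng_seed integer seed recorded with the spec.
#' @return An object of class `phantom_spec` (a named list).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = 2,
                         curve_control_points = default_af_curve(),
                         tube_radius_mm = 4,
                         density_falloff = 2,
                         dti_baselines = c(FA = 0.43, AD = 0.88, RD = 0.44),
                         subject_sd = c(FA = 0.02, AD = 0.03, RD = 0.025),
                         lesion_segments = integer(),
                         lesion_deltas = c(FA = -0.06, AD = -0.06, RD = 0.18),
                         n_segments = 15L,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    abort("`grid_shape` must be 3 positive integers.")
  }
  if (voxel_size_mm <= 0) abort("`voxel_size_mm` must be positive.")
  if (tube_radius_mm <= 0 || density_falloff <= 0) {
    abort("`tube_radius_mm` and `density_falloff` must be positive.")
  }
  b <- as.list(dti_baselines)
  for (p in c("FA", "AD", "RD")) {
    if (is.null(b[[p]])) abort(sprintf("`dti_baselines` must include %s.", p))
  }
  md <- (b$AD + 2 * b$RD) / 3
  if (!is.null(b$MD) && abs(b$MD - md) > 1e-3) {
    abort("`dti_baselines` MD must equal (AD + 2 RD) / 3.")
  }
  b$MD <- md
  if (!(b$AD >= b$MD && b$MD >= b$RD && b$RD > 0)) {
    abort("Baselines must satisfy AD >= MD >= RD > 0.")
  }
  if (b$FA <= 0 || b$FA >= 1) abort("Baseline FA must lie in (0, 1).")
  lesion_segments <- as.integer(lesion_segments)
  if (any(lesion_segments < 1L | lesion_segments > n_segments)) {
    abort("`lesion_segments` must lie in 1..n_segments.")
  }
  spec <- list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    curve_control_points = as.matrix(curve_control_points),
    tube_radius_mm = tube_radius_mm, density_falloff = density_falloff,
    dti_baselines = b,
    subject_sd = as.list(subject_sd),
    lesion_segments = lesion_segments,
    lesion_deltas = as.list(lesion_deltas),
    n_segments = as.integer(n_segments),
    rng_seed = as.integer(rng_seed)
  )
  structure(spec, class = "phantom_spec")
}

#' Default C-shaped (arcuate-like) centerline control points
#'
#' An arch in the sagittal plane x = -20 mm (left hemisphere of an
#' origin-centered RAS grid): anterior-superior frontal limb, a crest,
#' then a posterior descent toward an inferior temporal end.
#'
#' @return 7 x 3 matrix of mm coordinates.
#' @export
default_af_curve <- function() {
  cbind(
    x = rep(-20, 7),
    y = c(42, 30, 12, -8, -26, -34, -36),
    z = c(-2, 16, 28, 32, 22, 4, -16)
  )
}

#' Rasterize a tube around a centerline into a density volume
#'
#' Each voxel center at distance d <= `tube_radius_mm` from the sampled
#' centerline gets density D0 * exp(-d^2 / (2 s^2)) with s =
#' `density_falloff`; voxels beyond the radius are exactly zero. Every
#' in-tube voxel also receives the arc-length fraction t of its nearest
#' centerline sample, returned as a ground-truth parameter volume
#' (NA outside the tube).
#'
#' @param curve centerline tibble from [make_centerline()].
#' @param spec a [phantom_spec()].
#' @param d0 peak density on the centerline.
#' @return list with `density` and `truth_t` (both `scalar_volume`s) and
#'   the `affine` used.
#' @export
rasterize_tube <- function(curve, spec, d0 = 100) {
  aff <- ras_affine(spec$grid_shape, spec$voxel_size_mm)
  half <- (spec$grid_shape - 1) / 2 * spec$voxel_size_mm
  lo <- apply(curve[, c("x", "y", "z")], 2, min) - spec$tube_radius_mm
  hi <- apply(curve[, c("x", "y", "z")], 2, max) + spec$tube_radius_mm
  if (any(lo < -half - spec$voxel_size_mm / 2) ||
    any(hi > half + spec$voxel_size_mm / 2)) {
    abort(sprintf(
      "Tube extent [%s] x [%s] exceeds grid bounds +/-(%s) mm.",
      paste(round(lo, 1), collapse = ", "),
      paste(round(hi, 1), collapse = ", "),
      paste(round(half, 1), collapse = ", ")
    ))
  }
  dens <- array(0, dim = spec$grid_shape)
  tt <- array(NA_real_, dim = spec$grid_shape)
  xyz <- voxel_grid_mm(scalar_volume(dens, aff))
  # candidate voxels: inside the inflated bounding box of the curve
  cand <- which(
    xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
      xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
      xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  )
  pts <- as.matrix(curve[, c("x", "y", "z")])
  cx <- xyz[cand, , drop = FALSE]
  best_d2 <- rep(Inf, length(cand))
  best_i <- rep(1L, length(cand))
  for (i in seq_len(nrow(pts))) {
    d2 <- (cx[, 1] - pts[i, 1])^2 + (cx[, 2] - pts[i, 2])^2 +
      (cx[, 3] - pts[i, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  inside <- best_d2 <= spec$tube_radius_mm^2
  dens[cand[inside]] <- d0 * exp(-best_d2[inside] / (2 * spec$density_falloff^2))
  tt[cand[inside]] <- curve$t[best_i[inside]]
  list(
    density = scalar_volume(dens, aff),
    truth_t = scalar_volume(tt, aff),
    affine = aff
  )
}

#' Ground-truth segment labels from a truth-t volume
#'
#' @param truth_t `scalar_volume` of arc-length fractions (NA outside).
#' @param K number of segments.
#' @return `scalar_volume` of integer labels 1..K (NA outside).
#' @export
truth_segments <- function(truth_t, K = 15L) {
  lab <- array(NA_real_, dim(truth_t))
  idx <- which(!is.na(unclass(truth_t)))
  lab[idx] <- pmin(floor(unclass(truth_t)[idx] * K) + 1, K)
  scalar_volume(lab, vol_affine(truth_t))
}
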