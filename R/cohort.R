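#' Gaussian smoothing of a 3-D array (FFT, circular boundary)
#'
#' Used to give the synthetic noise fields a controllable spatial
#' autocorrelation; circular wrap-around is irrelevant for noise
#' generation.
#'
#' @param arr 3-D array.
#' @param sigma_vox Gaussian SD in voxels (scalar).
#' @return smoothed array, same dim.
#' @keywords internal
smooth_gaussian3d <- function(arr, sigma_vox = 2) {
  d <- dim(arr)
  k <- lapply(d, function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-x^2 / (2 * sigma_vox^2))
    g / sum(g)
  })
  K <- outer(outer(k[[1]], k[[2]]), k[[3]])
  dim(K) <- d
  Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
}

# one spatially smooth field with unit per-voxel SD
smooth_unit_field <- function(d, sigma_vox = 2) {
  f <- smooth_gaussian3d(array(rnorm(prod(d)), dim = d), sigma_vox)
  f / sd(f)
}

clamp_map <- function(arr, lo, hi, what) {
  n_bad <- sum(arr < lo | arr > hi, na.rm = TRUE)
  if (n_bad > 0) {
    warn(sprintf("%d %s voxels clamped to [%g, %g].", n_bad, what, lo, hi))
    arr <- pmin(pmax(arr, lo), hi)
  }
  arr
}

#' Patient design table for a synthetic cohort
#'
#' Two strata mirroring a low-grade / high-grade tumor contrast:
#' "LG"-like patients carry a short focal lesion (few segments, small
#' DTI offsets), "HG"-like patients a long severe one. Offsets scale
#' the phantom's `lesion_deltas`.
#'
#' @param n_lg,n_hg number of patients per stratum.
#' @param lg_segments,hg_segments lesioned segment indices per stratum.
#' @param lg_scale,hg_scale multipliers on `lesion_deltas`.
#' @return tibble with columns subject_id, group, hemisphere,
#'   lesion_segments (list), delta_scale.
#' @export
patient_design <- function(n_lg = 4, n_hg = 5,
                           lg_segments = c(7L, 8L), hg_segments = 5:13,
                           lg_scale = 0.35, hg_scale = 1) {
  tibble(
    subject_id = sprintf(
      "pat%02d", seq_len(n_lg + n_hg)
    ),
    group = rep(c("LG", "HG"), c(n_lg, n_hg)),
    hemisphere = "L",
    lesion_segments = c(
      rep(list(as.integer(lg_segments)), n_lg),
      rep(list(as.integer(hg_segments)), n_hg)
    ),
    delta_scale = rep(c(lg_scale, hg_scale), c(n_lg, n_hg))
  )
}

#' Generate a synthetic DTI cohort on a phantom tract
#'
#' Draws healthy-control and patient parameter maps (FA, MD, AD, RD) on
#' the phantom grid. Each subject map is baseline + a subject-level
#' offset + a smooth spatial noise field; the offset carries 80% and the
#' field 60% of the per-parameter SD so the per-voxel SD across
#' subjects equals `spec$subject_sd`. FA, AD and RD are drawn; MD is
#' derived as (AD + 2 RD)/3 so the tensor identity holds exactly.
#' Patients additionally receive `spec$lesion_deltas * delta_scale`
#' added to all voxels whose ground-truth segment is lesioned (the MD
#' lesion offset follows from AD and RD).
#'
#' @param spec a [phantom_spec()].
#' @param n_hc number of healthy controls (>= 2).
#' @param patients patient design tibble from [patient_design()], or
#'   NULL for a control-only cohort.
#' @param rng_seed integer seed (defaults to `spec$rng_seed`).
#' @param write_dir optional directory; when given, maps are written as
#'   NIfTI (.nii.gz) and the truth table as cohort_truth.tsv.
#' @return list with:
#'   * `subjects`: tibble (subject_id, group, hemisphere, maps) where
#'     `maps` is a list-column of named `scalar_volume` lists;
#'   * `truth`: tibble (subject_id, group, hemisphere, parameter,
#'     abnormal_segments, seed) — empty segment sets for controls;
#'   * `density`, `truth_t`, `truth_labels`: phantom volumes.
#' @export
make_dti_cohort <- function(spec, n_hc = 32L, patients = patient_design(),
                            rng_seed = spec$rng_seed, write_dir = NULL) {
  if (n_hc < 2L) abort("`n_hc` must be at least 2.")
  set.seed(rng_seed)
  curve <- make_centerline(spec$curve_control_points, n_samples = 400L)
  tube <- rasterize_tube(curve, spec)
  labels <- truth_segments(tube$truth_t, spec$n_segments)
  d <- spec$grid_shape
  b <- spec$dti_baselines
  s <- spec$subject_sd

  draw_subject <- function(lesion_segments = integer(), delta_scale = 0) {
    maps <- list()
    for (p in c("FA", "AD", "RD")) {
      off <- rnorm(1, 0, 0.8 * s[[p]])
      field <- smooth_unit_field(d) * 0.6 * s[[p]]
      maps[[p]] <- b[[p]] + off + field
    }
    if (length(lesion_segments) > 0 && delta_scale != 0) {
      les <- !is.na(unclass(labels)) & unclass(labels) %in% lesion_segments
      for (p in c("FA", "AD", "RD")) {
        dl <- spec$lesion_deltas[[p]]
        if (!is.null(dl) && dl != 0) maps[[p]][les] <- maps[[p]][les] + dl * delta_scale
      }
    }
    maps$MD <- (maps$AD + 2 * maps$RD) / 3
    maps$FA <- clamp_map(maps$FA, 1e-3, 1 - 1e-3, "FA")
    for (p in c("MD", "AD", "RD")) {
      maps[[p]] <- clamp_map(maps[[p]], 1e-6, Inf, p)
    }
    lapply(maps, scalar_volume, affine = tube$affine)
  }

  ids_hc <- sprintf("hc%03d", seq_len(n_hc))
  rows <- vector("list", n_hc + if (is.null(patients)) 0L else nrow(patients))
  for (i in seq_len(n_hc)) {
    rows[[i]] <- tibble(
      subject_id = ids_hc[i], group = "HC", hemisphere = "L",
      lesion_segments = list(integer()),
      maps = list(draw_subject())
    )
  }
  if (!is.null(patients)) {
    for (j in seq_len(nrow(patients))) {
      rows[[n_hc + j]] <- tibble(
        subject_id = patients$subject_id[j],
        group = patients$group[j],
        hemisphere = patients$hemisphere[j],
        lesion_segments = patients$lesion_segments[j],
        maps = list(draw_subject(
          patients$lesion_segments[[j]], patients$delta_scale[j]
        ))
      )
    }
  }
  subjects <- dplyr::bind_rows(rows)
  truth <- subjects |>
    dplyr::select("subject_id", "group", "hemisphere", "lesion_segments") |>
    tidyr::crossing(parameter = c("FA", "MD", "AD", "RD")) |>
    dplyr::mutate(
      abnormal_segments = purrr::map_chr(
        .data$lesion_segments,
        function(sg) paste(sg, collapse = ",")
      ),
      seed = rng_seed
    ) |>
    dplyr::select(
      "subject_id", "group", "hemisphere", "parameter",
      "abnormal_segments", "seed"
    )
  out <- list(
    subjects = dplyr::select(subjects, -"lesion_segments"),
    truth = truth,
    density = tube$density, truth_t = tube$truth_t, truth_labels = labels
  )
  if (!is.null(write_dir)) write_cohort(out, write_dir)
  out
}

#' Write a synthetic cohort to disk (NIfTI + TSV truth table)
#' @param cohort result of [make_dti_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(cohort$density, file.path(dir, "density.nii.gz"))
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    maps <- cohort$subjects$maps[[i]]
    for (p in names(maps)) {
      write_volume(maps[[p]], file.path(dir, sprintf("%s_%s.nii.gz", id, p)))
    }
  }
  readr::write_tsv(cohort$truth, file.path(dir, "cohort_truth.tsv"))
  invisible(dir)
}

#' Generate a lateralized activation Z-map
#'
#' Places suprathreshold voxels inside disjoint left/right ROI masks so
#' the realized laterality index (L - R)/(L + R) matches `target_li` up
#' to integer rounding; every other voxel stays strictly below
#' `z_active`.
#'
#' @param mask_left,mask_right binary `scalar_volume` masks on the same
#'   grid, disjoint.
#' @param target_li desired laterality index in \[-1, 1\].
#' @param z_active activation threshold (suprathreshold means z >
#'   `z_active`).
#' @param n_active total suprathreshold voxel budget (capped by mask
#'   capacity).
#' @param rng_seed integer seed.
#' @return list with `zmap` (`scalar_volume`), `n_left`, `n_right`,
#'   `realized_li`.
#' @export
make_zmap <- function(mask_left, mask_right, target_li, z_active = 3.1,
                      n_active = 400L, rng_seed = 1L) {
  if (target_li < -1 || target_li > 1) abort("`target_li` must lie in [-1, 1].")
  if (!same_grid(mask_left, mask_right)) abort("Masks must share a grid.")
  il <- which(unclass(mask_left) > 0)
  ir <- which(unclass(mask_right) > 0)
  if (length(intersect(il, ir)) > 0) abort("Left/right masks must be disjoint.")
  t_cap <- floor(min(
    if (target_li > -1) 2 * length(il) / (1 + target_li) else Inf,
    if (target_li < 1) 2 * length(ir) / (1 - target_li) else Inf
  ))
  if (!is.finite(t_cap) || t_cap < 1 || 1 / t_cap > 0.05) {
    abort(sprintf(
      "Masks too small to realize target LI %.2f within +/-0.05 (capacity %d).",
      target_li, max(t_cap, 0)
    ))
  }
  total <- min(t_cap, as.integer(n_active))
  n_left <- round(total * (1 + target_li) / 2)
  n_right <- total - n_left
  set.seed(rng_seed)
  z <- array(pmin(rnorm(prod(dim(mask_left))), z_active - 0.01),
    dim = dim(mask_left)
  )
  act_l <- sample(il, n_left)
  act_r <- sample(ir, n_right)
  z[act_l] <- z_active + 0.1 + abs(rnorm(n_left, 0, 1.5))
  z[act_r] <- z_active + 0.1 + abs(rnorm(n_right, 0, 1.5))
  list(
    zmap = scalar_volume(z, vol_affine(mask_left)),
    n_left = n_left, n_right = n_right,
    realized_li = (n_left - n_right) / total
  )
}
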