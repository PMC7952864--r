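#' Per-segment medians of a scalar map along a tract
#'
#' For each along-tract segment, the median of the map over the
#' segment's voxels, ignoring non-finite voxels (registration padding
#' produces NaN borders in real data). An even voxel count yields the
#' mean of the two central values.
#'
#' @param map `scalar_volume` of a DTI parameter.
#' @param labels `scalar_volume` of integer segment labels (NA outside
#'   the tract), or an integer vector paired with `voxel_index`.
#' @param K number of segments.
#' @param subject_id,hemisphere,parameter metadata carried into the
#'   output.
#' @return tibble (subject_id, hemisphere, parameter, segment, median,
#'   n_voxels), one row per segment 1..K; empty segments yield NA with
#'   a warning.
#' @export
segment_medians <- function(map, labels, K = 15L,
                            subject_id = NA_character_,
                            hemisphere = NA_character_,
                            parameter = NA_character_) {
  if (inherits(labels, "scalar_volume")) {
    if (!same_grid(map, labels)) abort("`map` and `labels` are on different grids.")
    lab <- unclass(labels)
    idx <- which(!is.na(lab))
    lab <- as.integer(lab[idx])
    vals <- unclass(map)[idx]
  } else {
    abort("`labels` must be a scalar_volume of segment labels.")
  }
  out <- tibble(
    subject_id = subject_id, hemisphere = hemisphere, parameter = parameter,
    segment = seq_len(K),
    median = NA_real_, n_voxels = 0L
  )
  for (k in seq_len(K)) {
    v <- vals[lab == k]
    v <- v[is.finite(v)]
    out$n_voxels[k] <- length(v)
    if (length(v) > 0) out$median[k] <- median(v)
  }
  if (any(out$n_voxels == 0L)) {
    warn(sprintf(
      "Empty segment(s) %s: median set to NA.",
      paste(out$segment[out$n_voxels == 0L], collapse = ", ")
    ))
  }
  out
}

#' Along-tract profiles for a whole cohort
#'
#' @param cohort result of [make_dti_cohort()] (or any tibble with
#'   subject_id, group, hemisphere and a `maps` list-column of named
#'   `scalar_volume`s).
#' @param labels segment-label `scalar_volume`.
#' @param K number of segments.
#' @param parameters which maps to profile.
#' @return long tibble (subject_id, group, hemisphere, parameter,
#'   segment, median, n_voxels).
#' @export
cohort_profiles <- function(cohort, labels, K = 15L,
                            parameters = c("FA", "MD", "AD", "RD")) {
  subjects <- if (is.data.frame(cohort)) cohort else cohort$subjects
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    purrr::map_dfr(parameters, function(p) {
      segment_medians(
        subjects$maps[[i]][[p]], labels,
        K = K,
        subject_id = subjects$subject_id[i],
        hemisphere = subjects$hemisphere[i],
        parameter = p
      )
    }) |>
      dplyr::mutate(group = subjects$group[i], .after = "subject_id")
  })
}

#' Subjects-by-segments profile matrix for one parameter/hemisphere
#'
#' @param profiles long profile tibble (as from [cohort_profiles()] or
#'   [segment_medians()] rows bound together).
#' @return wide tibble: one row per subject (sorted by id), columns
#'   `subject_id` then `seg_1` .. `seg_K`; missing segments are NA.
#'   Errors if subjects disagree on K.
#' @export
profile_matrix <- function(profiles) {
  ks <- profiles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(K = max(.data$segment), n = dplyr::n())
  if (length(unique(ks$K)) > 1L || length(unique(ks$n)) > 1L) {
    abort("Subjects have inconsistent segment counts.")
  }
  if (length(unique(profiles$parameter)) > 1L ||
    length(unique(profiles$hemisphere)) > 1L) {
    abort("`profile_matrix()` expects a single parameter and hemisphere.")
  }
  profiles |>
    dplyr::arrange(.data$subject_id, .data$segment) |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      segment = sprintf("seg_%d", .data$segment),
      median = .data$median
    ) |>
    tidyr::pivot_wider(names_from = "segment", values_from = "median")
}
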