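#' De-median a healthy-control profile set
#'
#' Subtracts the per-segment healthy-control median m_k from every
#' subject's segment value, so all segments of one parameter share a
#' common, zero-centered distribution that can be pooled.
#'
#' @param profiles long tibble for ONE parameter and hemisphere:
#'   columns subject_id, segment, median.
#' @return list with `demedianed` (input plus column `dm`) and
#'   `segment_medians` tibble (segment, m).
#' @export
demedian <- function(profiles) {
  per_seg <- profiles |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      m = median(.data$median, na.rm = TRUE),
      n_ok = sum(!is.na(.data$median)),
      n = dplyr::n()
    )
  if (any(per_seg$n_ok < 2)) {
    abort("Each segment needs at least 2 healthy-control values.")
  }
  if (any(per_seg$n_ok < per_seg$n / 2)) {
    abort("A segment is missing in more than half of the controls.")
  }
  dm <- profiles |>
    dplyr::left_join(per_seg[, c("segment", "m")], by = "segment") |>
    dplyr::mutate(dm = .data$median - .data$m)
  list(demedianed = dm, segment_medians = per_seg[, c("segment", "m")])
}

#' Remove outliers beyond a multiple of the mean absolute deviation
#'
#' The deviation scale is the literal mean absolute deviation about the
#' median: MAD = mean(|v - median(v)|). Values with
#' |v - median(v)| > factor * MAD are removed. `robust = TRUE` switches
#' to the conventional median absolute deviation instead.
#'
#' @param values numeric vector (>= 10 values).
#' @param factor removal threshold multiplier (default 3).
#' @param robust use median- instead of mean-absolute deviation.
#' @return list: `kept`, `removed`, `n_removed`, `mad`, `center`.
#' @export
remove_outliers <- function(values, factor = 3, robust = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) abort("Need at least 10 values for outlier removal.")
  ctr <- median(values)
  dev <- abs(values - ctr)
  mad <- if (robust) median(dev) else mean(dev)
  if (mad == 0) {
    warn("Zero absolute deviation (constant values): nothing removed.")
    return(list(
      kept = values, removed = numeric(0), n_removed = 0L,
      mad = 0, center = ctr
    ))
  }
  out <- dev > factor * mad
  list(
    kept = values[!out], removed = values[out], n_removed = sum(out),
    mad = mad, center = ctr
  )
}

#' Build normative along-tract ranges from healthy-control profiles
#'
#' For each parameter and hemisphere: de-median the control profile
#' matrix, pool the de-medianed values of all segments into one
#' distribution, remove outliers beyond `factor` times the mean
#' absolute deviation, and estimate the 2.5th-97.5th percentile
#' interval from the standard deviation of the kept values as
#' m_k +/- 1.959964 sigma. Intervals are symmetric about the
#' segment medians m_k.
#'
#' @param hc_profiles long tibble of control profiles: subject_id,
#'   hemisphere, parameter, segment, median.
#' @param factor outlier threshold multiplier (default 3).
#' @param robust use median-based absolute deviation (default FALSE).
#' @return An object of class `normative_model`: list with `intervals`
#'   (parameter, hemisphere, segment, m, lo, hi) and `scale`
#'   (parameter, hemisphere, sigma, halfwidth, n_outliers_removed,
#'   n_values_total).
#' @export
build_normative <- function(hc_profiles, factor = 3, robust = FALSE) {
  z975 <- qnorm(0.975)
  groups <- hc_profiles |>
    dplyr::distinct(.data$parameter, .data$hemisphere)
  intervals <- list()
  scale <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- hc_profiles |>
      dplyr::filter(
        .data$parameter == groups$parameter[i],
        .data$hemisphere == groups$hemisphere[i]
      )
    dd <- demedian(sub)
    pooled <- dd$demedianed$dm[is.finite(dd$demedianed$dm)]
    ro <- remove_outliers(pooled, factor = factor, robust = robust)
    if (length(ro$kept) < 10L) abort("Fewer than 10 values kept after outlier removal.")
    sigma <- sd(ro$kept)
    h <- z975 * sigma
    intervals[[i]] <- dd$segment_medians |>
      dplyr::transmute(
        parameter = groups$parameter[i],
        hemisphere = groups$hemisphere[i],
        segment = .data$segment,
        m = .data$m, lo = .data$m - h, hi = .data$m + h
      )
    scale[[i]] <- tibble(
      parameter = groups$parameter[i],
      hemisphere = groups$hemisphere[i],
      sigma = sigma, halfwidth = h,
      n_outliers_removed = ro$n_removed,
      n_values_total = length(pooled)
    )
  }
  structure(
    list(
      intervals = dplyr::bind_rows(intervals),
      scale = dplyr::bind_rows(scale),
      factor = factor, robust = robust
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model> %d parameter/hemisphere range set(s), K = %d segments\n",
    nrow(x$scale), max(x$intervals$segment)
  ))
  print(x$scale)
  invisible(x)
}

#' @rdname build_normative
#' @param x a `normative_model`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.normative_model <- function(x, ...) x$intervals

#' @rdname build_normative
#' @exportS3Method generics::glance
glance.normative_model <- function(x, ...) x$scale

#' Classify patient segments against a normative model
#'
#' A segment median strictly below the interval is "low", strictly
#' above is "high", otherwise "normal" (boundary values are normal);
#' missing segments stay unclassified (NA). No outlier removal is
#' applied to patients: out-of-range values are the signal.
#'
#' @param profiles long patient profile tibble (subject_id, hemisphere,
#'   parameter, segment, median; extra columns pass through).
#' @param model a `normative_model` covering the same
#'   parameter/hemisphere/segment combinations.
#' @return the input with columns `lo`, `hi` and `flag`
#'   ("low"/"normal"/"high"/NA).
#' @export
classify_segments <- function(profiles, model) {
  joined <- profiles |>
    dplyr::left_join(
      model$intervals,
      by = c("parameter", "hemisphere", "segment")
    )
  if (any(is.na(joined$lo) & !is.na(joined$median))) {
    abort("Model does not cover some parameter/hemisphere/segment combinations.")
  }
  joined |>
    dplyr::mutate(
      flag = dplyr::case_when(
        is.na(.data$median) ~ NA_character_,
        .data$median < .data$lo ~ "low",
        .data$median > .data$hi ~ "high",
        TRUE ~ "normal"
      )
    ) |>
    dplyr::select(-"m")
}

abnormal_direction <- c(FA = "low", AD = "low", MD = "high", RD = "high")

#' Per-subject summary metrics from classified profiles
#'
#' Counts abnormal segments per DTI parameter in the pathological
#' direction (decreased FA and AD, increased MD and RD), the two-sided
#' abnormal count, and the median of each parameter across segments.
#'
#' @param flagged output of [classify_segments()].
#' @return tibble: subject_id, group (if present), hemisphere,
#'   parameter, n_abnormal (directional), n_abnormal_two_sided,
#'   median_across_segments.
#' @export
summarize_subjects <- function(flagged) {
  grp_cols <- intersect(
    c("subject_id", "group", "hemisphere", "parameter"),
    names(flagged)
  )
  flagged |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      n_abnormal = sum(
        .data$flag == abnormal_direction[[.data$parameter[1]]],
        na.rm = TRUE
      ),
      n_abnormal_two_sided = sum(.data$flag %in% c("low", "high")),
      median_across_segments = median(.data$median, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Wide per-subject measure table for group statistics
#'
#' Spreads [summarize_subjects()] output into one row per subject with
#' the along-tract measures used in group comparisons:
#' `FA_dec_segments`, `AD_dec_segments`, `MD_inc_segments`,
#' `RD_inc_segments` (directional abnormal-segment counts) and
#' `median_FA` .. `median_RD`.
#'
#' @param subject_summary output of [summarize_subjects()].
#' @return wide tibble keyed by subject_id (group kept if present).
#' @export
subject_metrics <- function(subject_summary) {
  dir_lab <- c(FA = "FA_dec_segments", AD = "AD_dec_segments",
               MD = "MD_inc_segments", RD = "RD_inc_segments")
  id_cols <- intersect(c("subject_id", "group", "hemisphere"), names(subject_summary))
  counts <- subject_summary |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(id_cols)),
      measure = dir_lab[.data$parameter],
      value = as.numeric(.data$n_abnormal)
    )
  meds <- subject_summary |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(id_cols)),
      measure = paste0("median_", .data$parameter),
      value = .data$median_across_segments
    )
  dplyr::bind_rows(counts, meds) |>
    tidyr::pivot_wider(names_from = "measure", values_from = "value") |>
    dplyr::arrange(.data$subject_id)
}
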