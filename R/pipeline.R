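#' Configuration for a full synthetic along-tract run
#'
#' One source of truth for every tunable of the pipeline: the phantom,
#' the segmentation constants (density threshold fraction, K, voxel
#' connectivity, core limits), the activation threshold, the FDR level
#' and the seed.
#'
#' @param spec a [phantom_spec()].
#' @param n_hc number of healthy controls.
#' @param patients patient design tibble ([patient_design()]).
#' @param fraction density threshold fraction.
#' @param K segments along the tract.
#' @param connectivity voxel neighborhood (6/18/26).
#' @param y_max_mm,z_min_mm core-restriction limits (Inf/-Inf disable;
#'   disabled by default since the phantom tube has no cortical
#'   branching to trim).
#' @param z_thresh fMRI activation threshold.
#' @param fdr FDR level for significance flags.
#' @param seed master RNG seed for the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = phantom_spec(),
                       n_hc = 16L,
                       patients = patient_design(),
                       fraction = 0.10, K = 15L, connectivity = 26,
                       y_max_mm = Inf, z_min_mm = -Inf,
                       z_thresh = 3.1, fdr = 0.1, seed = 1L) {
  structure(
    list(
      spec = spec, n_hc = as.integer(n_hc), patients = patients,
      fraction = fraction, K = as.integer(K), connectivity = connectivity,
      y_max_mm = y_max_mm, z_min_mm = z_min_mm,
      z_thresh = z_thresh, fdr = fdr, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

config_hash <- function(config) {
  flat <- list(
    spec = config$spec[setdiff(names(config$spec), "curve_control_points")],
    curve = as.numeric(config$spec$curve_control_points),
    n_hc = config$n_hc,
    patients = lapply(
      seq_len(nrow(config$patients)),
      function(i) as.list(config$patients[i, setdiff(names(config$patients), "lesion_segments")])
    ),
    lesions = config$patients$lesion_segments,
    tunables = config[c(
      "fraction", "K", "connectivity", "y_max_mm", "z_min_mm",
      "z_thresh", "fdr", "seed"
    )]
  )
  rlang::hash(flat)
}

default_lobar_rois <- function(grid_shape, affine) {
  # mirror-symmetric lobar boxes placed as fractions of the grid
  # half-extent, so they fit any origin-centered grid
  half <- (grid_shape - 1) / 2 * sqrt(colSums(affine[1:3, 1:3]^2))
  box_pair <- function(lobe, x_abs, y, z) {
    tibble(
      lobe = lobe,
      left = list(make_box_roi(grid_shape, affine, -rev(x_abs), y, z)),
      right = list(make_box_roi(grid_shape, affine, x_abs, y, z))
    )
  }
  dplyr::bind_rows(
    box_pair(
      "frontal", c(0.35, 0.85) * half[1],
      c(0.25, 0.8) * half[2], c(-0.1, 0.45) * half[3]
    ),
    box_pair(
      "parietal", c(0.35, 0.85) * half[1],
      c(-0.85, -0.4) * half[2], c(0.3, 0.8) * half[3]
    ),
    box_pair(
      "temporal", c(0.4, 0.9) * half[1],
      c(-0.6, -0.1) * half[2], c(-0.5, 0) * half[3]
    )
  )
}

#' Run the full synthetic along-tract pipeline
#'
#' simulate -> parameterize -> profile -> normative -> classify ->
#' laterality -> group comparison and LI correlation. All stage outputs
#' are written under `out_dir` as NIfTI/TSV plus a JSON manifest
#' recording the configuration hash, seed, package and R versions and
#' stage wall-times. Re-running with the same config reproduces
#' identical tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return list of class `aftract_run`: config, parameterization,
#'   profiles, model, flagged, metrics, laterality, comparison,
#'   correlations, manifest, out_dir.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("aftract_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- clock("simulate", make_dti_cohort(
    config$spec,
    n_hc = config$n_hc, patients = config$patients,
    rng_seed = config$seed
  ))
  write_volume(cohort$density, file.path(out_dir, "density.nii.gz"))

  param <- clock("parameterize", parameterize_tract(
    cohort$density,
    fraction = config$fraction,
    y_max_mm = config$y_max_mm, z_min_mm = config$z_min_mm,
    connectivity = config$connectivity, K = config$K
  ))
  write_volume(param$t_volume, file.path(out_dir, "tract_t.nii.gz"))
  lab <- param$label_volume
  lab_out <- unclass(lab)
  attr(lab_out, "affine") <- NULL
  lab_out[is.na(lab_out)] <- 0
  write_volume(scalar_volume(lab_out, vol_affine(lab)),
    file.path(out_dir, "tract_segments.nii.gz"),
    datatype = "uint8"
  )

  profiles <- clock("profile", cohort_profiles(cohort, param$label_volume, K = config$K))
  readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"))

  model <- clock("normative", build_normative(
    dplyr::filter(profiles, .data$group == "HC")
  ))
  readr::write_tsv(tidy(model), file.path(out_dir, "normative_intervals.tsv"))
  readr::write_tsv(glance(model), file.path(out_dir, "normative_scale.tsv"))

  flagged <- clock("classify", classify_segments(
    dplyr::filter(profiles, .data$group != "HC"), model
  ))
  readr::write_tsv(flagged, file.path(out_dir, "patient_flags.tsv"))
  metrics <- subject_metrics(summarize_subjects(flagged))
  readr::write_tsv(metrics, file.path(out_dir, "subject_metrics.tsv"))

  li <- clock("laterality", pipeline_laterality(config, cohort))
  readr::write_tsv(li, file.path(out_dir, "laterality.tsv"))

  stats_out <- clock("stats", {
    li_wide <- li |>
      dplyr::mutate(measure = paste0("LI_", .data$lobe)) |>
      tidyr::pivot_wider(
        id_cols = "subject_id", names_from = "measure", values_from = "li"
      )
    met <- dplyr::left_join(metrics, li_wide, by = "subject_id")
    dti_measures <- c(
      "FA_dec_segments", "median_FA", "AD_dec_segments", "median_AD",
      "MD_inc_segments", "median_MD", "RD_inc_segments", "median_RD"
    )
    comparison <- group_compare(
      met, c(dti_measures, "LI_frontal", "LI_parietal", "LI_temporal"),
      groups = c("LG", "HG"), fdr = config$fdr
    )
    disc <- comparison$measure[comparison$significant &
      comparison$measure %in% dti_measures]
    correlations <- if (length(disc) >= 1) {
      correlate_with_li(met, li, disc, fdr = config$fdr)
    } else {
      correlate_with_li(met, li, dti_measures[c(5, 7)], fdr = config$fdr)
    }
    list(metrics = met, comparison = comparison, correlations = correlations)
  })
  readr::write_tsv(stats_out$comparison, file.path(out_dir, "group_comparison.tsv"))
  readr::write_tsv(stats_out$correlations, file.path(out_dir, "li_correlations.tsv"))

  manifest <- list(
    package = "aftract",
    version = as.character(utils::packageVersion("aftract")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = config_hash(config),
    stage_seconds = timings,
    n_hc = config$n_hc,
    n_patients = nrow(config$patients),
    K = config$K
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  structure(
    list(
      config = config, cohort_truth = cohort$truth, param = param,
      profiles = profiles, model = model, flagged = flagged,
      metrics = stats_out$metrics, laterality = li,
      comparison = stats_out$comparison,
      correlations = stats_out$correlations,
      manifest = manifest, out_dir = out_dir
    ),
    class = "aftract_run"
  )
}

# synthetic activation maps per patient: lobar LIs tied to lesion
# burden in the parietal lobe (rightward shift with longer lesions)
pipeline_laterality <- function(config, cohort) {
  aff <- vol_affine(cohort$density)
  rois <- default_lobar_rois(config$spec$grid_shape, aff)
  pats <- config$patients
  purrr::map_dfr(seq_len(nrow(pats)), function(i) {
    n_les <- length(pats$lesion_segments[[i]])
    sub_seed <- config$seed * 1000L + i
    set.seed(sub_seed)
    target <- c(
      frontal = 0.25 + runif(1, -0.15, 0.15),
      parietal = max(-0.9, min(0.9, 0.5 - 0.09 * n_les + runif(1, -0.05, 0.05))),
      temporal = 0.3 + runif(1, -0.15, 0.15)
    )
    purrr::map_dfr(seq_len(nrow(rois)), function(r) {
      zm <- make_zmap(
        rois$left[[r]], rois$right[[r]],
        target_li = target[[rois$lobe[r]]],
        z_active = config$z_thresh,
        rng_seed = sub_seed + r
      )
      lobar_laterality(
        zm$zmap, rois[r, ],
        z_thresh = config$z_thresh
      ) |>
        dplyr::mutate(subject_id = pats$subject_id[i], .before = 1)
    })
  })
}

#' @export
print.aftract_run <- function(x, ...) {
  cat(sprintf(
    "<aftract_run> %d controls + %d patients, K = %d; outputs in %s\n",
    x$config$n_hc, nrow(x$config$patients), x$config$K, x$out_dir
  ))
  invisible(x)
}

#' Render report figures and tables for a completed run
#'
#' Writes one along-tract profile figure per parameter/hemisphere
#' (normative band, control median, patient curves) and a formatted
#' comparison table.
#'
#' @param run an `aftract_run` from [run_pipeline()].
#' @param dir output directory (defaults to the run directory).
#' @param device figure file extension (default "png").
#' @return invisible list of ggplot objects, named
#'   `<parameter>_<hemisphere>`.
#' @export
make_report <- function(run, dir = run$out_dir, device = "png") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  combos <- run$model$scale[, c("parameter", "hemisphere")]
  plots <- list()
  for (i in seq_len(nrow(combos))) {
    p <- plot_profile(
      run$profiles, run$model,
      parameter = combos$parameter[i], hemisphere = combos$hemisphere[i]
    )
    nm <- sprintf("%s_%s", combos$parameter[i], combos$hemisphere[i])
    ggplot2::ggsave(
      file.path(dir, sprintf("profile_%s.%s", nm, device)),
      p,
      width = 7, height = 4, dpi = 120
    )
    plots[[nm]] <- p
  }
  readr::write_tsv(run$comparison, file.path(dir, "report_comparison.tsv"))
  invisible(plots)
}
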