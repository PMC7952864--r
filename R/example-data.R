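#' Example glioma cohort: tumor volumes by grade group
#'
#' A small reference cohort of nine patients with tumors in or near
#' language areas, stratified into low-grade (LG: one dysembryoplastic
#' neuroepithelial tumor plus three grade-II gliomas) and high-grade
#' (HG: two grade-III and three grade-IV gliomas) groups, with the
#' manually segmented tumor volume in cm^3. Used in examples and in
#' the reproducibility checks of the group-comparison statistics.
#'
#' @return tibble: subject_id, group ("LG"/"HG"), volume_cm3.
#' @export
example_glioma_volumes <- function() {
  tibble(
    subject_id = c(
      "T_L_I", "F_L_II", "I_L_II", "I_R_II",
      "P_L_III", "F_L_III", "P_L_IV", "F_L_IV", "T_L_IV"
    ),
    group = rep(c("LG", "HG"), c(4, 5)),
    volume_cm3 = c(4.2, 22.8, 122.0, 43.0, 26.4, 17.5, 13.1, 57.9, 115.7)
  )
}

#' Example 12-measure comparison p-values
#'
#' Unadjusted two-sided Mann-Whitney p-values of a twelve-measure
#' LG-vs-HG comparison (tumor volume, eight along-tract DTI measures,
#' three lobar fMRI laterality indices), bundled to demonstrate
#' Benjamini-Hochberg adjustment on a realistic measure battery.
#'
#' @return tibble: measure, p.
#' @export
example_group_pvalues <- function() {
  tibble(
    measure = c(
      "tumor_volume",
      "FA_dec_segments", "median_FA",
      "AD_dec_segments", "median_AD",
      "MD_inc_segments", "median_MD",
      "RD_inc_segments", "median_RD",
      "LI_frontal", "LI_parietal", "LI_temporal"
    ),
    p = c(1, 0.047, 0.142, 0.306, 0.027, 0.017, 0.014, 0.012, 0.086,
          0.221, 0.142, 0.806)
  )
}
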