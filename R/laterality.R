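#' Threshold an fMRI Z-map
#'
#' Strictly greater-than thresholding (z > `z_thresh` is active); the
#' strictness is configurable since both conventions appear in
#' practice.
#'
#' @param zmap `scalar_volume` of Z statistics.
#' @param z_thresh activation threshold (default 3.1).
#' @param strict use strict ">" (default TRUE); FALSE uses ">=".
#' @return binary `scalar_volume`.
#' @export
threshold_zmap <- function(zmap, z_thresh = 3.1, strict = TRUE) {
  act <- array(0, dim(zmap))
  z <- unclass(zmap)
  hit <- if (strict) z > z_thresh else z >= z_thresh
  act[!is.na(hit) & hit] <- 1
  scalar_volume(act, vol_affine(zmap))
}

#' Count activated voxels inside an ROI
#'
#' @param activation binary `scalar_volume`.
#' @param roi_mask binary `scalar_volume` on the same grid.
#' @return integer count of voxels active in both.
#' @export
count_in_roi <- function(activation, roi_mask) {
  if (!same_grid(activation, roi_mask)) abort("Activation and ROI are on different grids.")
  sum(unclass(activation) > 0 & unclass(roi_mask) > 0, na.rm = TRUE)
}

#' Hemispheric laterality index from voxel counts
#'
#' LI = (Left - Right) / (Left + Right) over activated voxel counts in
#' homologous left/right regions; LI > 0 indicates leftward, LI < 0
#' rightward dominance. Undefined (NA, with a warning) when both
#' counts are zero.
#'
#' @param n_left,n_right non-negative integer counts (vectorized).
#' @return numeric LI in \[-1, 1\] (NA where undefined).
#' @export
laterality_index <- function(n_left, n_right) {
  if (any(n_left < 0 | n_right < 0)) abort("Voxel counts must be non-negative.")
  tot <- n_left + n_right
  if (any(tot == 0)) warn("Zero activated voxels in both hemispheres: LI undefined.")
  ifelse(tot > 0, (n_left - n_right) / tot, NA_real_)
}

#' Lobar laterality indices from a Z-map and paired ROI masks
#'
#' @param zmap `scalar_volume` of Z statistics.
#' @param rois tibble/list with columns `lobe`, `left` and `right`
#'   (`scalar_volume` masks), e.g. frontal/parietal/temporal pairs.
#' @param z_thresh activation threshold (default 3.1).
#' @param strict strict ">" thresholding (default TRUE).
#' @return tibble (lobe, n_left, n_right, li).
#' @export
lobar_laterality <- function(zmap, rois, z_thresh = 3.1, strict = TRUE) {
  act <- threshold_zmap(zmap, z_thresh, strict)
  purrr::map_dfr(seq_along(rois$lobe), function(i) {
    nl <- count_in_roi(act, rois$left[[i]])
    nr <- count_in_roi(act, rois$right[[i]])
    tibble(
      lobe = rois$lobe[i], n_left = nl, n_right = nr,
      li = laterality_index(nl, nr)
    )
  })
}
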