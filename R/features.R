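#' Physical lung area of one mask slice
#'
#' @param mask a [lung_mask()].
#' @param slice_index 1-based slice index.
#' @return area in mm^2 (foreground voxel count times dy * dx).
#' @export
lung_area <- function(mask, slice_index) {
  if (!inherits(mask, "lung_mask")) abort("mask must be a lung_mask",
                                          "airtrapcad_input_error")
  d <- dim(mask$voxels)
  if (slice_index < 1L || slice_index > d[1])
    abort(sprintf("slice index %d out of range 1..%d", slice_index, d[1]),
          "airtrapcad_index_error")
  sum(mask$voxels[slice_index, , ] > 0) * mask$spacing[2] * mask$spacing[3]
}

#' Normalized area variation at the carina slice
#'
#' The 2-D air-trapping feature: the lung cross-sectional area at the carina
#' slice of each phase, with the change normalized by the inspiration area so
#' subjects of different size are comparable,
#' \deqn{\Delta S_N = (S_{insp} - S_{exp}) / S_{insp}.}
#'
#' @param mask_insp,mask_exp inspiration / expiration [lung_mask()]s.
#' @param carina_insp,carina_exp carina slice index in each phase.
#' @return the dimensionless fraction `delta_S_N`.  Negative values
#'   (expiration larger than inspiration) are kept but flagged with a
#'   warning.
#' @export
area_variation <- function(mask_insp, mask_exp, carina_insp, carina_exp) {
  s_i <- lung_area(mask_insp, carina_insp)
  s_e <- lung_area(mask_exp, carina_exp)
  if (s_i <= 0)
    abort("inspiration carina-slice area is zero", "airtrapcad_degenerate_error")
  val <- (s_i - s_e) / s_i
  if (val < 0)
    warning(sprintf("negative area variation (%.4f): expiration area exceeds inspiration",
                    val), call. = FALSE)
  val
}

#' Normalized volume variation with slice subsampling
#'
#' The 3-D air-trapping feature: total lung volume change from inspiration to
#' expiration, normalized by the inspiration volume.  To reduce computation,
#' the volume is estimated from every `subsample_step`-th slice (default every
#' 17th), each sampled slice representing `subsample_step` slice thicknesses:
#' \deqn{V \approx k\, dz \sum_{j} S(\textrm{slice } 1 + jk), \qquad
#'       \Delta V_N = (V_{insp} - V_{exp}) / V_{insp}.}
#' `subsample_step = 1` gives the exact full-mask volume.
#'
#' @inheritParams area_variation
#' @param subsample_step positive integer k; slices 1, 1+k, 1+2k, ... are
#'   used.
#' @return the dimensionless fraction `delta_V_N` (negative values kept but
#'   flagged with a warning).
#' @export
volume_variation <- function(mask_insp, mask_exp, subsample_step = 17L) {
  k <- as.integer(subsample_step)
  if (is.na(k) || k < 1L)
    abort("subsample_step must be a positive integer", "airtrapcad_parameter_error")
  vol <- function(mask) {
    d <- dim(mask$voxels)
    idx <- seq(1L, d[1], by = k)
    areas <- vapply(idx, function(s) lung_area(mask, s), numeric(1))
    sum(areas) * mask$spacing[1] * k
  }
  v_i <- vol(mask_insp)
  if (v_i <= 0)
    abort("inspiration mask volume is zero", "airtrapcad_degenerate_error")
  val <- (v_i - vol(mask_exp)) / v_i
  if (val < 0)
    warning(sprintf("negative volume variation (%.4f): expiration volume exceeds inspiration",
                    val), call. = FALSE)
  val
}

#' Extract the air-trapping feature pair from a CT pair
#'
#' Runs the full measurement chain on one subject: segments the lungs
#' ([segment_lungs()]), tracks the airway and detects the carina in each
#' phase independently ([track_trachea()], [detect_carina()]), and computes
#' the two normalized features ([area_variation()], [volume_variation()]).
#' Stage failures are re-raised with the failing stage and phase named.
#'
#' @param vol_insp,vol_exp inspiration / expiration [ct_volume()]s.
#' @param params a [snake_params()].
#' @param air_threshold seeding threshold, HU.
#' @param subsample_step slice subsampling step for the volume feature.
#' @param subject_id identifier for the output row (defaults to the
#'   inspiration volume's).
#' @param label optional known class label (`"normal"` / `"patient"`).
#' @return a one-row data frame: `subject_id`, `delta_S_N`, `delta_V_N`,
#'   `label`, with the detected carina slices as attributes `carina_insp`
#'   and `carina_exp`.
#' @export
extract_features <- function(vol_insp, vol_exp, params = snake_params(),
                             air_threshold = -320, subsample_step = 17L,
                             subject_id = NULL, label = NA_character_) {
  if (is.null(subject_id)) subject_id <- vol_insp$subject_id
  stage <- function(what, expr) {
    tryCatch(expr, airtrapcad_error = function(e)
      abort(sprintf("%s: %s", what, conditionMessage(e)), class(e)[1]))
  }
  tr_i <- stage("airway tracking (inspiration)", track_trachea(vol_insp, air_threshold))
  tr_e <- stage("airway tracking (expiration)", track_trachea(vol_exp, air_threshold))
  car_i <- stage("carina detection (inspiration)", detect_carina(tr_i))
  car_e <- stage("carina detection (expiration)", detect_carina(tr_e))
  m_i <- stage("segmentation (inspiration)",
               segment_lungs(vol_insp, params, air_threshold, airway_track = tr_i))
  m_e <- stage("segmentation (expiration)",
               segment_lungs(vol_exp, params, air_threshold, airway_track = tr_e))
  ds <- stage("area variation", area_variation(m_i, m_e, car_i, car_e))
  dv <- stage("volume variation", volume_variation(m_i, m_e, subsample_step))
  out <- data.frame(subject_id = subject_id, delta_S_N = ds, delta_V_N = dv,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "carina_insp") <- car_i
  attr(out, "carina_exp") <- car_e
  out
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b [lung_mask()]s (or plain binary arrays) of identical shape.
#' @return the Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  va <- if (inherits(a, "lung_mask")) a$voxels else a
  vb <- if (inherits(b, "lung_mask")) b$voxels else b
  if (!identical(dim(va), dim(vb)))
    abort("masks have different shapes", "airtrapcad_input_error")
  denom <- sum(va > 0) + sum(vb > 0)
  if (denom == 0) return(1)
  2 * sum(va > 0 & vb > 0) / denom
}
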