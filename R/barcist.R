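#' BARCIST 1.0 depot labeling from paired PET-CT
#'
#' Reference-standard BAT labeling: adipose voxels are ROI voxels with CT
#' attenuation in the closed window \[-190, -10\] HU; BAT voxels are adipose
#' voxels with SUV >= 1.5; a depot is BAT when it has at least
#' `min_bat_voxels` BAT voxels. An ROI with no adipose voxels is labeled
#' non-BAT and flagged with a warning record.
#'
#' @param ct,pet Congruent [volume_grid()] objects (HU and SUV).
#' @param roi A [depot_roi()] or binary mask.
#' @param min_bat_voxels Minimum BAT voxels for a positive depot (default 1).
#' @param hu_window,suv_threshold The BARCIST bounds.
#' @return Data frame row: `depot_id`, `adipose_voxel_count`,
#'   `bat_voxel_count`, `bat_flag`, `max_suv`, `mean_suv`, `warning`.
#' @export
label_depot <- function(ct, pet, roi, min_bat_voxels = 1L,
                        hu_window = c(-190, -10), suv_threshold = 1.5) {
  mask <- if (inherits(roi, "depot_roi")) roi$mask else array(as.integer(roi != 0), dim(roi))
  stopifnot_congruent(ct, pet, mask)
  inside <- mask != 0
  hu <- ct$values[inside]; suv <- pet$values[inside]
  adipose <- hu >= hu_window[1] & hu <= hu_window[2]
  bat <- adipose & suv >= suv_threshold
  warn <- !any(adipose)
  data.frame(depot_id = if (inherits(roi, "depot_roi")) roi$depot_id else NA_character_,
             patient_id = if (inherits(roi, "depot_roi")) roi$patient_id else NA_character_,
             adipose_voxel_count = sum(adipose),
             bat_voxel_count = sum(bat),
             bat_flag = sum(bat) >= min_bat_voxels,
             max_suv = if (any(adipose)) max(suv[adipose]) else NA_real_,
             mean_suv = if (any(adipose)) mean(suv[adipose]) else NA_real_,
             warning = warn)
}

#' Patient-level BAT label
#'
#' A patient is BAT positive iff at least one depot is BAT positive.
#'
#' @param depot_labels Data frame of [label_depot()] rows.
#' @return Logical (single patient) or a data frame per `patient_id`.
#' @export
label_patient <- function(depot_labels) {
  if (nrow(depot_labels) == 0L) stop("at least one depot required")
  if (!"patient_id" %in% names(depot_labels) || all(is.na(depot_labels$patient_id)))
    return(any(depot_labels$bat_flag))
  out <- aggregate(bat_flag ~ patient_id, depot_labels, any)
  names(out)[2] <- "bat_flag"
  out
}

#' Label every depot of a cohort
#'
#' @param cohort A cohort from [generate_cohort()].
#' @inheritParams label_depot
#' @return Data frame of depot labels across all patients.
#' @export
label_cohort <- function(cohort, min_bat_voxels = 1L) {
  rows <- lapply(cohort$patients, function(p)
    do.call(rbind, lapply(p$depots, function(roi)
      label_depot(p$ct, p$pet, roi, min_bat_voxels))))
  do.call(rbind, rows)
}
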