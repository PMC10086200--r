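#' 3D scalar volume with grid metadata
#'
#' A `volume_grid` is the package's container for one 3D scalar field: CT
#' attenuation in Hounsfield units (HU) or PET standardized uptake values
#' (SUV). Axis order is `(slice, row, column)` throughout the package, and
#' `spacing` gives the physical voxel size in mm along the same axes.
#'
#' @param values 3D numeric array, dimension `(slice, row, column)`.
#' @param spacing Numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> dim", paste(dim(x$values), collapse = "x"),
      " spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  cat("  value range [", signif(min(x$values), 5), ",",
      signif(max(x$values), 5), "]\n")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

stopifnot_congruent <- function(...) {
  vols <- list(...)
  dims <- lapply(vols, function(v) if (inherits(v, "volume_grid")) dim(v$values) else dim(v))
  for (i in seq_along(dims)[-1])
    if (!identical(dims[[1]], dims[[i]]))
      stop("volumes/masks are not congruent (differing dimensions)")
  invisible(TRUE)
}

#' Depot region of interest
#'
#' One adipose depot: a binary mask congruent with the patient's volumes plus
#' its anatomic region, laterality and identifiers. Cervical, supraclavicular
#' and axillary depots are bilateral (left/right); mediastinal depots are
#' midline.
#'
#' @param mask 3D binary (0/1 or logical) array.
#' @param region One of `"cervical"`, `"supraclavicular"`, `"axillary"`,
#'   `"mediastinal"`.
#' @param laterality One of `"left"`, `"right"`, `"midline"`.
#' @param patient_id,depot_id Identifiers.
#' @return An object of class `depot_roi`.
#' @export
depot_roi <- function(mask, region, laterality, patient_id, depot_id) {
  region <- match.arg(region, c("cervical", "supraclavicular", "axillary", "mediastinal"))
  laterality <- match.arg(laterality, c("left", "right", "midline"))
  if (region == "mediastinal" && laterality != "midline")
    stop("mediastinal depots must be midline")
  if (region != "mediastinal" && laterality == "midline")
    stop("bilateral depots must be left or right")
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  if (sum(mask) == 0L) stop("depot mask is empty")
  structure(list(mask = mask, region = region, laterality = laterality,
                 patient_id = patient_id, depot_id = depot_id),
            class = "depot_roi")
}

#' @export
print.depot_roi <- function(x, ...) {
  cat("<depot_roi>", x$depot_id, paste0("(", x$region, "/", x$laterality, ")"),
      "patient", x$patient_id, "-", sum(x$mask), "voxels\n")
  invisible(x)
}

#' Display windowing of a CT volume
#'
#' Clamps values to a window given by center and width, the way a
#' review workstation displays CT. This is a display utility only: it is not
#' part of the feature-extraction path, because a soft-tissue window
#' (e.g. center 40 / width 400 HU) would clip the entire adipose range
#' (-190 to -10 HU) to its lower bound.
#'
#' @param vol A [volume_grid()].
#' @param center,width Window center and width in HU.
#' @return A windowed `volume_grid`.
#' @export
apply_window <- function(vol, center = 40, width = 400) {
  lo <- center - width / 2
  hi <- center + width / 2
  v <- pmin(pmax(vol$values, lo), hi)
  volume_grid(array(v, dim(vol$values)), vol$spacing, vol$origin)
}

pad_array <- function(a, pad = 1L, value = 0) {
  d <- dim(a)
  out <- array(value, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- a
  out
}

mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

#' Write a cohort to disk as NIfTI volumes and CSV truth tables
#'
#' CT, PET, each depot mask and the territory masks are written as
#' compressed NIfTI; the depot truth table and the phantom specification are
#' written as CSV/JSON alongside.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest of written files.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(vg, path) {
    # NIfTI is (x,y,z)-ordered; store as (col,row,slice)
    img <- aperm(vg$values, c(3, 2, 1))
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = rev(vg$spacing)), path)
    path
  }
  for (p in cohort$patients) {
    pid <- p$patient_id
    files <- c(files, wr(p$ct, file.path(dir, paste0(pid, "_ct.nii.gz"))))
    files <- c(files, wr(p$pet, file.path(dir, paste0(pid, "_pet.nii.gz"))))
    for (roi in p$depots) {
      f <- file.path(dir, paste0(pid, "_", roi$depot_id, "_mask.nii.gz"))
      files <- c(files, wr(volume_grid(roi$mask + 0, p$ct$spacing), f))
    }
    for (tn in names(p$territories)) {
      f <- file.path(dir, paste0(pid, "_territory_", tn, ".nii.gz"))
      files <- c(files, wr(volume_grid(p$territories[[tn]] + 0, p$ct$spacing), f))
    }
  }
  truth_csv <- file.path(dir, "depot_truth.csv")
  write.csv(cohort$truth$depots, truth_csv, row.names = FALSE)
  spec_json <- file.path(dir, "phantom_spec.json")
  jsonlite::write_json(unclass(cohort$spec), spec_json, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truth_csv, spec_json))
}
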