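#' Detect calcified lesions in a territory
#'
#' A lesion is a per-slice, 8-connected (in-plane) component of voxels with
#' HU strictly greater than 130 inside the territory mask; components of
#' fewer than 3 pixels are discarded ("at least three adjacent pixels").
#' The Agatston convention scores slices independently, so no 3D bridging
#' is applied.
#'
#' @param ct A [volume_grid()] in HU.
#' @param territory_mask Binary array congruent with `ct`.
#' @param hu_threshold Detection threshold (strict `>`, default 130 HU).
#' @param min_pixels Minimum component size in pixels (default 3).
#' @return Data frame with one row per lesion-slice component: `lesion_id`,
#'   `slice`, `n_pixels`, `max_hu`; the voxel indices are kept in the
#'   `voxels` attribute (list of index matrices).
#' @export
detect_lesions <- function(ct, territory_mask, hu_threshold = 130, min_pixels = 3L) {
  stopifnot_congruent(ct, territory_mask)
  if (sum(territory_mask != 0) == 0L) stop("territory mask is empty")
  bright <- array(as.integer(ct$values > hu_threshold & territory_mask != 0),
                  dim(ct$values))
  lab <- cpp_label_components(bright, 8L)
  ids <- sort(unique(lab[lab != 0]))
  rows <- list(); voxlist <- list()
  for (id in ids) {
    vox <- which(lab == id, arr.ind = TRUE)
    if (nrow(vox) < min_pixels) next
    k <- length(rows) + 1L
    rows[[k]] <- data.frame(lesion_id = k, slice = vox[1, 1],
                            n_pixels = nrow(vox),
                            max_hu = max(ct$values[vox]))
    voxlist[[k]] <- vox
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(lesion_id = integer(0), slice = integer(0),
                         n_pixels = integer(0), max_hu = numeric(0))
  attr(out, "voxels") <- voxlist
  attr(out, "spacing") <- ct$spacing
  out
}

agatston_weight <- function(max_hu) {
  if (max_hu >= 400) 4L else if (max_hu >= 300) 3L else if (max_hu >= 200) 2L else 1L
}

#' Agatston score and calcium volume
#'
#' Per lesion-slice component: density weight 1-4 from the maximum HU
#' (130-199 / 200-299 / 300-399 / >= 400) and slice score = in-plane area
#' (mm^2) x weight; the total score sums over components and the calcium
#' volume is the voxel count times the voxel volume (mm^3). Scores are
#' computed at the spacing of the input volume, which is recorded in the
#' result (the classic Agatston assumption is 3 mm slices; no
#' slice-thickness rescaling is applied).
#'
#' @param lesions Output of [detect_lesions()].
#' @param spacing mm per axis; defaults to the spacing recorded in `lesions`.
#' @param territory Label stored in the result (`"CAC"` or `"TAC"`).
#' @return An object of class `calcium_result`: `territory`, `lesions`
#'   (with `area_mm2`, `weight`, `slice_score`), `agatston_score`,
#'   `calcium_volume`, `spacing`.
#' @export
agatston_score <- function(lesions, spacing = attr(lesions, "spacing"),
                           territory = "CAC") {
  pixel_area <- spacing[2] * spacing[3]
  voxel_vol <- prod(spacing)
  if (nrow(lesions)) {
    lesions$area_mm2 <- lesions$n_pixels * pixel_area
    lesions$weight <- vapply(lesions$max_hu, agatston_weight, 0L)
    lesions$slice_score <- lesions$area_mm2 * lesions$weight
    score <- sum(lesions$slice_score)
    vol <- sum(lesions$n_pixels) * voxel_vol
  } else { score <- 0; vol <- 0 }
  structure(list(territory = territory, lesions = lesions,
                 agatston_score = score, calcium_volume = vol,
                 spacing = spacing),
            class = "calcium_result")
}

#' @export
print.calcium_result <- function(x, ...) {
  cat("<calcium_result>", x$territory, "- score", signif(x$agatston_score, 5),
      "volume", signif(x$calcium_volume, 5), "mm^3 over", nrow(x$lesions),
      "lesion-slices\n")
  invisible(x)
}

#' Score one territory of one patient
#'
#' Convenience wrapper: [detect_lesions()] then [agatston_score()].
#' @inheritParams detect_lesions
#' @inheritParams agatston_score
#' @export
score_territory <- function(ct, territory_mask, territory = "CAC") {
  agatston_score(detect_lesions(ct, territory_mask), territory = territory)
}

#' Compare calcium burden between patient groups
#'
#' Incidence is the fraction of patients with a positive score; mean and SD
#' of score and volume are computed over calcium-positive patients only
#' (all patients still enter the between-group test).
#'
#' @param scores Named list (one element per group) of data frames with
#'   columns `agatston_score` and `calcium_volume` (one row per patient).
#' @return Data frame with one row per group: n, incidence, positive-only
#'   mean/SD of score and volume; `p_score`/`p_volume`/`p_incidence` for
#'   two-group input, via [group_compare()].
#' @export
territory_compare <- function(scores) {
  if (any(!vapply(scores, nrow, 0L))) stop("empty group")
  summ <- lapply(names(scores), function(g) {
    d <- scores[[g]]
    pos <- d$agatston_score > 0
    data.frame(group = g, n = nrow(d), incidence = mean(pos),
               score_mean = if (any(pos)) mean(d$agatston_score[pos]) else NA_real_,
               score_sd = if (sum(pos) > 1) stats::sd(d$agatston_score[pos]) else NA_real_,
               volume_mean = if (any(pos)) mean(d$calcium_volume[pos]) else NA_real_,
               volume_sd = if (sum(pos) > 1) stats::sd(d$calcium_volume[pos]) else NA_real_)
  })
  out <- do.call(rbind, summ)
  if (length(scores) == 2L) {
    a <- scores[[1]]; b <- scores[[2]]
    attr(out, "p_score") <- group_compare(a$agatston_score, b$agatston_score)$p_value
    attr(out, "p_volume") <- group_compare(a$calcium_volume, b$calcium_volume)$p_value
    attr(out, "p_incidence") <- group_compare(
      factor(a$agatston_score > 0, levels = c(FALSE, TRUE)),
      factor(b$agatston_score > 0, levels = c(FALSE, TRUE)), "categorical")$p_value
  }
  out
}
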