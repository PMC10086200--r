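#' Phantom cohort specification
#'
#' Defines the statistical structure of a synthetic PET-CT cohort: paired CT
#' (HU) and PET (SUV) volumes with adipose depot masks laid out in the
#' bilateral cervical / supraclavicular / axillary and midline mediastinal
#' pattern, plus coronary (CAC) and thoracic-aorta (TAC) territory masks with
#' optional calcified lesions.
#'
#' Brown adipose tissue (BAT) depots differ from white adipose tissue (WAT)
#' depots in three ways: the mean HU is shifted upward by
#' `bat_mean_hu_shift` (BAT is denser: small lipid droplets, abundant
#' mitochondria), the HU texture is rougher (`bat_texture_sd` >
#' `wat_texture_sd`, with a shorter spatial correlation length), and the PET
#' uptake is drawn from `bat_suv_range` (entirely >= 1.5) instead of
#' `wat_suv_range` (< 1.5). Depot HU values are clipped to the adipose window
#' [-190, -10] so the BARCIST fat criterion holds by construction.
#'
#' @param n_patients Number of patients.
#' @param bat_prevalence Probability that a patient harbours BAT.
#' @param depots_per_patient_range Integer interval within \[6, 13\].
#' @param wat_mean_hu Mean HU of WAT depots.
#' @param bat_mean_hu_shift Additive HU shift of BAT depots (>= 0).
#' @param wat_texture_sd,bat_texture_sd HU texture dispersion per class.
#' @param bat_suv_range,wat_suv_range SUV intervals; BAT must lie entirely at
#'   or above 1.5 and WAT entirely below 1.5.
#' @param calcium_rate_bat,calcium_rate_nonbat Per-territory probability of
#'   calcified lesions for BAT-positive / BAT-negative patients.
#' @param lesion_intensity_range HU range of injected calcium (> 130).
#' @param voxel_spacing mm per `(slice, row, column)` axis.
#' @param volume_dim Lattice size `(slices, rows, columns)`.
#' @param pair_bat_prob Within a BAT-positive patient, probability that a
#'   depot pair (or a mediastinal depot) is BAT.
#' @param asym_bat_rate Probability that a BAT pair is expressed on one side
#'   only (occasional asymmetric activation).
#' @param hu_heterogeneity_sd Between-depot biological variability: each
#'   depot's mean HU is jittered by a zero-mean Gaussian with this SD, so
#'   the BAT/WAT class distributions overlap as they do across real
#'   patients.
#' @param site_hu_shift Additive HU offset applied to the whole cohort,
#'   emulating a second scanner/site for external validation.
#' @param rng_seed Integer seed driving a hierarchical per-patient stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 86,
                         bat_prevalence = 0.5,
                         depots_per_patient_range = c(6L, 13L),
                         wat_mean_hu = -100,
                         bat_mean_hu_shift = 10,
                         wat_texture_sd = 8,
                         bat_texture_sd = 11,
                         bat_suv_range = c(2, 6),
                         wat_suv_range = c(0.3, 1.2),
                         calcium_rate_bat = 0.05,
                         calcium_rate_nonbat = 0.25,
                         lesion_intensity_range = c(150, 800),
                         voxel_spacing = c(5, 1, 1),
                         volume_dim = c(20L, 72L, 72L),
                         pair_bat_prob = 0.55,
                         asym_bat_rate = 0.1,
                         hu_heterogeneity_sd = 18,
                         site_hu_shift = 0,
                         rng_seed = 20260927L) {
  spec <- list(n_patients = as.integer(n_patients),
               bat_prevalence = bat_prevalence,
               depots_per_patient_range = as.integer(depots_per_patient_range),
               wat_mean_hu = wat_mean_hu,
               bat_mean_hu_shift = bat_mean_hu_shift,
               wat_texture_sd = wat_texture_sd,
               bat_texture_sd = bat_texture_sd,
               bat_suv_range = bat_suv_range,
               wat_suv_range = wat_suv_range,
               calcium_rate_bat = calcium_rate_bat,
               calcium_rate_nonbat = calcium_rate_nonbat,
               lesion_intensity_range = lesion_intensity_range,
               voxel_spacing = as.numeric(voxel_spacing),
               volume_dim = as.integer(volume_dim),
               pair_bat_prob = pair_bat_prob,
               asym_bat_rate = asym_bat_rate,
               hu_heterogeneity_sd = hu_heterogeneity_sd,
               site_hu_shift = site_hu_shift,
               rng_seed = as.integer(rng_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  fat <- c(-190, -10)
  if (s$n_patients < 1L) stop("n_patients must be >= 1")
  if (s$bat_prevalence < 0 || s$bat_prevalence > 1) stop("bat_prevalence must be in [0,1]")
  r <- s$depots_per_patient_range
  if (length(r) != 2L || r[1] > r[2]) stop("empty depots_per_patient_range")
  if (r[1] < 6L || r[2] > 13L) stop("depots_per_patient_range must lie within [6, 13]")
  if (s$wat_mean_hu < fat[1] || s$wat_mean_hu > fat[2])
    stop("wat_mean_hu outside the adipose window [-190, -10]")
  if (s$wat_mean_hu + s$bat_mean_hu_shift < fat[1] ||
      s$wat_mean_hu + s$bat_mean_hu_shift > fat[2])
    stop("wat_mean_hu + bat_mean_hu_shift outside the adipose window")
  if (min(s$bat_suv_range) < 1.5) stop("bat_suv_range must lie entirely at or above SUV 1.5")
  if (max(s$wat_suv_range) >= 1.5) stop("wat_suv_range must lie entirely below SUV 1.5")
  if (min(s$lesion_intensity_range) <= 130) stop("lesion intensities must exceed 130 HU")
  if (any(s$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  invisible(TRUE)
}

# anatomic template: nominal (slice, row, left-col, right-col) per pair slot
depot_template <- function(d) {
  # coordinates scale with the lattice; defaults assume >= 18 x 64 x 64
  list(
    cervical        = list(slice = 3,  row = round(d[2] * 0.26), cols = round(d[3] * c(0.37, 0.63))),
    cervical_b      = list(slice = 5,  row = round(d[2] * 0.34), cols = round(d[3] * c(0.30, 0.70))),
    supraclavicular = list(slice = 7,  row = round(d[2] * 0.42), cols = round(d[3] * c(0.24, 0.76))),
    supraclavicular_b = list(slice = 9, row = round(d[2] * 0.33), cols = round(d[3] * c(0.18, 0.82))),
    axillary        = list(slice = 11, row = round(d[2] * 0.50), cols = round(d[3] * c(0.13, 0.87))),
    axillary_b      = list(slice = 13, row = round(d[2] * 0.60), cols = round(d[3] * c(0.15, 0.85))),
    mediastinal     = list(slice = c(11, 13, 15), row = round(d[2] * 0.52), cols = round(d[3] * 0.5))
  )
}

fill_ellipsoid <- function(d, center, radii) {
  m <- array(0L, d)
  lo <- pmax(floor(center - radii), 1)
  hi <- pmin(ceiling(center + radii), d)
  if (any(lo > hi)) return(m)
  s <- lo[1]:hi[1]; r <- lo[2]:hi[2]; cc <- lo[3]:hi[3]
  g <- expand.grid(s = s, r = r, c = cc)
  u <- ((g$s - center[1]) / radii[1])^2 + ((g$r - center[2]) / radii[2])^2 +
    ((g$c - center[3]) / radii[3])^2
  sel <- g[u <= 1, , drop = FALSE]
  m[cbind(sel$s, sel$r, sel$c)] <- 1L
  m
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k / sum(k)
}

# Gaussian random field over the bounding box of `mask`, with per-axis
# correlation length (voxels), scaled to `sd` around `mean`.
grf_fill <- function(values, mask, mu, sdev, corr_len) {
  bb <- mask_bbox(mask, margin = 0L)
  sub <- crop_bbox(mask, bb)
  noise <- array(rnorm(length(sub)), dim(sub))
  for (ax in 1:3) {
    k <- gauss_kernel(corr_len[ax])
    if (length(k) > 1) noise <- cpp_conv_axis(noise, k, ax)
  }
  esd <- stats::sd(noise)
  if (esd > 0) noise <- noise / esd
  field <- mu + sdev * noise
  inside <- sub != 0
  tgt <- values[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  tgt[inside] <- field[inside]
  values[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- tgt
  values
}

#' Generate a synthetic PET-CT phantom cohort
#'
#' Builds `n_patients` paired CT/PET volumes with depot masks, CAC/TAC
#' territory masks, injected calcified lesions, patient covariates and a
#' ground-truth table. Identical spec and seed give a bit-identical cohort.
#' Within BAT-positive patients, BAT is assigned to bilateral pairs as a unit
#' (occasionally one-sided) and to mediastinal depots individually, so the
#' symmetric physiologic distribution the per-patient diagnosis rules exploit
#' is present in truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `spec`, `patients` (each with `patient_id`,
#'   `ct`, `pet`, `depots`, `territories`, `covariates`) and `truth`
#'   (`$depots`, `$patients`, `$lesions` data frames).
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$rng_seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, spec$n_patients)
  patients <- vector("list", spec$n_patients)
  depot_rows <- list(); patient_rows <- list(); lesion_rows <- list()
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", i)
    set.seed(pseeds[i])
    p <- generate_patient(spec, pid)
    patients[[i]] <- p$patient
    depot_rows[[i]] <- p$depot_truth
    patient_rows[[i]] <- p$patient_truth
    lesion_rows[[i]] <- p$lesion_truth
  }
  truth <- list(depots = do.call(rbind, depot_rows),
                patients = do.call(rbind, patient_rows),
                lesions = do.call(rbind, lesion_rows))
  stopifnot(all(tapply(truth$depots$bat_flag, truth$depots$patient_id, any) ==
                  truth$patients$bat_flag[order(truth$patients$patient_id)]))
  list(spec = spec, patients = patients, truth = truth)
}

generate_patient <- function(spec, pid) {
  d <- spec$volume_dim
  tpl <- depot_template(d)
  bat_patient <- runif(1) < spec$bat_prevalence

  # depot composition: 3 core bilateral pairs, extras from second pairs and
  # mediastinal depots
  r <- spec$depots_per_patient_range
  n_dep <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  m <- n_dep - 6L
  med <- m %% 2L
  if (m >= 2L && runif(1) < 0.5 && med == 0L) med <- 2L
  if (m - med > 6L) med <- med + 2L      # cannot exceed 3 extra pairs
  extra_pairs <- (m - med) %/% 2L
  med <- min(med, 3L)
  pair_slots <- c("cervical", "supraclavicular", "axillary",
                  sample(c("cervical_b", "supraclavicular_b", "axillary_b"))[seq_len(extra_pairs)])
  units <- c(pair_slots, if (med > 0L) paste0("mediastinal", seq_len(med)))

  # BAT assignment per unit
  repeat {
    unit_bat <- if (bat_patient) runif(length(units)) < spec$pair_bat_prob
                else rep(FALSE, length(units))
    if (!bat_patient || any(unit_bat)) break
  }

  ct <- array(40 + rnorm(prod(d), sd = 8), d)   # soft-tissue background
  pet <- array(pmax(0.8 + rnorm(prod(d), sd = 0.15), 0.05), d)

  # cardiovascular territories, reserved first so depots never touch them
  cac <- fill_ellipsoid(d, c(d[1] - 3, round(0.72 * d[2]), round(0.42 * d[3])),
                        c(1.6, 5, 5))
  tac <- fill_ellipsoid(d, c(d[1] - 5, round(0.82 * d[2]), round(0.52 * d[3])),
                        c(4.5, 3.5, 3.5))
  territories <- list(CAC = cac, TAC = tac)
  occ <- cpp_morph6(array(as.integer(cac | tac), d), 0L)

  depots <- list(); depot_truth <- list()
  di <- 0L
  for (u in seq_along(units)) {
    slot <- units[u]
    is_med <- startsWith(slot, "mediastinal")
    region <- if (is_med) "mediastinal" else sub("_b$", "", slot)
    sides <- if (is_med) "midline" else c("left", "right")
    bat_sides <- if (is_med) unit_bat[u] else {
      if (unit_bat[u] && runif(1) < spec$asym_bat_rate)
        sample(c(TRUE, FALSE)) else rep(unit_bat[u], 2)
    }
    rad <- c(runif(1, 1.0, 1.8), runif(1, 3.0, 5.5), runif(1, 3.0, 5.5))
    for (k in seq_along(sides)) {
      di <- di + 1L
      side <- sides[k]
      draw_center <- function() {
        if (is_med) {
          t <- tpl$mediastinal
          midx <- as.integer(sub("mediastinal", "", slot))
          ctr <- c(t$slice[midx] + sample(-1:1, 1), t$row + runif(1, -2, 2),
                   t$cols[1] + runif(1, -2, 2))
        } else {
          t <- tpl[[slot]]
          ctr <- c(t$slice + sample(-1:1, 1), t$row + runif(1, -2, 2),
                   t$cols[if (side == "left") 1 else 2] + runif(1, -2, 2))
        }
        ctr[1] <- min(max(ctr[1], 2), d[1] - 1)
        ctr
      }
      # rejitter when the occupancy constraint truncates the depot too far
      mask <- NULL
      for (attempt in 1:10) {
        cand <- fill_ellipsoid(d, draw_center(),
                               if (attempt <= 5) rad else pmax(rad, c(1.2, 4, 4)))
        cand[occ != 0L] <- 0L                 # depots stay pairwise disjoint
        if (sum(cand) >= 8L) { mask <- cand; break }
      }
      if (is.null(mask)) stop("phantom template could not place a depot")
      occ <- pmax(occ, cpp_morph6(mask, 0L))
      is_bat <- isTRUE(bat_sides[k])
      mu <- spec$wat_mean_hu + (if (is_bat) spec$bat_mean_hu_shift else 0) +
        rnorm(1, 0, spec$hu_heterogeneity_sd)
      mu <- min(max(mu, -180), -20)
      sdv <- max(if (is_bat) spec$bat_texture_sd else spec$wat_texture_sd, 1)
      cl <- if (is_bat) c(0.35, 0.8, 0.8) else c(0.45, 1.1, 1.1)
      ct <- grf_fill(ct, mask, mu, sdv, cl)
      ct[mask != 0] <- pmin(pmax(ct[mask != 0], -190), -10)
      if (is_bat) {
        suv_mu <- runif(1, spec$bat_suv_range[1], spec$bat_suv_range[2])
        pet <- grf_fill(pet, mask, suv_mu, 0.3, c(0.5, 1, 1))
        pet[mask != 0] <- pmax(pet[mask != 0], 1.5)
      } else {
        suv_mu <- runif(1, spec$wat_suv_range[1], spec$wat_suv_range[2])
        pet <- grf_fill(pet, mask, suv_mu, 0.1, c(0.5, 1, 1))
        pet[mask != 0] <- pmin(pmax(pet[mask != 0], 0.05), 1.45)
      }
      dep_id <- sprintf("%s_d%02d", pid, di)
      depots[[di]] <- depot_roi(mask, region, side, pid, dep_id)
      depot_truth[[di]] <- data.frame(patient_id = pid, depot_id = dep_id,
                                      region = region, laterality = side,
                                      bat_flag = is_bat)
    }
  }

  # calcium injection per territory
  lesion_truth <- list()
  rate <- if (bat_patient) spec$calcium_rate_bat else spec$calcium_rate_nonbat
  for (tn in names(territories)) {
    if (runif(1) < rate) {
      nles <- sample(1:2, 1)
      sizes <- sample(4:20, nles, replace = TRUE)
      inj <- inject_calcium(volume_grid(ct, spec$voxel_spacing), territories[[tn]],
                            n_lesions = nles,
                            intensity = spec$lesion_intensity_range,
                            lesion_size = sizes)
      ct <- inj$ct$values
      for (L in seq_along(inj$lesions))
        lesion_truth[[length(lesion_truth) + 1L]] <-
          data.frame(patient_id = pid, territory = tn,
                     n_voxels = nrow(inj$lesions[[L]]))
    }
  }
  ct <- ct + spec$site_hu_shift

  covariates <- data.frame(
    patient_id = pid, bat_flag = bat_patient,
    age = round(rnorm(1, if (bat_patient) 42 else 45, 12)),
    sex = sample(c("F", "M"), 1),
    weight = round(rnorm(1, 63, 10), 1),
    temp_low = round(rnorm(1, if (bat_patient) 3 else 5, 4), 1))

  list(patient = list(patient_id = pid,
                      ct = volume_grid(ct, spec$voxel_spacing),
                      pet = volume_grid(pet, spec$voxel_spacing),
                      depots = depots, territories = territories,
                      covariates = covariates),
       depot_truth = do.call(rbind, depot_truth),
       patient_truth = covariates,
       lesion_truth = if (length(lesion_truth)) do.call(rbind, lesion_truth) else NULL)
}

#' Inject calcified lesions into a CT volume
#'
#' Grows `n_lesions` connected bright components (HU drawn from `intensity`)
#' inside a territory mask, leaving all surrounding voxels unchanged. Lesions
#' are kept at least 2 voxels apart so they remain distinct connected
#' components under 26-connectivity.
#'
#' @param ct A [volume_grid()] in HU.
#' @param territory_mask Binary array congruent with `ct`.
#' @param n_lesions Number of lesions (0 returns the input unchanged).
#' @param intensity HU value or range; must exceed 130 HU.
#' @param lesion_size Target voxels per lesion (scalar or vector).
#' @return List with the modified `ct` and `lesions`, a list of voxel index
#'   matrices (one per lesion).
#' @export
inject_calcium <- function(ct, territory_mask, n_lesions, intensity = c(200, 800),
                           lesion_size = 10) {
  stopifnot_congruent(ct, territory_mask)
  if (sum(territory_mask) == 0) stop("territory mask is empty")
  if (min(intensity) <= 130) stop("calcium intensity must exceed 130 HU")
  n_lesions <- as.integer(n_lesions)
  if (n_lesions == 0L) return(list(ct = ct, lesions = list()))
  sizes <- rep_len(as.integer(lesion_size), n_lesions)
  d <- dim(ct$values)
  vals <- ct$values
  allowed <- territory_mask != 0
  lesions <- vector("list", n_lesions)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  grow_lesion <- function(size) {
    cand <- which(allowed)
    if (length(cand) == 0L) return(NULL)
    seed_i <- if (length(cand) == 1L) cand else sample(cand, 1)
    vox <- matrix(arrayInd(seed_i, d), ncol = 3)
    while (nrow(vox) < size) {
      nb <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        sweep(vox, 2, offs[k, ], `+`))))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      nb <- nb[allowed[nb] & !duplicated(rbind(vox, nb))[-seq_len(nrow(vox))], , drop = FALSE]
      if (nrow(nb) == 0L) break
      vox <- rbind(vox, nb[sample.int(nrow(nb), 1), ])
    }
    vox
  }
  for (L in seq_len(n_lesions)) {
    vox <- NULL
    for (attempt in 1:30) {   # re-seed when growth hits a fragmented pocket
      vox <- grow_lesion(sizes[L])
      if (!is.null(vox) && nrow(vox) >= max(3L, sizes[L])) break
      vox <- NULL
    }
    if (is.null(vox)) stop("lesion does not fit in territory")
    hu <- if (length(intensity) > 1) runif(nrow(vox), min(intensity), max(intensity))
          else rep(intensity, nrow(vox))
    vals[vox] <- hu
    lesions[[L]] <- vox
    # forbid a 1-voxel halo around this lesion for subsequent lesions
    halo <- unique(do.call(rbind, c(list(vox), lapply(seq_len(nrow(offs)), function(k)
      sweep(vox, 2, offs[k, ], `+`)))))
    ok <- halo[, 1] >= 1 & halo[, 1] <= d[1] & halo[, 2] >= 1 & halo[, 2] <= d[2] &
      halo[, 3] >= 1 & halo[, 3] <= d[3]
    allowed[halo[ok, , drop = FALSE]] <- FALSE
  }
  list(ct = volume_grid(vals, ct$spacing, ct$origin), lesions = lesions)
}
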