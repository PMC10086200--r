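#' @name features
#' @title Radiomics feature classes
#' @description
#' From-scratch implementations of the standard radiomics feature classes
#' computed per depot: 18 first-order statistics, 14 3D shape descriptors,
#' and the five gray-level texture-matrix families — co-occurrence (GLCM,
#' 22 features), run length (GLRLM, 16), size zone (GLSZM, 16), dependence
#' (GLDM, 14) and neighbouring gray tone difference (NGTDM, 5). Texture
#' matrices are accumulated in compiled code; feature formulas are evaluated
#' in R. Over the default 19-image-type filter bank this yields
#' 19 x (18 + 22 + 16 + 16 + 14 + 5) + 14 = 1,743 features per depot.
#'
#' Degenerate regions (a single gray level, or a single voxel) return
#' defined values rather than NaN: GLCM correlation is 1, the information
#' measures are 0, inverse variance sums over off-diagonal entries only,
#' skewness and kurtosis of a constant ROI are 0, and NGTDM ratios with a
#' zero denominator are 0 (coarseness is capped at 1e6).
NULL

fo_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "P10", "P90",
              "Maximum", "Mean", "Median", "InterquartileRange", "Range",
              "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
              "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

shape_names <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
                 "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
                 "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
                 "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
                 "Elongation", "Flatness")

glcm_names <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
                "Id", "Idn", "InverseVariance", "MaximumProbability",
                "SumEntropy", "SumSquares")

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
                 "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "GrayLevelVariance", "RunVariance", "RunEntropy",
                 "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                 "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
                 "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
                 "SizeZoneNonUniformityNormalized", "ZonePercentage",
                 "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
                 "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

gldm_names <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
                "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")

ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

#' Canonical feature-name registry
#'
#' Fixed, ordered names for every census entry:
#' `<image_type>_<class>_<feature>`. Shape features are computed once on the
#' original image (`original_shape_*`) and are not multiplied by image types.
#'
#' @param config A [preprocess_config()].
#' @return Character vector of length 1,743 under the default configuration.
#' @export
canonical_feature_names <- function(config = preprocess_config()) {
  types <- config$filter_bank
  per_type <- c(paste0("firstorder_", fo_names),
                paste0("glcm_", glcm_names),
                paste0("glrlm_", glrlm_names),
                paste0("glszm_", glszm_names),
                paste0("gldm_", gldm_names),
                paste0("ngtdm_", ngtdm_names))
  c(paste0("original_shape_", shape_names),
    unlist(lapply(types, function(t) paste0(t, "_", per_type))))
}

#' First-order intensity statistics
#'
#' @param values Numeric array or [volume_grid()].
#' @param mask Binary array congruent with `values`.
#' @param bin_width Bin width for the histogram-based entropy/uniformity.
#' @param voxel_volume Voxel volume in mm^3 (for total energy).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, mask, bin_width = 25, voxel_volume = 1) {
  if (inherits(values, "volume_grid")) {
    voxel_volume <- prod(values$spacing)
    values <- values$values
  }
  v <- values[mask != 0]
  if (length(v) == 0L) stop("empty mask")
  n <- length(v)
  m <- mean(v)
  varp <- mean((v - m)^2)             # population convention
  sdp <- sqrt(varp)
  q <- unname(quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  vr <- v[v >= q[1] & v <= q[5]]
  skew <- if (sdp > 0) mean((v - m)^3) / sdp^3 else 0
  kurt <- if (sdp > 0) mean((v - m)^4) / sdp^4 else 0
  p <- tabulate(discretize(array(v, c(n, 1, 1)), array(1L, c(n, 1, 1)), bin_width)$levels) / n
  p <- p[p > 0]
  c(Energy = sum(v^2),
    TotalEnergy = voxel_volume * sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(v), P10 = q[1], P90 = q[5], Maximum = max(v),
    Mean = m, Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = if (length(vr)) mean(abs(vr - mean(vr))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = skew, Kurtosis = kurt,
    Variance = varp,
    Uniformity = sum(p^2))
}

max_pairwise_dist <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  if (nrow(xy) > 1500L) xy <- xy[seq(1, nrow(xy), length.out = 1500L), , drop = FALSE]
  max(stats::dist(xy))
}

#' 3D shape descriptors of a binary mask
#'
#' Surface area and mesh volume come from a marching-tetrahedra iso-0.5
#' surface of the (lightly Gaussian-regularized) mask indicator, with mesh
#' volume obtained from the divergence theorem over the closed oriented
#' surface; on digital balls the resulting sphericity approaches 1 as the
#' radius grows. Axis lengths derive from the eigenvalues of the physical
#' voxel-coordinate covariance (`4 * sqrt(lambda)`); a degenerate direction
#' yields axis length 0, and a single-voxel mask reports elongation and
#' flatness of 1. Maximum 2D diameters are the largest in-plane distances
#' between boundary-voxel centers, maximized over the planes orthogonal to
#' each axis.
#'
#' @param mask Binary 3D array.
#' @param spacing mm per `(slice, row, column)` axis.
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing) {
  mask <- array(as.integer(mask != 0), dim(mask))
  nvox <- sum(mask)
  if (nvox == 0L) stop("empty mask")
  mt <- mesh_mask(mask, spacing)
  area <- mt[1]; mesh_vol <- mt[2]
  voxel_vol <- nvox * prod(spacing)

  idx <- which(mask != 0, arr.ind = TRUE)
  phys <- sweep(idx, 2, spacing, `*`)
  # boundary voxels: at least one 6-neighbour outside
  er <- cpp_morph6(mask, 1L)
  bidx <- which(mask != 0 & er == 0, arr.ind = TRUE)
  if (nrow(bidx) == 0L) bidx <- idx
  bphys <- sweep(bidx, 2, spacing, `*`)

  max3d <- max_pairwise_dist(bphys)
  plane_diam <- function(fixed_ax) {
    keep <- setdiff(1:3, fixed_ax)
    m <- 0
    for (u in unique(bidx[, fixed_ax])) {
      sel <- bidx[, fixed_ax] == u
      m <- max(m, max_pairwise_dist(bphys[sel, keep, drop = FALSE]))
    }
    m
  }
  # planes orthogonal to the slice axis (axial), column axis and row axis
  d_slice <- plane_diam(1); d_col <- plane_diam(3); d_row <- plane_diam(2)

  cv <- crossprod(sweep(phys, 2, colMeans(phys))) / nrow(phys)
  ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  sph <- if (area > 0) (36 * pi * mesh_vol^2)^(1 / 3) / area else 0
  c(MeshVolume = mesh_vol, VoxelVolume = voxel_vol, SurfaceArea = area,
    SurfaceVolumeRatio = if (mesh_vol > 0) area / mesh_vol else 0,
    Sphericity = sph,
    Maximum3DDiameter = max3d, Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col, Maximum2DDiameterRow = d_row,
    MajorAxisLength = axes[1], MinorAxisLength = axes[2],
    LeastAxisLength = axes[3], Elongation = elong, Flatness = flat)
}

entropy2 <- function(p) { p <- p[p > 0]; if (!length(p)) 0 else -sum(p * log2(p)) }

# Iso-0.5 marching-tetrahedra mesh of a binary mask. The indicator is first
# smoothed with a small Gaussian (in voxel units) so the extracted surface is
# a regularized estimate of the underlying smooth boundary rather than the
# voxel staircase; masks too small to clear the iso level after smoothing
# fall back to the raw indicator (edge-midpoint surface).
mesh_mask <- function(mask, spacing, sigma = 0.7) {
  h <- ceiling(3 * sigma)
  f <- pad_array(mask + 0, h + 1L)
  k <- gauss_kernel(sigma)
  sm <- f
  for (ax in 1:3) sm <- cpp_conv_axis(sm, k, ax)
  if (max(sm) <= 0.5) sm <- f
  cpp_march_tets(sm, as.numeric(spacing), 0.5)
}

.glcm_idx_cache <- new.env(parent = emptyenv())

glcm_idx <- function(L) {
  key <- as.character(L)
  got <- .glcm_idx_cache[[key]]
  if (!is.null(got)) return(got)
  i <- matrix(rep(seq_len(L), L), L, L)
  j <- t(i)
  out <- list(i = i, j = j,
              dgrp = as.vector(abs(i - j)) + 1L,   # |i-j| in 0..L-1
              sgrp = as.vector(i + j) - 1L,        # i+j in 2..2L
              off = as.vector(i != j))
  .glcm_idx_cache[[key]] <- out
  out
}

glcm_from_P <- function(P) {
  # P: symmetric, normalized co-occurrence matrix for one direction
  L <- nrow(P)
  ix <- glcm_idx(L)
  i <- ix$i; j <- ix$j
  pv <- as.vector(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  dvals <- 0:(L - 1)
  pxmy <- as.vector(rowsum(pv, ix$dgrp))        # groups 1..L are all present
  svals <- 2:(2 * L)
  pxpy <- as.vector(rowsum(pv, ix$sgrp))        # groups 1..2L-1, s = grp + 1
  da <- sum(dvals * pxmy)
  HX <- entropy2(px)
  HXY <- entropy2(P)
  pp <- outer(px, px)
  pos <- P > 0 & pp > 0
  HXY1 <- -sum(P[pos] * log2(pp[pos]))
  HXY2 <- entropy2(pp)
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- if (HXY2 >= HXY) sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)) else 0
  off <- i != j
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pxmy),
    DifferenceVariance = sum((dvals - da)^2 * pxmy),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1, Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / L)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / L)),
    InverseVariance = sum(P[off] / (i[off] - j[off])^2),
    MaximumProbability = max(P),
    SumEntropy = entropy2(pxpy),
    SumSquares = sig2)
}

#' Gray-level co-occurrence features
#'
#' Distance-1 co-occurrences over the 13 unique 3D directions; each
#' direction's matrix is symmetrized and normalized, features are averaged
#' over directions.
#'
#' @param levels Integer level array (0 outside the ROI), as produced by
#'   [discretize()].
#' @param n_levels Number of gray levels.
#' @return Named numeric vector of 22 features.
#' @export
glcm_features <- function(levels, n_levels = max(levels)) {
  L <- as.integer(n_levels)
  if (sum(levels != 0) == 0L) stop("empty ROI")
  counts <- cpp_glcm(as_int_array(levels), L)
  feats <- matrix(0, 22, 0)
  for (k in 1:13) {
    C <- matrix(counts[, , k], L, L)
    S <- C + t(C)
    tot <- sum(S)
    if (tot == 0) next                 # no valid pairs along this direction
    feats <- cbind(feats, glcm_from_P(S / tot))
  }
  if (ncol(feats) == 0) {              # isolated voxel(s): defined fallbacks
    P <- matrix(0, L, L); P[1, 1] <- 1
    feats <- cbind(feats, glcm_from_P(P))
  }
  setNames(rowMeans(feats), glcm_names)
}

szm_style_features <- function(P, n_voxels, names, size_is_dep = FALSE) {
  # shared formula set for GLRLM / GLSZM (P indexed level x size)
  Ns <- sum(P)
  if (Ns == 0) return(setNames(rep(0, 16), names))
  i <- row(P); j <- col(P)
  p <- P / Ns
  gsum <- rowSums(P); ssum <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  setNames(c(
    sum(P / col(P)^2) / Ns,
    sum(P * col(P)^2) / Ns,
    sum(gsum^2) / Ns,
    sum(gsum^2) / Ns^2,
    sum(ssum^2) / Ns,
    sum(ssum^2) / Ns^2,
    Ns / n_voxels,
    sum((i - mu_i)^2 * p),
    sum((j - mu_j)^2 * p),
    entropy2(p),
    sum(P / row(P)^2) / Ns,
    sum(P * row(P)^2) / Ns,
    sum(P / (row(P)^2 * col(P)^2)) / Ns,
    sum(P * row(P)^2 / col(P)^2) / Ns,
    sum(P * col(P)^2 / row(P)^2) / Ns,
    sum(P * row(P)^2 * col(P)^2) / Ns), names)
}

#' Gray-level run-length features
#'
#' Runs of identical levels along each of the 13 unique 3D directions;
#' features averaged over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, n_levels = max(levels)) {
  L <- as.integer(n_levels)
  nvox <- sum(levels != 0)
  if (nvox == 0L) stop("empty ROI")
  counts <- cpp_glrlm(as_int_array(levels), L)
  maxrun <- dim(counts)[2]
  feats <- vapply(1:13, function(k)
    szm_style_features(matrix(counts[, , k], L, maxrun), nvox, glrlm_names),
    numeric(16))
  setNames(rowMeans(feats), glrlm_names)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal level; the zone-size matrix is
#' direction-free.
#'
#' @inheritParams glcm_features
#' @param connectivity 26 (default) or 8 (in-plane only).
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(levels, n_levels = max(levels), connectivity = 26L) {
  L <- as.integer(n_levels)
  nvox <- sum(levels != 0)
  if (nvox == 0L) stop("empty ROI")
  lab <- cpp_label_components(as_int_array(levels), as.integer(connectivity))
  sel <- lab != 0
  sizes <- tabulate(lab[sel])
  zlev <- levels[sel][match(seq_along(sizes), lab[sel])]
  P <- matrix(0, L, max(sizes))
  for (z in seq_along(sizes)) P[zlev[z], sizes[z]] <- P[zlev[z], sizes[z]] + 1
  szm_style_features(P, nvox, glszm_names)
}

#' Gray-level dependence features
#'
#' Dependence of a voxel = number of 26-neighbours inside the ROI whose
#' level differs by at most `alpha` (default 0). The dependence matrix is
#' indexed level x (dependence + 1).
#'
#' @inheritParams glcm_features
#' @param alpha Level-difference tolerance.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, n_levels = max(levels), alpha = 0L) {
  L <- as.integer(n_levels)
  nvox <- sum(levels != 0)
  if (nvox == 0L) stop("empty ROI")
  P <- cpp_gldm(as_int_array(levels), L, as.integer(alpha))
  P <- P[, seq_len(max(which(colSums(P) > 0))), drop = FALSE]
  Nz <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / Nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  setNames(c(
    sum(P / col(P)^2) / Nz,
    sum(P * col(P)^2) / Nz,
    sum(rowSums(P)^2) / Nz,
    sum(colSums(P)^2) / Nz,
    sum(colSums(P)^2) / Nz^2,
    sum((i - mu_i)^2 * p),
    sum((j - mu_j)^2 * p),
    entropy2(p),
    sum(P / row(P)^2) / Nz,
    sum(P * row(P)^2) / Nz,
    sum(P / (row(P)^2 * col(P)^2)) / Nz,
    sum(P * row(P)^2 / col(P)^2) / Nz,
    sum(P * col(P)^2 / row(P)^2) / Nz,
    sum(P * row(P)^2 * col(P)^2) / Nz), gldm_names)
}

#' Neighbouring gray-tone difference features
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels, n_levels = max(levels)) {
  L <- as.integer(n_levels)
  if (sum(levels != 0) == 0L) stop("empty ROI")
  st <- cpp_ngtdm(as_int_array(levels), L)
  n_i <- st[, 1]; s_i <- st[, 2]
  Nvp <- sum(n_i)
  if (Nvp == 0) return(setNames(c(1e6, 0, 0, 0, 0), ngtdm_names))
  p_i <- n_i / Nvp
  lv <- seq_len(L)
  act <- p_i > 0
  Ngp <- sum(act)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    sum(outer(p_i, p_i) * outer(lv, lv, `-`)^2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  } else 0
  busy_den <- sum(abs(outer(lv * p_i, lv * p_i, `-`)[outer(act, act)]))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  cplx <- 0; strength <- 0
  if (Ngp > 0) {
    ii <- which(act)
    for (a in ii) for (b in ii) {
      cplx <- cplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
      strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
    }
    cplx <- cplx / Nvp
    strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  }
  setNames(c(coarseness, contrast, busyness, cplx, strength), ngtdm_names)
}

as_int_array <- function(x) {
  a <- array(as.integer(x), dim(x))
  a
}

#' Extract the full radiomics feature vector for one depot
#'
#' Applies the filter bank to the CT volume, discretizes each image type
#' over the depot mask with the configured bin width, and evaluates all
#' feature classes. Shape features are computed once from the mask. The
#' result is the package's full census: 1,743 named features under the
#' default configuration.
#'
#' @param ct A [volume_grid()] (resampled CT).
#' @param roi A [depot_roi()] or a binary mask array.
#' @param config A [preprocess_config()].
#' @param filtered Optional precomputed output of [apply_filter_bank()] for
#'   `ct` (reused across depots of the same patient).
#' @return Named numeric vector in [canonical_feature_names()] order.
#' @export
extract_features <- function(ct, roi, config = preprocess_config(), filtered = NULL) {
  mask <- if (inherits(roi, "depot_roi")) roi$mask else array(as.integer(roi != 0), dim(roi))
  stopifnot_congruent(ct, mask)
  if (sum(mask) == 0L) stop("empty depot mask")
  if (is.null(filtered)) filtered <- apply_filter_bank(ct, config)

  bb <- mask_bbox(mask, margin = 0L)
  msub <- crop_bbox(mask, bb)
  out <- numeric(0)
  out <- c(out, setNames(shape_features(mask, ct$spacing),
                         paste0("original_shape_", shape_names)))
  for (tn in config$filter_bank) {
    vsub <- crop_bbox(filtered[[tn]]$values, bb)
    dz <- discretize(vsub, msub, config$bin_width)
    fo <- first_order_features(vsub, msub, config$bin_width, prod(ct$spacing))
    vals <- c(setNames(fo, paste0(tn, "_firstorder_", fo_names)),
              setNames(glcm_features(dz$levels, dz$n_levels), paste0(tn, "_glcm_", glcm_names)),
              setNames(glrlm_features(dz$levels, dz$n_levels), paste0(tn, "_glrlm_", glrlm_names)),
              setNames(glszm_features(dz$levels, dz$n_levels), paste0(tn, "_glszm_", glszm_names)),
              setNames(gldm_features(dz$levels, dz$n_levels), paste0(tn, "_gldm_", gldm_names)),
              setNames(ngtdm_features(dz$levels, dz$n_levels), paste0(tn, "_ngtdm_", ngtdm_names)))
    out <- c(out, vals)
  }
  out[canonical_feature_names(config)]
}

#' Extract features for every depot of a cohort
#'
#' @param cohort A cohort from [generate_cohort()] (or any list of patients
#'   with `ct` and `depots`).
#' @param config A [preprocess_config()].
#' @param masks Optional named list (by depot id) of replacement masks, e.g.
#'   a second rater's segmentations from [perturb_mask()].
#' @param resample Logical; resample CT in-plane to the configured spacing
#'   first.
#' @param progress Logical; print per-patient progress.
#' @return Data frame: `patient_id`, `depot_id`, `region`, `laterality`,
#'   then one column per canonical feature.
#' @export
extract_cohort_features <- function(cohort, config = preprocess_config(),
                                    masks = NULL, resample = FALSE,
                                    progress = FALSE) {
  fnames <- canonical_feature_names(config)
  vals <- list(); meta <- list()
  for (p in cohort$patients) {
    ct <- p$ct
    if (resample) ct <- resample_volume(ct, config)
    filtered <- apply_filter_bank(ct, config)
    for (roi in p$depots) {
      m <- roi$mask
      if (!is.null(masks) && roi$depot_id %in% names(masks)) m <- masks[[roi$depot_id]]
      if (resample) {
        mv <- resample_volume(volume_grid(m + 0, p$ct$spacing), config, mask = TRUE)
        m <- mv$values
      }
      k <- length(vals) + 1L
      vals[[k]] <- extract_features(ct, m, config, filtered = filtered)
      meta[[k]] <- data.frame(patient_id = roi$patient_id, depot_id = roi$depot_id,
                              region = roi$region, laterality = roi$laterality)
    }
    if (progress) message("extracted ", p$patient_id)
  }
  x <- do.call(rbind, vals)
  colnames(x) <- fnames
  cbind(do.call(rbind, meta), as.data.frame(x, check.names = FALSE))
}

#' Split a feature table into metadata and feature matrix
#' @param tab Output of [extract_cohort_features()].
#' @return List with `meta` (data frame) and `x` (numeric matrix).
#' @export
feature_matrix <- function(tab) {
  meta_cols <- intersect(c("patient_id", "depot_id", "region", "laterality"), names(tab))
  x <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  list(meta = tab[, meta_cols, drop = FALSE], x = x)
}
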