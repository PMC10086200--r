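#' Preprocessing configuration
#'
#' Controls image conditioning before feature extraction: resampling to
#' 1 x 1 mm in-plane (slice spacing preserved; a zero in `target_spacing`
#' means "keep the input spacing" on that axis), the filter bank, and the
#' fixed-bin-width gray-level discretization used by all texture matrices.
#'
#' The default filter bank yields 19 image types: the original image, the 8
#' sub-bands of a single-level stationary (undecimated) Haar wavelet
#' transform (LLL ... HHH), Laplacian-of-Gaussian at sigma = 1..5 mm, and the
#' square, square-root, logarithm, exponential and gradient-magnitude
#' intensity transforms.
#'
#' @param target_spacing mm per `(slice, row, column)`; 0 keeps the axis.
#' @param interpolation Spline order for image resampling: 0 (nearest) or
#'   1 (trilinear).
#' @param window_center,window_width Display window (HU); retained as
#'   metadata, not applied before feature extraction (see [apply_window()]).
#' @param filter_bank Character vector of image-type names.
#' @param bin_width Gray-level bin width in HU (> 0).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(0, 1, 1),
                              interpolation = 1L,
                              window_center = 40, window_width = 400,
                              filter_bank = default_filter_bank(),
                              bin_width = 25) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (any(target_spacing < 0)) stop("target spacing must be non-negative")
  if (!interpolation %in% c(0L, 1L)) stop("interpolation order must be 0 or 1")
  unknown <- setdiff(filter_bank, default_filter_bank())
  if (length(unknown)) stop("unknown filter name(s): ", paste(unknown, collapse = ", "))
  structure(list(target_spacing = as.numeric(target_spacing),
                 interpolation = as.integer(interpolation),
                 window_center = window_center, window_width = window_width,
                 filter_bank = filter_bank, bin_width = bin_width),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @export
default_filter_bank <- function() {
  c("original",
    paste0("wavelet.", c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")),
    paste0("log.sigma.", 1:5),
    "square", "squareroot", "logarithm", "exponential", "gradient")
}

#' Resample a volume to a target grid spacing
#'
#' Order-1 B-spline (trilinear) interpolation for images, nearest-neighbour
#' for binary masks (`mask = TRUE`), onto a grid sharing the input origin.
#' Axes whose target spacing is 0 are left untouched.
#'
#' @param vol A [volume_grid()].
#' @param config A [preprocess_config()] (or a spacing triple).
#' @param mask Logical; resample as a binary mask (nearest, re-binarized).
#' @return A resampled `volume_grid`.
#' @export
resample_volume <- function(vol, config = preprocess_config(), mask = FALSE) {
  tsp <- if (inherits(config, "preprocess_config")) config$target_spacing else as.numeric(config)
  order <- if (inherits(config, "preprocess_config")) config$interpolation else 1L
  new_sp <- ifelse(tsp == 0, vol$spacing, tsp)
  d <- dim(vol$values)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(1L, as.integer(floor(extent / new_sp)) + 1L)
  # physical coordinates of output voxels, in units of input voxel index
  coords <- lapply(1:3, function(ax) (seq_len(nd[ax]) - 1) * new_sp[ax] / vol$spacing[ax] + 1)
  if (mask || order == 0L) {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(coords[[ax]]), 1), d[ax]))
    out <- vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    if (mask) out <- array(as.integer(out != 0), dim(out))
  } else {
    i0 <- lapply(1:3, function(ax) pmin(pmax(floor(coords[[ax]]), 1), max(d[ax] - 1, 1)))
    fr <- lapply(1:3, function(ax) pmin(pmax(coords[[ax]] - i0[[ax]], 0), 1))
    v <- vol$values
    out <- array(0, nd)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      ia <- pmin(i0[[1]] + a, d[1]); ib <- pmin(i0[[2]] + b, d[2]); ic <- pmin(i0[[3]] + cc, d[3])
      wa <- if (a == 0) 1 - fr[[1]] else fr[[1]]
      wb <- if (b == 0) 1 - fr[[2]] else fr[[2]]
      wc <- if (cc == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wa, wb), wc)
      out <- out + w * v[ia, ib, ic, drop = FALSE]
    }
  }
  volume_grid(out, new_sp, vol$origin)
}

haar_filters <- function() {
  list(L = c(1, 1) / sqrt(2), H = c(-1, 1) / sqrt(2))
}

# stationary (undecimated) single-level wavelet transform along all axes.
# Even-length Haar filters are centred by zero-padding to odd length.
swt_band <- function(x, band) {
  f <- haar_filters()
  for (ax in 1:3) {
    k <- f[[substr(band, ax, ax)]]
    x <- cpp_conv_axis(x, c(k, 0), ax)
  }
  x
}

gaussian_smooth <- function(x, sigma_mm, spacing) {
  for (ax in 1:3) {
    s <- sigma_mm / spacing[ax]
    k <- gauss_kernel(s)
    if (length(k) > 1) x <- cpp_conv_axis(x, k, ax)
  }
  x
}

laplacian3d <- function(x, spacing) {
  out <- array(0, dim(x))
  for (ax in 1:3) {
    k <- c(1, -2, 1) / spacing[ax]^2
    out <- out + cpp_conv_axis(x, k, ax)
  }
  out
}

gradient_magnitude <- function(x, spacing) {
  acc <- array(0, dim(x))
  for (ax in 1:3) {
    g <- cpp_conv_axis(x, c(1, 0, -1) / (2 * spacing[ax]), ax)
    acc <- acc + g^2
  }
  sqrt(acc)
}

#' Apply the radiomics filter bank
#'
#' Produces one filtered volume per configured image type (19 under the
#' default bank, counting the original). Intensity transforms are
#' magnitude-normalized so filtered images stay on a scale comparable to the
#' input: with `M = max(abs(x))` and `R = range`,
#' square `x^2 / M`; squareroot `sign(x) * sqrt(M * abs(x))`; logarithm
#' `sign(x) * log1p(abs(x)) * M / log1p(M)`; exponential
#' `exp((x - min x) * log1p(R) / R)` (min-anchored so narrow-range CT ROIs
#' are not compressed into a single gray-level bin). LoG is
#' scale-normalized by `sigma^2`.
#'
#' @param vol A resampled [volume_grid()].
#' @param config A [preprocess_config()].
#' @return Named list of `volume_grid` objects, one per image type, in the
#'   order of `config$filter_bank`.
#' @export
apply_filter_bank <- function(vol, config = preprocess_config()) {
  x <- vol$values
  sp <- vol$spacing
  M <- max(abs(x))
  R <- diff(range(x))
  out <- lapply(config$filter_bank, function(fn) {
    v <- if (fn == "original") x
    else if (startsWith(fn, "wavelet.")) swt_band(x, sub("wavelet.", "", fn, fixed = TRUE))
    else if (startsWith(fn, "log.sigma.")) {
      s <- as.numeric(sub("log.sigma.", "", fn, fixed = TRUE))
      s^2 * laplacian3d(gaussian_smooth(x, s, sp), sp)
    }
    else if (fn == "square") { if (M > 0) x^2 / M else x * 0 }
    else if (fn == "squareroot") sign(x) * sqrt(M * abs(x))
    else if (fn == "logarithm") { if (M > 0) sign(x) * log1p(abs(x)) * M / log1p(M) else x * 0 }
    else if (fn == "exponential") { if (R > 0) exp((x - min(x)) * log1p(R) / R) else array(1, dim(x)) }
    else if (fn == "gradient") gradient_magnitude(x, sp)
    else stop("unknown filter: ", fn)
    volume_grid(v, sp, vol$origin)
  })
  names(out) <- config$filter_bank
  out
}

#' Fixed-bin-width gray-level discretization
#'
#' Maps ROI voxel values to integer levels
#' `level(v) = floor((v - min) / bin_width) + 1`, where `min` is the ROI
#' minimum, so levels start at 1 and binning is shift-invariant. Voxels
#' outside the mask are coded 0.
#'
#' @param values 3D numeric array (or a [volume_grid()]).
#' @param mask Binary array congruent with `values`.
#' @param bin_width Bin width on the intensity scale (> 0).
#' @return List with `levels` (integer array, 0 outside mask) and `n_levels`.
#' @export
discretize <- function(values, mask, bin_width = 25) {
  if (inherits(values, "volume_grid")) values <- values$values
  if (bin_width <= 0) stop("bin_width must be > 0")
  stopifnot_congruent(values, mask)
  inside <- mask != 0
  if (!any(inside)) stop("empty mask")
  lev <- array(0L, dim(values))
  v <- values[inside]
  lev[inside] <- as.integer(floor((v - min(v)) / bin_width)) + 1L
  list(levels = lev, n_levels = max(lev))
}
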