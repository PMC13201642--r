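#' Per-class intensity statistics
#'
#' Computes, over the voxels of one tissue class, the sample count, mean,
#' population standard deviation (divisor N), an intensity histogram
#' realizing the class's empirical intensity distribution, and the class
#' maximum. These statistics drive the piecewise linear intensity
#' standardization: the brain-class maximum anchors the shift of the
#' WMH/vessel reference means to a new image.
#'
#' @param volume a [as_volume()] or 3-D array.
#' @param labels integer label array aligned with `volume`.
#' @param class_id class code (see [wmh_classes()]).
#' @param n_bins number of histogram bins (default 256).
#' @return An object of class `wmh_class_stats`: list with `class_id`, `n`,
#'   `mean`, `sd`, `histogram` (list of `breaks`, `counts`, `mids`) and
#'   `max_intensity`.
#' @examples
#' lab <- array(1L, c(4, 1, 1))
#' v <- array(c(1, 2, 3, 4), c(4, 1, 1))
#' s <- class_stats(v, lab, 1L)
#' c(s$mean, s$sd)  # 2.5, sqrt(1.25)
#' @export
class_stats <- function(volume, labels, class_id, n_bins = 256) {
  dat <- vol_data(volume)
  if (!identical(dim(dat), dim(labels)))
    stop("labels and volume dimensions differ", call. = FALSE)
  vals <- dat[labels == class_id]
  if (length(vals) == 0L)
    stop("class ", class_id, " has no voxels in the label map", call. = FALSE)
  n <- length(vals)
  mu <- mean(vals)
  sdev <- sqrt(sum((vals - mu)^2) / n)   # population sd, divisor N
  rng <- range(vals)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  structure(list(class_id = class_id, n = n, mean = mu, sd = sdev,
                 histogram = list(breaks = breaks, counts = counts,
                                  mids = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2),
                 max_intensity = max(vals)),
            class = "wmh_class_stats")
}

#' @export
print.wmh_class_stats <- function(x, ...) {
  cat(sprintf("<wmh_class_stats> class %s: n=%d mean=%.4g sd=%.4g max=%.4g\n",
              format(x$class_id), x$n, x$mean, x$sd, x$max_intensity))
  invisible(x)
}

#' Modal intensity of the masked intensity distribution
#'
#' The centre of the maximal histogram bin of the masked voxels — the
#' intensity of highest empirical probability, used as the anchor of the
#' piecewise rescaling under the assumption that healthy brain tissue
#' dominates the volume. Ties between equally maximal bins break toward the
#' lowest-intensity bin.
#'
#' @param volume a [as_volume()] or 3-D array.
#' @param mask logical array selecting the voxels to histogram.
#' @param n_bins number of histogram bins.
#' @return Scalar intensity (bin centre).
#' @export
pdf_mode <- function(volume, mask, n_bins = 256) {
  dat <- vol_data(volume)
  m <- as_mask(mask, dat)
  vals <- dat[m]
  if (length(vals) == 0L) stop("mask is empty", call. = FALSE)
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  i <- which.max(counts)   # which.max takes the first (lowest-intensity) tie
  (breaks[i] + breaks[i + 1L]) / 2
}

#' Bounds of the piecewise linear intensity transformation
#'
#' Shifts the reference WMH-class and vessel-class means to the new image by
#' the offset between its modal intensity and the reference brain-class
#' maximum, then places the stretch bounds three reference standard
#' deviations below/above the shifted means:
#' `mu_T' = N_PDF - N_max_B + mu_T`, `mu_V'` analogously,
#' `P_min = mu_T' - 3 sd_T`, `P_max = mu_V' + 3 sd_V`.
#'
#' @param stats_T [class_stats()] of the reference WMH (lesion) class.
#' @param stats_V [class_stats()] of the reference vessel class.
#' @param n_pdf modal intensity of the new image (see [pdf_mode()]).
#' @param n_max_B reference brain-class maximum intensity.
#' @return An object of class `wmh_transform_bounds`: list with `p_min`,
#'   `p_max`, `mu_T_new`, `mu_V_new`, `n_pdf`.
#' @export
transform_bounds <- function(stats_T, stats_V, n_pdf, n_max_B) {
  vals <- c(stats_T$mean, stats_T$sd, stats_V$mean, stats_V$sd, n_pdf, n_max_B)
  if (any(!is.finite(vals))) stop("inputs must be finite", call. = FALSE)
  shift <- n_pdf - n_max_B
  mu_T_new <- shift + stats_T$mean
  mu_V_new <- shift + stats_V$mean
  p_min <- mu_T_new - 3 * stats_T$sd
  p_max <- mu_V_new + 3 * stats_V$sd
  if (p_min >= p_max)
    stop("degenerate transformation bounds: p_min >= p_max", call. = FALSE)
  structure(list(p_min = p_min, p_max = p_max, mu_T_new = mu_T_new,
                 mu_V_new = mu_V_new, n_pdf = n_pdf),
            class = "wmh_transform_bounds")
}

#' Piecewise linear contrast stretch
#'
#' Maps intensities inside `[p_min, p_max]` affinely onto `[1, 255]`
#' (`(I - P_min)/(P_max - P_min) * 254 + 1`) and everything outside to 0,
#' stretching the tissue-specific range while suppressing background.
#'
#' @param volume a [as_volume()] or 3-D array.
#' @param bounds a [transform_bounds()] object.
#' @return Same type as `volume`, values in `{0} U [1, 255]`.
#' @export
piecewise_rescale <- function(volume, bounds) {
  stopifnot(inherits(bounds, "wmh_transform_bounds"))
  dat <- vol_data(volume)
  out <- array(0, dim(dat))
  inside <- dat >= bounds$p_min & dat <= bounds$p_max
  out[inside] <- (dat[inside] - bounds$p_min) /
    (bounds$p_max - bounds$p_min) * 254 + 1
  if (is_volume(volume)) as_volume(out, volume$spacing) else out
}

# normalized, truncated 1-D Gaussian kernel (separable factor of the 3-D one)
gaussian_kernel1 <- function(sigma, truncate = 3) {
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along axis `along` with replicate padding
conv_axis3 <- function(a, kernel, along) {
  r <- (length(kernel) - 1L) / 2
  out <- array(0, dim(a))
  for (i in seq_along(kernel)) {
    off <- i - 1L - r
    sh <- switch(along,
                 shift3(a, off, 0, 0, fill = NA),
                 shift3(a, 0, off, 0, fill = NA),
                 shift3(a, 0, 0, off, fill = NA))
    # replicate edges: fill NA planes with nearest valid plane
    if (anyNA(sh)) {
      d <- dim(a)
      idx <- pmin(pmax(seq_len(d[along]) - off, 1L), d[along])
      sh <- switch(along,
                   a[idx, , , drop = FALSE],
                   a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
    }
    out <- out + kernel[i] * sh
  }
  out
}

#' Denoise a volume
#'
#' Median filtering over a cubic neighbourhood removes impulsive
#' salt-and-pepper noise while preserving edges; an optional normalized
#' discrete Gaussian convolution (separable, truncated at 3 sigma, edges
#' replicated) further suppresses high-frequency noise.
#'
#' @param volume a [as_volume()] or 3-D array.
#' @param median_window odd window edge length in voxels (1 disables the
#'   median stage); default 3.
#' @param gaussian_sigma Gaussian standard deviation in voxels, or `NULL`
#'   (default) to skip smoothing.
#' @return Same type as `volume`.
#' @export
denoise <- function(volume, median_window = 3, gaussian_sigma = NULL) {
  median_window <- as.integer(median_window)
  if (median_window < 1L || median_window %% 2L == 0L)
    stop("median_window must be odd and >= 1", call. = FALSE)
  dat <- vol_data(volume)
  out <- dat
  if (median_window > 1L) {
    out <- array(.median_filter3_cpp(as.numeric(out), dim(out),
                                     median_window), dim(out))
  }
  if (!is.null(gaussian_sigma)) {
    if (gaussian_sigma <= 0) stop("gaussian_sigma must be > 0", call. = FALSE)
    k <- gaussian_kernel1(gaussian_sigma)
    for (ax in 1:3) out <- conv_axis3(out, k, ax)
  }
  if (is_volume(volume)) as_volume(out, volume$spacing) else out
}

#' Z-score plus min-max intensity normalization
#'
#' Standardizes the volume by the brain-mask mean and standard deviation
#' (optionally computed from percentile-clipped masked values, e.g. the 2nd
#' to 95th percentile range), then min-max rescales the whole volume to
#' `[0, 1]` so its minimum is exactly 0 and maximum exactly 1.
#'
#' @param volume a [as_volume()] or 3-D array.
#' @param mask logical brain mask (non-empty).
#' @param percentile_clip `NULL` or two percentiles in `[0, 100]` (e.g.
#'   `c(2, 95)`) restricting the voxels entering the mean/sd.
#' @return Same type as `volume`, values in `[0, 1]`.
#' @export
normalize_intensity <- function(volume, mask, percentile_clip = NULL) {
  dat <- vol_data(volume)
  m <- as_mask(mask, dat)
  vals <- dat[m]
  if (length(vals) == 0L) stop("mask is empty", call. = FALSE)
  if (!is.null(percentile_clip)) {
    q <- stats::quantile(vals, percentile_clip / 100, names = FALSE)
    vals <- vals[vals >= q[1] & vals <= q[2]]
  }
  mu <- mean(vals)
  sdev <- stats::sd(vals)
  if (!is.finite(sdev) || sdev == 0)
    stop("masked intensities have zero variance", call. = FALSE)
  z <- (dat - mu) / sdev
  out <- (z - min(z)) / (max(z) - min(z))
  if (is_volume(volume)) as_volume(out, volume$spacing) else out
}

#' Adaptive-threshold candidate WMH detection
#'
#' Thresholds the (normalized) volume at `T = mu_B + k * sd_B`, with the
#' brain mean and standard deviation recomputed over the supplied mask on
#' this image. Voxels inside the mask at or above the threshold become
#' candidates; everything else is false. `k` controls sensitivity: small
#' values admit faint lesions (and noise), large values keep only the most
#' hyperintense voxels.
#'
#' @param volume a [as_volume()] or 3-D array (typically the normalized
#'   image).
#' @param mask logical brain mask.
#' @param k threshold multiplier.
#' @return Logical candidate mask.
#' @export
candidate_wmh <- function(volume, mask, k) {
  dat <- vol_data(volume)
  m <- as_mask(mask, dat)
  vals <- dat[m]
  if (length(vals) == 0L) stop("mask is empty", call. = FALSE)
  thr <- mean(vals) + k * stats::sd(vals)
  m & dat >= thr
}

#' Binary erosion and dilation
#'
#' 3-D morphology with a ball (default) or box structuring element of the
#' given voxel radius.
#'
#' @param mask logical 3-D array.
#' @param radius structuring-element radius in voxels (>= 1).
#' @param shape `"ball"` or `"box"`.
#' @return Logical array.
#' @export
morph_erode <- function(mask, radius = 1, shape = c("ball", "box")) {
  shape <- match.arg(shape)
  m <- as_mask(mask)
  off <- struct_offsets(radius, shape)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift3(m, off$dx[i], off$dy[i], off$dz[i], fill = FALSE)
  out
}

#' @rdname morph_erode
#' @export
morph_dilate <- function(mask, radius = 1, shape = c("ball", "box")) {
  shape <- match.arg(shape)
  m <- as_mask(mask)
  off <- struct_offsets(radius, shape)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift3(m, off$dx[i], off$dy[i], off$dz[i], fill = FALSE)
  out
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same structuring element; removes
#' clusters smaller than the element (isolated noise voxels) while
#' preserving larger lesion structures.
#'
#' @inheritParams morph_erode
#' @return Logical array.
#' @export
morph_open <- function(mask, radius = 1, shape = c("ball", "box")) {
  shape <- match.arg(shape)
  if (radius < 1) stop("structuring radius must be >= 1", call. = FALSE)
  morph_dilate(morph_erode(mask, radius, shape), radius, shape)
}

#' Segmented lesion volume
#'
#' True-voxel count times the physical voxel volume.
#'
#' @param mask logical 3-D array.
#' @param spacing mm per voxel along each axis (ignored if `mask` carries
#'   none and left at default 1 mm isotropic).
#' @return Volume in mm^3.
#' @export
lesion_volume <- function(mask, spacing = c(1, 1, 1)) {
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(as_mask(mask)) * prod(spacing)
}

#' Segmentation parameters
#'
#' The tunable parameters of the candidate-detection stage: the threshold
#' multiplier `k`, the opening structuring radius, and the tissue weights
#' combining the normalized image, candidate-WMH mask and vessel mask into
#' the composite network input.
#'
#' @param k threshold multiplier.
#' @param structuring_radius opening radius in voxels (>= 1).
#' @param weights named numeric `c(w_B=, w_T=, w_V=)`, all >= 0.
#' @return An object of class `wmh_seg_params`.
#' @export
segmentation_params <- function(k = 2, structuring_radius = 1,
                                weights = c(w_B = 1, w_T = 0, w_V = 0)) {
  if (structuring_radius < 1) stop("structuring_radius must be >= 1",
                                   call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  stopifnot(all(c("w_B", "w_T", "w_V") %in% names(weights)))
  structure(list(k = k, structuring_radius = structuring_radius,
                 weights = weights[c("w_B", "w_T", "w_V")]),
            class = "wmh_seg_params")
}

#' @export
print.wmh_seg_params <- function(x, ...) {
  cat(sprintf("<wmh_seg_params> k=%.4g radius=%g weights=(%.3g, %.3g, %.3g)\n",
              x$k, x$structuring_radius, x$weights[1], x$weights[2],
              x$weights[3]))
  invisible(x)
}

#' Tissue-weighted composite input
#'
#' Pointwise `w_B * I_m + w_T * I_WMH + w_V * I_vessel`: the normalized
#' image blended with the candidate-WMH and vessel masks according to the
#' configured tissue weights.
#'
#' @param i_m normalized intensity volume ([as_volume()] or array).
#' @param i_wmh candidate-WMH binary mask.
#' @param i_vessel vessel binary mask.
#' @param params a [segmentation_params()] (or a length-3 weight vector).
#' @return Same type as `i_m`.
#' @export
compose_input <- function(i_m, i_wmh, i_vessel, params) {
  w <- if (inherits(params, "wmh_seg_params")) params$weights
       else as.numeric(params)
  dat <- vol_data(i_m)
  mw <- as_mask(i_wmh, dat)
  mv <- as_mask(i_vessel, dat)
  out <- w[1] * dat + w[2] * mw + w[3] * mv
  if (is_volume(i_m)) as_volume(out, i_m$spacing) else out
}

# linear interpolation of a 2-D slice at arbitrary (mm) sample points
resample_slice_linear <- function(slice, in_spacing, out_x, out_y) {
  nx <- nrow(slice); ny <- ncol(slice)
  # voxel-centre positions of the input grid, mm
  fx <- out_x / in_spacing[1] + 0.5   # fractional input index
  fy <- out_y / in_spacing[2] + 0.5
  x0 <- pmin(pmax(floor(fx), 1), nx); x1 <- pmin(x0 + 1, nx)
  y0 <- pmin(pmax(floor(fy), 1), ny); y1 <- pmin(y0 + 1, ny)
  wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
  s00 <- slice[cbind(rep(x0, length(y0)), rep(y0, each = length(x0)))]
  s10 <- slice[cbind(rep(x1, length(y0)), rep(y0, each = length(x0)))]
  s01 <- slice[cbind(rep(x0, length(y1)), rep(y1, each = length(x0)))]
  s11 <- slice[cbind(rep(x1, length(y1)), rep(y1, each = length(x0)))]
  wxm <- rep(wx, length(y0)); wym <- rep(wy, each = length(x0))
  v <- (1 - wxm) * (1 - wym) * s00 + wxm * (1 - wym) * s10 +
    (1 - wxm) * wym * s01 + wxm * wym * s11
  matrix(v, length(out_x), length(out_y))
}

# centre-crop or zero-pad a 2-D matrix to target size, keeping the centre
crop_pad2 <- function(m, target) {
  out <- matrix(0, target[1], target[2])
  n <- dim(m)
  # source range
  s1 <- max(1L, floor((n[1] - target[1]) / 2) + 1L)
  s2 <- max(1L, floor((n[2] - target[2]) / 2) + 1L)
  e1 <- min(n[1], s1 + target[1] - 1L)
  e2 <- min(n[2], s2 + target[2] - 1L)
  # destination range
  d1 <- max(1L, floor((target[1] - n[1]) / 2) + 1L)
  d2 <- max(1L, floor((target[2] - n[2]) / 2) + 1L)
  out[d1:(d1 + (e1 - s1)), d2:(d2 + (e2 - s2))] <- m[s1:e1, s2:e2]
  out
}

#' Standardize in-plane geometry
#'
#' Resamples the two in-plane axes to the target spacing (linear
#' interpolation at voxel centres), then centre-crops or zero-pads each
#' axial slice to the target size. The through-plane axis is untouched.
#' This reproduces the common convention of fixing every axial slice to
#' 200 x 200 voxels at 0.5 mm in-plane spacing.
#'
#' @param volume a [as_volume()] (spacing required for resampling).
#' @param target_inplane target in-plane size in voxels (default 200).
#' @param target_spacing target in-plane spacing in mm (default 0.5).
#' @return A [as_volume()] of size `target_inplane x target_inplane x nz`.
#' @export
standardize_geometry <- function(volume, target_inplane = 200,
                                 target_spacing = 0.5) {
  stopifnot(is_volume(volume))
  dat <- volume$data; sp <- volume$spacing
  d <- dim(dat)
  needs_resample <- !(isTRUE(all.equal(sp[1], target_spacing)) &&
                        isTRUE(all.equal(sp[2], target_spacing)))
  if (needs_resample) {
    nx <- max(1L, round(d[1] * sp[1] / target_spacing))
    ny <- max(1L, round(d[2] * sp[2] / target_spacing))
    out_x <- (seq_len(nx) - 0.5) * target_spacing
    out_y <- (seq_len(ny) - 0.5) * target_spacing
  } else {
    nx <- d[1]; ny <- d[2]
  }
  out <- array(0, c(target_inplane, target_inplane, d[3]))
  for (z in seq_len(d[3])) {
    sl <- dat[, , z]
    if (needs_resample)
      sl <- resample_slice_linear(sl, sp[1:2], out_x, out_y)
    out[, , z] <- crop_pad2(sl, c(target_inplane, target_inplane))
  }
  as_volume(out, c(target_spacing, target_spacing, sp[3]))
}

#' Run the full preprocessing chain
#'
#' Applies the standardization pipeline in order — piecewise rescale (from
#' reference class statistics), denoise, normalize, adaptive threshold,
#' morphological opening — and returns every intermediate stage. Reference
#' WMH/vessel statistics and the reference brain-class maximum come from a
#' labelled calibration volume (on phantoms, the phantom itself).
#'
#' @param volume input [as_volume()].
#' @param brain_mask logical brain mask.
#' @param ref_stats list with elements `T` and `V` ([class_stats()] of the
#'   reference WMH and vessel classes) and `n_max_B` (reference brain-class
#'   maximum), or `NULL` to skip the rescale stage.
#' @param params a [segmentation_params()].
#' @param median_window,gaussian_sigma see [denoise()].
#' @param percentile_clip see [normalize_intensity()].
#' @return List of stages: `rescaled`, `denoised`, `normalized`,
#'   `candidate`, `opened`, `composite`, plus `volume_mm3` (opened-mask
#'   lesion volume) and `bounds`.
#' @export
wmh_preprocess <- function(volume, brain_mask, ref_stats = NULL,
                           params = segmentation_params(),
                           median_window = 3, gaussian_sigma = NULL,
                           percentile_clip = NULL) {
  stopifnot(is_volume(volume))
  m <- as_mask(brain_mask, volume)
  bounds <- NULL
  rescaled <- volume
  if (!is.null(ref_stats)) {
    n_pdf <- pdf_mode(volume, m)
    bounds <- transform_bounds(ref_stats$T, ref_stats$V, n_pdf,
                               ref_stats$n_max_B)
    rescaled <- piecewise_rescale(volume, bounds)
  }
  denoised <- denoise(rescaled, median_window, gaussian_sigma)
  normalized <- normalize_intensity(denoised, m, percentile_clip)
  candidate <- candidate_wmh(normalized, m, params$k)
  opened <- morph_open(candidate, params$structuring_radius)
  composite <- compose_input(normalized, opened,
                             array(FALSE, dim(volume$data)), params)
  list(rescaled = rescaled, denoised = denoised, normalized = normalized,
       candidate = candidate, opened = opened, composite = composite,
       volume_mm3 = lesion_volume(opened, volume$spacing), bounds = bounds)
}
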