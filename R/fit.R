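#' Fit a PSO-tuned white-matter-hyperintensity segmenter
#'
#' Tunes the adaptive-threshold segmentation stage against a reference
#' lesion mask by particle swarm optimization. The decision variables are
#' the threshold multiplier `k` (continuous) and the opening structuring
#' radius (rounded to the nearest integer in its range); the objective is
#' the (optionally weighted) Dice loss of the thresholded-and-opened
#' candidate mask against the reference. The volume is normalized once and
#' the brain-mask statistics reused across evaluations, so a fit is a few
#' hundred cheap mask operations.
#'
#' @param volume input [as_volume()] (raw or preprocessed intensities).
#' @param brain_mask logical brain mask.
#' @param reference logical reference lesion mask (non-empty) the fit
#'   targets.
#' @param search named list of `[lo, hi]` bounds for `k` (default
#'   `c(0.5, 4)`) and `radius` (default `c(1, 2)`).
#' @param swarm a [swarm_config()] without bounds, or `NULL` for the
#'   default (20 particles, 40 iterations, seed 1).
#' @param weights optional [weight_map()] (or weight array) for the
#'   weighted Dice loss objective.
#' @param median_window,gaussian_sigma denoising applied once before
#'   normalization; see [denoise()].
#' @param percentile_clip see [normalize_intensity()].
#' @return An object of class `wmh_segmenter` with components `params`
#'   (tuned [segmentation_params()]), `loss` (best Dice loss), `history`
#'   (best loss per iteration), `fitted_mask`, `dsc` (against the
#'   reference), `pso` (the optimizer result) and `call`.
#' @examples
#' ph <- make_phantom(phantom_config(shape = c(32, 32, 24), noise_sd = 0,
#'                                   bias_amplitude = 0, seed = 3))
#' fit <- wmh_segmenter(ph$volume, brain_mask_of(ph),
#'                      ph$truth_masks$definite,
#'                      swarm = swarm_config(n_particles = 8, max_iter = 10,
#'                                           seed = 1,
#'                                           bounds = rbind(c(0.5, 1),
#'                                                          c(4, 2))))
#' coef(fit)
#' @export
wmh_segmenter <- function(volume, brain_mask, reference,
                          search = list(k = c(0.5, 4), radius = c(1, 2)),
                          swarm = NULL, weights = NULL,
                          median_window = 3, gaussian_sigma = NULL,
                          percentile_clip = NULL) {
  stopifnot(is_volume(volume))
  m <- as_mask(brain_mask, volume)
  ref <- as_mask(reference, volume)
  if (!any(ref))
    stop("reference mask is empty; nothing to fit against", call. = FALSE)
  if (inherits(weights, "wmh_weight_map")) weights <- weights$weights

  denoised <- denoise(volume, median_window, gaussian_sigma)
  normalized <- normalize_intensity(denoised, m, percentile_clip)
  nd <- vol_data(normalized)
  vals <- nd[m]
  mu_b <- mean(vals); sd_b <- stats::sd(vals)

  radius_range <- round(search$radius)
  segment_at <- function(k, radius) {
    cand <- m & nd >= mu_b + k * sd_b
    morph_open(cand, radius)
  }
  objective <- function(par) {
    k <- par[1]
    radius <- max(1, round(par[2]))
    dice_loss(segment_at(k, radius) * 1, ref, weights = weights)
  }
  bounds <- rbind(c(search$k[1], radius_range[1]),
                  c(search$k[2], radius_range[2]))
  degenerate_radius <- radius_range[1] >= radius_range[2]
  if (degenerate_radius) {
    bounds <- rbind(c(search$k[1]), c(search$k[2]))
    objective1 <- function(par)
      objective(c(par[1], radius_range[1]))
  }
  if (is.null(swarm))
    swarm <- swarm_config(n_particles = 20, max_iter = 40, seed = 1L,
                          bounds = bounds)
  else if (is.null(swarm$bounds) || ncol(swarm$bounds) != ncol(bounds))
    stop("swarm config bounds must match the search dimensions",
         call. = FALSE)
  fit <- if (degenerate_radius) pso_optimize(objective1, swarm)
         else pso_optimize(objective, swarm)

  k_hat <- fit$par[1]
  radius_hat <- if (degenerate_radius) radius_range[1]
                else max(1, round(fit$par[2]))
  params <- segmentation_params(k = k_hat, structuring_radius = radius_hat)
  fitted_mask <- segment_at(k_hat, radius_hat)
  structure(list(params = params, loss = fit$value, history = fit$history,
                 fitted_mask = fitted_mask,
                 dsc = dsc(ref, fitted_mask),
                 normalized = normalized, brain_mask = m,
                 reference = ref, pso = fit,
                 median_window = median_window,
                 gaussian_sigma = gaussian_sigma,
                 percentile_clip = percentile_clip,
                 call = match.call()),
            class = "wmh_segmenter")
}

#' @export
print.wmh_segmenter <- function(x, ...) {
  cat("PSO-tuned WMH segmenter\n")
  cat(sprintf("  k = %.4f, structuring radius = %d\n",
              x$params$k, as.integer(x$params$structuring_radius)))
  cat(sprintf("  Dice loss %.4f (DSC %.4f) after %d iterations\n",
              x$loss, x$dsc, x$pso$iterations))
  invisible(x)
}

#' @export
summary.wmh_segmenter <- function(object, ...) {
  res <- list(params = object$params, loss = object$loss, dsc = object$dsc,
              iterations = object$pso$iterations,
              history = object$history,
              lesion_voxels = sum(object$fitted_mask),
              reference_voxels = sum(object$reference))
  class(res) <- "summary.wmh_segmenter"
  res
}

#' @export
print.summary.wmh_segmenter <- function(x, ...) {
  cat("PSO-tuned WMH segmenter\n")
  print(x$params)
  cat(sprintf("  best Dice loss: %.4f  (DSC %.4f)\n", x$loss, x$dsc))
  cat(sprintf("  iterations: %d  (best-loss trace length %d)\n",
              x$iterations, length(x$history)))
  cat(sprintf("  segmented voxels: %d  reference voxels: %d\n",
              x$lesion_voxels, x$reference_voxels))
  invisible(x)
}

#' @export
coef.wmh_segmenter <- function(object, ...) {
  c(k = object$params$k,
    radius = as.numeric(object$params$structuring_radius))
}

#' Segment a volume with a fitted segmenter
#'
#' Applies the tuned threshold multiplier and opening radius to a new
#' volume (denoised and normalized with the settings used at fit time), or
#' returns the fitted mask when no new data is given.
#'
#' @param object a [wmh_segmenter()] fit.
#' @param volume new [as_volume()] (optional).
#' @param brain_mask brain mask for the new volume (required with
#'   `volume`).
#' @param ... unused.
#' @return Logical segmentation mask.
#' @export
predict.wmh_segmenter <- function(object, volume = NULL, brain_mask = NULL,
                                  ...) {
  if (is.null(volume)) return(object$fitted_mask)
  stopifnot(is_volume(volume))
  if (is.null(brain_mask))
    stop("brain_mask is required when predicting on a new volume",
         call. = FALSE)
  m <- as_mask(brain_mask, volume)
  denoised <- denoise(volume, object$median_window, object$gaussian_sigma)
  normalized <- normalize_intensity(denoised, m, object$percentile_clip)
  cand <- candidate_wmh(normalized, m, object$params$k)
  morph_open(cand, object$params$structuring_radius)
}

#' @export
plot.wmh_segmenter <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "iteration", ylab = "best Dice loss",
                 main = "PSO convergence", ...)
  invisible(x)
}

#' @export
residuals.wmh_segmenter <- function(object, ...) {
  object$fitted_mask * 1 - object$reference * 1
}
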