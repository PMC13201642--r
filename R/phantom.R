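#' Tissue class codes used throughout the toolkit
#'
#' Label maps code voxels as background (0), brain tissue (1), vessel (2),
#' suspected WMH (3) and definite WMH (4). Definite WMH is the
#' high-confidence lesion core; the suspected class is the uncertain rim
#' surrounding it, which drives the distance-based weight map of the
#' weighted Dice loss.
#'
#' @return Named integer vector of class codes.
#' @export
wmh_classes <- function() {
  c(background = 0L, brain = 1L, vessel = 2L, suspected = 3L, definite = 4L)
}

#' Phantom configuration
#'
#' Describes a synthetic brain volume: an ellipsoidal brain of class
#' "brain", thin curvilinear vessels, spherical punctate lesions and blobby
#' confluent lesions (class "definite") each wrapped in a 1-voxel
#' intermediate-intensity rim (class "suspected"). Voxel intensities are
#' drawn per class from Gaussians, then corrupted by a smooth multiplicative
#' bias field and additive noise. The defaults give the separable,
#' hyperintense-lesion contrast that the intensity-standardization equations
#' assume of FLAIR-like images.
#'
#' @param shape integer vector of 3 voxel counts per axis.
#' @param spacing mm per voxel along each axis; positive.
#' @param class_means,class_sds named numeric vectors over
#'   `names(wmh_classes())`: per-class intensity mean and standard
#'   deviation. By default definite WMH (150) is hyperintense relative to
#'   brain tissue (100); this ordering is asserted unless
#'   `assert_hyperintense = FALSE`.
#' @param n_punctate number of small spherical lesions.
#' @param n_confluent number of larger multi-sphere confluent lesions.
#' @param lesion_radius_range mm; radii are drawn uniformly in this range.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param bias_amplitude amplitude of the smooth multiplicative bias field
#'   (0 disables it); the field varies in `1 +/- bias_amplitude`.
#' @param rician if `TRUE`, noise is Rician (magnitude of two Gaussian
#'   channels) instead of additive Gaussian.
#' @param n_vessels number of curvilinear vessel tracks.
#' @param seed integer seed making generation fully reproducible.
#' @param assert_hyperintense check that definite mean exceeds brain mean.
#' @return An object of class `wmh_phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 48),
                           spacing = c(1, 1, 1),
                           class_means = c(background = 0, brain = 100,
                                           vessel = 170, suspected = 135,
                                           definite = 150),
                           class_sds = c(background = 0, brain = 5,
                                         vessel = 6, suspected = 5,
                                         definite = 5),
                           n_punctate = 4,
                           n_confluent = 1,
                           lesion_radius_range = c(3, 5),
                           noise_sd = 2,
                           bias_amplitude = 0.05,
                           rician = FALSE,
                           n_vessels = 3,
                           seed = 1L,
                           assert_hyperintense = TRUE) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0))
    stop("shape must be 3 positive voxel counts", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values", call. = FALSE)
  cls <- names(wmh_classes())
  if (!all(cls %in% names(class_means)) || !all(cls %in% names(class_sds)))
    stop("class_means and class_sds must name every tissue class",
         call. = FALSE)
  if (any(class_sds < 0)) stop("class sds must be >= 0", call. = FALSE)
  if (any(lesion_radius_range <= 0) || length(lesion_radius_range) != 2L)
    stop("lesion_radius_range must be two positive radii (mm)", call. = FALSE)
  if (noise_sd < 0 || bias_amplitude < 0)
    stop("noise_sd and bias_amplitude must be >= 0", call. = FALSE)
  if (assert_hyperintense &&
      class_means[["definite"]] <= class_means[["brain"]])
    stop("definite-WMH mean must exceed brain mean (hyperintense lesions); ",
         "set assert_hyperintense = FALSE to override", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 class_means = class_means[cls], class_sds = class_sds[cls],
                 n_punctate = as.integer(n_punctate),
                 n_confluent = as.integer(n_confluent),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 rician = isTRUE(rician), n_vessels = as.integer(n_vessels),
                 seed = as.integer(seed)),
            class = "wmh_phantom_config")
}

# voxel-centre coordinate grids in mm
coord_grids <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# logical mask of a sphere (mm centre and radius) on the voxel grid
sphere_mask <- function(shape, spacing, centre, radius) {
  g <- coord_grids(shape, spacing)
  dx2 <- (g$x - centre[1])^2
  dy2 <- (g$y - centre[2])^2
  dz2 <- (g$z - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

#' Generate a synthetic brain phantom
#'
#' Builds the label map (ellipsoidal brain, vessels, punctate/confluent
#' definite-WMH lesions with suspected rims), draws per-class Gaussian
#' intensities, applies a smooth multiplicative bias field and noise, and
#' returns the volume together with per-class truth masks. Lesion centres
#' are rejection-sampled inside an eroded brain mask, so lesions never touch
#' the brain boundary. Generation is fully deterministic given the
#' configured seed.
#'
#' @param config a [phantom_config()].
#' @return An object of class `wmh_phantom`: list with `volume`
#'   ([as_volume()]), `labels` (integer array of [wmh_classes()] codes),
#'   `truth_masks` (named list of logical arrays per class),
#'   `true_lesion_volume` (mm^3 of definite-WMH voxels) and `config`.
#' @examples
#' ph <- make_phantom(phantom_config(shape = c(32, 32, 24), seed = 7))
#' ph$true_lesion_volume
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "wmh_phantom_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  shape <- config$shape; spacing <- config$spacing
  cls <- wmh_classes()
  labels <- array(cls[["background"]], shape)

  # ellipsoidal brain centred in the volume
  g <- coord_grids(shape, spacing)
  ctr <- vapply(g, function(v) mean(range(v)), numeric(1))
  semi <- c(diff(range(g$x)), diff(range(g$y)), diff(range(g$z))) / 2 * 0.85
  ex <- ((g$x - ctr[1]) / semi[1])^2
  ey <- ((g$y - ctr[2]) / semi[2])^2
  ez <- ((g$z - ctr[3]) / semi[3])^2
  brain <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  labels[brain] <- cls[["brain"]]

  # erode the brain mask so lesion + rim stay strictly interior
  margin_vox <- ceiling(max(config$lesion_radius_range) / min(spacing)) + 2L
  repeat {
    interior <- if (margin_vox >= 1L)
      morph_erode(brain, radius = margin_vox, shape = "ball") else brain
    interior_idx <- which(interior)
    if (length(interior_idx) > 0L || margin_vox == 0L) break
    margin_vox <- margin_vox - 1L   # small phantoms: relax the margin
  }

  definite <- array(FALSE, shape)
  draw_centre <- function() {
    if (length(interior_idx) == 0L)
      stop("phantom too small for the configured lesion radii", call. = FALSE)
    i <- interior_idx[sample.int(length(interior_idx), 1L)]
    ci <- arrayInd(i, shape)
    (as.numeric(ci) - 0.5) * spacing
  }
  rrange <- config$lesion_radius_range
  if (config$n_punctate > 0) {
    for (i in seq_len(config$n_punctate)) {
      r <- stats::runif(1, rrange[1], rrange[2])
      definite <- definite | sphere_mask(shape, spacing, draw_centre(), r)
    }
  }
  if (config$n_confluent > 0) {
    for (i in seq_len(config$n_confluent)) {
      c0 <- draw_centre()
      for (k in seq_len(3L)) {
        r <- stats::runif(1, rrange[1], rrange[2])
        jitter <- stats::runif(3, -r, r) * 0.6
        definite <- definite |
          sphere_mask(shape, spacing, c0 + jitter, r)
      }
    }
  }
  definite <- definite & brain

  # suspected WMH: 1-voxel rim of intermediate intensity around each lesion
  suspected <- morph_dilate(definite, radius = 1, shape = "ball") &
    !definite & brain

  # thin curvilinear vessels: quadratic Bezier tracks rasterised at 1 voxel
  vessel <- array(FALSE, shape)
  if (config$n_vessels > 0) {
    for (v in seq_len(config$n_vessels)) {
      pts <- replicate(3, draw_centre())   # 3 control points, mm
      tt <- seq(0, 1, length.out = 4L * max(shape))
      bez <- sapply(1:3, function(a)
        (1 - tt)^2 * pts[a, 1] + 2 * (1 - tt) * tt * pts[a, 2] + tt^2 * pts[a, 3])
      vi <- unique(round(sweep(bez, 2, spacing, "/") + 0.5))
      ok <- vi[, 1] >= 1 & vi[, 1] <= shape[1] &
        vi[, 2] >= 1 & vi[, 2] <= shape[2] &
        vi[, 3] >= 1 & vi[, 3] <= shape[3]
      vessel[vi[ok, , drop = FALSE]] <- TRUE
    }
  }
  vessel <- vessel & brain & !definite & !suspected

  labels[vessel] <- cls[["vessel"]]
  labels[suspected] <- cls[["suspected"]]
  labels[definite] <- cls[["definite"]]

  # per-class Gaussian intensities
  vol <- array(0, shape)
  for (nm in names(cls)) {
    idx <- which(labels == cls[[nm]])
    if (nm == "background" || length(idx) == 0L) next
    mu <- config$class_means[[nm]]; sd <- config$class_sds[[nm]]
    vol[idx] <- if (sd > 0) stats::rnorm(length(idx), mu, sd) else mu
  }

  # smooth multiplicative bias field: low-frequency cosine products
  if (config$bias_amplitude > 0) {
    ph <- stats::runif(3, 0, 2 * pi)
    bx <- cos(2 * pi * g$x / diff(range(g$x)) + ph[1])
    by <- cos(2 * pi * g$y / diff(range(g$y)) + ph[2])
    bz <- cos(2 * pi * g$z / diff(range(g$z)) + ph[3])
    bias <- 1 + config$bias_amplitude * outer(outer(bx, by), bz)
    vol <- vol * bias
  }

  if (config$noise_sd > 0) {
    if (config$rician) {
      n1 <- stats::rnorm(length(vol), 0, config$noise_sd)
      n2 <- stats::rnorm(length(vol), 0, config$noise_sd)
      vol <- sqrt((vol + n1)^2 + n2^2)
    } else {
      vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd)
    }
  }
  vol[labels == cls[["background"]] & vol < 0] <- 0
  dim(vol) <- shape

  truth <- lapply(cls, function(code) labels == code)
  names(truth) <- names(cls)
  vox_mm3 <- prod(spacing)
  structure(list(volume = as_volume(vol, spacing), labels = labels,
                 truth_masks = truth,
                 true_lesion_volume = sum(truth$definite) * vox_mm3,
                 config = config),
            class = "wmh_phantom")
}

#' @export
print.wmh_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<wmh_phantom> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  counts <- vapply(x$truth_masks, sum, numeric(1))
  cat("  voxels per class:", paste(names(counts), counts, sep = "=",
                                   collapse = ", "), "\n")
  cat(sprintf("  true lesion volume: %.1f mm^3\n", x$true_lesion_volume))
  invisible(x)
}

#' Brain mask of a phantom
#'
#' The union of every non-background class; a stand-in for the skull-stripped
#' brain mask an external extraction tool would provide on real data.
#'
#' @param phantom a [make_phantom()] result.
#' @return Logical 3-D array.
#' @export
brain_mask_of <- function(phantom) {
  stopifnot(inherits(phantom, "wmh_phantom"))
  phantom$labels != wmh_classes()[["background"]]
}

#' Write a phantom to disk
#'
#' Writes the intensity volume and label map as NIfTI (matching spacing)
#' plus a JSON sidecar recording the generating configuration and the true
#' lesion volume.
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "wmh_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(volume = file.path(dir, "phantom.nii.gz"),
             labels = file.path(dir, "labels.nii.gz"),
             sidecar = file.path(dir, "phantom.json"))
  write_volume(phantom$volume, paths[["volume"]])
  write_volume(as_volume(array(as.numeric(phantom$labels),
                               dim(phantom$labels)),
                         phantom$volume$spacing),
               paths[["labels"]], datatype = "uint8")
  side <- phantom$config
  class(side) <- NULL
  side$true_lesion_volume_mm3 <- phantom$true_lesion_volume
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
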