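# The evaluation battery: weighted Dice loss with distance-based weight
# maps, DSC, HD95, precision/recall/F1 (voxel and lesion level), AVD,
# PSNR/MSE, SSIM and UQI. Degenerate inputs are flagged as undefined
# rather than silently zeroed so batch evaluation never crashes.

#' Distance-based weight map for the weighted Dice loss
#'
#' Definite-WMH voxels get weight 2. Suspected voxels get `1 + f(dis)`
#' where `dis` is the Euclidean distance (mm) from the voxel to the
#' centroid of the nearest definite-WMH connected component and
#' `f(dis) = 1 - dis / dis_max` with `dis_max` the largest such distance
#' over the suspected voxels, so `f` falls from 1 (at a centroid) to 0 (at
#' the farthest suspected voxel). All other voxels get weight 1.
#'
#' @param definite logical mask of confirmed WMH (non-empty whenever
#'   `suspected` is non-empty).
#' @param suspected logical mask of the uncertain rim.
#' @param spacing mm per voxel per axis.
#' @return An object of class `wmh_weight_map`: list with `weights`
#'   (numeric array in `[1, 2]`) and `dis_max` (mm).
#' @export
weight_map <- function(definite, suspected, spacing = c(1, 1, 1)) {
  def <- as_mask(definite)
  sus <- as_mask(suspected)
  if (!identical(dim(def), dim(sus)))
    stop("definite and suspected masks must be aligned", call. = FALSE)
  w <- array(1, dim(def))
  dis_max <- 0
  if (any(sus)) {
    if (!any(def))
      stop("suspected voxels present but no definite region to anchor the ",
           "distance weighting", call. = FALSE)
    lab <- label_components3(def, connectivity = 26)
    ncomp <- max(lab)
    centroids <- t(vapply(seq_len(ncomp), function(i) {
      ci <- arrayInd(which(lab == i), dim(def))
      colMeans(sweep(ci - 0.5, 2, spacing, "*"))
    }, numeric(3)))
    si <- arrayInd(which(sus), dim(def))
    smm <- sweep(si - 0.5, 2, spacing, "*")
    d2 <- vapply(seq_len(ncomp), function(i)
      (smm[, 1] - centroids[i, 1])^2 + (smm[, 2] - centroids[i, 2])^2 +
        (smm[, 3] - centroids[i, 3])^2, numeric(nrow(smm)))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = nrow(smm))
    dis <- sqrt(apply(d2, 1, min))
    dis_max <- max(dis)
    f <- if (dis_max > 0) 1 - dis / dis_max else rep(1, length(dis))
    w[sus] <- 1 + f
  }
  w[def] <- 2
  structure(list(weights = w, dis_max = dis_max), class = "wmh_weight_map")
}

#' Dice loss
#'
#' `1 - (1/C) * sum_c 2 sum(p g) / (sum(p^2) + sum(g^2))`, averaged over
#' classes; the weighted variant multiplies per-voxel weights into both the
#' numerator and denominator sums of each class term. A perfect prediction
#' scores 0; disjoint prediction and truth score 1 per class. A class empty
#' in both prediction and truth contributes 0 loss.
#'
#' @param pred numeric array of predicted probabilities in `[0, 1]` (one
#'   class) or a list of such arrays (one per class).
#' @param truth binary array or list of binary arrays, aligned with `pred`.
#' @param weights `NULL`, a numeric weight array, or a [weight_map()];
#'   recycled over classes.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, weights = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have the same number of classes", call. = FALSE)
  if (inherits(weights, "wmh_weight_map")) weights <- weights$weights
  terms <- vapply(seq_along(pred), function(ci) {
    p <- if (is_volume(pred[[ci]])) pred[[ci]]$data else pred[[ci]]
    g <- as_mask(truth[[ci]]) * 1
    p <- p * 1
    if (!identical(dim(p), dim(g)))
      stop("pred and truth shapes differ", call. = FALSE)
    w <- if (is.null(weights)) 1 else {
      if (!identical(dim(weights), dim(p)))
        stop("weight map shape differs from pred", call. = FALSE)
      weights
    }
    num <- 2 * sum(w * p * g)
    den <- sum(w * p^2) + sum(w * g^2)
    if (den == 0) 1 else num / den   # both empty -> dice 1 -> loss 0
  }, numeric(1))
  1 - mean(terms)
}

#' Dice similarity coefficient
#'
#' `2 |G intersect P| / (|G| + |P|)`; the proportion of space shared by the
#' two masks. Two empty masks are defined to agree perfectly (DSC 1).
#'
#' @param g ground-truth binary mask.
#' @param p predicted binary mask.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(g, p) {
  gm <- as_mask(g); pm <- as_mask(p)
  if (!identical(dim(gm), dim(pm)))
    stop("masks must be aligned", call. = FALSE)
  den <- sum(gm) + sum(pm)
  if (den == 0) return(1)
  2 * sum(gm & pm) / den
}

# boundary voxels: mask minus its erosion (face-connected cross element)
mask_boundary <- function(m) {
  er <- m
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    er <- er & shift3(m, o[1], o[2], o[3], fill = FALSE)
  m & !er
}

# directed 95th-percentile boundary distance (mm), nearest-rank K=ceil(.95 N)
h95_directed <- function(from_mm, to_mm) {
  n <- nrow(from_mm)
  dmin <- vapply(seq_len(n), function(i) {
    sqrt(min((to_mm[, 1] - from_mm[i, 1])^2 +
               (to_mm[, 2] - from_mm[i, 2])^2 +
               (to_mm[, 3] - from_mm[i, 3])^2))
  }, numeric(1))
  sort(dmin)[ceiling(0.95 * n)]
}

#' 95th-percentile Hausdorff distance
#'
#' Symmetric 95th-percentile directed boundary distance in physical mm:
#' `max(h95(G, P), h95(P, G))`, where `h95` takes, over the boundary voxels
#' of one mask, the nearest-rank 95th percentile (`K = ceil(0.95 N)`) of
#' nearest-neighbour distances to the other mask's boundary. The
#' percentile masks outlier boundary excursions that make the plain
#' Hausdorff distance unstable.
#'
#' @param g,p non-empty binary masks.
#' @param spacing mm per voxel per axis.
#' @return Distance in mm.
#' @export
hd95 <- function(g, p, spacing = c(1, 1, 1)) {
  gm <- as_mask(g); pm <- as_mask(p)
  if (!identical(dim(gm), dim(pm)))
    stop("masks must be aligned", call. = FALSE)
  if (!any(gm) || !any(pm))
    stop("hd95 is undefined for empty masks", call. = FALSE)
  gb <- mask_boundary(gm); pb <- mask_boundary(pm)
  gmm <- sweep(arrayInd(which(gb), dim(gm)) - 0.5, 2, spacing, "*")
  pmm <- sweep(arrayInd(which(pb), dim(pm)) - 0.5, 2, spacing, "*")
  max(h95_directed(gmm, pmm), h95_directed(pmm, gmm))
}

#' Voxel-level precision, recall and F1
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and F1 their
#' harmonic mean, from voxel counts. A zero denominator flags the metric
#' undefined and reports it as 0.
#'
#' @param g ground-truth binary mask.
#' @param p predicted binary mask.
#' @return Named list `precision`, `recall`, `f1`, plus logical `defined`
#'   flags per metric.
#' @export
precision_recall_f1 <- function(g, p) {
  gm <- as_mask(g); pm <- as_mask(p)
  if (!identical(dim(gm), dim(pm)))
    stop("masks must be aligned", call. = FALSE)
  tp <- sum(gm & pm); fp <- sum(!gm & pm); fn <- sum(gm & !pm)
  prec_def <- (tp + fp) > 0
  rec_def <- (tp + fn) > 0
  precision <- if (prec_def) tp / (tp + fp) else 0
  recall <- if (rec_def) tp / (tp + fn) else 0
  f1_def <- prec_def && rec_def && (precision + recall) > 0
  f1 <- if (f1_def) 2 * recall * precision / (recall + precision) else 0
  list(precision = precision, recall = recall, f1 = f1,
       defined = c(precision = prec_def, recall = rec_def, f1 = f1_def))
}

#' Lesion-level detection recall and F1
#'
#' Reinterprets TP/FN over 3-D connected components (26-connectivity): a
#' ground-truth lesion counts as detected when the prediction overlaps it
#' by at least one voxel, and a predicted component with no ground-truth
#' overlap counts as a false positive.
#'
#' @param g,p binary masks.
#' @return Named list `recall`, `precision`, `f1`, `n_truth_lesions`,
#'   `n_pred_components`.
#' @export
lesion_detection <- function(g, p) {
  gm <- as_mask(g); pm <- as_mask(p)
  if (!identical(dim(gm), dim(pm)))
    stop("masks must be aligned", call. = FALSE)
  gl <- label_components3(gm, 26)
  pl <- label_components3(pm, 26)
  ng <- max(gl); np <- max(pl)
  hit_g <- if (ng > 0) vapply(seq_len(ng), function(i)
    any(pm[gl == i]), logical(1)) else logical(0)
  hit_p <- if (np > 0) vapply(seq_len(np), function(i)
    any(gm[pl == i]), logical(1)) else logical(0)
  recall <- if (ng > 0) mean(hit_g) else 0
  precision <- if (np > 0) mean(hit_p) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(recall = recall, precision = precision, f1 = f1,
       n_truth_lesions = ng, n_pred_components = np)
}

#' Average volume difference
#'
#' `|A - B| / B * 100` with `A` the segmented volume and `B` the truth
#' volume (any consistent unit).
#'
#' @param p_volume segmented volume A (> 0 not required).
#' @param g_volume ground-truth volume B (> 0).
#' @return Percentage.
#' @export
avd <- function(p_volume, g_volume) {
  if (g_volume <= 0)
    stop("ground-truth volume must be > 0", call. = FALSE)
  abs(p_volume - g_volume) / g_volume * 100
}

#' PSNR and MSE
#'
#' `MSE = mean((x - y)^2)`; `PSNR = 10 log10(k_max^2 / MSE)` in dB with
#' `k_max` the nominal peak (255 for 8-bit images). Identical images have
#' MSE 0 and PSNR `Inf`.
#'
#' @param x,y aligned numeric arrays.
#' @param k_max peak signal value (default 255).
#' @return Named list `psnr` (dB, possibly `Inf`) and `mse`.
#' @export
psnr_mse <- function(x, y, k_max = 255) {
  x <- vol_data3(x); y <- vol_data3(y)
  if (!identical(dim2(x), dim2(y)))
    stop("images must be aligned", call. = FALSE)
  mse <- mean((x - y)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(k_max^2 / mse)
  list(psnr = psnr, mse = mse)
}

# accept volume, array or matrix for image-quality metrics
vol_data3 <- function(x) {
  if (is_volume(x)) x$data else x
}
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Structural similarity index
#'
#' Mean over sliding windows (uniform `window x window`, stride 1) of
#' `((2 m1 m2 + c1)(2 cov + c2)) / ((m1^2 + m2^2 + c1)(s1^2 + s2^2 + c2))`
#' with `c1 = (k1 L)^2`, `c2 = (k2 L)^2` and `L` the dynamic range.
#' Symmetric in its arguments; 1 exactly when the images are identical.
#' Anticorrelated windows can push individual terms negative; the mean is
#' reported as computed.
#'
#' @param x,y aligned numeric matrices.
#' @param window window edge length (default 8); must fit in the image.
#' @param k1,k2 stabilizer scales (defaults 0.01, 0.03).
#' @param dynamic_range `L`; defaults to the observed joint range (or 1
#'   for constant pairs).
#' @return Scalar SSIM.
#' @export
ssim_index <- function(x, y, window = 8, k1 = 0.01, k2 = 0.03,
                       dynamic_range = NULL) {
  x <- as.matrix(vol_data3(x)); y <- as.matrix(vol_data3(y))
  if (!identical(dim(x), dim(y)))
    stop("images must be aligned", call. = FALSE)
  if (window > min(dim(x)))
    stop("window larger than image", call. = FALSE)
  if (is.null(dynamic_range)) {
    dynamic_range <- max(x, y) - min(x, y)
    if (dynamic_range == 0) dynamic_range <- 1
  }
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  # window sums via integral images
  isum <- function(m) {
    p <- matrix(0, nrow(m) + 1, ncol(m) + 1)
    # apply over rows returns its result transposed
    p[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    p
  }
  wsum <- function(p, w) {
    nr <- nrow(p) - w; nc <- ncol(p) - w
    p[(w + 1):(w + nr), (w + 1):(w + nc)] - p[1:nr, (w + 1):(w + nc)] -
      p[(w + 1):(w + nr), 1:nc] + p[1:nr, 1:nc]
  }
  n <- window^2
  sx <- wsum(isum(x), window); sy <- wsum(isum(y), window)
  sxx <- wsum(isum(x * x), window); syy <- wsum(isum(y * y), window)
  sxy <- wsum(isum(x * y), window)
  m1 <- sx / n; m2 <- sy / n
  v1 <- sxx / n - m1^2; v2 <- syy / n - m2^2
  cv <- sxy / n - m1 * m2
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  ssim_map <- ((2 * m1 * m2 + c1) * (2 * cv + c2)) /
    ((m1^2 + m2^2 + c1) * (v1 + v2 + c2))
  mean(ssim_map)
}

#' Universal quality index
#'
#' Product of three factors computed globally over the image pair: the
#' correlation coefficient, the mean-luminance similarity
#' `2 m1 m2 / (m1^2 + m2^2)`, and the contrast similarity
#' `2 s1 s2 / (s1^2 + s2^2)`. Ranges over `[-1, 1]`; equals 1 only for
#' identical images and -1 for `pred = 2 mean(gt) - gt`. Zero variance in
#' either image leaves the correlation factor undefined and the index is
#' returned as `NA`.
#'
#' @param gt ground-truth image (array, matrix or [as_volume()]).
#' @param pred predicted image, aligned with `gt`.
#' @return Scalar in `[-1, 1]`, or `NA` if undefined.
#' @seealso [uqi_factors()] for the individual factors.
#' @export
uqi <- function(gt, pred) {
  f <- uqi_factors(gt, pred)
  if (!f$defined) return(NA_real_)
  f$correlation * f$mean_similarity * f$contrast_similarity
}

#' @rdname uqi
#' @return `uqi_factors()` returns a list with `correlation`,
#'   `mean_similarity`, `contrast_similarity` and a `defined` flag (false
#'   when either image has zero variance).
#' @export
uqi_factors <- function(gt, pred) {
  g <- as.numeric(vol_data3(gt)); p <- as.numeric(vol_data3(pred))
  if (length(g) != length(p))
    stop("images must be aligned", call. = FALSE)
  n <- length(g)
  m1 <- mean(g); m2 <- mean(p)
  s1 <- sqrt(sum((g - m1)^2) / n); s2 <- sqrt(sum((p - m2)^2) / n)
  cov <- sum((g - m1) * (p - m2)) / n
  defined <- s1 > 0 && s2 > 0
  corr <- if (defined) cov / (s1 * s2) else NA_real_
  msim <- if (m1 == 0 && m2 == 0) 1 else 2 * m1 * m2 / (m1^2 + m2^2)
  csim <- if (s1 == 0 && s2 == 0) 1 else 2 * s1 * s2 / (s1^2 + s2^2)
  list(correlation = corr, mean_similarity = msim,
       contrast_similarity = csim, defined = defined)
}

#' Full evaluation report
#'
#' Runs the whole battery on a predicted mask against a truth mask (and
#' optionally an image pair for the fidelity metrics), flagging any metric
#' whose preconditions fail instead of crashing.
#'
#' @param pred predicted binary mask.
#' @param truth ground-truth binary mask.
#' @param spacing mm per voxel per axis.
#' @param image_pred,image_truth optional aligned intensity images for
#'   MSE/PSNR/SSIM/UQI (default: the masks as 0/1 images).
#' @param weights optional [weight_map()] for the weighted Dice loss.
#' @param k_max peak value for PSNR.
#' @param ssim_window SSIM window (applied slice-wise on 3-D inputs, using
#'   the central slice).
#' @return An object of class `wmh_metric_report`: named list of metric
#'   values plus a `defined` logical vector.
#' @export
metric_report <- function(pred, truth, spacing = c(1, 1, 1),
                          image_pred = NULL, image_truth = NULL,
                          weights = NULL, k_max = 255, ssim_window = 8) {
  pm <- as_mask(pred); gm <- as_mask(truth)
  if (is.null(image_pred)) image_pred <- pm * 1
  if (is.null(image_truth)) image_truth <- gm * 1
  defined <- c(dice_loss = TRUE, dsc = TRUE, hd95 = TRUE, precision = TRUE,
               recall = TRUE, f1 = TRUE, avd = TRUE, psnr = TRUE,
               mse = TRUE, ssim = TRUE, uqi = TRUE)
  dl <- dice_loss(pm * 1, gm, weights = weights)
  ds <- dsc(gm, pm)
  hd <- tryCatch(hd95(gm, pm, spacing), error = function(e) {
    defined[["hd95"]] <<- FALSE
    NA_real_
  })
  prf <- precision_recall_f1(gm, pm)
  defined[c("precision", "recall", "f1")] <- prf$defined
  av <- tryCatch(avd(sum(pm) * prod(spacing), sum(gm) * prod(spacing)),
                 error = function(e) {
                   defined[["avd"]] <<- FALSE
                   NA_real_
                 })
  pm_img <- vol_data3(image_pred); gt_img <- vol_data3(image_truth)
  pq <- psnr_mse(gt_img, pm_img, k_max)
  # SSIM on the central axial slice for 3-D input, whole image for 2-D
  to2d <- function(a) {
    if (length(dim2(a)) == 3L) a[, , ceiling(dim(a)[3] / 2)] else as.matrix(a)
  }
  ss <- tryCatch(ssim_index(to2d(gt_img), to2d(pm_img), window = ssim_window),
                 error = function(e) {
                   defined[["ssim"]] <<- FALSE
                   NA_real_
                 })
  uq <- uqi(gt_img, pm_img)
  if (is.na(uq)) defined[["uqi"]] <- FALSE
  structure(list(dice_loss = dl, dsc = ds, hd95 = hd,
                 precision = prf$precision, recall = prf$recall,
                 f1 = prf$f1, avd = av, psnr = pq$psnr, mse = pq$mse,
                 ssim = ss, uqi = uq, defined = defined),
            class = "wmh_metric_report")
}

#' @export
print.wmh_metric_report <- function(x, digits = 4, ...) {
  cat("<wmh_metric_report>\n")
  for (nm in setdiff(names(x), "defined")) {
    flag <- if (isTRUE(x$defined[[nm]])) "" else "  [undefined]"
    cat(sprintf("  %-10s %s%s\n", nm, format(signif(x[[nm]], digits)), flag))
  }
  invisible(x)
}
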