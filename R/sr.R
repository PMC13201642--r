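# Variance-gated patch routing and the three-block super-resolution
# mapping (representation -> non-linear mapping -> reconstruction), with
# its mean-squared loss and a PSO-trained desk-scale variant.

#' Super-resolution parameters
#'
#' Filter banks and biases of the three-block mapping. Layer 1
#' (representation) convolves the input with `n1` filters of spatial size
#' `f1`; layer 2 (non-linear mapping) applies `n2` 1 x 1 filters; layer 3
#' (reconstruction) applies `f3 x f3` filters producing the output
#' channels. Layers 1 and 2 are rectified; layer 3 is linear.
#'
#' @param S1 array `m x f1 x f1 x n1` (input channels, height, width,
#'   filters).
#' @param V1 numeric length `n1`.
#' @param S2 array `n1 x 1 x 1 x n2`.
#' @param V2 numeric length `n2`.
#' @param S3 array `n2 x f3 x f3 x out`.
#' @param V3 numeric length `out`.
#' @return An object of class `wmh_sr_params`.
#' @export
sr_params <- function(S1, V1, S2, V2, S3, V3) {
  chk <- function(S, nm) {
    if (!is.array(S) || length(dim(S)) != 4L)
      stop(nm, " must be a 4-D array (in, h, w, out)", call. = FALSE)
  }
  chk(S1, "S1"); chk(S2, "S2"); chk(S3, "S3")
  if (dim(S1)[4] != dim(S2)[1])
    stop("layer-1 output channels must feed layer-2 input", call. = FALSE)
  if (dim(S2)[4] != dim(S3)[1])
    stop("layer-2 output channels must feed layer-3 input", call. = FALSE)
  if (length(V1) != dim(S1)[4] || length(V2) != dim(S2)[4] ||
      length(V3) != dim(S3)[4])
    stop("bias lengths must match filter counts", call. = FALSE)
  structure(list(S1 = S1, V1 = V1, S2 = S2, V2 = V2, S3 = S3, V3 = V3),
            class = "wmh_sr_params")
}

# number of free parameters in an sr_params object
sr_n_params <- function(params) {
  sum(vapply(params, length, numeric(1)))
}

# multi-channel 2-D cross-correlation with zero same-padding.
# input: H x W x Cin array; bank: Cin x fh x fw x Cout; returns H x W x Cout
conv2_same <- function(input, bank, bias) {
  d <- dim(input)
  fh <- dim(bank)[2]; fw <- dim(bank)[3]; cout <- dim(bank)[4]
  rh <- (fh - 1) %/% 2; rw <- (fw - 1) %/% 2
  out <- array(0, c(d[1], d[2], cout))
  for (o in seq_len(cout)) {
    acc <- matrix(bias[o], d[1], d[2])
    for (ci in seq_len(d[3])) for (a in seq_len(fh)) for (b in seq_len(fw)) {
      w <- bank[ci, a, b, o]
      if (w == 0) next
      di <- a - 1L - rh; dj <- b - 1L - rw
      src <- matrix(0, d[1], d[2])
      ri <- seq_len(d[1]) + di; cj <- seq_len(d[2]) + dj
      oki <- ri >= 1 & ri <= d[1]; okj <- cj >= 1 & cj <= d[2]
      src[oki, okj] <- input[ri[oki], cj[okj], ci]
      acc <- acc + w * src
    }
    out[, , o] <- acc
  }
  out
}

#' Three-block super-resolution forward pass
#'
#' `F1 = max(0, S1 * X + V1)`, `F2 = max(0, S2 * F1 + V2)`,
#' `F = S3 * F2 + V3`, all convolutions same-padded so the output has the
#' input's spatial shape. The input is typically a bicubic-upsampled
#' low-resolution patch; the output is the reconstructed high-resolution
#' estimate.
#'
#' @param patch numeric matrix (single channel) or `H x W x C` array.
#' @param params a [sr_params()].
#' @return Matrix (if the output has one channel) or array.
#' @export
sr_forward <- function(patch, params) {
  stopifnot(inherits(params, "wmh_sr_params"))
  x <- if (is.matrix(patch)) array(patch, c(dim(patch), 1L)) else patch
  if (length(dim(x)) != 3L)
    stop("patch must be a matrix or H x W x C array", call. = FALSE)
  if (dim(x)[3] != dim(params$S1)[1])
    stop("input channels do not match S1", call. = FALSE)
  f1 <- pmax(conv2_same(x, params$S1, params$V1), 0)
  f2 <- pmax(conv2_same(f1, params$S2, params$V2), 0)
  f <- conv2_same(f2, params$S3, params$V3)
  if (dim(f)[3] == 1L) f[, , 1] else f
}

#' Super-resolution training loss
#'
#' Mean over training pairs of the sum of squared residuals between the
#' reconstruction of the (upsampled) low-resolution patch and its
#' high-resolution target.
#'
#' @param params a [sr_params()].
#' @param pairs list of `list(x = low-res-upsampled patch, y = high-res
#'   patch)`.
#' @return Scalar loss.
#' @export
sr_loss <- function(params, pairs) {
  if (length(pairs) == 0L) stop("need at least one training pair",
                                call. = FALSE)
  losses <- vapply(pairs, function(p) {
    r <- sr_forward(p$x, params) - p$y
    sum(r^2)
  }, numeric(1))
  mean(losses)
}

# flatten/unflatten sr_params to a numeric vector for the optimizer
sr_flatten <- function(params) {
  unlist(lapply(unclass(params), as.numeric), use.names = FALSE)
}

sr_unflatten <- function(vec, template) {
  out <- unclass(template)
  pos <- 0L
  for (nm in names(out)) {
    n <- length(out[[nm]])
    piece <- vec[(pos + 1L):(pos + n)]
    if (is.array(out[[nm]])) dim(piece) <- dim(out[[nm]])
    out[[nm]] <- piece
    pos <- pos + n
  }
  class(out) <- "wmh_sr_params"
  out
}

#' Train the super-resolution mapping by particle swarm optimization
#'
#' Minimizes [sr_loss()] over the free parameters of a small filter-bank
#' template using the swarm optimizer. Intended for desk-scale
#' parameterizations only; templates with more than `max_free` parameters
#' are refused (use pre-trained banks for anything larger).
#'
#' @param pairs training pairs as in [sr_loss()].
#' @param template a [sr_params()] giving the shapes to optimize.
#' @param config a [swarm_config()]; its bounds default to
#'   `[-bound, bound]` per parameter when not supplied.
#' @param bound symmetric search bound per parameter (default 4).
#' @param max_free refusal threshold on free parameters (default 50).
#' @return List with `params` (fitted [sr_params()]), `loss`, and
#'   `history` (global-best loss per iteration).
#' @export
train_sr <- function(pairs, template, config = NULL, bound = 4,
                     max_free = 50) {
  np <- sr_n_params(template)
  if (np > max_free)
    stop("template has ", np, " free parameters; the swarm trainer is ",
         "desk-scale only (<= ", max_free, "). Reduce the filter banks or ",
         "supply pre-trained bases.", call. = FALSE)
  if (is.null(config))
    config <- swarm_config(n_particles = 60, max_iter = 250,
                           stall_iter = 250,
                           bounds = matrix(c(-bound, bound), 2, np), seed = 1L)
  obj <- function(v) sr_loss(sr_unflatten(v, template), pairs)
  fit <- pso_optimize(obj, config)
  list(params = sr_unflatten(fit$par, template), loss = fit$value,
       history = fit$history)
}

#' Route image patches by variance
#'
#' Partitions the image into `patch_size x patch_size` patches (edge
#' patches may be smaller, so every pixel belongs to exactly one patch) and
#' routes each by its variance: contentful patches (variance above the
#' threshold) go to the super-resolution path, near-constant patches to the
#' plain up-sampling path.
#'
#' @param image numeric matrix.
#' @param patch_size patch edge length (default 10).
#' @param var_threshold routing threshold on the patch variance (>= 0).
#' @return List with `sr` and `upsample`, each a list of patches carrying
#'   attributes `row`/`col` (top-left position).
#' @export
route_patches <- function(image, patch_size = 10, var_threshold = 0) {
  if (var_threshold < 0) stop("var_threshold must be >= 0", call. = FALSE)
  d <- dim(image)
  rs <- seq(1L, d[1], by = patch_size)
  cs <- seq(1L, d[2], by = patch_size)
  sr <- list(); up <- list()
  for (r in rs) for (c in cs) {
    p <- image[r:min(r + patch_size - 1L, d[1]),
               c:min(c + patch_size - 1L, d[2]), drop = FALSE]
    attr(p, "row") <- r; attr(p, "col") <- c
    v <- stats::var(as.numeric(p))
    if (is.na(v)) v <- 0   # 1-pixel patch
    if (v > var_threshold) sr[[length(sr) + 1L]] <- p
    else up[[length(up) + 1L]] <- p
  }
  list(sr = sr, upsample = up)
}

#' Sobel gradient magnitude
#'
#' Magnitude of the horizontal and vertical Sobel responses, used to
#' enhance patches before quality-based selection. The response ignores
#' constant offsets and peaks along step edges.
#'
#' @param patch numeric matrix.
#' @return Matrix of the same shape (replicate-padded borders).
#' @export
sobel_enhance <- function(patch) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  d <- dim(patch)
  pad <- patch[pmin(pmax(0:(d[1] + 1), 1), d[1]),
               pmin(pmax(0:(d[2] + 1), 1), d[2]), drop = FALSE]
  gx <- matrix(0, d[1], d[2]); gy <- gx
  for (a in 1:3) for (b in 1:3) {
    sub <- pad[a:(a + d[1] - 1), b:(b + d[2] - 1), drop = FALSE]
    gx <- gx + kx[a, b] * sub
    gy <- gy + ky[a, b] * sub
  }
  sqrt(gx^2 + gy^2)
}

# Keys bicubic kernel (a = -0.5)
cubic_kernel <- function(t) {
  at <- abs(t)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

#' Bicubic up-sampling
#'
#' Separable Keys bicubic interpolation by an integer factor; the plain
#' up-sampling path for low-information patches.
#'
#' @param image numeric matrix.
#' @param factor integer magnification (>= 1).
#' @return Matrix of `factor`-times the size.
#' @export
upscale_bicubic <- function(image, factor = 2) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(image)
  interp_axis <- function(m, n_out) {
    n_in <- nrow(m)
    # output sample i (centre-aligned) falls at input position:
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    base <- floor(pos)
    out <- matrix(0, n_out, ncol(m))
    for (k in -1:2) {
      idx <- pmin(pmax(base + k, 1), n_in)
      w <- cubic_kernel(pos - (base + k))
      out <- out + w * m[idx, , drop = FALSE]
    }
    out
  }
  t(interp_axis(t(interp_axis(image, nrow(image) * factor)),
                ncol(image) * factor))
}

#' Patch-based super-resolution of an image
#'
#' Bicubic-upsamples the image, then routes the upsampled patches by
#' variance: contentful patches pass through the fitted three-block mapping
#' ([sr_forward()]), low-information patches are kept as plain upsampling.
#'
#' @param image numeric matrix (low resolution).
#' @param params a [sr_params()].
#' @param factor integer magnification.
#' @param patch_size routing patch size on the upsampled grid.
#' @param var_threshold routing threshold.
#' @return Matrix of the upsampled size.
#' @export
super_resolve <- function(image, params, factor = 2, patch_size = 10,
                          var_threshold = 0) {
  up <- upscale_bicubic(image, factor)
  routed <- route_patches(up, patch_size, var_threshold)
  out <- up
  for (p in routed$sr) {
    r <- attr(p, "row"); c <- attr(p, "col")
    rec <- sr_forward(unclass(p), params)
    out[r:(r + nrow(p) - 1L), c:(c + ncol(p) - 1L)] <- rec
  }
  out
}
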