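# Blockwise-DCT image fusion and the SRCNN-style super-resolution path.
#
# The orthonormal 2-D DCT-II pair is used throughout so that
# idct2(dct2(B)) == B exactly; block quality only depends on relative AC
# energies, which the normalization does not affect.

dct_matrix <- function(n) {
  C <- matrix(0, n, n)
  for (u in 0:(n - 1)) {
    cu <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
    C[u + 1, ] <- cu * cos((2 * (0:(n - 1)) + 1) * u * pi / (2 * n))
  }
  C
}

#' Two-dimensional DCT of a square block
#'
#' Orthonormal 2-D DCT-II (`dct2`) and its exact inverse (`idct2`). The
#' transform of a constant block has a single nonzero coefficient (the DC
#' term) and satisfies Parseval's identity: the sum of squared coefficients
#' equals the sum of squared pixels.
#'
#' @param block square numeric matrix (8 x 8 in the fusion pipeline).
#' @param coefficients square coefficient matrix from [dct2()].
#' @return Square matrix of the same size.
#' @examples
#' b <- matrix(rnorm(64), 8, 8)
#' max(abs(idct2(dct2(b)) - b)) < 1e-9
#' @export
dct2 <- function(block) {
  if (!is.matrix(block) || nrow(block) != ncol(block))
    stop("block must be a square matrix", call. = FALSE)
  C <- dct_matrix(nrow(block))
  C %*% block %*% t(C)
}

#' @rdname dct2
#' @export
idct2 <- function(coefficients) {
  if (!is.matrix(coefficients) || nrow(coefficients) != ncol(coefficients))
    stop("coefficients must be a square matrix", call. = FALSE)
  C <- dct_matrix(nrow(coefficients))
  t(C) %*% coefficients %*% C
}

#' JPEG zigzag scan order
#'
#' Row/column indices of an `n x n` block in zigzag order, running from the
#' DC term (index 1) through the AC coefficients from low to high spatial
#' frequency.
#'
#' @param n block edge length (default 8).
#' @return Integer matrix with `n^2` rows and columns `row`, `col`.
#' @export
zigzag_indices <- function(n = 8) {
  ord <- matrix(0L, n * n, 2)
  r <- 1L; c <- 1L
  up <- TRUE
  for (i in seq_len(n * n)) {
    ord[i, ] <- c(r, c)
    if (up) {
      if (c == n) { r <- r + 1L; up <- FALSE }
      else if (r == 1L) { c <- c + 1L; up <- FALSE }
      else { r <- r - 1L; c <- c + 1L }
    } else {
      if (r == n) { c <- c + 1L; up <- TRUE }
      else if (c == 1L) { r <- r + 1L; up <- TRUE }
      else { r <- r + 1L; c <- c - 1L }
    }
  }
  colnames(ord) <- c("row", "col")
  ord
}

#' Block quality from DCT coefficients
#'
#' With the DC coefficient zeroed, the 63 AC coefficients are ordered by the
#' zigzag scan and their squares summed over the low band (zigzag indices
#' 1-31) and high band (indices 32-63). The quality ratio
#' `BQ = H / (L + eps)` is large for blocks rich in high-frequency detail
#' (sharp content) and small for blurred blocks; it is capped at `1/eps`.
#'
#' @param coefficients 8 x 8 (or `n x n`) DCT coefficient matrix.
#' @param eps stabilizer added to the denominator (default 1e-12).
#' @return An object of class `wmh_block_quality`: list with `low` (L),
#'   `high` (H) and `bq`.
#' @export
block_quality <- function(coefficients, eps = 1e-12) {
  n <- nrow(coefficients)
  if (length(coefficients) < 2L)
    stop("need at least a 2 x 2 coefficient block", call. = FALSE)
  zz <- zigzag_indices(n)
  v <- coefficients[zz]        # zigzag-ordered; v[1] is DC
  ac2 <- v[-1]^2
  half <- length(ac2) %/% 2L   # low band: zigzag 1-31 for 8x8
  L <- sum(ac2[seq_len(half)])
  H <- sum(ac2[(half + 1L):length(ac2)])
  bq <- min(H / (L + eps), 1 / eps)
  structure(list(low = L, high = H, bq = bq), class = "wmh_block_quality")
}

# pad a matrix to multiples of `b` by edge replication
pad_to_blocks <- function(m, b) {
  d <- dim(m)
  nr <- ceiling(d[1] / b) * b
  nc <- ceiling(d[2] / b) * b
  m[pmin(seq_len(nr), d[1]), pmin(seq_len(nc), d[2]), drop = FALSE]
}

# per-block BQ map of an image (rows x cols of blocks)
bq_map <- function(img, block_size = 8, eps = 1e-12) {
  p <- pad_to_blocks(img, block_size)
  nbr <- nrow(p) / block_size; nbc <- ncol(p) / block_size
  out <- matrix(0, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    blk <- p[((i - 1) * block_size + 1):(i * block_size),
             ((j - 1) * block_size + 1):(j * block_size)]
    out[i, j] <- block_quality(dct2(blk), eps)$bq
  }
  out
}

# 3x3 majority vote over a logical decision map; ties keep the original
majority_vote3 <- function(dec) {
  nr <- nrow(dec); nc <- ncol(dec)
  votes <- matrix(0, nr, nc); tot <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    valid_i <- seq_len(nr) + di >= 1 & seq_len(nr) + di <= nr
    valid_j <- seq_len(nc) + dj >= 1 & seq_len(nc) + dj <= nc
    vm <- outer(valid_i, valid_j, "&")
    sh <- dec[ri, cj, drop = FALSE]
    votes <- votes + sh * vm
    tot <- tot + vm
  }
  out <- dec
  out[votes * 2 > tot] <- TRUE
  out[votes * 2 < tot] <- FALSE
  out
}

#' Fuse two images by blockwise DCT block quality
#'
#' Both images are partitioned into 8 x 8 blocks (edge-replicated to a
#' multiple of 8), each block transformed by the orthonormal 2-D DCT, and
#' for every block position the source with the greater block quality
#' ([block_quality()]) wins; ties go to image A. A consistency-verification
#' step smooths the binary decision map by a 3 x 3 majority vote before the
#' winning blocks' full coefficient sets (DC included) are inverse
#' transformed and cropped back to the original shape.
#'
#' @param image_a,image_b numeric matrices of equal shape.
#' @param block_size block edge length (default 8).
#' @param consistency apply the 3 x 3 majority-vote smoothing (default
#'   `TRUE`).
#' @param eps block-quality stabilizer.
#' @return An object of class `wmh_fusion`: list with `fused` (matrix,
#'   original shape), `decision` (logical block map, `TRUE` where A won),
#'   `bq_a`, `bq_b` (per-block quality maps).
#' @export
fuse_images <- function(image_a, image_b, block_size = 8,
                        consistency = TRUE, eps = 1e-12) {
  if (!identical(dim(image_a), dim(image_b)))
    stop("images must have identical shapes", call. = FALSE)
  d <- dim(image_a)
  pa <- pad_to_blocks(image_a, block_size)
  pb <- pad_to_blocks(image_b, block_size)
  nbr <- nrow(pa) / block_size; nbc <- ncol(pa) / block_size
  bqa <- matrix(0, nbr, nbc); bqb <- matrix(0, nbr, nbc)
  ca <- vector("list", nbr * nbc); cb <- vector("list", nbr * nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    ri <- ((i - 1) * block_size + 1):(i * block_size)
    cj <- ((j - 1) * block_size + 1):(j * block_size)
    da <- dct2(pa[ri, cj]); db <- dct2(pb[ri, cj])
    ca[[(j - 1) * nbr + i]] <- da; cb[[(j - 1) * nbr + i]] <- db
    bqa[i, j] <- block_quality(da, eps)$bq
    bqb[i, j] <- block_quality(db, eps)$bq
  }
  decision <- bqa >= bqb          # TRUE -> take A; tie -> A
  if (consistency) decision <- majority_vote3(decision)
  fused <- matrix(0, nrow(pa), ncol(pa))
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    ri <- ((i - 1) * block_size + 1):(i * block_size)
    cj <- ((j - 1) * block_size + 1):(j * block_size)
    coefs <- if (decision[i, j]) ca[[(j - 1) * nbr + i]]
             else cb[[(j - 1) * nbr + i]]
    fused[ri, cj] <- idct2(coefs)
  }
  structure(list(fused = fused[seq_len(d[1]), seq_len(d[2]), drop = FALSE],
                 decision = decision, bq_a = bqa, bq_b = bqb),
            class = "wmh_fusion")
}

#' @export
print.wmh_fusion <- function(x, ...) {
  cat(sprintf("<wmh_fusion> %d x %d image, %d x %d blocks (%.0f%% from A)\n",
              nrow(x$fused), ncol(x$fused), nrow(x$decision),
              ncol(x$decision), 100 * mean(x$decision)))
  invisible(x)
}
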