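# Shared fixtures: small phantoms and independent oracles.

# tight-spread, zero-noise phantom: the separable-class condition under
# which the intensity-standardization chain should recover lesions cleanly
separable_phantom <- function(seed = 3, shape = c(48, 48, 32)) {
  make_phantom(phantom_config(
    shape = shape, noise_sd = 0, bias_amplitude = 0,
    class_sds = c(background = 0, brain = 2, vessel = 2,
                  suspected = 2, definite = 2),
    seed = seed))
}

small_phantom <- function(seed = 7, ...) {
  make_phantom(phantom_config(shape = c(32, 32, 24), seed = seed, ...))
}

# Independent 2-D orthonormal DCT-II oracle: direct double-loop evaluation
# of the basis sums, no matrix factorization shared with the implementation.
naive_dct2 <- function(block) {
  n <- nrow(block)
  out <- matrix(0, n, n)
  cu <- function(u) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    s <- 0
    for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
      s <- s + block[x + 1, y + 1] *
        cos((2 * x + 1) * u * pi / (2 * n)) *
        cos((2 * y + 1) * v * pi / (2 * n))
    }
    out[u + 1, v + 1] <- cu(u) * cu(v) * s
  }
  out
}

# Independent zigzag derivation: sort by anti-diagonal; odd diagonals walk
# with increasing row, even diagonals with decreasing row.
naive_zigzag <- function(n) {
  g <- expand.grid(u = 0:(n - 1), v = 0:(n - 1))
  s <- g$u + g$v
  g <- g[order(s, ifelse(s %% 2 == 1, g$u, -g$u)), ]
  cbind(row = g$u + 1L, col = g$v + 1L)
}

# Independent block-quality oracle built on the naive DCT and zigzag sort.
naive_bq <- function(block, eps = 1e-12) {
  co <- naive_dct2(block)
  v <- co[naive_zigzag(nrow(co))]
  ac2 <- v[-1]^2
  L <- sum(ac2[1:31]); H <- sum(ac2[32:63])
  min(H / (L + eps), 1 / eps)
}

# 3-voxel-wide toy arrays for the hand-worked metric cases
arr3 <- function(x, d = c(length(x), 1, 1)) array(x, d)

# Gaussian blur of a 2-D slice via the package-independent stats::filter-free
# path: simple separable convolution with edge replication.
blur2 <- function(sl, sigma = 1.5) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  convax <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      idx <- pmin(pmax(seq_len(nrow(m)) + i - 1 - r, 1), nrow(m))
      out <- out + k[i] * m[idx, , drop = FALSE]
    }
    out
  }
  t(convax(t(convax(sl))))
}
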