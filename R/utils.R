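# Internal array helpers shared across modules.

# Shift a 3-D array by integer offsets, filling exposed planes with `fill`.
shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  xin <- sx - dx; yin <- sy - dy; zin <- sz - dz
  okx <- xin >= 1 & xin <= d[1]
  oky <- yin >= 1 & yin <= d[2]
  okz <- zin >= 1 & zin <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[xin[okx], yin[oky], zin[okz]]
  out
}

# Offsets of a structuring element: "ball" keeps |offset| <= radius in voxel
# units, "box" keeps the full cube of half-width radius.
struct_offsets <- function(radius, shape = c("ball", "box")) {
  shape <- match.arg(shape)
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  if (shape == "ball")
    g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  g
}

# Connected components of a 3-D logical mask (6 or 26 connectivity).
# Returns an integer array: 0 outside, component id inside.
label_components3 <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(connectivity %in% c(6, 26))
  off <- struct_offsets(1, if (connectivity == 26) "box" else "ball")
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), , drop = FALSE]
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  coords <- arrayInd(idx, d)
  # map linear index -> row of coords for O(1) membership
  inside <- array(FALSE, d); inside[idx] <- TRUE
  nxt <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (o in seq_len(nrow(off))) {
        x <- ci[1] + off$dx[o]; y <- ci[2] + off$dy[o]; z <- ci[3] + off$dz[o]
        if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3]) next
        li <- x + (y - 1L) * strides[2] + (z - 1L) * strides[3]
        if (inside[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# md5 of an R object via its serialization, for run manifests.
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
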