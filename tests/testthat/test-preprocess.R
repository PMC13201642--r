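test_that("class statistics match hand-computed values", {
  lab <- arr3(rep(1L, 4))
  s <- class_stats(arr3(c(1, 2, 3, 4)), lab, 1L)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(1.25))          # population divisor N
  expect_equal(s$n, 4)
  expect_equal(s$max_intensity, 4)
  expect_equal(sum(s$histogram$counts), s$n)

  const <- class_stats(arr3(rep(5, 10)), arr3(rep(2L, 10)), 2L)
  expect_equal(const$mean, 5)
  expect_equal(const$sd, 0)
  expect_equal(const$max_intensity, 5)

  expect_error(class_stats(arr3(1:4), lab, 9L), "no voxels")
})

test_that("pdf_mode finds the dominant histogram bin with low tie-break", {
  vals <- c(rep(100, 90), seq(0, 80, length.out = 10))
  v <- arr3(vals)
  m <- arr3(rep(TRUE, length(vals)))
  expect_lt(abs(pdf_mode(v, m) - 100), (100 - 0) / 256)

  # bimodal 70/30: mode in the dominant component
  set.seed(1)
  vals2 <- c(rnorm(700, 40, 1), rnorm(300, 80, 1))
  expect_lt(abs(pdf_mode(arr3(vals2), arr3(rep(TRUE, 1000))) - 40), 2)

  # exact tie between two bins: lower-intensity bin wins
  v3 <- arr3(c(0, 0, 10, 10))
  expect_lt(pdf_mode(v3, arr3(rep(TRUE, 4)), n_bins = 2), 5)

  expect_error(pdf_mode(v, arr3(rep(FALSE, length(vals)))), "empty")
})

test_that("transform bounds follow the shifted three-sigma rule", {
  st <- list(mean = 120, sd = 10)
  sv <- list(mean = 140, sd = 5)
  b <- transform_bounds(st, sv, n_pdf = 100, n_max_B = 150)
  expect_equal(b$p_min, 40)     # (100-150+120) - 30
  expect_equal(b$p_max, 105)    # (100-150+140) + 15

  # no shift when the mode equals the reference brain maximum
  b2 <- transform_bounds(st, sv, n_pdf = 150, n_max_B = 150)
  expect_equal(b2$p_min, 120 - 30)

  expect_error(transform_bounds(list(mean = 100, sd = 0),
                                list(mean = 100, sd = 0),
                                n_pdf = 150, n_max_B = 150),
               "degenerate")
})

test_that("piecewise rescale maps the bounds to [1, 255] and clips to 0", {
  b <- transform_bounds(list(mean = 130, sd = 10),
                        list(mean = 170, sd = 10), 100, 100)
  # p_min = 100, p_max = 200
  v <- arr3(c(100, 150, 200, 99.9, 200.1, 0))
  out <- piecewise_rescale(v, b)
  expect_equal(out[1:3], c(1, 128, 255))
  expect_equal(out[4:6], c(0, 0, 0))

  # monotone non-decreasing inside the stretch range
  xs <- arr3(seq(100, 200, length.out = 50))
  ys <- piecewise_rescale(xs, b)
  expect_true(all(diff(as.numeric(ys)) >= 0))
  expect_true(all(ys >= 1 & ys <= 255))
})

test_that("median filter removes an isolated impulse", {
  v <- array(10, c(7, 7, 7))
  v[4, 4, 4] <- 1000
  out <- denoise(v, median_window = 3)
  # direct evaluation over the 27-voxel window: median of 26 tens and one
  # impulse is 10 everywhere
  expect_equal(out, array(10, c(7, 7, 7)))
  expect_error(denoise(v, median_window = 2), "odd")
  # constant volume unchanged by both filters
  cv <- array(3, c(6, 6, 6))
  expect_equal(denoise(cv, 3, gaussian_sigma = 0.8), cv)
})

test_that("gaussian smoothing preserves the mean of an interior plateau", {
  set.seed(2)
  v <- array(rnorm(10^3, mean = 50, sd = 1), c(10, 10, 10))
  out <- denoise(v, median_window = 1, gaussian_sigma = 0.7)
  # normalized kernel: smoothing is an average, global mean is conserved up
  # to edge replication effects
  expect_lt(abs(mean(out) - mean(v)), 0.05)
  expect_lt(stats::sd(out), stats::sd(v))
})

test_that("normalization hits exactly [0, 1] and rejects constant input", {
  ph <- small_phantom()
  m <- brain_mask_of(ph)
  out <- normalize_intensity(ph$volume, m)
  expect_equal(min(out$data), 0)
  expect_equal(max(out$data), 1)
  # affine in the input: perfectly correlated
  expect_equal(stats::cor(as.numeric(out$data),
                          as.numeric(ph$volume$data)), 1)
  expect_error(normalize_intensity(arr3(rep(4, 8)), arr3(rep(TRUE, 8))),
               "zero variance")
  # percentile clipping changes the standardization but keeps the range
  out2 <- normalize_intensity(ph$volume, m, percentile_clip = c(2, 95))
  expect_equal(range(out2$data), c(0, 1))
})

test_that("adaptive threshold behaves at its extremes", {
  ph <- separable_phantom()
  m <- brain_mask_of(ph)
  nd <- normalize_intensity(ph$volume, m)
  at_mean <- candidate_wmh(nd, m, 0)
  vals <- nd$data[m]
  expect_equal(sum(at_mean), sum(vals >= mean(vals)))
  expect_equal(sum(candidate_wmh(nd, m, 1e6)), 0)
  # separated lesions: candidates cover the lesions without grabbing
  # typical brain tissue
  cand <- candidate_wmh(nd, m, 2.5)
  expect_gt(sum(cand & ph$truth_masks$definite) /
              sum(ph$truth_masks$definite), 0.95)
  expect_lt(sum(cand & ph$truth_masks$brain) / sum(ph$truth_masks$brain),
            0.01)
})

test_that("morphological opening removes specks and keeps solid shapes", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  expect_equal(sum(morph_open(m, 1)), 0)

  cube <- array(FALSE, c(13, 13, 13))
  cube[3:11, 3:11, 3:11] <- TRUE
  expect_equal(morph_open(cube, 1, shape = "box"), cube)

  empty <- array(FALSE, c(5, 5, 5))
  expect_equal(sum(morph_open(empty, 1)), 0)
})

test_that("opening is idempotent and bounded by dilation", {
  ph <- small_phantom(seed = 11)
  m <- ph$truth_masks$definite
  o1 <- morph_open(m, 1)
  expect_equal(morph_open(o1, 1), o1)
  expect_true(all(!o1 | morph_dilate(m, 1)))   # open(M) subset dilate(M)
})

test_that("lesion volume multiplies counts by voxel volume", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:4, 1:5, 1:5] <- TRUE   # 100 voxels
  expect_equal(lesion_volume(m, c(1, 1, 1)), 100)
  m2 <- array(FALSE, c(2, 2, 2))
  m2[] <- TRUE               # 8 voxels
  expect_equal(lesion_volume(m2, c(0.5, 0.5, 1)), 2)
  expect_equal(lesion_volume(array(FALSE, c(3, 3, 3))), 0)
})

test_that("composite input blends tissue channels pointwise", {
  v <- array(c(0.2, 0.4, 0.6, 0.8), c(2, 2, 1))
  wm <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
  vs <- array(c(FALSE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(compose_input(v, wm, vs, c(1, 0, 0)), v)
  expect_equal(compose_input(v, wm, vs, c(0, 1, 0)), wm * 1)
  out <- compose_input(v, wm, vs,
                       segmentation_params(weights = c(w_B = 0.5, w_T = 0.25,
                                                       w_V = 0.25)))
  expect_equal(out, 0.5 * v + 0.25 * wm + 0.25 * vs)
  expect_error(compose_input(v, array(TRUE, c(3, 3, 1)), vs, c(1, 0, 0)))
})

test_that("geometry standardization fixes in-plane size and spacing", {
  v <- as_volume(array(stats::rnorm(181 * 217 * 3), c(181, 217, 3)),
                 spacing = c(1, 1, 3))
  out <- standardize_geometry(v)
  expect_equal(dim(out$data), c(200, 200, 3))
  expect_equal(out$spacing, c(0.5, 0.5, 3))

  # already on target: unchanged
  v2 <- as_volume(array(stats::rnorm(200 * 200 * 2), c(200, 200, 2)),
                  spacing = c(0.5, 0.5, 6))
  out2 <- standardize_geometry(v2)
  expect_equal(out2$data, v2$data)

  # 256 x 256 at target spacing: pure centre crop, centroid preserved
  big <- array(0, c(256, 256, 1))
  big[121:136, 121:136, 1] <- 1
  v3 <- as_volume(big, spacing = c(0.5, 0.5, 1))
  out3 <- standardize_geometry(v3)
  expect_equal(dim(out3$data), c(200, 200, 1))
  ci_in <- colMeans(which(big == 1, arr.ind = TRUE))[1:2]
  ci_out <- colMeans(which(out3$data == 1, arr.ind = TRUE))[1:2]
  expect_lt(max(abs((ci_in - 28) - ci_out)), 1)   # crop offset 28 voxels
})

test_that("standardization chain recovers lesions on a separable phantom", {
  ph <- separable_phantom()
  m <- brain_mask_of(ph)
  cls <- wmh_classes()
  ref <- list(T = class_stats(ph$volume, ph$labels, cls[["definite"]]),
              V = class_stats(ph$volume, ph$labels, cls[["vessel"]]),
              n_max_B = class_stats(ph$volume, ph$labels,
                                    cls[["brain"]])$max_intensity)
  best <- 0
  for (k in seq(0.5, 4, by = 0.25)) {
    st <- wmh_preprocess(ph$volume, m, ref,
                         segmentation_params(k = k, structuring_radius = 1),
                         median_window = 1)
    best <- max(best, dsc(ph$truth_masks$definite, st$opened))
  }
  expect_gte(best, 0.95)
})
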