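test_that("weight map assigns 2 on definite and decays over suspected", {
  def <- array(FALSE, c(11, 11, 11))
  def[5:7, 5:7, 5:7] <- TRUE
  sus <- morph_dilate(def, 1) & !def
  wm <- weight_map(def, sus, c(1, 1, 1))
  expect_true(all(wm$weights[def] == 2))
  expect_true(all(wm$weights[!def & !sus] == 1))
  expect_true(all(wm$weights[sus] >= 1 & wm$weights[sus] <= 2))
  # the farthest suspected voxel sits exactly at dis_max: weight 1
  expect_equal(min(wm$weights[sus]), 1)

  # a suspected voxel at a definite centroid has dis = 0: weight 2.
  # a diagonal-connected ring of definite voxels around (5, 5, 5) forms a
  # single component whose centroid is the (empty) ring centre
  def2 <- array(FALSE, c(9, 9, 9))
  def2[cbind(c(4, 6, 5, 5), c(5, 5, 4, 6), 5)] <- TRUE
  sus2 <- array(FALSE, c(9, 9, 9))
  sus2[5, 5, 5] <- TRUE                 # coincides with the centroid
  sus2[5, 8, 5] <- TRUE                 # a distant rim voxel
  wm2 <- weight_map(def2, sus2, c(1, 1, 1))
  expect_equal(wm2$weights[5, 5, 5], 2)
  expect_equal(wm2$weights[5, 8, 5], 1)

  # suspected without definite is ill-posed
  sus3 <- array(FALSE, c(3, 3, 3)); sus3[2, 2, 2] <- TRUE
  expect_error(weight_map(array(FALSE, c(3, 3, 3)), sus3), "definite")
})

test_that("dice loss reproduces hand-worked values", {
  p <- arr3(c(1, 1, 0, 0))
  g <- arr3(c(1, 0, 0, 0))
  expect_equal(dice_loss(p, g), 1 - 2 / 3)
  expect_equal(dice_loss(g, g), 0)
  expect_equal(dice_loss(arr3(c(1, 0, 0, 0)), arr3(c(0, 1, 0, 0))), 1)
  # uniform unit weights change nothing
  expect_equal(dice_loss(p, g, weights = array(1, c(4, 1, 1))),
               dice_loss(p, g))
  # the definite-voxel weight emphasizes core disagreement
  w <- array(1, c(4, 1, 1)); w[1] <- 2
  expect_equal(dice_loss(p, g, weights = w), 1 - (2 * 2) / (2 * 1 + 1 + 2))
  # both empty: zero loss
  z <- arr3(rep(0, 4))
  expect_equal(dice_loss(z, z), 0)
  expect_error(dice_loss(p, arr3(c(1, 0))), "shape")
})

test_that("dsc matches set arithmetic and handles empties", {
  g <- array(FALSE, c(4, 4, 1)); g[1:4, 1, 1] <- TRUE           # |G| = 4
  p <- array(FALSE, c(4, 4, 1)); p[1:3, 1, 1] <- TRUE
  p[1:3, 2, 1] <- TRUE                                          # |P| = 6
  # |G ∩ P| = 3 -> 2*3 / 10
  expect_equal(dsc(g, p), 0.6)
  expect_equal(dsc(g, g), 1)
  q <- array(FALSE, c(4, 4, 1)); q[1, 4, 1] <- TRUE
  expect_equal(dsc(g, q), 0)
  e <- array(FALSE, c(4, 4, 1))
  expect_equal(dsc(e, e), 1)
})

test_that("dsc equals the f1 computed from the same voxel counts", {
  set.seed(50)
  for (i in 1:10) {
    g <- array(stats::runif(125) < 0.3, c(5, 5, 5))
    p <- array(stats::runif(125) < 0.3, c(5, 5, 5))
    if (!any(g) || !any(p)) next
    prf <- precision_recall_f1(g, p)
    expect_equal(dsc(g, p), prf$f1, tolerance = 1e-12)
  }
})

test_that("hd95 measures boundary distances in millimetres", {
  a <- array(FALSE, c(12, 12, 12)); a[3, 3, 3] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[8, 3, 3] <- TRUE
  expect_equal(hd95(a, b, c(1, 1, 1)), 5)     # single 5 mm gap
  expect_equal(hd95(a, a), 0)
  expect_error(hd95(a, array(FALSE, c(12, 12, 12))), "empty")
  # symmetry and linear scaling with isotropic spacing
  set.seed(51)
  g <- morph_dilate(array(stats::runif(5^3) < 0.05, c(5, 5, 5)), 1)
  p <- morph_dilate(array(stats::runif(5^3) < 0.05, c(5, 5, 5)), 1)
  if (any(g) && any(p)) {
    expect_equal(hd95(g, p), hd95(p, g))
    expect_equal(hd95(g, p, c(2, 2, 2)), 2 * hd95(g, p, c(1, 1, 1)))
  }
})

test_that("precision/recall/f1 match hand counts and flag degeneracies", {
  g <- array(FALSE, c(6, 1, 1)); g[1:5, 1, 1] <- TRUE
  p <- array(FALSE, c(6, 1, 1)); p[c(1:3, 6), 1, 1] <- TRUE
  # TP 3, FP 1, FN 2
  prf <- precision_recall_f1(g, p)
  expect_equal(prf$precision, 0.75)
  expect_equal(prf$recall, 0.6)
  expect_equal(prf$f1, 2 * 0.6 * 0.75 / 1.35)
  expect_equal(round(prf$f1, 4), 0.6667)

  same <- precision_recall_f1(g, g)
  expect_equal(c(same$precision, same$recall, same$f1), c(1, 1, 1))

  empty_pred <- precision_recall_f1(g, array(FALSE, c(6, 1, 1)))
  expect_equal(empty_pred$recall, 0)
  expect_false(empty_pred$defined[["precision"]])
})

test_that("lesion-level detection counts connected components", {
  g <- array(FALSE, c(12, 12, 4))
  g[2:3, 2:3, 2] <- TRUE       # lesion 1
  g[9:10, 9:10, 2] <- TRUE     # lesion 2
  p <- array(FALSE, c(12, 12, 4))
  p[2, 2, 2] <- TRUE           # clips lesion 1 only
  det <- lesion_detection(g, p)
  expect_equal(det$n_truth_lesions, 2)
  expect_equal(det$recall, 0.5)
  expect_equal(det$precision, 1)
})

test_that("avd reproduces the worked percentage", {
  expect_equal(avd(120, 100), 20)
  expect_equal(avd(100, 100), 0)
  expect_error(avd(10, 0), "> 0")
})

test_that("psnr and mse match hand evaluation", {
  x <- matrix(c(10, 10, 10, 10), 2, 2)
  y <- matrix(c(10, 12, 12, 10), 2, 2)
  pm <- psnr_mse(x, y)
  expect_equal(pm$mse, 2)
  same <- psnr_mse(x, x)
  expect_equal(same$mse, 0)
  expect_equal(same$psnr, Inf)
  # uniform difference of 16 at k_max 255
  u <- psnr_mse(matrix(0, 3, 3), matrix(16, 3, 3))
  expect_equal(u$psnr, 10 * log10(255^2 / 256))
  expect_equal(round(u$psnr, 2), 24.05)
})

test_that("ssim is 1 for identical images and symmetric", {
  set.seed(52)
  x <- matrix(stats::runif(16 * 16), 16, 16)
  y <- matrix(stats::runif(16 * 16), 16, 16)
  expect_equal(ssim_index(x, x), 1)
  expect_equal(ssim_index(x, y), ssim_index(y, x))
  expect_error(ssim_index(x[1:4, 1:4], y[1:4, 1:4], window = 8), "window")
  # two constant images: only the luminance factor differs from 1
  a <- matrix(2, 8, 8); b <- matrix(5, 8, 8)
  L <- 3; c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  expect_equal(ssim_index(a, b), (2 * 2 * 5 + c1) / (4 + 25 + c1))
})

test_that("uqi attains its stated extremes and factors", {
  set.seed(53)
  g <- matrix(stats::runif(64), 8, 8)
  expect_equal(uqi(g, g), 1)
  expect_equal(uqi(g, 2 * mean(g) - g), -1)
  # term-by-term check on the 4-pixel toy pair
  gt <- matrix(c(1, 2, 3, 4), 2, 2)
  pr <- matrix(c(1, 2, 3, 5), 2, 2)
  f <- uqi_factors(gt, pr)
  m1 <- mean(gt); m2 <- mean(pr)
  s1 <- sqrt(mean((gt - m1)^2)); s2 <- sqrt(mean((pr - m2)^2))
  cv <- mean((gt - m1) * (pr - m2))
  expect_equal(f$correlation, cv / (s1 * s2))
  expect_equal(f$mean_similarity, 2 * m1 * m2 / (m1^2 + m2^2))
  expect_equal(f$contrast_similarity, 2 * s1 * s2 / (s1^2 + s2^2))
  expect_equal(uqi(gt, pr),
               f$correlation * f$mean_similarity * f$contrast_similarity)
  # zero variance is flagged undefined
  expect_true(is.na(uqi(matrix(1, 3, 3), g[1:3, 1:3])))
})

test_that("uqi depends only on joint pixel statistics", {
  set.seed(54)
  x <- matrix(stats::runif(100), 10, 10)
  y <- matrix(stats::runif(100), 10, 10)
  perm <- sample(100)
  expect_equal(uqi(x, y), uqi(matrix(x[perm], 10), matrix(y[perm], 10)))
})

test_that("the full report hits ideal values on truth vs truth", {
  ph <- small_phantom(seed = 61)
  truth <- ph$truth_masks$definite
  rep <- metric_report(truth, truth, spacing = ph$volume$spacing,
                       image_pred = ph$volume$data,
                       image_truth = ph$volume$data)
  expect_equal(rep$dice_loss, 0)
  expect_equal(rep$dsc, 1)
  expect_equal(rep$hd95, 0)
  expect_equal(rep$avd, 0)
  expect_equal(rep$mse, 0)
  expect_equal(rep$psnr, Inf)
  expect_equal(rep$ssim, 1)
  expect_equal(rep$uqi, 1)
  expect_true(all(rep$defined))
})

test_that("the report flags undefined metrics instead of failing", {
  ph <- small_phantom(seed = 62)
  truth <- ph$truth_masks$definite
  empty <- array(FALSE, dim(truth))
  rep <- metric_report(empty, truth, spacing = ph$volume$spacing)
  expect_false(rep$defined[["hd95"]])
  expect_false(rep$defined[["precision"]])
  expect_equal(rep$recall, 0)
})
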