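identity_params <- function() {
  sr_params(S1 = array(1, c(1, 1, 1, 1)), V1 = 0,
            S2 = array(1, c(1, 1, 1, 1)), V2 = 0,
            S3 = array(1, c(1, 1, 1, 1)), V3 = 0)
}

test_that("the forward pass reproduces hand-evaluated layer algebra", {
  p <- identity_params()
  x <- matrix(c(0.3, 0.7, 0.1, 0.9), 2, 2)
  expect_equal(sr_forward(x, p), x)   # identity configuration

  # zero filters and biases: zero output
  pz <- sr_params(S1 = array(0, c(1, 1, 1, 1)), V1 = 0,
                  S2 = array(0, c(1, 1, 1, 1)), V2 = 0,
                  S3 = array(0, c(1, 1, 1, 1)), V3 = 0)
  expect_equal(sr_forward(x, pz), matrix(0, 2, 2))

  # weights (2, 1, 0.5), biases (-1, 0, 0) on constant 3:
  # F1 = max(0, 2*3 - 1) = 5; F2 = 5; F = 2.5
  pw <- sr_params(S1 = array(2, c(1, 1, 1, 1)), V1 = -1,
                  S2 = array(1, c(1, 1, 1, 1)), V2 = 0,
                  S3 = array(0.5, c(1, 1, 1, 1)), V3 = 0)
  expect_equal(sr_forward(matrix(3, 4, 4), pw), matrix(2.5, 4, 4))

  # rectification clips negative pre-activations
  pn <- sr_params(S1 = array(1, c(1, 1, 1, 1)), V1 = -10,
                  S2 = array(1, c(1, 1, 1, 1)), V2 = 0,
                  S3 = array(1, c(1, 1, 1, 1)), V3 = 0)
  expect_equal(sr_forward(matrix(3, 2, 2), pn), matrix(0, 2, 2))

  # chained shape validation
  expect_error(sr_params(S1 = array(1, c(1, 1, 1, 2)), V1 = c(0, 0),
                         S2 = array(1, c(1, 1, 1, 1)), V2 = 0,
                         S3 = array(1, c(1, 1, 1, 1)), V3 = 0),
               "feed")
})

test_that("the loss is the mean per-pair sum of squared residuals", {
  pz <- sr_params(S1 = array(0, c(1, 1, 1, 1)), V1 = 0,
                  S2 = array(0, c(1, 1, 1, 1)), V2 = 0,
                  S3 = array(0, c(1, 1, 1, 1)), V3 = 0)
  # constant residual 1 over a 4 x 4 patch -> 16
  pair <- list(x = matrix(0.5, 4, 4), y = matrix(1, 4, 4))
  expect_equal(sr_loss(pz, list(pair)), 16)
  # doubling residuals quadruples the loss
  pair2 <- list(x = matrix(0.5, 4, 4), y = matrix(2, 4, 4))
  expect_equal(sr_loss(pz, list(pair2)), 64)
  # exact reproduction scores zero
  p <- identity_params()
  expect_equal(sr_loss(p, list(list(x = matrix(0.3, 3, 3),
                                    y = matrix(0.3, 3, 3)))), 0)
  expect_error(sr_loss(p, list()), "pair")
})

test_that("patch routing partitions the image by variance", {
  img <- matrix(0, 20, 20)
  img[1:10, 11:20] <- matrix(stats::rnorm(100), 10, 10)   # one busy patch
  routed <- route_patches(img, patch_size = 10, var_threshold = 1e-6)
  expect_equal(length(routed$sr), 1)
  expect_equal(length(routed$upsample), 3)
  # constant patches always take the upsample path
  expect_true(all(vapply(routed$upsample,
                         function(p) stats::var(as.numeric(p)) <= 1e-6,
                         logical(1))))
  # every pixel assigned exactly once
  n_px <- sum(vapply(c(routed$sr, routed$upsample), length, numeric(1)))
  expect_equal(n_px, length(img))

  # threshold 0 sends every non-constant patch to SR
  routed0 <- route_patches(img, 10, 0)
  expect_equal(length(routed0$sr), 1)

  # checkerboard with variance v against threshold v/2 routes to SR
  cb <- matrix(rep(c(0, 1), length.out = 100), 10, 10)
  v <- stats::var(as.numeric(cb))
  r <- route_patches(cb, 10, v / 2)
  expect_equal(length(r$sr), 1)

  # ragged edges still partition
  rag <- route_patches(matrix(stats::rnorm(13 * 17), 13, 17), 10, 0)
  n_px <- sum(vapply(c(rag$sr, rag$upsample), length, numeric(1)))
  expect_equal(n_px, 13 * 17)
})

test_that("sobel enhancement responds to edges, not offsets", {
  expect_equal(sobel_enhance(matrix(5, 6, 6)), matrix(0, 6, 6))
  # vertical step edge: maximal response on the edge columns
  step <- matrix(rep(c(0, 0, 0, 1, 1, 1), each = 6), 6, 6)
  g <- sobel_enhance(step)
  expect_equal(which.max(colSums(g)) %in% c(3, 4), TRUE)
  expect_equal(sobel_enhance(step + 100), g)   # offset invariant
})

test_that("bicubic upsampling preserves constants and grows the grid", {
  expect_equal(upscale_bicubic(matrix(2, 5, 5), 2), matrix(2, 10, 10))
  img <- matrix(stats::rnorm(36), 6, 6)
  up <- upscale_bicubic(img, 3)
  expect_equal(dim(up), c(18, 18))
  expect_equal(upscale_bicubic(img, 1), img)
})

test_that("swarm training recovers a scalar gain-2 mapping", {
  set.seed(40)
  pairs <- lapply(1:6, function(i) {
    x <- matrix(stats::runif(16, 0.2, 1), 4, 4)
    list(x = x, y = 2 * x)
  })
  template <- identity_params()
  fit <- train_sr(pairs, template,
                  config = swarm_config(n_particles = 60, max_iter = 250,
                                        seed = 7, stall_iter = 250,
                                        bounds = matrix(c(-4, 4), 2, 6)))
  expect_lt(fit$loss, 1e-3)
  gain <- sr_forward(matrix(1, 4, 4), fit$params)[1, 1]
  expect_lt(abs(gain - 2), 0.05)
  # global-best loss never increases
  expect_true(all(diff(fit$history) <= 0))
})

test_that("oversized templates are refused and trivial optima returned", {
  big <- sr_params(S1 = array(0, c(1, 5, 5, 2)), V1 = c(0, 0),
                   S2 = array(0, c(2, 1, 1, 2)), V2 = c(0, 0),
                   S3 = array(0, c(2, 3, 3, 1)), V3 = 0)
  expect_error(train_sr(list(list(x = matrix(1, 3, 3),
                                  y = matrix(1, 3, 3))), big),
               "desk-scale")
})
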