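test_that("SE block preserves shape, gates in (0,1), and kills zero input", {
  set.seed(1)
  x <- array(rnorm(2 * 8 * 5 * 6), c(2, 8, 5, 6))
  y <- se_block(x, reduction = 4, seed = 5)
  expect_equal(dim(y), dim(x))
  w <- attr(y, "channel_weights")
  expect_true(all(w > 0 & w < 1))

  z <- se_block(array(0, c(1, 8, 4, 4)), reduction = 4, seed = 5)
  expect_equal(as.numeric(z), rep(0, 8 * 16))

  expect_error(se_block(x, reduction = 3), class = "spotspray_config_error")
})

test_that("SE with hand-set weights matches scalar arithmetic", {
  # 2-channel 1x1 input; identity-ish weights, zero biases
  x <- array(c(1.5, -2), c(1, 2, 1, 1))
  W1 <- matrix(c(1, 0), 2, 1)        # hidden = squeeze of channel 1
  W2 <- matrix(c(1, 1), 1, 2)
  wts <- list(W1 = W1, b1 = 0, W2 = W2, b2 = c(0, 0))
  y <- se_block(x, reduction = 2, weights = wts)
  # squeeze = (1.5, -2); hidden = relu(1.5) = 1.5; gates = sigmoid(1.5)
  g <- 1 / (1 + exp(-1.5))
  expect_equal(as.numeric(y[1, , 1, 1]), c(1.5 * g, -2 * g))
  expect_equal(attr(y, "channel_weights")[1, ], c(g, g))
})

test_that("forcing SE gates to one recovers the unscaled map exactly", {
  set.seed(2)
  x <- array(rnorm(1 * 4 * 3 * 3), c(1, 4, 3, 3))
  wts <- list(W1 = matrix(0, 4, 1), b1 = 0,
              W2 = matrix(0, 1, 4), b2 = rep(1e6, 4))  # sigmoid -> 1.0
  y <- se_block(x, reduction = 4, weights = wts)
  expect_identical(as.numeric(y), as.numeric(x))
})

test_that("depthwise-separable convolution composes its two stages", {
  set.seed(3)
  # k = 1 depthwise is per-channel scaling
  x <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  wts <- list(dw = array(c(2, -1, 0.5), c(1, 1, 3)),
              pw = array(diag(3), c(1, 1, 3, 3)))
  y <- depthwise_separable_conv(x, k = 1, c_out = 3, weights = wts)
  for (c3 in 1:3) {
    expect_equal(y[1, c3, , ], x[1, c3, , ] * wts$dw[1, 1, c3])
  }
  # stride 2 halves spatial dims under same-padding
  x2 <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  y2 <- depthwise_separable_conv(x2, k = 3, c_out = 6, stride = 2, seed = 1)
  expect_equal(dim(y2), c(1, 6, 4, 4))
})

test_that("MAC ratio matches 1/c_out + 1/k^2 by direct counting", {
  # paper-scale example: k = 3, c_out = 64
  r <- mac_depthwise_separable(20, 20, 32, 64, 3) /
    mac_standard_conv(20, 20, 32, 64, 3)
  expect_equal(r, 1 / 64 + 1 / 9, tolerance = 1e-12)
  expect_equal(round(r, 4), 0.1267)

  # exact counts against the brute-force per-position counters, and the
  # separable block is cheaper for every k >= 2, c_out >= 2
  for (k in c(1, 3, 5)) {
    for (co in c(2, 8, 64)) {
      expect_equal(mac_depthwise_separable(12, 10, 16, co, k),
                   count_macs_dsc(12, 10, 16, co, k))
      expect_equal(mac_standard_conv(12, 10, 16, co, k),
                   count_macs_std(12, 10, 16, co, k))
      if (k >= 2) {
        expect_lt(mac_depthwise_separable(12, 10, 16, co, k),
                  mac_standard_conv(12, 10, 16, co, k))
      }
    }
  }
})

test_that("bottleneck reduces to its shortcut with zero conv weights", {
  set.seed(4)
  x <- array(rnorm(1 * 6 * 8 * 8), c(1, 6, 8, 8))
  y <- mnv3_bottleneck(x, expand_channels = 12, out_channels = 6,
                       stride = 1, zero_weights = TRUE)
  expect_equal(y, x, ignore_attr = TRUE)

  # stride 2: no shortcut, spatial halved, zero weights -> zero output
  y2 <- mnv3_bottleneck(x, expand_channels = 12, out_channels = 8,
                        stride = 2, zero_weights = TRUE)
  expect_equal(dim(y2), c(1, 8, 4, 4))
  expect_equal(max(abs(y2)), 0)
})

test_that("bottleneck parameter count matches the closed-form count", {
  count_closed <- function(cin, cexp, cout, k, use_se, r) {
    n <- 0
    if (cexp != cin) n <- n + cin * cexp + 2 * cexp       # expand + BN
    n <- n + k * k * cexp + 2 * cexp                      # depthwise + BN
    if (use_se) n <- n + cexp * (cexp / r) + cexp / r +
        (cexp / r) * cexp + cexp                          # SE fc stack
    n + cexp * cout + 2 * cout                            # project + BN
  }
  cases <- list(c(16, 16, 16, 3, 1), c(16, 72, 24, 3, 0),
                c(24, 96, 40, 5, 1), c(48, 288, 96, 5, 1))
  for (cs in cases) {
    expect_equal(
      mnv3_bottleneck_n_params(cs[1], cs[2], cs[3], k = cs[4],
                               use_se = cs[5] == 1, se_reduction = 4),
      count_closed(cs[1], cs[2], cs[3], cs[4], cs[5] == 1, 4))
  }
})

test_that("letterbox scales the long side and pads the short one", {
  img <- array(runif(1080 * 1920 * 3), c(1080, 1920, 3))
  lb <- letterbox(img, 640)
  expect_equal(dim(lb$image), c(640, 640, 3))
  expect_equal(lb$transform$scale, 1 / 3)
  expect_equal(lb$transform$pad_y, 140)
  expect_equal(lb$transform$pad_x, 0)
  # padding rows are constant grey
  expect_true(all(lb$image[1:140, , ] == 114 / 255))
  expect_true(all(lb$image[501:640, , ] == 114 / 255))

  sq <- array(runif(640 * 640 * 3), c(640, 640, 3))
  lb2 <- letterbox(sq, 640)
  expect_identical(lb2$image, sq)
  expect_equal(lb2$transform$pad_x, 0)

  sm <- array(runif(320 * 320 * 3), c(320, 320, 3))
  lb3 <- letterbox(sm, 640)
  expect_equal(lb3$transform$scale, 2)
  expect_equal(dim(lb3$image), c(640, 640, 3))

  # box round-trip through the transform
  b <- pred_boxes(c(100, 700), c(50, 400), c(300, 1500), c(600, 900))
  fwd <- letterbox_boxes(b, lb$transform)
  back <- letterbox_boxes(fwd, lb$transform, invert = TRUE)
  expect_equal(back$x1, b$x1)
  expect_equal(back$y2, b$y2)
})

test_that("anchor K-means degenerate and separated-cluster behaviour", {
  # all boxes identical -> every anchor equals that box
  wh <- matrix(rep(c(30, 40), 12), ncol = 2, byrow = TRUE)
  a <- kmeans_anchors(wh, k = 9, seed = 1)
  expect_true(all(a[, 1] == 30 & a[, 2] == 40))

  # k distinct boxes, k clusters -> anchors are the boxes
  wh2 <- cbind(c(10, 20, 40, 80), c(12, 25, 45, 90))
  a2 <- kmeans_anchors(wh2, k = 4, seed = 2)
  expect_equal(unclass(a2), unname(wh2[order(wh2[, 1] * wh2[, 2]), ]),
               ignore_attr = TRUE)

  # two well-separated clusters: centroids near the cluster means; the
  # oracle enumerates every 2-partition of <= 16 boxes and picks the one
  # minimising total (1 - IoU) to its mean
  set.seed(3)
  c1 <- cbind(runif(8, 9, 11), runif(8, 9, 11))
  c2 <- cbind(runif(8, 95, 105), runif(8, 95, 105))
  wh3 <- rbind(c1, c2)
  best <- NULL; best_cost <- Inf
  for (mask in 1:(2^16 - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:15)))
    if (sum(sel) < 1 || sum(sel) > 15) next
    m1 <- colMeans(wh3[sel, , drop = FALSE])
    m2 <- colMeans(wh3[!sel, , drop = FALSE])
    d1 <- 1 - spotspray:::iou_wh(wh3[sel, , drop = FALSE],
                                 matrix(m1, 1))[, 1]
    d2 <- 1 - spotspray:::iou_wh(wh3[!sel, , drop = FALSE],
                                 matrix(m2, 1))[, 1]
    cost <- sum(d1) + sum(d2)
    if (cost < best_cost) { best_cost <- cost; best <- rbind(m1, m2) }
  }
  best <- best[order(best[, 1] * best[, 2]), ]
  a3 <- kmeans_anchors(wh3, k = 2, seed = 4)
  expect_equal(unclass(a3), unname(best), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(unname(unclass(a3)[1, ]), unname(colMeans(c1)),
               tolerance = 0.05)
  expect_equal(unname(unclass(a3)[2, ]), unname(colMeans(c2)),
               tolerance = 0.05)

  expect_error(kmeans_anchors(wh2, k = 9), class = "spotspray_config_error")
})

test_that("mosaic remaps boxes by the per-quadrant affine transform", {
  set.seed(5)
  samples <- lapply(1:4, function(i) {
    img <- array(runif(48 * 64 * 3), c(48, 64, 3))
    list(image = img,
         boxes = pred_boxes(c(5, 30), c(5, 20), c(25, 60), c(20, 45)))
  })
  mo <- mosaic_augment(samples, canvas = 96, seed = 11)
  expect_equal(dim(mo$image), c(96, 96, 3))
  # all boxes inside the canvas, none degenerate
  expect_true(all(mo$boxes$x1 >= 0 & mo$boxes$x2 <= 96 &
                    mo$boxes$y1 >= 0 & mo$boxes$y2 <= 96))
  expect_true(all(mo$boxes$x2 - mo$boxes$x1 >= 2))

  # per-box oracle: map each source box corner independently
  expected <- no_boxes()
  for (q in 1:4) {
    tf <- mo$transforms[[q]]
    b <- samples[[q]]$boxes
    eb <- pred_boxes(b$x1 * tf$sx + tf$ox, b$y1 * tf$sy + tf$oy,
                     b$x2 * tf$sx + tf$ox, b$y2 * tf$sy + tf$oy)
    expected <- rbind(expected, eb)
  }
  expected <- clip_boxes(expected, 96, 96)
  expected <- expected[expected$x2 - expected$x1 >= 2 &
                         expected$y2 - expected$y1 >= 2, ]
  expect_equal(mo$boxes$x1, expected$x1)
  expect_equal(mo$boxes$y2, expected$y2)

  # fixed centre at the midpoint with four identical inputs gives four
  # congruent quadrants
  same <- lapply(1:4, function(i) samples[[1]])
  mo2 <- mosaic_augment(same, canvas = 96, center = c(48, 48))
  expect_equal(mo2$image[1:48, 1:48, ], mo2$image[1:48, 49:96, ])
  expect_equal(mo2$image[1:48, 1:48, ], mo2$image[49:96, 1:48, ])
})
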