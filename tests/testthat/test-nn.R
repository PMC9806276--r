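test_that("offset-decomposed convolution equals the naive direct oracle", {
  set.seed(3)
  cases <- list(c(k = 1, s = 1), c(k = 3, s = 1), c(k = 3, s = 2),
                c(k = 5, s = 1), c(k = 5, s = 2))
  for (cs in cases) {
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    W <- array(rnorm(cs["k"]^2 * 3 * 4), c(cs["k"], cs["k"], 3, 4))
    got <- spotspray:::conv_forward(x, W, NULL, cs["s"])
    expect_equal(got, naive_conv(x, W, cs["s"]), tolerance = 1e-12)
  }
})

test_that("depthwise convolution is channel-independent and matches dense", {
  set.seed(4)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  Wd <- array(rnorm(9 * 3), c(3, 3, 3))
  got <- spotspray:::dwconv_forward(x, Wd, 1)
  # oracle: dense conv with a block-diagonal kernel
  Wdense <- array(0, c(3, 3, 3, 3))
  for (c3 in 1:3) Wdense[, , c3, c3] <- Wd[, , c3]
  expect_equal(got, naive_conv(x, Wdense, 1), tolerance = 1e-12)
})

test_that("batch normalisation standardises channels in training mode", {
  set.seed(5)
  l <- spotspray:::l_conv(3, 4, k = 3, act = "linear")
  x <- array(rnorm(12 * 12 * 3, mean = 3, sd = 2), c(12, 12, 3))
  y <- spotspray:::layer_forward(l, x, train = TRUE)
  ym <- y; dim(ym) <- c(144, 4)
  expect_equal(colMeans(ym), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(ym, 2, function(v) mean(v^2)), rep(1, 4),
               tolerance = 1e-4)  # off by eps/var from the BN epsilon
})

test_that("upsampling backward is the exact adjoint of forward", {
  set.seed(6)
  x <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
  y <- array(rnorm(10 * 14 * 2), c(10, 14, 2))
  lhs <- sum(spotspray:::upsample2_forward(x) * y)
  rhs <- sum(x * spotspray:::upsample2_backward(y))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("layer gradients agree with central finite differences", {
  set.seed(8)
  layers <- list(
    list(l = spotspray:::l_conv(3, 4, k = 3, stride = 1, act = "hswish"),
         cin = 3),
    list(l = spotspray:::l_conv(3, 4, k = 1, act = "linear", use_bn = FALSE),
         cin = 3),
    list(l = spotspray:::l_dwconv(4, k = 3, stride = 2, act = "relu"),
         cin = 4),
    list(l = spotspray:::l_se(8, 4), cin = 8),
    list(l = spotspray:::l_bneck(6, 12, 6, k = 3, stride = 1,
                                 use_se = TRUE, act = "hswish",
                                 se_reduction = 4), cin = 6)
  )
  eps <- 1e-6
  for (case in layers) {
    l <- case$l
    ps <- spotspray:::collect_params(l)
    jitter_params(ps, sd = 0.05, seed = 42)
    x <- array(rnorm(6 * 6 * case$cin), c(6, 6, case$cin))
    loss <- function() sum(spotspray:::layer_forward(l, x, train = TRUE)^2)
    spotspray:::zero_grads(ps)
    y <- spotspray:::layer_forward(l, x, train = TRUE)
    dx <- spotspray:::layer_backward(l, 2 * y)
    # parameter gradients (sampled entries)
    set.seed(1)
    for (p in ps) {
      val <- get(p$name, envir = p$layer)
      for (idx in sample(length(val), min(4, length(val)))) {
        v0 <- val[idx]
        val[idx] <- v0 + eps; assign(p$name, val, envir = p$layer)
        lp <- loss()
        val[idx] <- v0 - eps; assign(p$name, val, envir = p$layer)
        lm <- loss()
        val[idx] <- v0; assign(p$name, val, envir = p$layer)
        g_num <- (lp - lm) / (2 * eps)
        g_an <- get(paste0("g_", p$name), envir = p$layer)[idx]
        expect_lt(abs(g_num - g_an) / max(1e-4, abs(g_num) + abs(g_an)),
                  1e-5)
      }
    }
    # input gradients (sampled entries)
    for (idx in sample(length(x), 5)) {
      v0 <- x[idx]
      x[idx] <- v0 + eps; lp <- loss()
      x[idx] <- v0 - eps; lm <- loss()
      x[idx] <- v0
      g_num <- (lp - lm) / (2 * eps)
      expect_lt(abs(g_num - dx[idx]) / max(1e-4, abs(g_num) + abs(dx[idx])),
                1e-5)
    }
  }
})

test_that("whole-network gradients check out end to end", {
  cfg <- detector_config(input_size = 32, width_mult = 0.25,
                         neck_channels = 16,
                         anchors = cbind(c(4, 6, 8, 10, 14, 18, 22, 26, 30),
                                         c(5, 7, 9, 11, 15, 19, 23, 27, 31)))
  det <- build_detector(cfg, seed = 2)
  params <- spotspray:::detector_params(det)
  jitter_params(params, sd = 0.05, seed = 13)
  set.seed(21)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  boxes <- pred_boxes(c(4, 18), c(6, 12), c(12, 30), c(15, 26))
  loss_of <- function() {
    preds <- spotspray:::detector_forward_hwc(det, x, train = TRUE)
    total_loss(preds, boxes, cfg$anchors, cfg$strides, cfg$lambda, 1)$total
  }
  spotspray:::zero_grads(params)
  preds <- spotspray:::detector_forward_hwc(det, x, train = TRUE)
  lt <- total_loss(preds, boxes, cfg$anchors, cfg$strides, cfg$lambda, 1,
                   need_grad = TRUE)
  invisible(spotspray:::detector_backward_hwc(
    det, list(p3 = lt$grads[[1]], p4 = lt$grads[[2]], p5 = lt$grads[[3]])))
  bnl <- do.call(c, lapply(spotspray:::detector_layers(det),
                           spotspray:::collect_bn_layers))
  snap <- lapply(bnl, function(l) list(mu = l$run_mu, var = l$run_var))
  restore_bn <- function() for (i in seq_along(bnl)) {
    bnl[[i]]$run_mu <- snap[[i]]$mu
    bnl[[i]]$run_var <- snap[[i]]$var
  }
  eps <- 1e-5
  set.seed(31)
  for (trial in 1:25) {
    p <- params[[sample(length(params), 1)]]
    val <- get(p$name, envir = p$layer)
    idx <- sample(length(val), 1)
    g_an <- get(paste0("g_", p$name), envir = p$layer)[idx]
    v0 <- val[idx]
    val[idx] <- v0 + eps; assign(p$name, val, envir = p$layer)
    restore_bn(); lp <- loss_of()
    val[idx] <- v0 - eps; assign(p$name, val, envir = p$layer)
    restore_bn(); lm <- loss_of()
    val[idx] <- v0; assign(p$name, val, envir = p$layer)
    g_num <- (lp - lm) / (2 * eps)
    expect_lt(abs(g_num - g_an) / max(1e-4, abs(g_num) + abs(g_an)), 1e-4)
  }
})

test_that("cosine schedule hits its endpoints and its midpoint", {
  expect_equal(cosine_lr(0, 100, 0.01, 1e-4), 0.01)
  expect_equal(cosine_lr(100, 100, 0.01, 1e-4), 1e-4)
  expect_equal(cosine_lr(50, 100, 0.01, 1e-4), (0.01 + 1e-4) / 2)
  # monotone decreasing across the cycle
  lrs <- cosine_lr(0:50, 50, 0.01, 1e-4)
  expect_true(all(diff(lrs) < 0))
})
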