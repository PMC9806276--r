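# The lightweight single-stage weed detector: a MobileNetv3-Small
# backbone truncated at its stride-8/16/32 stages, a squeeze-and-
# excitation block on each of the three backbone outputs (the
# modification that sharpens small-target response), a PANet neck
# (top-down feature-pyramid fusion followed by a bottom-up path, fusing
# by channel concatenation), and three anchor-based detection heads with
# 3 x (5 + n_classes) output channels each.

# round a scaled channel count to a hardware-friendly multiple, never
# dropping below 90% of the requested width
make_divisible <- function(v, divisor = 8) {
  nv <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

# MobileNetv3-Small bottleneck table truncated after the last stride-32
# block: kernel, expansion, output channels, SE, activation, stride
MNV3_SMALL_TABLE <- list(
  list(k = 3, exp = 16,  out = 16, se = TRUE,  act = "relu",   stride = 2),
  list(k = 3, exp = 72,  out = 24, se = FALSE, act = "relu",   stride = 2),
  list(k = 3, exp = 88,  out = 24, se = FALSE, act = "relu",   stride = 1),
  list(k = 5, exp = 96,  out = 40, se = TRUE,  act = "hswish", stride = 2),
  list(k = 5, exp = 240, out = 40, se = TRUE,  act = "hswish", stride = 1),
  list(k = 5, exp = 240, out = 40, se = TRUE,  act = "hswish", stride = 1),
  list(k = 5, exp = 120, out = 48, se = TRUE,  act = "hswish", stride = 1),
  list(k = 5, exp = 144, out = 48, se = TRUE,  act = "hswish", stride = 1),
  list(k = 5, exp = 288, out = 96, se = TRUE,  act = "hswish", stride = 2),
  list(k = 5, exp = 576, out = 96, se = TRUE,  act = "hswish", stride = 1),
  list(k = 5, exp = 576, out = 96, se = TRUE,  act = "hswish", stride = 1)
)

# default anchor set for 640 px input (w, h in input pixels), 3 per scale
# sorted by area; replaced by kmeans_anchors() when a dataset is at hand
DEFAULT_ANCHORS <- matrix(c(10, 13, 16, 30, 33, 23,
                            30, 61, 62, 45, 59, 119,
                            116, 90, 156, 198, 373, 326),
                          ncol = 2, byrow = TRUE)

#' Detector configuration
#'
#' @param input_size network input side in pixels; must be divisible
#'   by 32 (default 640).
#' @param n_classes number of object classes (default 1: a single weed
#'   class).
#' @param width_mult channel width multiplier for the whole network; 1
#'   is the published MobileNetv3-Small width, smaller values give toy
#'   models for CPU-scale experiments.
#' @param neck_channels channel width of the PANet neck (applied through
#'   `width_mult`).
#' @param se_reduction reduction ratio of all squeeze-and-excitation
#'   blocks (default 4).
#' @param conf_thr,nms_thr confidence and non-maximum-suppression IoU
#'   thresholds used at prediction time (defaults 0.5 / 0.5).
#' @param anchors 9 x 2 matrix of anchor (w, h) in input pixels, rows
#'   sorted by area, 3 per output scale; default is the conventional
#'   640-px anchor set.
#' @param lambda length-3 balance coefficients `(cls, loc, obj)` of the
#'   training loss.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(input_size = 640, n_classes = 1,
                            width_mult = 1, neck_channels = 64,
                            se_reduction = 4, conf_thr = 0.5,
                            nms_thr = 0.5, anchors = NULL,
                            lambda = c(cls = 0.5, loc = 0.05, obj = 1)) {
  if (input_size %% 32 != 0 || input_size <= 0) {
    stop_config("`input_size` must be a positive multiple of 32")
  }
  check_positive(n_classes, "n_classes")
  check_positive(width_mult, "width_mult")
  if (is.null(anchors)) {
    anchors <- DEFAULT_ANCHORS * input_size / 640
  }
  anchors <- as.matrix(anchors)
  if (!all(dim(anchors) == c(9, 2)) || any(anchors <= 0)) {
    stop_config("`anchors` must be a 9 x 2 matrix of positive sizes")
  }
  stopifnot(length(lambda) == 3, all(lambda >= 0))
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 width_mult = width_mult,
                 neck_channels = as.integer(neck_channels),
                 se_reduction = as.integer(se_reduction),
                 conf_thr = conf_thr, nms_thr = nms_thr,
                 anchors = anchors,
                 lambda = stats::setNames(as.numeric(lambda),
                                          c("cls", "loc", "obj")),
                 strides = c(8L, 16L, 32L)),
            class = "detector_config")
}

#' Build the weed detector network
#'
#' Assembles backbone, post-backbone SE blocks, neck and heads with
#' freshly initialised weights (He-normal, seeded for reproducibility).
#'
#' @param config a [detector_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `weed_detector`.
#' @examples
#' \donttest{
#' det <- build_detector(detector_config(input_size = 64, width_mult = 0.25))
#' det
#' }
#' @export
build_detector <- function(config = detector_config(), seed = 0) {
  stopifnot(inherits(config, "detector_config"))
  set.seed(derive_seed(seed, "init"))
  wm <- config$width_mult
  ch <- function(c) make_divisible(c * wm)
  r <- config$se_reduction

  net <- new.env(parent = emptyenv())
  net$stem <- l_conv(3, ch(16), k = 3, stride = 2, act = "hswish")
  cin <- ch(16)
  net$blocks <- vector("list", length(MNV3_SMALL_TABLE))
  for (i in seq_along(MNV3_SMALL_TABLE)) {
    tb <- MNV3_SMALL_TABLE[[i]]
    net$blocks[[i]] <- l_bneck(cin, ch(tb$exp), ch(tb$out), k = tb$k,
                               stride = tb$stride, use_se = tb$se,
                               act = tb$act, se_reduction = r)
    cin <- ch(tb$out)
  }
  c3 <- ch(24); c4 <- ch(48); c5 <- ch(96)
  net$tap <- c(3L, 8L, 11L)  # block indices emitting stride 8 / 16 / 32

  # SE attention appended to the three backbone outputs
  net$se3 <- l_se(c3, r); net$se4 <- l_se(c4, r); net$se5 <- l_se(c5, r)

  nw <- make_divisible(config$neck_channels * wm)
  net$lat3 <- l_conv(c3, nw, 1, 1, "hswish")
  net$lat4 <- l_conv(c4, nw, 1, 1, "hswish")
  net$lat5 <- l_conv(c5, nw, 1, 1, "hswish")
  net$td4 <- l_conv(2 * nw, nw, 3, 1, "hswish")   # after upsample+concat
  net$td3 <- l_conv(2 * nw, nw, 3, 1, "hswish")
  net$down4 <- l_conv(nw, nw, 3, 2, "hswish")     # bottom-up path
  net$pan4 <- l_conv(2 * nw, nw, 3, 1, "hswish")
  net$down5 <- l_conv(nw, nw, 3, 2, "hswish")
  net$pan5 <- l_conv(2 * nw, nw, 3, 1, "hswish")

  hc <- 3L * (5L + config$n_classes)
  net$head3 <- l_conv(nw, hc, 1, 1, "linear", use_bn = FALSE)
  net$head4 <- l_conv(nw, hc, 1, 1, "linear", use_bn = FALSE)
  net$head5 <- l_conv(nw, hc, 1, 1, "linear", use_bn = FALSE)

  model <- structure(list(config = config, net = net, seed = seed),
                     class = "weed_detector")
  model
}

detector_layers <- function(model) {
  net <- model$net
  c(list(net$stem), net$blocks,
    list(net$se3, net$se4, net$se5,
         net$lat3, net$lat4, net$lat5, net$td4, net$td3,
         net$down4, net$pan4, net$down5, net$pan5,
         net$head3, net$head4, net$head5))
}

detector_params <- function(model) {
  do.call(c, lapply(detector_layers(model), collect_params))
}

#' Number of trainable parameters
#' @param model a [build_detector()] object.
#' @return total parameter count (weights, biases, BN scales/shifts).
#' @export
n_parameters <- function(model) {
  n_param_values(detector_params(model))
}

#' @export
print.weed_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "<weed_detector> MobileNetv3-Small + SE + PANet\n",
    "  input %dx%d, %d class(es), width x%.2f, %s parameters\n",
    "  heads at strides 8/16/32 with %d channels each\n"),
    cfg$input_size, cfg$input_size, cfg$n_classes, cfg$width_mult,
    format(n_parameters(x), big.mark = ","), 3 * (5 + cfg$n_classes)))
  invisible(x)
}

# single-sample forward through the whole network; input (H, W, 3)
detector_forward_hwc <- function(model, x, train = FALSE) {
  net <- model$net
  h <- layer_forward(net$stem, x, train)
  taps <- list()
  for (i in seq_along(net$blocks)) {
    h <- layer_forward(net$blocks[[i]], h, train)
    if (i %in% net$tap) taps[[length(taps) + 1L]] <- h
  }
  c3 <- layer_forward(net$se3, taps[[1]], train)
  c4 <- layer_forward(net$se4, taps[[2]], train)
  c5 <- layer_forward(net$se5, taps[[3]], train)

  l5 <- layer_forward(net$lat5, c5, train)
  l4 <- layer_forward(net$lat4, c4, train)
  l3 <- layer_forward(net$lat3, c3, train)

  u5 <- upsample2_forward(l5)
  p4 <- layer_forward(net$td4, abind3(u5, l4), train)
  u4 <- upsample2_forward(p4)
  p3 <- layer_forward(net$td3, abind3(u4, l3), train)

  d4 <- layer_forward(net$down4, p3, train)
  n4 <- layer_forward(net$pan4, abind3(d4, p4), train)
  d5 <- layer_forward(net$down5, n4, train)
  n5 <- layer_forward(net$pan5, abind3(d5, l5), train)

  net$split <- c(dim(l4)[3], dim(l3)[3], dim(p4)[3], dim(l5)[3])
  list(p3 = layer_forward(net$head3, p3, train),
       p4 = layer_forward(net$head4, n4, train),
       p5 = layer_forward(net$head5, n5, train))
}

# backward: douts is list(p3, p4, p5) of gradients wrt the head outputs
detector_backward_hwc <- function(model, douts) {
  net <- model$net
  nw <- net$split

  dp3_h <- layer_backward(net$head3, douts$p3)
  dn4 <- layer_backward(net$head4, douts$p4)
  dn5 <- layer_backward(net$head5, douts$p5)

  dcat5 <- layer_backward(net$pan5, dn5)
  dd5 <- dcat5[, , seq_len(nw[4]), drop = FALSE]
  dl5_a <- dcat5[, , -seq_len(nw[4]), drop = FALSE]
  dn4 <- dn4 + layer_backward(net$down5, dd5)
  dcat4 <- layer_backward(net$pan4, dn4)
  dd4 <- dcat4[, , seq_len(nw[3]), drop = FALSE]
  dp4_a <- dcat4[, , -seq_len(nw[3]), drop = FALSE]
  dp3 <- dp3_h + layer_backward(net$down4, dd4)

  dcat3 <- layer_backward(net$td3, dp3)
  du4 <- dcat3[, , seq_len(nw[3]), drop = FALSE]
  dl3 <- dcat3[, , -seq_len(nw[3]), drop = FALSE]
  dp4 <- dp4_a + upsample2_backward(du4)
  dcat4t <- layer_backward(net$td4, dp4)
  du5 <- dcat4t[, , seq_len(nw[4]), drop = FALSE]
  dl4 <- dcat4t[, , -seq_len(nw[4]), drop = FALSE]
  dl5 <- dl5_a + upsample2_backward(du5)

  dc5 <- layer_backward(net$lat5, dl5)
  dc4 <- layer_backward(net$lat4, dl4)
  dc3 <- layer_backward(net$lat3, dl3)

  dt5 <- layer_backward(net$se5, dc5)
  dt4 <- layer_backward(net$se4, dc4)
  dt3 <- layer_backward(net$se3, dc3)

  taps <- net$tap
  d <- dt5
  for (i in rev(seq_along(net$blocks))) {
    if (i == taps[2]) d <- d + dt4
    if (i == taps[1]) d <- d + dt3
    d <- layer_backward(net$blocks[[i]], d)
  }
  layer_backward(net$stem, d)
}

# concatenate two (H, W, C) maps along channels
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

#' Run the detector forward pass
#'
#' @param model a [build_detector()] object.
#' @param x either an `(H, W, 3)` image array in `[0, 1]` or a 4-axis
#'   `(N, 3, H, W)` batch; H and W must be divisible by 32.
#' @param train logical; use batch statistics and retain caches for a
#'   subsequent backward pass.
#' @return for `(H, W, 3)` input, a list of three head outputs at
#'   strides 8/16/32, each an `(H/s, W/s, 3 * (5 + n_classes))` array;
#'   for batched input, a list of such lists.
#' @export
detector_forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "weed_detector"))
  d <- dim(x)
  if (length(d) == 3) {
    if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
      stop_config("input height and width must be divisible by 32")
    }
    return(detector_forward_hwc(model, x, train))
  }
  if (length(d) == 4) {
    return(lapply(seq_len(d[1]), function(n) {
      img <- aperm(x[n, , , , drop = FALSE][1, , , ], c(2, 3, 1))
      detector_forward_hwc(model, img, train)
    }))
  }
  stop_config("x must be an (H, W, 3) image or an (N, 3, H, W) batch")
}
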