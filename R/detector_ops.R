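# Stand-alone building-block operations of the detector, exposed as pure
# functions on 4-axis (N, C, H, W) arrays so each primitive can be
# exercised and checked in isolation from the assembled network.

as_hwc <- function(x, n) {
  d <- dim(x)
  aperm(array(x[n, , , ], d[2:4]), c(2, 3, 1))
}

check_nchw <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4 || any(dim(x) <= 0)) {
    stop_config("expected a 4-axis (N, C, H, W) array")
  }
  # keep channel axis even for C = 1
  x
}

from_hwc <- function(y) aperm(y, c(3, 1, 2))

map_batch <- function(x, f) {
  d <- dim(x)
  out <- NULL
  for (n in seq_len(d[1])) {
    xn <- array(x[n, , , ], d[2:4])          # (C, H, W)
    yn <- f(aperm(xn, c(2, 3, 1)))           # f works on (H, W, C)
    if (is.null(out)) out <- array(0, c(d[1], dim(yn)[3], dim(yn)[1], dim(yn)[2]))
    out[n, , , ] <- from_hwc(yn)
  }
  out
}

#' Squeeze-and-excitation block
#'
#' Channel attention: each channel's spatial map is squeezed to one real
#' number by global average pooling, a two-layer fully-connected
#' bottleneck (`C -> C/r -> C`) produces one weight per channel through a
#' logistic sigmoid, and the input is rescaled channel-by-channel. The
#' spatial shape never changes and all channel weights are strictly
#' inside (0, 1), so a zero input maps to a zero output.
#'
#' @param x `(N, C, H, W)` array; `C` must be divisible by `reduction`.
#' @param reduction bottleneck reduction ratio (default 4).
#' @param weights optional list `W1 (C x C/r)`, `b1`, `W2 (C/r x C)`,
#'   `b2` to use instead of seeded random weights.
#' @param seed seed for random weight initialisation when `weights` is
#'   NULL.
#' @return array of the same shape as `x`, with the per-sample channel
#'   weights attached as attribute `"channel_weights"` (N x C matrix).
#' @export
se_block <- function(x, reduction = 4, weights = NULL, seed = 0) {
  check_nchw(x)
  ch <- dim(x)[2]
  set.seed(derive_seed(seed, "se_block"))
  l <- l_se(ch, reduction)
  if (!is.null(weights)) {
    stopifnot(all(c("W1", "b1", "W2", "b2") %in% names(weights)))
    l$W1 <- weights$W1; l$b1 <- weights$b1
    l$W2 <- weights$W2; l$b2 <- weights$b2
  }
  d <- dim(x)
  wmat <- matrix(0, d[1], ch)
  out <- array(0, d)
  for (n in seq_len(d[1])) {
    yn <- layer_forward(l, as_hwc(x, n), train = FALSE)
    wmat[n, ] <- l$cache$wgt
    out[n, , , ] <- from_hwc(yn)
  }
  attr(out, "channel_weights") <- wmat
  out
}

#' Depthwise-separable convolution
#'
#' The MobileNet cost-reduction primitive: a per-channel `k x k`
#' convolution (depthwise) followed by a `1 x 1` cross-channel
#' convolution (pointwise), with same-padding. Multiply-accumulate cost
#' is `c_in k^2 H' W' + c_in c_out H' W'` against `k^2 c_in c_out H' W'`
#' for a standard convolution — a ratio of `1/c_out + 1/k^2`.
#'
#' @param x `(N, C, H, W)` array.
#' @param k depthwise kernel size (odd).
#' @param c_out output channels.
#' @param stride spatial stride.
#' @param weights optional list with `dw` (`k x k x C` array) and `pw`
#'   (`1 x 1 x C x c_out` array).
#' @param seed seed used when `weights` is NULL.
#' @return `(N, c_out, H', W')` array.
#' @seealso [mac_depthwise_separable()], [mac_standard_conv()]
#' @export
depthwise_separable_conv <- function(x, k, c_out, stride = 1,
                                     weights = NULL, seed = 0) {
  check_nchw(x)
  cin <- dim(x)[2]
  set.seed(derive_seed(seed, "dsc"))
  if (is.null(weights)) {
    weights <- list(dw = he_init(c(k, k, cin), k * k),
                    pw = he_init(c(1, 1, cin, c_out), cin))
  }
  stopifnot(all(dim(weights$dw) == c(k, k, cin)),
            all(dim(weights$pw) == c(1, 1, cin, c_out)))
  map_batch(x, function(h) {
    conv_forward(dwconv_forward(h, weights$dw, stride), weights$pw,
                 NULL, 1)
  })
}

#' Multiply-accumulate counts of convolution blocks
#'
#' Exact MAC counts for same-padded convolutions on an `h x w` input.
#' `mac_depthwise_separable()` counts the depthwise stage plus the
#' pointwise stage; `mac_standard_conv()` counts a dense `k x k`
#' convolution. Their ratio is `1/c_out + 1/k^2`.
#'
#' @param h,w input spatial size.
#' @param c_in,c_out channel counts.
#' @param k kernel size.
#' @param stride spatial stride.
#' @return MAC count (numeric scalar).
#' @export
mac_depthwise_separable <- function(h, w, c_in, c_out, k, stride = 1) {
  ho <- conv_out_len(h, k, stride); wo <- conv_out_len(w, k, stride)
  c_in * k^2 * ho * wo + c_in * c_out * ho * wo
}

#' @rdname mac_depthwise_separable
#' @export
mac_standard_conv <- function(h, w, c_in, c_out, k, stride = 1) {
  ho <- conv_out_len(h, k, stride); wo <- conv_out_len(w, k, stride)
  k^2 * c_in * c_out * ho * wo
}

#' Inverted-residual bottleneck block
#'
#' The MobileNetv3 building block: `1 x 1` expansion (skipped when the
#' expanded width equals the input width), depthwise `k x k`
#' convolution, optional squeeze-and-excitation on the expanded
#' channels, `1 x 1` linear projection, with a shortcut connection
#' added when the block keeps both stride and channel count.
#'
#' @param x `(N, C, H, W)` array.
#' @param expand_channels expanded (inner) width.
#' @param out_channels output width.
#' @param k depthwise kernel size.
#' @param stride 1 or 2.
#' @param use_se add squeeze-and-excitation on the expanded channels.
#' @param activation `"relu"` or `"hswish"`.
#' @param se_reduction SE reduction ratio.
#' @param seed weight-initialisation seed.
#' @param zero_weights set every convolution weight to zero (the block
#'   then reduces to its shortcut: identity when `stride = 1` and
#'   `C = out_channels`, zero otherwise).
#' @return `(N, out_channels, H', W')` array.
#' @export
mnv3_bottleneck <- function(x, expand_channels, out_channels, k = 3,
                            stride = 1, use_se = TRUE,
                            activation = "hswish", se_reduction = 4,
                            seed = 0, zero_weights = FALSE) {
  check_nchw(x)
  cin <- dim(x)[2]
  set.seed(derive_seed(seed, "bneck"))
  l <- l_bneck(cin, expand_channels, out_channels, k = k, stride = stride,
               use_se = use_se, act = activation,
               se_reduction = se_reduction)
  if (zero_weights) {
    if (!is.null(l$expand)) l$expand$W[] <- 0
    l$dw$W[] <- 0
    l$project$W[] <- 0
  }
  map_batch(x, function(h) layer_forward(l, h, train = FALSE))
}

#' Count the trainable parameters of one bottleneck block
#'
#' Closed-form count matching [mnv3_bottleneck()]'s construction,
#' including batch-normalisation scale/shift pairs.
#'
#' @inheritParams mnv3_bottleneck
#' @param c_in input channels.
#' @return parameter count.
#' @export
mnv3_bottleneck_n_params <- function(c_in, expand_channels, out_channels,
                                     k = 3, stride = 1, use_se = TRUE,
                                     se_reduction = 4) {
  l <- l_bneck(c_in, expand_channels, out_channels, k = k, stride = stride,
               use_se = use_se, se_reduction = se_reduction)
  n_param_values(collect_params(l))
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving resize: the longer side is scaled to `target_size`,
#' the shorter side is padded symmetrically with constant grey
#' (114/255). The returned transform maps original-image pixel
#' coordinates into the letterboxed frame and is exactly invertible for
#' remapping predicted boxes.
#'
#' @param image `(H, W, C)` numeric array in `[0, 1]`.
#' @param target_size output side length (default 640).
#' @return list with `image` (`target_size` square array), and
#'   `transform = list(scale, pad_x, pad_y, width, height)`.
#' @export
letterbox <- function(image, target_size = 640) {
  stopifnot(is.array(image), length(dim(image)) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]; ch <- dim(image)[3]
  scale <- target_size / max(h, w)
  nh <- round(h * scale); nw <- round(w * scale)
  resized <- if (nh == h && nw == w) image else {
    r <- EBImage::resize(image, w = nh, h = nw)
    array(as.numeric(r), c(nh, nw, ch))
  }
  pad_y <- (target_size - nh) %/% 2
  pad_x <- (target_size - nw) %/% 2
  out <- array(114 / 255, c(target_size, target_size, ch))
  out[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- resized
  list(image = out,
       transform = list(scale = scale, pad_x = pad_x, pad_y = pad_y,
                        width = w, height = h))
}

#' Map boxes through (or back through) a letterbox transform
#'
#' @param boxes a [pred_boxes()] data.frame.
#' @param transform the `transform` element of a [letterbox()] result.
#' @param invert map from letterboxed coordinates back to the original
#'   image (clipping to its bounds).
#' @return the remapped box data.frame.
#' @export
letterbox_boxes <- function(boxes, transform, invert = FALSE) {
  if (nrow(boxes) == 0) return(boxes)
  tf <- transform
  if (!invert) {
    boxes$x1 <- boxes$x1 * tf$scale + tf$pad_x
    boxes$x2 <- boxes$x2 * tf$scale + tf$pad_x
    boxes$y1 <- boxes$y1 * tf$scale + tf$pad_y
    boxes$y2 <- boxes$y2 * tf$scale + tf$pad_y
    boxes
  } else {
    boxes$x1 <- (boxes$x1 - tf$pad_x) / tf$scale
    boxes$x2 <- (boxes$x2 - tf$pad_x) / tf$scale
    boxes$y1 <- (boxes$y1 - tf$pad_y) / tf$scale
    boxes$y2 <- (boxes$y2 - tf$pad_y) / tf$scale
    clip_boxes(boxes, tf$width, tf$height)
  }
}

# intersection-over-union of (w, h) pairs with boxes co-located at the
# origin; `wh` n x 2 against `centers` k x 2 -> n x k matrix
iou_wh <- function(wh, centers) {
  n <- nrow(wh); k <- nrow(centers)
  iw <- outer(wh[, 1], centers[, 1], pmin)
  ih <- outer(wh[, 2], centers[, 2], pmin)
  inter <- iw * ih
  union <- outer(wh[, 1] * wh[, 2], centers[, 1] * centers[, 2], `+`) - inter
  inter / union
}

#' Cluster anchor boxes by K-means under 1 - IoU distance
#'
#' Box width/height pairs are clustered with Lloyd iterations where the
#' distance between a box and a centroid is `1 - IoU` of the two
#' rectangles co-located at the origin, and centroids are updated to the
#' arithmetic mean of their members. Deterministic given `seed`.
#'
#' @param wh an `n x 2` matrix (or data.frame) of box widths/heights in
#'   pixels; `n >= k`.
#' @param k number of anchors (default 9, three per output scale).
#' @param iterations maximum Lloyd iterations.
#' @param seed RNG seed for the initial centroid draw.
#' @return a `k x 2` matrix of anchors sorted by increasing area, class
#'   `anchor_set`, with the per-box cluster assignment as attribute
#'   `"assignment"` and mean best-IoU as `"mean_iou"`.
#' @export
kmeans_anchors <- function(wh, k = 9, iterations = 50, seed = 0) {
  wh <- as.matrix(wh)
  stopifnot(ncol(wh) == 2)
  if (any(wh <= 0)) stop_config("box sizes must be positive")
  n <- nrow(wh)
  if (n < k) stop_config(sprintf("need at least k = %d boxes, got %d", k, n))
  set.seed(derive_seed(seed, "anchors"))
  centers <- wh[sample.int(n, k), , drop = FALSE]
  assign_prev <- rep(0L, n)
  for (it in seq_len(iterations)) {
    iou <- iou_wh(wh, centers)
    assign <- max.col(iou, ties.method = "first")
    if (all(assign == assign_prev)) break
    assign_prev <- assign
    for (j in seq_len(k)) {
      members <- wh[assign == j, , drop = FALSE]
      if (nrow(members)) centers[j, ] <- colMeans(members)
    }
  }
  ord <- order(centers[, 1] * centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  dimnames(centers) <- list(NULL, c("w", "h"))
  structure(centers, class = c("anchor_set", class(centers)),
            assignment = order(ord)[assign_prev],
            mean_iou = mean(apply(iou_wh(wh, centers), 1, max)))
}

#' Mosaic augmentation
#'
#' Composites four annotated samples onto one square canvas split into
#' four quadrants by a random centre point; each sample is resized to
#' fill its quadrant and its boxes are remapped by the corresponding
#' affine transform, clipped to the canvas, and dropped when the
#' residual extent falls below 2 px in either direction.
#'
#' @param samples list of exactly 4 lists, each with `image` (`(H,W,C)`
#'   array) and `boxes` (a [pred_boxes()] data.frame).
#' @param canvas output side length (default 640).
#' @param seed RNG seed for the centre draw.
#' @param center optional fixed centre `c(x, y)` in canvas pixels
#'   (overrides the random draw).
#' @return list with `image`, `boxes`, `center`, and `transforms` (per
#'   sample `list(sx, sy, ox, oy)` mapping source to canvas pixels).
#' @export
mosaic_augment <- function(samples, canvas = 640, seed = 0, center = NULL) {
  stopifnot(length(samples) == 4)
  if (is.null(center)) {
    set.seed(derive_seed(seed, "mosaic"))
    center <- round(stats::runif(2, 0.25 * canvas, 0.75 * canvas))
  }
  cx <- round(center[1]); cy <- round(center[2])
  stopifnot(cx > 0, cx < canvas, cy > 0, cy < canvas)
  ch <- dim(samples[[1]]$image)[3]
  out <- array(114 / 255, c(canvas, canvas, ch))
  # quadrant pixel rectangles [x1,x2) x [y1,y2): TL, TR, BL, BR
  quads <- list(c(0, 0, cx, cy), c(cx, 0, canvas, cy),
                c(0, cy, cx, canvas), c(cx, cy, canvas, canvas))
  transforms <- vector("list", 4)
  all_boxes <- no_boxes()
  for (q in 1:4) {
    s <- samples[[q]]
    qd <- quads[[q]]
    wq <- qd[3] - qd[1]; hq <- qd[4] - qd[2]
    h0 <- dim(s$image)[1]; w0 <- dim(s$image)[2]
    rs <- if (h0 == hq && w0 == wq) s$image else {
      array(as.numeric(EBImage::resize(s$image, w = hq, h = wq)),
            c(hq, wq, ch))
    }
    out[qd[2] + seq_len(hq), qd[1] + seq_len(wq), ] <- rs
    tf <- list(sx = wq / w0, sy = hq / h0, ox = qd[1], oy = qd[2])
    transforms[[q]] <- tf
    b <- s$boxes
    if (nrow(b)) {
      b$x1 <- b$x1 * tf$sx + tf$ox; b$x2 <- b$x2 * tf$sx + tf$ox
      b$y1 <- b$y1 * tf$sy + tf$oy; b$y2 <- b$y2 * tf$sy + tf$oy
      all_boxes <- rbind(all_boxes, b)
    }
  }
  all_boxes <- clip_boxes(all_boxes, canvas, canvas)
  keep <- (all_boxes$x2 - all_boxes$x1 >= 2) &
    (all_boxes$y2 - all_boxes$y1 >= 2)
  all_boxes <- all_boxes[keep, , drop = FALSE]
  class(all_boxes) <- c("pred_box", "data.frame")
  list(image = out, boxes = all_boxes, center = c(cx, cy),
       transforms = transforms)
}
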