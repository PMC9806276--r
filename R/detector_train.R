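# Training loop (Adam + cosine-annealed learning rate) and inference
# (decode + non-maximum suppression) for the detector.

#' Train the detector
#'
#' Stochastic training with Adam, one image per step, under a cosine
#' learning-rate schedule from `lr_max` down to `lr_min` across the
#' epochs. The checkpoint returned is the parameter set of the
#' lowest-mean-loss epoch among the final training cycles (the last
#' `checkpoint_frac` of all epochs), where the annealed learning rate is
#' small and per-epoch losses are stable.
#'
#' @param model a [build_detector()] object (modified in place).
#' @param dataset list of samples, each `list(image, boxes)` with
#'   `image` an `(H, W, 3)` array in `[0, 1]` (letterboxed to the
#'   configured input size if needed) and `boxes` a [pred_boxes()]
#'   data.frame in image pixels.
#' @param epochs number of epochs.
#' @param lr_max,lr_min cosine schedule endpoints.
#' @param seed seed controlling shuffling (and mosaic draws when
#'   `augment = TRUE`).
#' @param augment build each step's sample as a 4-image mosaic instead
#'   of a raw image (requires >= 4 samples); off by default so small
#'   datasets can be overfitted deterministically.
#' @param checkpoint_frac final fraction of epochs eligible for
#'   checkpoint selection.
#' @return a list of class `detector_training`: `model` (with the
#'   checkpoint weights restored), `history` (data.frame epoch / mean
#'   loss / lr), `best_epoch`.
#' @export
train_detector <- function(model, dataset, epochs = 50, lr_max = 5e-3,
                           lr_min = lr_max / 50, seed = 0,
                           augment = FALSE, checkpoint_frac = 0.2) {
  stopifnot(inherits(model, "weed_detector"))
  if (length(dataset) == 0) stop_config("empty training dataset")
  if (augment && length(dataset) < 4) {
    stop_config("mosaic augmentation needs at least 4 samples")
  }
  cfg <- model$config
  sz <- cfg$input_size
  dataset <- lapply(dataset, function(s) {
    d <- dim(s$image)
    if (d[1] != sz || d[2] != sz) {
      lb <- letterbox(s$image, sz)
      s$boxes <- letterbox_boxes(s$boxes, lb$transform)
      s$image <- lb$image
    }
    s
  })
  params <- detector_params(model)
  state <- adam_state(params)
  set.seed(derive_seed(seed, "train"))
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  best <- list(loss = Inf, snap = NULL, bn = NULL, epoch = NA_integer_)
  bn_layers <- do.call(c, lapply(detector_layers(model), collect_bn_layers))
  ckpt_from <- epochs - ceiling(checkpoint_frac * epochs) + 1
  t_step <- 0
  for (ep in seq_len(epochs)) {
    lr <- cosine_lr(ep - 1, max(epochs - 1, 1), lr_max, lr_min)
    ord <- sample(length(dataset))
    ep_loss <- 0
    for (i in ord) {
      if (augment) {
        pick <- sample(length(dataset), 4, replace = length(dataset) < 4)
        mo <- mosaic_augment(dataset[pick], canvas = sz,
                             seed = sample.int(2^30, 1))
        img <- mo$image; boxes <- mo$boxes
      } else {
        img <- dataset[[i]]$image; boxes <- dataset[[i]]$boxes
      }
      zero_grads(params)
      preds <- detector_forward_hwc(model, img, train = TRUE)
      lt <- total_loss(preds, boxes, cfg$anchors, cfg$strides,
                       cfg$lambda, cfg$n_classes, need_grad = TRUE)
      detector_backward_hwc(model, list(p3 = lt$grads[[1]],
                                        p4 = lt$grads[[2]],
                                        p5 = lt$grads[[3]]))
      t_step <- t_step + 1
      state <- adam_step(params, state, lr, t_step)
      ep_loss <- ep_loss + lt$total
    }
    ep_loss <- ep_loss / length(dataset)
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss, lr = lr))
    if (ep >= ckpt_from && ep_loss < best$loss) {
      best$loss <- ep_loss
      best$snap <- snapshot_params(params)
      best$bn <- lapply(bn_layers, function(l) list(mu = l$run_mu,
                                                    var = l$run_var))
      best$epoch <- ep
    }
  }
  if (!is.null(best$snap)) {
    restore_params(params, best$snap)
    for (i in seq_along(bn_layers)) {
      bn_layers[[i]]$run_mu <- best$bn[[i]]$mu
      bn_layers[[i]]$run_var <- best$bn[[i]]$var
    }
  }
  structure(list(model = model, history = history,
                 best_epoch = best$epoch),
            class = "detector_training")
}

#' @export
print.detector_training <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<detector_training> %d epochs, loss %.4f -> %.4f (checkpoint: epoch %d, %.4f)\n",
    nrow(h), h$loss[1], h$loss[nrow(h)], x$best_epoch,
    h$loss[h$epoch == x$best_epoch]))
  invisible(x)
}

# greedy non-maximum suppression; returns indices to keep
nms_keep <- function(boxes, scores, iou_thr) {
  ord <- order(-scores)
  keep <- integer()
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    iou <- box_iou(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
    ord <- rest[iou < iou_thr]
  }
  keep
}

# IoU between one box (1 x 4 matrix x1,y1,x2,y2) and n boxes
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a[1, 3], b[, 3]) - pmax(a[1, 1], b[, 1]))
  iy <- pmax(0, pmin(a[1, 4], b[, 4]) - pmax(a[1, 2], b[, 2]))
  inter <- ix * iy
  area_a <- (a[1, 3] - a[1, 1]) * (a[1, 4] - a[1, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (area_a + area_b - inter)
}

# decode raw head outputs into boxes in letterboxed-image pixels
decode_predictions <- function(preds, cfg) {
  blk <- 5 + cfg$n_classes
  out <- no_boxes()
  for (s in seq_along(cfg$strides)) {
    p <- preds[[s]]
    stride <- cfg$strides[s]
    gh <- dim(p)[1]; gw <- dim(p)[2]
    anch <- cfg$anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
    for (a in 1:3) {
      base <- (a - 1) * blk
      obj <- sigmoid(p[, , base + 5])
      cls <- array(sigmoid(p[, , base + 5 + seq_len(cfg$n_classes)]),
                   c(gh, gw, cfg$n_classes))
      best_cls <- apply(cls, c(1, 2), which.max)
      best_p <- apply(cls, c(1, 2), max)
      conf <- obj * best_p
      hit <- which(conf > cfg$conf_thr, arr.ind = TRUE)
      if (!nrow(hit)) next
      for (r in seq_len(nrow(hit))) {
        iy <- hit[r, 1]; ix <- hit[r, 2]
        tx <- p[iy, ix, base + 1]; ty <- p[iy, ix, base + 2]
        tw <- p[iy, ix, base + 3]; th <- p[iy, ix, base + 4]
        cx <- (2 * sigmoid(tx) - 0.5 + (ix - 1)) * stride
        cy <- (2 * sigmoid(ty) - 0.5 + (iy - 1)) * stride
        w <- (2 * sigmoid(tw))^2 * anch[a, 1]
        h <- (2 * sigmoid(th))^2 * anch[a, 2]
        out <- rbind(out, pred_boxes(cx - w / 2, cy - h / 2,
                                     cx + w / 2, cy + h / 2,
                                     class_id = best_cls[iy, ix] - 1L,
                                     confidence = conf[iy, ix]))
      }
    }
  }
  class(out) <- c("pred_box", "data.frame")
  out
}

#' Detect weeds in an image
#'
#' Letterboxes the image to the configured input size, runs the forward
#' pass, decodes the three head outputs, applies per-class greedy
#' non-maximum suppression, and maps surviving boxes back to the
#' original image frame.
#'
#' @param model a (trained) [build_detector()] object.
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param conf_thr,nms_thr override the configured thresholds.
#' @return a [pred_boxes()] data.frame in original-image pixels.
#' @export
detect_weeds <- function(model, image, conf_thr = NULL, nms_thr = NULL) {
  stopifnot(inherits(model, "weed_detector"))
  cfg <- model$config
  if (!is.null(conf_thr)) cfg$conf_thr <- conf_thr
  if (!is.null(nms_thr)) cfg$nms_thr <- nms_thr
  lb <- letterbox(image, cfg$input_size)
  preds <- detector_forward_hwc(model, lb$image, train = FALSE)
  det <- decode_predictions(preds, cfg)
  if (nrow(det)) {
    kept <- no_boxes()
    for (cl in unique(det$class_id)) {
      d <- det[det$class_id == cl, , drop = FALSE]
      keep <- nms_keep(as.matrix(d[, c("x1", "y1", "x2", "y2")]),
                       d$confidence, cfg$nms_thr)
      kept <- rbind(kept, d[keep, , drop = FALSE])
    }
    det <- kept
    class(det) <- c("pred_box", "data.frame")
  }
  det <- letterbox_boxes(det, lb$transform, invert = TRUE)
  rownames(det) <- NULL
  det
}
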