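# Training loss of the detector. The total is a weighted sum of three
# terms, Loss = l_cls * L_cls + l_loc * L_loc + l_obj * L_obj:
#   L_obj - binary cross-entropy of the objectness logit over every
#           (cell, anchor) of every scale (target 1 at positives);
#   L_cls - binary cross-entropy of the class logits at positives;
#   L_loc - mean squared error of the decoded box against its target at
#           positives, in grid units with sizes normalised by the anchor.
# Positive samples are assigned by cross-grid matching: a target claims
# its own cell plus the horizontally and vertically adjacent cells whose
# centre offset is within half a cell, on every anchor whose width/height
# ratio to the target is below 4.

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable binary cross-entropy from logits
bce_logits <- function(t, y) {
  pmax(t, 0) - t * y + log1p(exp(-abs(t)))
}

# Assign targets for one scale. boxes: pred_boxes in input pixels.
# Returns a data.frame of positives: cell (iy, ix, 0-based), anchor
# (1..3), target centre (gx, gy) and size (gw, gh) in grid units, class.
assign_targets_scale <- function(boxes, stride, anchors_px, grid_h, grid_w,
                                 ratio_thr = 4) {
  out <- data.frame(iy = integer(), ix = integer(), anchor = integer(),
                    gx = numeric(), gy = numeric(), gw = numeric(),
                    gh = numeric(), cls = integer())
  if (nrow(boxes) == 0) return(out)
  a_g <- anchors_px / stride
  for (b in seq_len(nrow(boxes))) {
    gx <- (boxes$x1[b] + boxes$x2[b]) / 2 / stride
    gy <- (boxes$y1[b] + boxes$y2[b]) / 2 / stride
    gw <- (boxes$x2[b] - boxes$x1[b]) / stride
    gh <- (boxes$y2[b] - boxes$y1[b]) / stride
    for (a in seq_len(nrow(a_g))) {
      r <- max(gw / a_g[a, 1], a_g[a, 1] / gw,
               gh / a_g[a, 2], a_g[a, 2] / gh)
      if (r >= ratio_thr) next
      ix0 <- min(max(floor(gx), 0), grid_w - 1)
      iy0 <- min(max(floor(gy), 0), grid_h - 1)
      cells <- list(c(ix0, iy0))
      fx <- gx - floor(gx); fy <- gy - floor(gy)
      if (fx < 0.5 && ix0 >= 1) cells <- c(cells, list(c(ix0 - 1, iy0)))
      if (fx >= 0.5 && ix0 <= grid_w - 2) cells <- c(cells, list(c(ix0 + 1, iy0)))
      if (fy < 0.5 && iy0 >= 1) cells <- c(cells, list(c(ix0, iy0 - 1)))
      if (fy >= 0.5 && iy0 <= grid_h - 2) cells <- c(cells, list(c(ix0, iy0 + 1)))
      for (cl in cells) {
        out <- rbind(out, data.frame(iy = cl[2], ix = cl[1], anchor = a,
                                     gx = gx, gy = gy, gw = gw, gh = gh,
                                     cls = boxes$class_id[b]))
      }
    }
  }
  # one target per (cell, anchor): first (largest-area-first would need a
  # sort; input order is the documented tie-break)
  out[!duplicated(out[, c("iy", "ix", "anchor")]), , drop = FALSE]
}

#' Detector training loss
#'
#' Computes the three loss terms and their weighted total for one
#' sample, together with (optionally) the exact gradient with respect to
#' every head output element.
#'
#' @param preds list of head output arrays, one per scale, each
#'   `(grid_h, grid_w, 3 * (5 + n_classes))` — the per-anchor channel
#'   blocks are `(tx, ty, tw, th, t_obj, t_cls...)`.
#' @param target_boxes a [pred_boxes()] data.frame of ground-truth boxes
#'   in input pixels (`class_id` used for classification).
#' @param anchors `(3 * n_scales) x 2` anchor matrix in input pixels,
#'   three consecutive rows per scale.
#' @param strides integer vector of scale strides (e.g. `c(8, 16, 32)`).
#' @param lambda balance coefficients `(cls, loc, obj)`.
#' @param n_classes number of classes.
#' @param need_grad also return `grads`, a list of arrays shaped like
#'   `preds`.
#' @return a list of class `loss_terms`: `total`, `cls`, `loc`, `obj`
#'   (unweighted terms), `lambda`, `n_positive`, and `grads` when
#'   requested.
#' @export
total_loss <- function(preds, target_boxes, anchors, strides,
                       lambda = c(cls = 0.5, loc = 0.05, obj = 1),
                       n_classes = 1, need_grad = FALSE) {
  stopifnot(length(preds) == length(strides),
            nrow(anchors) == 3 * length(strides))
  lambda <- as.numeric(lambda)
  nc <- n_classes
  blk <- 5 + nc
  obj_sum <- 0; obj_n <- 0
  loc_sum <- 0; cls_sum <- 0; n_pos <- 0
  grads <- if (need_grad) lapply(preds, function(p) array(0, dim(p)))
  pos_by_scale <- vector("list", length(strides))

  for (s in seq_along(strides)) {
    p <- preds[[s]]
    gh <- dim(p)[1]; gw <- dim(p)[2]
    anch <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
    pos <- assign_targets_scale(target_boxes, strides[s], anch, gh, gw)
    pos_by_scale[[s]] <- pos
    n_pos <- n_pos + nrow(pos)
  }

  # objectness target maps, then the per-scale BCE over everything
  for (s in seq_along(strides)) {
    p <- preds[[s]]
    gh <- dim(p)[1]; gw <- dim(p)[2]
    pos <- pos_by_scale[[s]]
    obj_t <- array(0, c(gh, gw, 3))
    if (nrow(pos)) {
      obj_t[cbind(pos$iy + 1, pos$ix + 1, pos$anchor)] <- 1
    }
    obj_ch <- (seq_len(3) - 1) * blk + 5
    t_obj <- p[, , obj_ch, drop = FALSE]
    obj_sum <- obj_sum + sum(bce_logits(t_obj, obj_t))
    obj_n <- obj_n + length(t_obj)
    if (need_grad) {
      grads[[s]][, , obj_ch] <- sigmoid(t_obj) - obj_t  # scaled later
    }
  }

  # localisation + classification at positives
  for (s in seq_along(strides)) {
    pos <- pos_by_scale[[s]]
    if (!nrow(pos)) next
    p <- preds[[s]]
    anch_g <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE] / strides[s]
    for (r in seq_len(nrow(pos))) {
      iy <- pos$iy[r] + 1; ix <- pos$ix[r] + 1; a <- pos$anchor[r]
      base <- (a - 1) * blk
      t <- p[iy, ix, base + 1:4]
      sx <- sigmoid(t[1]); sy <- sigmoid(t[2])
      sw <- sigmoid(t[3]); sh <- sigmoid(t[4])
      px <- 2 * sx - 0.5 + (ix - 1)
      py <- 2 * sy - 0.5 + (iy - 1)
      rw <- (2 * sw)^2                      # predicted w / anchor w
      rh <- (2 * sh)^2
      tw <- pos$gw[r] / anch_g[a, 1]        # target w / anchor w
      th <- pos$gh[r] / anch_g[a, 2]
      dx <- px - pos$gx[r]; dy <- py - pos$gy[r]
      dw <- rw - tw; dh <- rh - th
      loc_sum <- loc_sum + dx^2 + dy^2 + dw^2 + dh^2
      if (nc > 0) {
        tcls <- p[iy, ix, base + 5 + seq_len(nc)]
        ycls <- as.numeric(seq_len(nc) - 1 == pos$cls[r])
        cls_sum <- cls_sum + sum(bce_logits(tcls, ycls))
      }
      if (need_grad) {
        g <- grads[[s]]
        g[iy, ix, base + 1] <- g[iy, ix, base + 1] +
          2 * dx * 2 * sx * (1 - sx)
        g[iy, ix, base + 2] <- g[iy, ix, base + 2] +
          2 * dy * 2 * sy * (1 - sy)
        g[iy, ix, base + 3] <- g[iy, ix, base + 3] +
          2 * dw * 8 * sw * sw * (1 - sw)
        g[iy, ix, base + 4] <- g[iy, ix, base + 4] +
          2 * dh * 8 * sh * sh * (1 - sh)
        if (nc > 0) {
          idx <- base + 5 + seq_len(nc)
          g[iy, ix, idx] <- g[iy, ix, idx] + (sigmoid(tcls) - ycls)
        }
        grads[[s]] <- g
      }
    }
  }

  L_obj <- obj_sum / obj_n
  L_loc <- if (n_pos) loc_sum / n_pos else 0
  L_cls <- if (n_pos && nc > 0) cls_sum / (n_pos * nc) else 0
  total <- lambda[1] * L_cls + lambda[2] * L_loc + lambda[3] * L_obj

  res <- structure(list(total = total, cls = L_cls, loc = L_loc,
                        obj = L_obj,
                        lambda = stats::setNames(lambda, c("cls", "loc", "obj")),
                        n_positive = n_pos),
                   class = "loss_terms")
  if (need_grad) {
    # fold the per-term normalisations and balance weights into grads:
    # obj grads are (sig - y) for every element; loc/cls grads were
    # accumulated unnormalised at positives
    blk_obj <- function(s) (seq_len(3) - 1) * blk + 5
    for (s in seq_along(preds)) {
      g <- grads[[s]]
      och <- blk_obj(s)
      sel_obj <- array(FALSE, dim(g)); sel_obj[, , och] <- TRUE
      g[sel_obj] <- g[sel_obj] * lambda[3] / obj_n
      if (n_pos) {
        loc_ch <- as.vector(outer(1:4, (seq_len(3) - 1) * blk, `+`))
        sel_loc <- array(FALSE, dim(g)); sel_loc[, , loc_ch] <- TRUE
        g[sel_loc] <- g[sel_loc] * lambda[2] / n_pos
        if (nc > 0) {
          cls_ch <- as.vector(outer(5 + seq_len(nc),
                                    (seq_len(3) - 1) * blk, `+`))
          sel_cls <- array(FALSE, dim(g)); sel_cls[, , cls_ch] <- TRUE
          g[sel_cls] <- g[sel_cls] * lambda[1] / (n_pos * nc)
        }
      }
      grads[[s]] <- g
    }
    res$grads <- grads
  }
  res
}

#' @export
print.loss_terms <- function(x, ...) {
  cat(sprintf(
    "<loss_terms> total %.4f = %.2f*cls %.4f + %.2f*loc %.4f + %.2f*obj %.4f (%d positives)\n",
    x$total, x$lambda[1], x$cls, x$lambda[2], x$loc, x$lambda[3], x$obj,
    x$n_positive))
  invisible(x)
}
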