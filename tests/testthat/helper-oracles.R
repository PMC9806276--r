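# Independent brute-force oracles used across the suite.

# Pixel-rasterised intersection area of two half-open integer rectangles:
# counts unit pixels covered by both. Exact for integer coordinates.
raster_intersection <- function(a, b) {
  xs <- seq(floor(min(a$x1, b$x1)), ceiling(max(a$x2, b$x2)) - 1)
  ys <- seq(floor(min(a$y1, b$y1)), ceiling(max(a$y2, b$y2)) - 1)
  if (!length(xs) || !length(ys)) return(0)
  g <- expand.grid(x = xs, y = ys)
  inside <- function(r) g$x >= r$x1 & g$x < r$x2 & g$y >= r$y1 & g$y < r$y2
  sum(inside(a) & inside(b))
}

# 1-D interval union length (intervals as 2-col matrix)
interval_union_length <- function(iv) {
  if (nrow(iv) == 0) return(0)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur[2]) cur[2] <- max(cur[2], iv[i, 2])
    else { tot <- tot + cur[2] - cur[1]; cur <- iv[i, ] }
  }
  tot + cur[2] - cur[1]
}

# brute-force AP oracle: at every distinct confidence threshold, rematch
# the retained detections from scratch, collect the (recall, precision)
# points, and integrate the same all-points precision envelope
ap_threshold_sweep <- function(det, gt, iou_thr = 0.5) {
  if (nrow(gt) == 0 || nrow(det) == 0) return(0)
  thrs <- sort(unique(det$confidence), decreasing = TRUE)
  rec <- numeric(); prec <- numeric()
  for (tau in thrs) {
    keep <- det[det$confidence >= tau, , drop = FALSE]
    m <- spotspray:::match_detections(keep, gt, iou_thr)
    tp <- sum(m$tp_flag)
    rec <- c(rec, tp / nrow(gt))
    prec <- c(prec, tp / nrow(keep))
  }
  ord <- order(rec)
  rec <- rec[ord]; prec <- prec[ord]
  env <- rev(cummax(rev(prec)))
  sum((rec - c(0, head(rec, -1))) * env)
}

# count complete open/close cycles started in any sliding 1 s window;
# returns the max over windows anchored at each opening instant
max_cycles_per_second <- function(opens) {
  if (!length(opens)) return(0)
  vapply(opens, function(t0) sum(opens >= t0 & opens < t0 + 1), numeric(1)) |>
    max()
}
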