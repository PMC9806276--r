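# Synthetic frame rendering: soil-textured background with weeds drawn
# as irregular green blobs at their projected pixel positions, plus
# pixel-accurate ground-truth boxes. Emulates a downward-looking boom
# camera; optional styles reproduce the awkward imaging conditions met
# in the field (canopy shadow, wet dark soil, overexposure, partial
# light occlusion).

#' Render one camera frame of a scene
#'
#' Projects the weeds of a [generate_scene()] scene into the pixel frame
#' of one camera at a given vehicle position and draws them over a soil
#' background. The returned ground-truth boxes are the bounding squares
#' of the canopy discs, clipped to the image; weeds without any visible
#' extent are omitted.
#'
#' @param scene a [generate_scene()] result.
#' @param vehicle_pos_m ground position (m along the travel axis) of the
#'   footprint's trailing edge.
#' @param setup a [camera_setup()].
#' @param camera 1-based camera index (cameras tile the boom left to
#'   right).
#' @param style one of `"plain"`, `"shadow"`, `"wet"`, `"overexposed"`,
#'   `"occluded"`.
#' @param seed RNG seed for texture and blob shapes.
#' @return list with `image` (`(H, W, 3)` array in `[0, 1]`) and
#'   `boxes` (a [pred_boxes()] data.frame).
#' @export
render_frame <- function(scene, vehicle_pos_m, setup = camera_setup(),
                         camera = 1,
                         style = c("plain", "shadow", "wet",
                                   "overexposed", "occluded"),
                         seed = 0) {
  stopifnot(inherits(scene, "field_scene"),
            camera >= 1, camera <= setup$n_cameras)
  style <- match.arg(style)
  set.seed(derive_seed(seed, "render"))
  scale <- ground_scale(setup)
  mm_px <- scale$mm_per_px
  H <- setup$image_height_px; W <- setup$image_width_px
  cam_width_m <- setup$boom_width_m / setup$n_cameras
  x0 <- (camera - 1) * cam_width_m
  footprint_m <- H * mm_px / 1000
  y_lead <- vehicle_pos_m + footprint_m

  # soil background: brownish base with coarse and fine noise
  base <- if (style == "wet") c(0.23, 0.16, 0.11) else c(0.45, 0.33, 0.22)
  img <- array(0, c(H, W, 3))
  coarse <- matrix(stats::rnorm(ceiling(H / 8) * ceiling(W / 8), 0, 0.05),
                   ceiling(H / 8))
  coarse <- coarse[rep(seq_len(nrow(coarse)), each = 8)[seq_len(H)],
                   rep(seq_len(ncol(coarse)), each = 8)[seq_len(W)]]
  fine <- matrix(stats::rnorm(H * W, 0, 0.03), H)
  for (c3 in 1:3) img[, , c3] <- base[c3] + coarse + fine

  boxes <- no_boxes()
  w <- scene$weeds
  for (i in seq_len(nrow(w))) {
    cx <- (w$x[i] - x0) * 1000 / mm_px
    cy <- (y_lead - w$y[i]) * 1000 / mm_px
    r <- w$radius[i] * 1000 / mm_px
    if (cx + r <= 0 || cx - r >= W || cy + r <= 0 || cy - r >= H) next
    # irregular blob: radius modulated by two angular harmonics
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(2, 0.05, 0.15)
    rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    py <- rep(rows - 0.5, times = length(cols))
    px <- rep(cols - 0.5, each = length(rows))
    d <- sqrt((px - cx)^2 + (py - cy)^2)
    th <- atan2(py - cy, px - cx)
    rb <- r * (1 - amp[1] - amp[2] +
                 amp[1] * (1 + sin(3 * th + ph[1])) / 2 +
                 amp[2] * (1 + sin(7 * th + ph[2])) / 2)
    inside <- d <= rb
    if (any(inside)) {
      sel <- cbind(rep(rows, times = length(cols))[inside],
                   rep(cols, each = length(rows))[inside])
      g <- 0.45 + 0.25 * (1 - d[inside] / r) +
        stats::rnorm(sum(inside), 0, 0.03)
      img[cbind(sel, 1)] <- 0.13 + 0.1 * (1 - d[inside] / r)
      img[cbind(sel, 2)] <- g
      img[cbind(sel, 3)] <- 0.10 + 0.05 * (1 - d[inside] / r)
      if (style == "shadow") {
        srows <- pmin(pmax(sel[, 1] + ceiling(r / 3), 1), H)
        scols <- pmin(pmax(sel[, 2] + ceiling(r / 3), 1), W)
        sh <- cbind(srows, scols)
        shadow_only <- !(paste(sh[, 1], sh[, 2]) %in%
                           paste(sel[, 1], sel[, 2]))
        for (c3 in 1:3) {
          img[cbind(sh[shadow_only, , drop = FALSE], c3)] <-
            img[cbind(sh[shadow_only, , drop = FALSE], c3)] * 0.45
        }
      }
    }
    bx <- clip_boxes(pred_boxes(cx - r, cy - r, cx + r, cy + r), W, H)
    boxes <- rbind(boxes, bx)
  }
  class(boxes) <- c("pred_box", "data.frame")

  if (style == "overexposed") img <- img * 1.9 + 0.15
  if (style == "occluded") {
    ramp <- seq(1.6, 0.35, length.out = W)
    for (c3 in 1:3) img[, , c3] <- sweep(img[, , c3], 2, ramp, `*`)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, boxes = boxes)
}

#' Generate a synthetic detection dataset
#'
#' Renders `n` frames of freshly drawn small scenes and returns them as
#' in-memory samples ready for [train_detector()]; optionally writes
#' each as a PNG plus a PASCAL VOC XML annotation.
#'
#' @param n number of images.
#' @param size square image side in pixels.
#' @param weeds_per_image expected weeds per image (Poisson-distributed
#'   per scene).
#' @param radius_px_range canopy radius range in pixels (uniform).
#' @param seed RNG seed.
#' @param dir optional output directory (`<stem>.png` / `<stem>.xml`).
#' @param styles style pool sampled per image (see [render_frame()]).
#' @return list of samples `list(image, boxes)`, invisibly when `dir`
#'   is given.
#' @export
gen_detection_data <- function(n, size = 64, weeds_per_image = 2,
                               radius_px_range = c(5, 12), seed = 0,
                               dir = NULL, styles = "plain") {
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, paste0("img", i))
    set.seed(si)
    # one small scene whose footprint equals the image exactly
    px_m <- 0.001  # 1 mm/px: size px -> size mm footprint
    setup <- camera_setup(size, size, boom_width_m = size * px_m,
                          n_cameras = 1, mount_height_m = 1)
    k <- stats::rpois(1, weeds_per_image)
    r_px <- stats::runif(k, radius_px_range[1], radius_px_range[2])
    margin <- max(radius_px_range) + 1
    weeds <- data.frame(
      x = stats::runif(k, margin, size - margin) * px_m,
      y = stats::runif(k, margin, size - margin) * px_m,
      radius = r_px * px_m)
    scene <- structure(list(area = c(size * px_m, size * px_m),
                            weeds = weeds), class = "field_scene")
    style <- if (length(styles) == 1) styles else sample(styles, 1)
    fr <- render_frame(scene, vehicle_pos_m = 0, setup = setup,
                       style = style, seed = si)
    samples[[i]] <- fr
    if (!is.null(dir)) {
      stem <- file.path(dir, sprintf("synthetic_%04d", i))
      write_image(paste0(stem, ".png"), fr$image)
      write_voc_xml(paste0(stem, ".xml"),
                    basename(paste0(stem, ".png")), size, size, fr$boxes)
    }
  }
  if (is.null(dir)) samples else invisible(samples)
}
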