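# The grille decision algorithm: a single row of grid cells drawn across
# the frame, one cell per solenoid valve. A cell's bit is set when some
# prediction box overlaps it by strictly more than a configured area, and
# the resulting 0/1 vector drives the valve group. Decisions are stateless
# per frame: a cell "pops up" again the first frame its boxes leave.
#
# All rectangles are 0-based, half-open pixel rectangles [x1,x2) x [y1,y2)
# with the origin at the top-left corner and y growing downwards.

#' Prediction boxes
#'
#' Builds a data.frame of detection boxes in half-open pixel coordinates.
#' Vectorised: each argument may have length > 1.
#'
#' @param x1,y1,x2,y2 box corners in pixels, `x2 > x1`, `y2 > y1`.
#' @param class_id integer class label (single-class default 0).
#' @param confidence detection confidence in `[0, 1]`.
#' @return a data.frame of class `pred_box` with the five columns.
#' @export
pred_boxes <- function(x1, y1, x2, y2, class_id = 0L, confidence = 1) {
  df <- data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
                   x2 = as.numeric(x2), y2 = as.numeric(y2),
                   class_id = as.integer(class_id),
                   confidence = as.numeric(confidence))
  if (nrow(df) && any(df$x2 <= df$x1 | df$y2 <= df$y1)) {
    stop_config("boxes must satisfy x2 > x1 and y2 > y1")
  }
  if (nrow(df) && any(df$confidence < 0 | df$confidence > 1)) {
    stop_config("confidence must lie in [0, 1]")
  }
  class(df) <- c("pred_box", "data.frame")
  df
}

#' An empty box list
#' @return a zero-row [pred_boxes()] data.frame.
#' @export
no_boxes <- function() {
  df <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                   y2 = numeric(), class_id = integer(),
                   confidence = numeric())
  class(df) <- c("pred_box", "data.frame")
  df
}

#' Clip boxes to image bounds
#'
#' Boxes are intersected with `[0, width) x [0, height)`; boxes left empty
#' are dropped.
#'
#' @param boxes a [pred_boxes()] data.frame.
#' @param width,height image size in pixels.
#' @return the clipped box data.frame.
#' @export
clip_boxes <- function(boxes, width, height) {
  if (nrow(boxes) == 0) return(boxes)
  boxes$x1 <- pmax(boxes$x1, 0); boxes$y1 <- pmax(boxes$y1, 0)
  boxes$x2 <- pmin(boxes$x2, width); boxes$y2 <- pmin(boxes$y2, height)
  boxes[boxes$x2 > boxes$x1 & boxes$y2 > boxes$y1, , drop = FALSE]
}

#' Grille configuration
#'
#' One row of `n_cells` cells tiling the image width exactly; the number
#' of cells equals the number of solenoid valves fed by this camera. The
#' default row height of 60 px gives, at 0.859 mm/px, a 51.54 mm ground
#' band — wide enough to out-run one frame's vehicle advance at working
#' speeds, and wide enough to guarantee a base valve opening time over
#' small weeds.
#'
#' @param n_cells number of cells (valves); cells differ in width by at
#'   most one pixel and tile `[0, image_width_px)` exactly.
#' @param image_width_px frame width in pixels.
#' @param image_height_px frame height in pixels.
#' @param row_height_px grille row height in pixels (default 60).
#' @param row_top_px pixel row of the grille top; defaults to the bottom
#'   of the frame (the ground image scrolls downward as the machine
#'   advances).
#' @param area_threshold_px2 a cell's bit is set only when a box overlaps
#'   it by strictly more than this area; default 0, i.e. any positive
#'   overlap opens the valve (maximum coverage redundancy).
#' @return an object of class `grille_config`.
#' @export
grille_config <- function(n_cells = 11, image_width_px = 1920,
                          image_height_px = 1080, row_height_px = 60,
                          row_top_px = image_height_px - row_height_px,
                          area_threshold_px2 = 0) {
  check_positive(n_cells, "n_cells")
  check_positive(image_width_px, "image_width_px")
  check_positive(image_height_px, "image_height_px")
  check_positive(row_height_px, "row_height_px")
  if (n_cells != round(n_cells)) stop_config("`n_cells` must be an integer")
  if (n_cells > image_width_px) {
    stop_config("more cells than image columns: n_cells > image_width_px")
  }
  if (row_top_px < 0 || row_top_px + row_height_px > image_height_px) {
    stop_config("grille row must lie within the image")
  }
  if (area_threshold_px2 < 0) {
    stop_config("`area_threshold_px2` must be non-negative")
  }
  structure(list(n_cells = as.integer(n_cells),
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 row_height_px = as.integer(row_height_px),
                 row_top_px = as.numeric(row_top_px),
                 area_threshold_px2 = as.numeric(area_threshold_px2)),
            class = "grille_config")
}

#' Build the grille cell rectangles
#'
#' Cells are contiguous and pairwise disjoint, their widths differ by at
#' most one pixel, and they sum exactly to the image width. When the
#' width is not divisible by `n_cells` the extra pixels go to the
#' leftmost cells.
#'
#' @param config a [grille_config()].
#' @return a data.frame with one row per cell: `cell`, `x1`, `y1`, `x2`,
#'   `y2` (half-open pixel rectangles).
#' @examples
#' table(with(build_grille(grille_config(11, 1920)), x2 - x1))
#' @export
build_grille <- function(config) {
  stopifnot(inherits(config, "grille_config"))
  n <- config$n_cells
  w <- config$image_width_px
  base <- w %/% n
  extra <- w %% n
  widths <- rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
  x2 <- cumsum(widths)
  data.frame(cell = seq_len(n) - 1L,
             x1 = c(0, x2[-n]),
             y1 = config$row_top_px,
             x2 = x2,
             y2 = config$row_top_px + config$row_height_px)
}

#' Rectangle intersection area
#'
#' Overlap area of half-open axis-aligned rectangles,
#' `max(0, overlap_x) * max(0, overlap_y)`. Vectorised over rows of
#' either argument (recycled against each other row-wise).
#'
#' @param box,cell data.frames (or lists) with columns `x1,y1,x2,y2`.
#' @return numeric vector of intersection areas in square pixels.
#' @export
intersection_area <- function(box, cell) {
  ox <- pmin(box$x2, cell$x2) - pmax(box$x1, cell$x1)
  oy <- pmin(box$y2, cell$y2) - pmax(box$y1, cell$y1)
  pmax(0, ox) * pmax(0, oy)
}

#' Decide the valve bit vector for one frame
#'
#' Bit i is 1 iff some prediction box overlaps cell i by strictly more
#' than the configured threshold area — the per-cell decision is a
#' logical OR over boxes. Boxes are clipped to the image first. Index 0
#' is the leftmost cell.
#'
#' @param boxes a [pred_boxes()] data.frame (possibly empty).
#' @param config a [grille_config()].
#' @return an integer 0/1 vector of length `n_cells`, class
#'   `decision_vector`.
#' @export
decide_frame <- function(boxes, config) {
  stopifnot(inherits(config, "grille_config"))
  cells <- build_grille(config)
  bits <- integer(config$n_cells)
  boxes <- clip_boxes(boxes, config$image_width_px, config$image_height_px)
  if (nrow(boxes)) {
    for (i in seq_len(config$n_cells)) {
      a <- intersection_area(boxes, cells[i, ])
      if (any(a > config$area_threshold_px2)) bits[i] <- 1L
    }
  }
  structure(bits, class = "decision_vector")
}

#' @export
print.decision_vector <- function(x, ...) {
  cat("<decision_vector>", paste0(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Decide a stream of frames
#'
#' Stateless per-frame re-evaluation of [decide_frame()]: a bit drops
#' back to 0 in the first frame whose boxes no longer exceed the
#' threshold, like a touch switch that pops up when the box leaves.
#'
#' @param frame_boxes list of [pred_boxes()] data.frames, one per frame.
#' @param config a [grille_config()].
#' @return a list of `decision_vector`s, one per frame.
#' @export
decision_stream <- function(frame_boxes, config) {
  lapply(frame_boxes, decide_frame, config = config)
}
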