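# Pixel-to-ground calibration for a boom-mounted downward camera rig, and
# the real-time constraint linking grille width, ground scale and forward
# speed. The boom is split evenly between the cameras with no overlap, so
# the ground span imaged by one camera is boom_width_m / n_cameras.

#' Camera and boom geometry
#'
#' Describes the sprayer's imaging setup: one or more downward-facing
#' cameras sharing the boom's operating width equally. The default values
#' are a 3.3 m boom imaged by two 1920x1080 cameras mounted 1 m above the
#' ground, which gives a ground scale of 0.859 mm per pixel.
#'
#' @param image_width_px,image_height_px sensor resolution in pixels.
#' @param boom_width_m operating width of the spray boom in metres.
#' @param n_cameras number of cameras sharing the boom width.
#' @param mount_height_m camera height above ground in metres
#'   (metadata only; the scale is fixed by boom span and pixel width).
#' @return an object of class `camera_setup`.
#' @seealso [ground_scale()]
#' @examples
#' camera_setup()
#' @export
camera_setup <- function(image_width_px = 1920, image_height_px = 1080,
                         boom_width_m = 3.3, n_cameras = 2,
                         mount_height_m = 1) {
  check_positive(image_width_px, "image_width_px")
  check_positive(image_height_px, "image_height_px")
  check_positive(boom_width_m, "boom_width_m")
  check_positive(n_cameras, "n_cameras")
  check_positive(mount_height_m, "mount_height_m")
  if (n_cameras != round(n_cameras)) {
    stop_config("`n_cameras` must be a whole number")
  }
  structure(
    list(image_width_px = as.numeric(image_width_px),
         image_height_px = as.numeric(image_height_px),
         boom_width_m = as.numeric(boom_width_m),
         n_cameras = as.integer(n_cameras),
         mount_height_m = as.numeric(mount_height_m)),
    class = "camera_setup")
}

#' @export
print.camera_setup <- function(x, ...) {
  cat(sprintf("<camera_setup> %dx%d px, boom %.2f m / %d camera(s), height %.2f m\n",
              x$image_width_px, x$image_height_px, x$boom_width_m,
              x$n_cameras, x$mount_height_m))
  invisible(x)
}

#' Ground scale of one image pixel
#'
#' Each camera images a ground span of `boom_width_m / n_cameras`, so one
#' pixel corresponds to that span divided by the horizontal resolution.
#' The unrounded value is carried internally; the conventional 3-decimal
#' report (e.g. 0.859 mm/px for a 3.3 m boom, two cameras, 1920 px) is
#' available as `mm_per_px_rounded`.
#'
#' @param setup a [camera_setup()], or a single positive number taken
#'   directly as millimetres per pixel.
#' @return an object of class `ground_scale` with fields `mm_per_px`
#'   (unrounded) and `mm_per_px_rounded` (3 decimals).
#' @examples
#' ground_scale(camera_setup())            # 0.859 mm/px
#' ground_scale(camera_setup(1920, 1080, boom_width_m = 1.92, n_cameras = 1))
#' @export
ground_scale <- function(setup) {
  if (is.numeric(setup) && length(setup) == 1L) {
    check_positive(setup, "mm_per_px")
    mm <- as.numeric(setup)
  } else {
    stopifnot(inherits(setup, "camera_setup"))
    mm <- (setup$boom_width_m / setup$n_cameras) * 1000 / setup$image_width_px
  }
  structure(list(mm_per_px = mm,
                 mm_per_px_rounded = round_half_up(mm, 3)),
            class = "ground_scale")
}

#' @export
print.ground_scale <- function(x, ...) {
  cat(sprintf("<ground_scale> %.3f mm/px (unrounded %.6f)\n",
              x$mm_per_px_rounded, x$mm_per_px))
  invisible(x)
}

#' Vehicle motion profile
#'
#' @param speed_kmh forward speed in km/h (may be zero).
#' @param fps frames processed per second by the detection pipeline.
#' @return an object of class `motion_profile`.
#' @export
motion_profile <- function(speed_kmh, fps) {
  if (!is.numeric(speed_kmh) || length(speed_kmh) != 1L || is.na(speed_kmh) ||
      speed_kmh < 0) {
    stop_config("`speed_kmh` must be a single non-negative number")
  }
  check_positive(fps, "fps")
  structure(list(speed_kmh = as.numeric(speed_kmh), fps = as.numeric(fps)),
            class = "motion_profile")
}

#' Ground distance advanced while one frame is processed
#'
#' Converts the forward speed to mm/s and divides by the frame rate. This
#' is the distance the sprayer moves between successive valve decisions,
#' and hence the minimum ground width the decision grille must cover.
#'
#' @param motion a [motion_profile()].
#' @return distance in millimetres.
#' @examples
#' advance_per_frame(motion_profile(4, 26.73))  # ~41.57 mm
#' @export
advance_per_frame <- function(motion) {
  stopifnot(inherits(motion, "motion_profile"))
  motion$speed_kmh * 1e6 / 3600 / motion$fps
}

#' Check the real-time grille-width constraint
#'
#' The grille row's ground width must exceed the distance the vehicle
#' advances per processed frame, otherwise ground can pass under the
#' nozzle line without ever being scanned and weeds are missed.
#'
#' @param grille_width_px grille row height in pixels (e.g. 60).
#' @param scale a [ground_scale()] (or mm/px number).
#' @param motion a [motion_profile()].
#' @return a list with `pass` (logical), `margin_mm`
#'   (`grille width on the ground - advance per frame`), `grille_mm`, and
#'   `advance_mm`.
#' @examples
#' check_grille_constraint(60, ground_scale(0.859), motion_profile(4, 26.73))
#' @export
check_grille_constraint <- function(grille_width_px, scale, motion) {
  check_positive(grille_width_px, "grille_width_px")
  if (!inherits(scale, "ground_scale")) scale <- ground_scale(scale)
  stopifnot(inherits(motion, "motion_profile"))
  grille_mm <- grille_width_px * scale$mm_per_px
  advance_mm <- advance_per_frame(motion)
  list(pass = grille_mm > advance_mm,
       margin_mm = grille_mm - advance_mm,
       grille_mm = grille_mm,
       advance_mm = advance_mm)
}
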