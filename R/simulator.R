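# In-silico field pass of the target sprayer: synthetic weed scenes,
# sprayer kinematics frame by frame, the grille decision pipeline, valve
# schedules, sprayed ground strips and the resulting trial-table rates.
#
# Ground frame: x across the boom [m] (0 at the left edge of the
# simulated camera's span), y along the direction of travel [m]
# (increasing ahead of the start line). The camera footprint advances in
# +y; the image's bottom edge is the footprint's trailing (smallest-y)
# edge, so ground scrolls downward through the image as the machine
# advances.

#' Synthetic weed scene
#'
#' Weed positions follow a homogeneous spatial Poisson process with the
#' given density over the rectangular area; canopy radii are drawn from
#' a log-normal. Reproducible for a fixed seed.
#'
#' @param density expected weeds per square metre.
#' @param area `c(length_m, width_m)` of the field strip; the default
#'   20 x 3 m matches a typical trial plot.
#' @param radius_meanlog,radius_sdlog log-normal canopy radius
#'   parameters, in metres (defaults give a median canopy radius of
#'   ~45 mm, a young rosette-stage weed).
#' @param seed RNG seed.
#' @return an object of class `field_scene`: list with `area` and
#'   `weeds` (data.frame `x`, `y` [m], `radius` [m]).
#' @export
generate_scene <- function(density, area = c(20, 3),
                           radius_meanlog = log(0.045),
                           radius_sdlog = 0.25, seed = 0) {
  if (density < 0) stop_config("`density` must be non-negative")
  stopifnot(length(area) == 2, all(area > 0))
  set.seed(derive_seed(seed, "scene"))
  n <- stats::rpois(1, density * area[1] * area[2])
  weeds <- data.frame(
    x = stats::runif(n, 0, area[2]),
    y = stats::runif(n, 0, area[1]),
    radius = stats::rlnorm(n, radius_meanlog, radius_sdlog))
  structure(list(area = area, weeds = weeds), class = "field_scene")
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene> %.0f x %.0f m, %d weeds\n",
              x$area[1], x$area[2], nrow(x$weeds)))
  invisible(x)
}

#' Simulation parameters
#'
#' Describes one sprayer pass. The two speed-coupled degradation
#' mechanisms emulate what field trials attribute to terrain-induced
#' vibration: image blur lowers the per-frame detection probability
#' (`p_detect_frame * exp(-detect_speed_penalty * speed)`), and nozzle
#' vibration displaces the sprayed strip laterally and longitudinally
#' (`sigma_vib = sigma_vib0_mm * speed`).
#'
#' @param speed_kmh forward speed in km/h.
#' @param fps detection frame rate (default 26.73).
#' @param p_detect_frame probability that a weed overlapping the grille
#'   band is detected in any single frame, at rest.
#' @param detect_speed_penalty per-(km/h) exponential penalty on the
#'   detection probability (default 0.06).
#' @param sigma_loc_mm localisation noise of a detected box, mm on the
#'   ground.
#' @param sigma_vib0_mm nozzle vibration displacement per km/h of speed
#'   (mm); applied to each sprayed strip (default 5).
#' @param latency_ms processing-to-actuation delay; shifts strips
#'   backwards along the travel axis (default 0).
#' @param nozzle_spacing_m lateral nozzle spacing (default 0.15).
#' @param margin_mm longitudinal redundancy margin added to each strip
#'   (defaults to the grille band's ground depth at run time when NA).
#' @param hit_criterion `"center"` (canopy centre inside the strip) or
#'   `"area"` (at least `hit_area_frac` of the canopy disc covered).
#' @param hit_area_frac canopy coverage fraction for the `"area"`
#'   criterion.
#' @param seed RNG seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(speed_kmh = 2, fps = 26.73, p_detect_frame = 0.85,
                       detect_speed_penalty = 0.06, sigma_loc_mm = 3,
                       sigma_vib0_mm = 5, latency_ms = 0,
                       nozzle_spacing_m = 0.15, margin_mm = NA,
                       hit_criterion = c("center", "area"),
                       hit_area_frac = 0.5, seed = 0) {
  stopifnot(speed_kmh >= 0, fps > 0,
            p_detect_frame >= 0, p_detect_frame <= 1,
            detect_speed_penalty >= 0, sigma_loc_mm >= 0,
            sigma_vib0_mm >= 0, latency_ms >= 0, nozzle_spacing_m > 0)
  structure(list(speed_kmh = speed_kmh, fps = fps,
                 p_detect_frame = p_detect_frame,
                 detect_speed_penalty = detect_speed_penalty,
                 sigma_loc_mm = sigma_loc_mm,
                 sigma_vib0_mm = sigma_vib0_mm,
                 latency_ms = latency_ms,
                 nozzle_spacing_m = nozzle_spacing_m,
                 margin_mm = margin_mm,
                 hit_criterion = match.arg(hit_criterion),
                 hit_area_frac = hit_area_frac,
                 seed = seed),
            class = "sim_params")
}

#' Sprayed ground strips from a valve timeline
#'
#' Each open interval becomes one ground strip in its valve's lane:
#' the longitudinal span is the nozzle-line travel during the interval
#' plus the redundancy margin, the lateral span is the lane width.
#' Overlapping strips within a lane are merged.
#'
#' @param timeline a [apply_rate_limit()] result.
#' @param speed_kmh forward speed.
#' @param margin_mm longitudinal redundancy margin (mm).
#' @param y0_m nozzle-line ground position (m) at time 0.
#' @return list with one `n x 2` matrix of `[y_start, y_end)` metre
#'   intervals per valve lane.
#' @export
coverage_map <- function(timeline, speed_kmh, margin_mm = 0, y0_m = 0) {
  stopifnot(inherits(timeline, "valve_timeline"))
  v_ms <- speed_kmh / 3.6
  lapply(timeline$intervals, function(iv) {
    if (!nrow(iv)) return(matrix(numeric(), ncol = 2))
    strips <- cbind(y0_m + v_ms * iv[, 1],
                    y0_m + v_ms * iv[, 2] + margin_mm / 1000)
    merge_intervals(strips[order(strips[, 1]), , drop = FALSE])
  })
}

#' Simulate one sprayer pass over a scene
#'
#' The boom's cameras tile its width; each camera footprint advances
#' frame by frame at the configured speed. A weed whose canopy disc
#' overlaps its camera's grille band ground projection is detected in
#' that frame with the (speed-penalised) per-frame detection
#' probability; detected weeds contribute pixel boxes (perturbed by
#' localisation noise) to their camera's grille decision, the per-frame
#' decision vectors of all cameras are concatenated into one valve
#' request stream, shaped into a timeline by [apply_rate_limit()], and
#' turned into sprayed ground strips whose positions are perturbed by
#' speed-proportional vibration. A weed counts as identified when it
#' was detected in at least one frame, and as hit when a sprayed strip
#' covering its position exists under the configured hit criterion
#' (weeds straddling a lane boundary may be covered by either
#' neighbouring lane).
#'
#' @param scene a [generate_scene()] result; scene x (width) must not
#'   exceed the boom width.
#' @param params a [sim_params()].
#' @param grille a per-camera [grille_config()]; defaults to one cell
#'   per nozzle (`nozzle_spacing_m`).
#' @param setup a [camera_setup()].
#' @return an object of class `sim_result`: `counts` ([trial_counts()]),
#'   `rates` ([rates_from_counts()]), `events` (per-weed log:
#'   `n_frames_in_band`, `n_detections`, `identified`, `hit`, `lane`),
#'   `timeline`, `strips`, `lanes`, `p_detect_effective`, `constraint`,
#'   `params`.
#' @export
simulate_pass <- function(scene, params, grille = NULL, setup = camera_setup()) {
  stopifnot(inherits(scene, "field_scene"), inherits(params, "sim_params"))
  scale <- ground_scale(setup)
  cam_width_m <- setup$boom_width_m / setup$n_cameras
  if (is.null(grille)) {
    n_cells <- max(1L, round(cam_width_m / params$nozzle_spacing_m))
    grille <- grille_config(n_cells, setup$image_width_px,
                            setup$image_height_px)
  }
  motion <- motion_profile(params$speed_kmh, params$fps)
  cons <- check_grille_constraint(grille$row_height_px, scale, motion)
  if (!cons$pass) {
    warning(sprintf(
      "grille band (%.1f mm) narrower than per-frame advance (%.1f mm): expect misses",
      cons$grille_mm, cons$advance_mm))
  }
  set.seed(derive_seed(params$seed, "pass"))

  mm_px <- scale$mm_per_px
  v_ms <- params$speed_kmh / 3.6
  dt <- 1 / params$fps
  weeds <- scene$weeds
  nw <- nrow(weeds)
  band_mm <- grille$row_height_px * mm_px
  band_m <- band_mm / 1000
  footprint_m <- setup$image_height_px * mm_px / 1000
  n_cam <- setup$n_cameras
  n_cells <- grille$n_cells
  n_lanes <- n_cam * n_cells

  # effective per-frame detection probability under the speed penalty
  p_eff <- params$p_detect_frame *
    exp(-params$detect_speed_penalty * params$speed_kmh)

  # ground lane boundaries from the pixel grille cells, so that the
  # decision cell and the sprayed lane of a weed agree exactly
  cells <- build_grille(grille)
  lanes <- do.call(rbind, lapply(seq_len(n_cam) - 1L, function(cam) {
    data.frame(lane = cam * n_cells + cells$cell + 1L,
               x_lo = cam * cam_width_m + cells$x1 * mm_px / 1000,
               x_hi = cam * cam_width_m + cells$x2 * mm_px / 1000)
  }))
  lane_of <- function(x) {
    i <- findInterval(x, c(lanes$x_lo, lanes$x_hi[n_lanes]),
                      rightmost.closed = TRUE)
    pmin(pmax(i, 1L), n_lanes)
  }
  lane <- lane_of(weeds$x)
  in_span <- weeds$x >= 0 & weeds$x < n_cam * cam_width_m

  # the grille band's trailing edge starts just behind the plot and
  # travels past its far end
  y_start <- -band_m
  n_frames <- if (v_ms == 0) 1 else {
    ceiling((scene$area[1] + band_m + footprint_m) / (v_ms * dt)) + 1
  }

  requests <- matrix(0L, nrow = n_frames, ncol = n_lanes)
  detect_count <- integer(nw)
  frames_in_band <- integer(nw)
  cam_of_weed <- pmin(pmax(floor(weeds$x / cam_width_m), 0L), n_cam - 1L)

  for (f in seq_len(n_frames)) {
    y_band0 <- y_start + (f - 1) * v_ms * dt  # trailing edge of band [m]
    y_band1 <- y_band0 + band_m
    in_band <- which(in_span & weeds$y + weeds$radius > y_band0 &
                       weeds$y - weeds$radius < y_band1)
    if (!length(in_band)) next
    frames_in_band[in_band] <- frames_in_band[in_band] + 1L
    det <- in_band[stats::runif(length(in_band)) < p_eff]
    if (!length(det)) next
    detect_count[det] <- detect_count[det] + 1L
    # ground y of image row 0 (the leading edge side)
    y_top <- y_band1 + grille$row_top_px * mm_px / 1000
    ex <- stats::rnorm(length(det), 0, params$sigma_loc_mm) / 1000
    ey <- stats::rnorm(length(det), 0, params$sigma_loc_mm) / 1000
    cy_px <- (y_top - (weeds$y[det] + ey)) * 1000 / mm_px
    r_px <- weeds$radius[det] * 1000 / mm_px
    for (cam in unique(cam_of_weed[det])) {
      sel <- which(cam_of_weed[det] == cam)
      cx_px <- (weeds$x[det][sel] + ex[sel] - cam * cam_width_m) *
        1000 / mm_px
      b <- pred_boxes(cx_px - r_px[sel], cy_px[sel] - r_px[sel],
                      cx_px + r_px[sel], cy_px[sel] + r_px[sel])
      bits <- as.integer(unclass(decide_frame(b, grille)))
      cols <- cam * n_cells + seq_len(n_cells)
      requests[f, cols] <- pmax(requests[f, cols], bits)
    }
  }

  timeline <- apply_rate_limit(requests, params$fps)
  margin_mm <- if (is.na(params$margin_mm)) band_mm else params$margin_mm
  # nozzle line at the grille band's trailing ground edge; actuation
  # latency shifts coverage backwards relative to the target
  lat_shift <- -params$latency_ms / 1000 * v_ms
  strips <- coverage_map(timeline, params$speed_kmh, margin_mm,
                         y0_m = y_start + lat_shift)

  # vibration: one lateral + one longitudinal displacement per strip
  sigma_vib_m <- params$sigma_vib0_mm * params$speed_kmh / 1000
  hit <- logical(nw)
  identified <- detect_count > 0
  for (j in seq_len(n_lanes)) {
    st <- strips[[j]]
    if (!nrow(st)) next
    # candidate weeds: identified, in this lane or near its boundary
    members <- which(identified &
                       weeds$x >= lanes$x_lo[j] - 0.02 &
                       weeds$x < lanes$x_hi[j] + 0.02)
    if (!length(members)) next
    for (k in seq_len(nrow(st))) {
      dx <- stats::rnorm(1, 0, sigma_vib_m)
      dy <- stats::rnorm(1, 0, sigma_vib_m)
      x_lo <- lanes$x_lo[j] + dx; x_hi <- lanes$x_hi[j] + dx
      y_lo <- st[k, 1] + dy; y_hi <- st[k, 2] + dy
      for (w in members) {
        if (hit[w]) next
        ok <- if (params$hit_criterion == "center") {
          weeds$x[w] >= x_lo && weeds$x[w] < x_hi &&
            weeds$y[w] >= y_lo && weeds$y[w] < y_hi
        } else {
          disc_rect_coverage(weeds$x[w], weeds$y[w], weeds$radius[w],
                             x_lo, y_lo, x_hi, y_hi) >=
            params$hit_area_frac
        }
        if (ok) hit[w] <- TRUE
      }
    }
  }

  counts <- trial_counts(nw, sum(identified), sum(hit & identified))
  structure(list(
    counts = counts,
    rates = if (nw > 0) rates_from_counts(counts) else NULL,
    events = data.frame(weed = seq_len(nw), x = weeds$x, y = weeds$y,
                        radius = weeds$radius, lane = lane,
                        n_frames_in_band = frames_in_band,
                        n_detections = detect_count,
                        identified = identified, hit = hit & identified),
    timeline = timeline, strips = strips, lanes = lanes,
    p_detect_effective = p_eff,
    constraint = cons, params = params),
    class = "sim_result")
}

# fraction of a disc's area inside an axis-aligned rectangle, by
# midpoint quadrature on a 21x21 grid (adequate for a hit criterion)
disc_rect_coverage <- function(cx, cy, r, x_lo, y_lo, x_hi, y_hi) {
  g <- seq(-r, r, length.out = 21)
  px <- rep(cx + g, times = 21); py <- rep(cy + g, each = 21)
  inside_disc <- (px - cx)^2 + (py - cy)^2 <= r^2
  inside_rect <- px >= x_lo & px < x_hi & py >= y_lo & py < y_hi
  sum(inside_disc & inside_rect) / max(1, sum(inside_disc))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.1f km/h: ", x$params$speed_kmh))
  if (is.null(x$rates)) cat("empty scene\n") else {
    cat(sprintf("u %.2f%%  w' %.2f%%  w %.2f%%  (%d/%d/%d)\n",
                x$rates$percent[["u"]], x$rates$percent[["w_rel"]],
                x$rates$percent[["w_abs"]], x$counts$n_total,
                x$counts$n_identified, x$counts$n_hit))
  }
  invisible(x)
}

#' Sweep a scene across forward speeds
#'
#' Runs [simulate_pass()] on the same scene at each speed, optionally
#' averaged over several paired seeds (the same seed list is reused at
#' every speed, so speed comparisons use common random numbers), and
#' reports a trial-style table.
#'
#' @param scene a [generate_scene()] result.
#' @param speeds numeric vector of at least 2 forward speeds (km/h).
#' @param params a [sim_params()] template (its speed and seed fields
#'   are overridden).
#' @param n_seeds number of paired replicate seeds per speed.
#' @param grille,setup forwarded to [simulate_pass()].
#' @return a data.frame of class `speed_sweep`: one row per (speed,
#'   seed) with counts and unrounded percentage rates, plus attribute
#'   `"summary"` with per-speed means.
#' @export
speed_sweep <- function(scene, speeds, params = sim_params(),
                        n_seeds = 1, grille = NULL,
                        setup = camera_setup()) {
  if (length(speeds) < 2) stop_config("need at least 2 speeds")
  rows <- list()
  for (v in speeds) {
    for (s in seq_len(n_seeds)) {
      p <- params
      p$speed_kmh <- v
      p$seed <- derive_seed(params$seed, paste0("sweep", s))
      r <- simulate_pass(scene, p, grille = grille, setup = setup)
      rows[[length(rows) + 1L]] <- data.frame(
        speed_kmh = v, seed = s,
        n_total = r$counts$n_total,
        n_identified = r$counts$n_identified,
        n_hit = r$counts$n_hit,
        u_pct = 100 * r$rates$u,
        w_rel_pct = 100 * r$rates$w_rel,
        w_abs_pct = 100 * r$rates$w_abs)
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(out[, c("u_pct", "w_rel_pct", "w_abs_pct")],
                           by = list(speed_kmh = out$speed_kmh), FUN = mean)
  attr(out, "summary") <- summ
  class(out) <- c("speed_sweep", "data.frame")
  out
}
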