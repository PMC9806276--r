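test_that("scene generation is Poisson in count and seed-reproducible", {
  empty <- generate_scene(0, c(20, 3), seed = 1)
  expect_equal(nrow(empty$weeds), 0)

  expect_identical(generate_scene(1, c(20, 3), seed = 42)$weeds,
                   generate_scene(1, c(20, 3), seed = 42)$weeds)

  counts <- vapply(1:200, function(s) {
    nrow(generate_scene(1, c(20, 3), seed = s)$weeds)
  }, numeric(1))
  # pooled count over 200 seeds is Poisson(12000); check its 99.9% range
  lim <- qpois(c(0.0005, 0.9995), 200 * 60)
  expect_gt(sum(counts), lim[1])
  expect_lt(sum(counts), lim[2])
  # and individual counts concentrate in the Poisson(60) 99% range
  qr <- qpois(c(0.005, 0.995), 60)
  expect_gt(mean(counts >= qr[1] & counts <= qr[2]), 0.95)
  # weeds stay inside the area, radii positive
  sc <- generate_scene(2, c(10, 2), seed = 3)
  expect_true(all(sc$weeds$x >= 0 & sc$weeds$x <= 2))
  expect_true(all(sc$weeds$y >= 0 & sc$weeds$y <= 10))
  expect_true(all(sc$weeds$radius > 0))
})

test_that("rendered frames project weeds where the geometry says", {
  setup <- camera_setup(64, 64, boom_width_m = 0.064, n_cameras = 1)
  empty <- structure(list(area = c(0.064, 0.064),
                          weeds = data.frame(x = numeric(), y = numeric(),
                                             radius = numeric())),
                     class = "field_scene")
  fr0 <- render_frame(empty, 0, setup)
  expect_equal(nrow(fr0$boxes), 0)
  expect_equal(dim(fr0$image), c(64, 64, 3))

  # single weed at the footprint centre: box centred mid-image with side
  # ~ 2 r / mm_per_px (1 mm/px here)
  one <- structure(list(area = c(0.064, 0.064),
                        weeds = data.frame(x = 0.032, y = 0.032,
                                           radius = 0.010)),
                   class = "field_scene")
  fr1 <- render_frame(one, 0, setup)
  expect_equal(nrow(fr1$boxes), 1)
  expect_equal((fr1$boxes$x1 + fr1$boxes$x2) / 2, 32, tolerance = 1e-6)
  expect_equal((fr1$boxes$y1 + fr1$boxes$y2) / 2, 32, tolerance = 1e-6)
  expect_equal(fr1$boxes$x2 - fr1$boxes$x1, 20, tolerance = 1e-6)
  # and green dominates inside the canopy
  expect_gt(fr1$image[32, 32, 2], fr1$image[32, 32, 1])

  # boxes stay inside the image for random scenes and positions
  for (s in 1:50) {
    set.seed(s)
    sc <- generate_scene(400, c(0.064, 0.064), radius_meanlog = log(0.008),
                         seed = s)
    fr <- render_frame(sc, runif(1, -0.02, 0.02), setup, seed = s)
    if (nrow(fr$boxes)) {
      expect_true(all(fr$boxes$x1 >= 0 & fr$boxes$x2 <= 64 &
                        fr$boxes$y1 >= 0 & fr$boxes$y2 <= 64))
    }
  }
})

test_that("coverage strips follow speed, margin and interval union", {
  req <- matrix(0L, nrow = 100, ncol = 2)
  req[11:20, 1] <- 1L              # one 10-frame open
  req[c(31:33, 35:37), 2] <- 1L    # two opens separated by one frame
  fps <- 20
  tl <- apply_rate_limit(req, fps = fps, max_freq = 10, min_open_s = 0)
  v <- 2  # km/h
  m <- coverage_map(tl, v, margin_mm = 50, y0_m = 0)
  v_ms <- v / 3.6
  # strip = travel during the interval plus the margin
  iv <- tl$intervals[[1]]
  expect_equal(unname(m[[1]][1, ]),
               unname(c(v_ms * iv[1, 1], v_ms * iv[1, 2] + 0.05)))
  # second valve: strips merge iff gaps close under the margin
  iv2 <- tl$intervals[[2]]
  raw <- cbind(v_ms * iv2[, 1], v_ms * iv2[, 2] + 0.05)
  expect_equal(sum(m[[2]][, 2] - m[[2]][, 1]), interval_union_length(raw),
               tolerance = 1e-12)
})

test_that("an ideal pass identifies and hits every weed", {
  scene <- generate_scene(1, c(20, 3), seed = 10)
  ideal <- sim_params(speed_kmh = 2, p_detect_frame = 1,
                      detect_speed_penalty = 0, sigma_loc_mm = 0,
                      sigma_vib0_mm = 0, latency_ms = 0, seed = 1)
  r <- simulate_pass(scene, ideal)
  expect_equal(r$rates$u, 1)
  expect_equal(r$rates$w_rel, 1)
  expect_equal(r$rates$w_abs, 1)

  # and a blind pass identifies nothing
  blind <- sim_params(speed_kmh = 2, p_detect_frame = 0, seed = 1)
  r0 <- simulate_pass(scene, blind)
  expect_equal(r0$counts$n_identified, 0)
  expect_equal(r0$rates$w_abs, 0)
  expect_true(r0$rates$degenerate)
})

test_that("pass results are seed-deterministic and Eq-consistent", {
  scene <- generate_scene(1.5, c(10, 3), seed = 2)
  p <- sim_params(speed_kmh = 3, p_detect_frame = 0.7, seed = 33)
  r1 <- simulate_pass(scene, p)
  r2 <- simulate_pass(scene, p)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counts, r2$counts)
  # recognition/hit identity holds exactly on the unrounded rates
  expect_equal(r1$rates$w_abs, r1$rates$u * r1$rates$w_rel,
               tolerance = 1e-12)
  # rates consistent with the event log
  expect_equal(r1$counts$n_identified, sum(r1$events$identified))
  expect_equal(r1$counts$n_hit, sum(r1$events$hit))
})

test_that("empirical recognition matches the per-frame detection model", {
  # >= 500 weeds; moderate p so the per-weed pass probability is not
  # saturated; oracle: p_pass_i = 1 - (1 - p)^frames_in_band_i
  scene <- generate_scene(9, c(20, 3), seed = 6)
  expect_gte(nrow(scene$weeds), 500)
  p <- sim_params(speed_kmh = 4, p_detect_frame = 0.25,
                  detect_speed_penalty = 0, sigma_loc_mm = 0,
                  sigma_vib0_mm = 0, seed = 17)
  r <- simulate_pass(scene, p)
  ev <- r$events
  p_pass <- 1 - (1 - r$p_detect_effective)^ev$n_frames_in_band
  mu <- sum(p_pass)
  sd <- sqrt(sum(p_pass * (1 - p_pass)))
  got <- r$counts$n_identified
  expect_gt(got, mu - 1.96 * sd)
  expect_lt(got, mu + 1.96 * sd)
})

test_that("speed sweeps report one row per speed and stay ideal when noiseless", {
  scene <- generate_scene(1, c(10, 3), seed = 5)
  ideal <- sim_params(p_detect_frame = 1, detect_speed_penalty = 0,
                      sigma_loc_mm = 0, sigma_vib0_mm = 0, seed = 9)
  sw <- speed_sweep(scene, c(2, 3, 4), ideal, n_seeds = 2)
  expect_equal(nrow(sw), 6)
  expect_true(all(sw$u_pct == 100 & sw$w_abs_pct == 100))
  summ <- attr(sw, "summary")
  expect_equal(summ$speed_kmh, c(2, 3, 4))
  expect_error(speed_sweep(scene, 2, ideal), class = "spotspray_config_error")
})

test_that("a sub-constraint grille warns and misses weeds", {
  scene <- generate_scene(2, c(10, 3), seed = 8)
  # 10 px band (8.6 mm) vs 41.6 mm advance at 4 km/h: under-scanned
  gr <- grille_config(11, 1920, 1080, row_height_px = 10)
  p <- sim_params(speed_kmh = 4, p_detect_frame = 1,
                  detect_speed_penalty = 0, sigma_loc_mm = 0,
                  sigma_vib0_mm = 0, seed = 3)
  expect_warning(r <- simulate_pass(scene, p, grille = gr),
                 "narrower than")
  expect_false(r$constraint$pass)
  # weeds can slip through entirely between frames only when small;
  # with a canopy larger than the gap all are still seen, so just check
  # the constraint result is reported honestly
  expect_lt(r$constraint$margin_mm, 0)
})
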