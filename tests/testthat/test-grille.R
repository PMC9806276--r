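test_that("grille cells tile the image width with near-equal widths", {
  g <- build_grille(grille_config(11, 1920))
  w <- g$x2 - g$x1
  expect_equal(sort(unique(w)), c(174, 175))
  expect_equal(as.vector(table(w)), c(5, 6))  # 175 x 6, 174 x 5
  expect_equal(sum(w), 1920)
  expect_true(all(diff(w) <= 0))  # remainder distributed left-to-right

  g1 <- build_grille(grille_config(1, 1920))
  expect_equal(c(g1$x1, g1$x2), c(0, 1920))

  # random configs: pairwise disjoint, contiguous, exact tiling
  set.seed(1)
  for (i in 1:20) {
    wpx <- sample(50:2000, 1)
    n <- sample(1:min(wpx, 40), 1)
    cfg <- grille_config(n, wpx, image_height_px = 200, row_height_px = 10)
    cells <- build_grille(cfg)
    expect_equal(cells$x1, c(0, cells$x2[-n]))
    expect_equal(cells$x2[n], wpx)
    expect_true(all(cells$x2 - cells$x1 >= 1))
    expect_lte(diff(range(cells$x2 - cells$x1)), 1)
  }
  expect_error(grille_config(100, 50), class = "spotspray_config_error")
})

test_that("analytic intersection area equals pixel rasterisation", {
  box <- pred_boxes(100, 500, 250, 600)
  cell <- list(x1 = 174, y1 = 480, x2 = 349, y2 = 540)
  expect_equal(intersection_area(box, cell), 3040)
  expect_equal(raster_intersection(box, cell), 3040)

  expect_equal(intersection_area(pred_boxes(0, 0, 10, 10),
                                 list(x1 = 10, y1 = 0, x2 = 20, y2 = 10)), 0)
  big <- pred_boxes(0, 0, 100, 100)
  expect_equal(intersection_area(big, list(x1 = 20, y1 = 30, x2 = 40, y2 = 50)),
               20 * 20)

  set.seed(99)
  for (i in 1:300) {
    a <- sort(sample(0:60, 2)); b <- sort(sample(0:60, 2))
    cx <- sort(sample(0:60, 2)); cy <- sort(sample(0:60, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1
    if (b[1] == b[2]) b[2] <- b[2] + 1
    if (cx[1] == cx[2]) cx[2] <- cx[2] + 1
    if (cy[1] == cy[2]) cy[2] <- cy[2] + 1
    box <- pred_boxes(a[1], b[1], a[2], b[2])
    cell <- list(x1 = cx[1], y1 = cy[1], x2 = cx[2], y2 = cy[2])
    expect_identical(as.numeric(intersection_area(box, cell)),
                     as.numeric(raster_intersection(box, cell)))
  }
})

test_that("frame decisions set exactly the over-threshold cells", {
  cfg <- grille_config(11, 1920, 1080, row_height_px = 60,
                       area_threshold_px2 = 0)
  expect_equal(unclass(decide_frame(no_boxes(), cfg)), rep(0L, 11))

  # box spanning cells 3 and 4 (0-based): cells cover x in [525,700) and
  # [700,875); grille row occupies y in [1020, 1080)
  cells <- build_grille(cfg)
  b <- pred_boxes(600, 1000, 800, 1080)
  bits <- decide_frame(b, cfg)
  expect_equal(which(bits == 1L) - 1L, c(3L, 4L))

  # threshold equal to the full cell area with an exactly-covering box:
  # strict inequality keeps the bit at 0
  cell0 <- cells[1, ]
  cfg_thr <- grille_config(11, 1920, 1080, row_height_px = 60,
                           area_threshold_px2 = (cell0$x2 - cell0$x1) * 60)
  exact <- pred_boxes(cell0$x1, cell0$y1, cell0$x2, cell0$y2)
  expect_equal(unclass(decide_frame(exact, cfg_thr)), rep(0L, 11))
})

test_that("decisions are monotone in box size and threshold", {
  set.seed(5)
  cfg0 <- grille_config(8, 800, 600, row_height_px = 40)
  for (i in 1:50) {
    x1 <- runif(1, 0, 700); y1 <- runif(1, 500, 590)
    bx <- pred_boxes(x1, y1, x1 + runif(1, 5, 100), y1 + runif(1, 5, 60))
    thr <- runif(1, 0, 500)
    cfg <- grille_config(8, 800, 600, row_height_px = 40,
                         area_threshold_px2 = thr)
    base <- unclass(decide_frame(bx, cfg))
    # dilating the box never clears a bit
    grown <- pred_boxes(bx$x1 - 10, bx$y1 - 10, bx$x2 + 10, bx$y2 + 10)
    expect_true(all(unclass(decide_frame(grown, cfg)) >= base))
    # raising the threshold never sets a bit
    cfg_hi <- grille_config(8, 800, 600, row_height_px = 40,
                            area_threshold_px2 = thr + 100)
    expect_true(all(unclass(decide_frame(bx, cfg_hi)) <= base))
    # OR-decomposition over singleton boxes
    two <- rbind(bx, grown)
    class(two) <- c("pred_box", "data.frame")
    expect_equal(unclass(decide_frame(two, cfg)),
                 pmax(unclass(decide_frame(bx, cfg)),
                      unclass(decide_frame(grown, cfg))))
  }
})

test_that("a moving box sets bits exactly while its overlap exceeds threshold", {
  cfg <- grille_config(4, 400, 300, row_height_px = 50, row_top_px = 250,
                       area_threshold_px2 = 100)
  cells <- build_grille(cfg)
  # box of 60x40 px moving downward through the grille, 10 px per frame,
  # until it exits the bottom of the frame entirely
  frames <- lapply(0:20, function(t) {
    y1 <- 100 + 10 * t
    pred_boxes(120, y1, 180, y1 + 40)
  })
  got <- decision_stream(frames, cfg)
  for (t in seq_along(frames)) {
    clipped <- clip_boxes(frames[[t]], 400, 300)
    expected <- vapply(seq_len(nrow(cells)), function(i) {
      if (nrow(clipped) == 0) return(0L)
      as.integer(raster_intersection(clipped, cells[i, ]) > 100)
    }, integer(1))
    expect_equal(unclass(got[[t]]), expected)
  }
  # the bit has returned to 0 once the box has left the image
  expect_equal(unclass(got[[21]]), rep(0L, 4))
})

test_that("identical frames decide identically and clipping drops outside boxes", {
  cfg <- grille_config(6, 600, 400, row_height_px = 30)
  b <- pred_boxes(100, 380, 220, 460)  # extends below the image; clipped
  s <- decision_stream(list(b, b, b), cfg)
  expect_equal(s[[1]], s[[2]])
  expect_equal(s[[2]], s[[3]])
  outside <- pred_boxes(650, 100, 700, 200)
  expect_equal(unclass(decide_frame(outside, cfg)), rep(0L, 6))
})
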