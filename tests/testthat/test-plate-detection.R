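test_that("iou matches lattice-cell counting and its invariants", {
  a <- bounding_box(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_box(20, 20, 30, 30)), 0)
  # (0,0,10,10) vs (5,0,15,10): 50 shared cells of 150 total
  expect_equal(iou(a, bounding_box(5, 0, 15, 10)), 1 / 3)
  expect_error(bounding_box(5, 0, 5, 10), class = "octscreen_param_error")

  # symmetry, bounds, and iou == 1 iff identical, on random boxes
  withr::with_seed(42, {
    for (i in 1:50) {
      p <- sort(sample(0:30, 2)); q <- sort(sample(0:30, 2))
      r <- sort(sample(0:30, 2)); s <- sort(sample(0:30, 2))
      if (p[1] == p[2] || q[1] == q[2] || r[1] == r[2] || s[1] == s[2]) next
      b1 <- bounding_box(p[1], q[1], p[2], q[2])
      b2 <- bounding_box(r[1], s[1], r[2], s[2])
      v <- iou(b1, b2)
      expect_equal(v, iou(b2, b1))
      expect_gte(v, 0); expect_lte(v, 1)
      identical_boxes <- p[1] == r[1] && p[2] == r[2] &&
        q[1] == s[1] && q[2] == s[2]
      expect_equal(v == 1, identical_boxes)
    }
  })
})

test_that("mean average precision enumerates the threshold grid correctly", {
  truth <- tibble::tibble(image = "a", x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  perfect <- dplyr::mutate(truth, confidence = 1)
  expect_equal(map_score(perfect, truth), 1)
  expect_equal(map_score(perfect[0, ], truth), 0)
  # half-height prediction: IoU exactly 0.5 -> AP 1 only at the 0.50 bar
  half <- tibble::tibble(image = "a", x0 = 0, y0 = 0, x1 = 10, y1 = 5,
                         confidence = 0.9)
  expect_equal(map_score(half, truth), 0.1)
  expect_error(mean_average_precision(perfect, truth[0, ]),
               class = "octscreen_param_error")
})

test_that("average precision is non-increasing in the IoU threshold", {
  withr::with_seed(7, {
    truth <- tibble::tibble(
      image = rep(sprintf("im%d", 1:5), each = 2),
      x0 = runif(10, 0, 40), y0 = runif(10, 0, 40))
    truth$x1 <- truth$x0 + runif(10, 5, 20)
    truth$y1 <- truth$y0 + runif(10, 5, 20)
    pred <- dplyr::mutate(truth,
                          x0 = x0 + rnorm(10, sd = 2),
                          y1 = y1 + rnorm(10, sd = 2),
                          confidence = runif(10))
    ap <- mean_average_precision(pred, truth)$ap
    expect_true(all(diff(ap) <= 1e-12))
  })
})

test_that("centroid shift is the Euclidean distance in um", {
  expect_equal(centroid_shift(c(15, 15), c(15, 15)), 0)
  expect_equal(centroid_shift(c(15.010, 15), c(15, 15)), 10)
  withr::with_seed(1, {
    for (i in 1:20) {
      p <- runif(2, 0, 30); q <- runif(2, 0, 30)
      expect_equal(centroid_shift(p, q),
                   sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2) * 1000)
    }
  })
})

test_that("centroid-to-stage conversion is the stated affine map", {
  cal0 <- stage_calibration()
  expect_equal(centroid_to_stage(c(0, 0), cal0), c(0, 0))
  cal <- stage_calibration(mm_per_volt = c(5, 5), reference_voltage = c(1, 1))
  expect_equal(centroid_to_stage(c(10, 0), cal), c(3.0, 1.0))
  expect_error(stage_calibration(mm_per_volt = c(0, 1)),
               class = "octscreen_param_error")
  # round trip recovers the centroid
  cal2 <- stage_calibration(webcam_to_oct_offset_mm = c(1.25, -0.5),
                            mm_per_volt = c(2.5, -3), reference_voltage = c(4, 7))
  withr::with_seed(2, {
    for (i in 1:20) {
      c0 <- runif(2, 0, 30)
      expect_equal(stage_to_centroid(centroid_to_stage(c0, cal2), cal2), c0,
                   tolerance = 1e-9)
    }
  })
})

test_that("baseline detector localises phantom explants to sub-pixel", {
  spec <- phantom_spec(image_size_px = c(300, 300), occupancy = 1)
  mpp <- 30 / 300
  for (s in 1:10) {
    w <- make_well_image(spec, seed = s)
    d <- detect_tissue_baseline(w$image)
    expect_equal(d$status, "found")
    expect_lt(centroid_shift(d$centroid_mm, w$truth$centroid_mm) / 1000, mpp)
    expect_gte(iou(d$box, w$truth$bbox_px), 0.5)
  }
})

test_that("baseline detector reports void on empty wells", {
  spec <- phantom_spec(image_size_px = c(300, 300), occupancy = 0)
  for (s in 1:10) {
    w <- make_well_image(spec, seed = 100 + s)
    expect_equal(detect_tissue_baseline(w$image)$status, "void")
  }
  expect_error(detect_tissue_baseline(matrix(numeric(0), 0, 0)),
               class = "octscreen_param_error")
})

test_that("components below the area floor are ignored", {
  # two blobs: a large ellipse and a speck below min_area_mm2
  img <- matrix(0.8, 200, 200)
  img[80:120, 60:140] <- 0.4        # large: 41 x 81 px
  img[20:22, 20:22] <- 0.4          # speck: 9 px << 1 mm^2 at 0.15 mm/px
  d <- detect_tissue_baseline(img, mm_per_pixel = 0.15, smooth_mm = 0.15)
  expect_equal(d$status, "found")
  expect_gte(iou(d$box, bounding_box(59, 79, 140, 120)), 0.8)
  expect_false(d$box$x1 < 40)  # box is not on the speck
})
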