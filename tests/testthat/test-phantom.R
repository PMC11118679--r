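test_that("phantom specs are validated", {
  expect_error(phantom_spec(image_size_px = c(0, 10)), class = "octscreen_param_error")
  expect_error(phantom_spec(occupancy = 1.5), class = "octscreen_param_error")
  expect_error(phantom_spec(specular_column_rate = -0.1),
               class = "octscreen_param_error")
  expect_error(phantom_spec(tissue_radii_mm = c(2, -1)),
               class = "octscreen_param_error")
  expect_error(phantom_spec(thickness_profile = list(type = "cone")),
               class = "octscreen_param_error")
})

test_that("well images are deterministic and carry exact geometry", {
  spec <- phantom_spec(image_size_px = c(600, 600), well_fov_mm = 30,
                       tissue_center_mm = c(15, 15),
                       tissue_radii_mm = c(4, 3), occupancy = 1)
  w1 <- make_well_image(spec, seed = 7)
  w2 <- make_well_image(spec, seed = 7)
  expect_identical(w1$image, w2$image)
  expect_true(w1$truth$has_tissue)
  # geometry oracle: rasterise the ellipse on pixel centres, take extents
  mpp <- 30 / 600
  x <- (seq_len(600) - 0.5) * mpp; y <- x
  inside <- outer(((y - 15) / 3)^2, ((x - 15) / 4)^2, `+`) <= 1
  cols <- which(apply(inside, 2, any)); rows <- which(apply(inside, 1, any))
  b <- w1$truth$bbox_px
  expect_equal(c(b$x0, b$y0, b$x1, b$y1),
               c(min(cols) - 1, min(rows) - 1, max(cols), max(rows)))
  # 8 mm x 6 mm spans at 20 px/mm, within one pixel
  expect_lt(abs((b$x1 - b$x0) - 8 / mpp), 1.5)
  expect_lt(abs((b$y1 - b$y0) - 6 / mpp), 1.5)
  expect_equal(w1$truth$centroid_mm, c(15, 15))
})

test_that("occupancy 0 gives an empty well with absent box", {
  w <- make_well_image(phantom_spec(occupancy = 0), seed = 1)
  expect_false(w$truth$has_tissue)
  expect_null(w$truth$bbox_px)
  expect_null(w$truth$centroid_mm)
})

test_that("uniform-slab volumes have exact per-column voxel counts", {
  spec <- small_clean_spec(oct_fov_mm = 6, tissue_radii_mm = c(2, 2),
                           thickness_profile = list(type = "uniform",
                                                    thickness_um = 180),
                           dz_um = 2)
  v <- make_oct_volume(spec, seed = 1)
  counts <- do.call(rbind, lapply(v$truth$mask$masks, colSums))
  in_fp <- v$truth$thickness_map_um > 0
  expect_true(all(counts[in_fp] == 90))
  expect_true(all(counts[!in_fp] == 0))
})

test_that("noise-free tissue voxels share a single intensity value", {
  spec <- small_clean_spec()
  v <- make_oct_volume(spec, seed = 2)
  vals <- unlist(lapply(seq_along(v$volume$frames), function(j)
    v$volume$frames[[j]][v$truth$mask$masks[[j]] == 1L]))
  expect_length(unique(vals), 1L)
})

test_that("volumes are bit-identical for identical spec and seed", {
  spec <- small_noisy_spec()
  v1 <- make_oct_volume(spec, seed = 11)
  v2 <- make_oct_volume(spec, seed = 11)
  expect_identical(v1$volume$frames, v2$volume$frames)
  expect_identical(v1$truth$mask$masks, v2$truth$mask$masks)
})

test_that("dome-profile analytic volume matches a quadrature oracle", {
  spec <- small_clean_spec(
    tissue_radii_mm = c(2, 2),
    thickness_profile = list(type = "dome", peak_um = 200, edge_um = 100))
  v <- make_oct_volume(spec, seed = 1, render = FALSE)
  # quadrature oracle at 10x the lateral resolution of the test grid
  n <- 960
  g <- (seq_len(n) - 0.5) * 6 / n
  rho2 <- outer(((g - 3) / 2)^2, ((g - 3) / 2)^2, `+`)
  t_um <- ifelse(rho2 <= 1, 200 - 100 * rho2, 0)
  oracle_mm3 <- sum(t_um) * (6 / n)^2 * 1e-3
  expect_rel_error(v$truth$volume_mm3, oracle_mm3, 0.01)
})

test_that("thickness profiles that do not fit the axial range error", {
  expect_error(
    make_oct_volume(small_clean_spec(
      thickness_profile = list(type = "uniform", thickness_um = 5000)),
      seed = 1),
    class = "octscreen_param_error")
})

test_that("masks never touch the membrane and sit strictly above it", {
  spec <- small_noisy_spec(membrane_brightness = 0.9)
  v <- make_oct_volume(spec, seed = 5)
  clean <- make_oct_volume(small_clean_spec(), seed = 5)
  # membrane rows are where the noise-free frame is at membrane brightness
  mem_rows <- which(apply(clean$volume$frames[[1]] == 0.9, 1, all))
  expect_gt(length(mem_rows), 0)
  for (j in seq(1, spec$n_bscans, by = 5)) {
    tissue_rows <- which(apply(v$truth$mask$masks[[j]] == 1L, 1, any))
    if (length(tissue_rows) > 0)
      expect_lt(max(tissue_rows), min(mem_rows))
  }
})

test_that("depth stacks are unimodal with the optimum at the target", {
  spec <- small_clean_spec()
  s <- make_depth_stack(spec, n_positions = 11, optimal_index = 7, seed = 1)
  mi <- vapply(s$stack$frames, mean_frame_intensity, numeric(1))
  expect_equal(which.max(mi), 7L)
  expect_true(all(diff(mi[1:7]) > 0))
  expect_true(all(diff(mi[7:11]) < 0))
  expect_identical(s$truth$optimal_z_index, 7L)
  expect_error(make_depth_stack(spec, 11, 12), class = "octscreen_param_error")
  one <- make_depth_stack(spec, 1, 1, seed = 2)
  expect_length(one$stack$frames, 1L)
})

test_that("screen datasets follow the configured group model", {
  # no repetition noise => repetitions identical within sample x timepoint
  d0 <- make_screen_dataset(repeat_sd = 0, seed = 3,
                            area_params = list(mean = 15.2, sd = 0.755,
                                               negative_change = -0.2,
                                               positive_change = 0,
                                               repeat_sd = 0),
                            volume_params = list(mean = 2.92, sd = 0.107,
                                                 negative_change = -0.44,
                                                 positive_change = 0.3,
                                                 repeat_sd = 0))
  spread <- d0 |>
    dplyr::summarise(s = stats::sd(thickness_um),
                     .by = c(sample_id, timepoint))
  expect_true(all(spread$s == 0))

  # day-10 negative mean recovers baseline x (1 + change) ~ 133.7 um
  big <- make_screen_dataset(n_negative = 2000, n_positive = 2,
                             n_repeats = 2, seed = 4)
  d10 <- big[big$group == "negative" & big$timepoint == "day10", ]
  expect_lt(abs(mean(d10$thickness_um) - 191.8 * (1 - 0.303)), 1)

  # law of large numbers: day-10 negative SD converges to configured SD
  per_sample <- d10 |>
    dplyr::summarise(v = mean(thickness_um), .by = sample_id)
  expect_rel_error(stats::sd(per_sample$v), 11.5 * (1 - 0.303), 0.05)
})

test_that("screen datasets are reproducible from their seed", {
  expect_identical(make_screen_dataset(seed = 9), make_screen_dataset(seed = 9))
})
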