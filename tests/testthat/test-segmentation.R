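test_that("segmentation metrics follow the counting formulas", {
  m <- matrix(0L, 10, 10); m[3:6, 3:8] <- 1L
  expect_equal(seg_metrics(m, m),
               tibble::tibble(recall = 1, precision = 1, dice = 1))
  # prediction covering exactly half the truth, no false positives
  half <- m; half[3:6, 3:5] <- 0L
  stopifnot(sum(half) * 2 == sum(m))
  got <- seg_metrics(half, m)
  expect_equal(got$recall, 0.5)
  expect_equal(got$precision, 1)
  expect_equal(got$dice, 2 / 3)
  # empty-set conventions
  empty <- matrix(0L, 10, 10)
  expect_equal(unlist(seg_metrics(empty, m)),
               c(recall = 0, precision = 0, dice = 0))
  expect_equal(unlist(seg_metrics(m, empty)),
               c(recall = 0, precision = 0, dice = 0))
  expect_equal(unlist(seg_metrics(empty, empty)),
               c(recall = 1, precision = 1, dice = 1))
  expect_error(seg_metrics(m, matrix(0L, 5, 5)),
               class = "octscreen_param_error")
})

test_that("dice equals 2PR/(P+R) on random masks", {
  withr::with_seed(21, {
    for (i in 1:25) {
      a <- matrix(as.integer(runif(400) < 0.3), 20, 20)
      b <- matrix(as.integer(runif(400) < 0.3), 20, 20)
      g <- seg_metrics(a, b)
      if (g$precision + g$recall > 0)
        expect_equal(g$dice,
                     2 * g$precision * g$recall / (g$precision + g$recall))
    }
  })
})

test_that("classical segmenter is exact on noise-free phantoms", {
  v <- make_oct_volume(small_clean_spec(), seed = 1)
  seg <- segment_volume(v$volume)
  expect_equal(seg_metrics(seg, v$truth$mask)$dice, 1)
})

test_that("classical segmenter survives the default artifact load", {
  # speckle 0.3, 2% saturated columns, membrane on
  v <- make_oct_volume(small_noisy_spec(), seed = 8)
  seg <- segment_volume(v$volume)
  expect_gte(seg_metrics(seg, v$truth$mask)$dice, 0.90)
})

test_that("membrane-only frames segment to empty masks", {
  spec <- small_clean_spec(tissue_radii_mm = c(0.5, 0.5))
  v <- make_oct_volume(spec, seed = 1)
  # B-scan far outside the footprint: membrane only
  f <- v$volume$frames[[1]]
  stopifnot(sum(v$truth$mask$masks[[1]]) == 0)
  expect_equal(sum(segment_classical(f, dz_um = 2)), 0)
})

test_that("fully saturated frames are signalled as unsegmentable", {
  expect_error(segment_classical(matrix(1, 64, 64)),
               class = "octscreen_unsegmentable")
  expect_warning(
    segment_volume(oct_volume(list(matrix(1, 64, 64)), 12, 12, 2)),
    "unsegmentable")
})

test_that("segmentation is invariant to global affine intensity rescaling", {
  v <- make_oct_volume(small_noisy_spec(), seed = 12)
  f <- v$volume$frames[[5]]
  base <- segment_classical(f, dz_um = 2)
  expect_identical(segment_classical(3.7 * f + 11, dz_um = 2), base)
})

test_that("segmentation commutes with horizontal flips of clean frames", {
  v <- make_oct_volume(small_clean_spec(), seed = 4)
  f <- v$volume$frames[[8]]
  flipped <- f[, rev(seq_len(ncol(f)))]
  got <- segment_classical(flipped, dz_um = 2)
  expect_identical(got[, rev(seq_len(ncol(got)))],
                   segment_classical(f, dz_um = 2))
})

test_that("augmentations behave as involutions / identities where stated", {
  v <- make_oct_volume(small_clean_spec(), seed = 2)
  img <- v$volume$frames[[10]]; msk <- v$truth$mask$masks[[10]]
  once <- apply_augment(img, msk, flip_h = TRUE)
  twice <- apply_augment(once$image, once$mask, flip_h = TRUE)
  expect_identical(twice$image, img)
  expect_identical(twice$mask, msk)
  same <- apply_augment(img, msk, translate = c(0L, 0L))
  expect_identical(same$image, img)

  # translation preserves mask voxels up to pixels shifted off-frame
  tr <- apply_augment(img, msk, translate = c(5L, -3L), bg = 0.05)
  kept <- msk[1:(nrow(msk) - 5), 4:ncol(msk)]
  expect_equal(sum(tr$mask), sum(kept))
})

test_that("random augmentation draws are seeded and mask-consistent", {
  v <- make_oct_volume(small_clean_spec(), seed = 2)
  img <- v$volume$frames[[10]]; msk <- v$truth$mask$masks[[10]]
  a1 <- augment(img, msk, n = 3, seed = 5, bg = 0.05)
  a2 <- augment(img, msk, n = 3, seed = 5, bg = 0.05)
  expect_identical(a1, a2)
  for (p in a1) {
    expect_identical(dim(p$image), dim(img))
    expect_true(all(p$mask %in% c(0L, 1L)))
    # contrast never alters the mask
    expect_lte(sum(p$mask), sum(msk))
  }
})
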