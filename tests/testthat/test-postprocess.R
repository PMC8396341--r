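test_that("negative clipping is elementwise, idempotent, and NaN-safe", {
  m <- matrix(c(-2, 0, 3, -0.5), 2, 2)
  expect_equal(clip_negative(m), matrix(c(0, 0, 3, 0), 2, 2))
  allneg <- matrix(-runif(16), 4, 4)
  expect_true(all(clip_negative(allneg) == 0))
  nonneg <- matrix(runif(16), 4, 4)
  expect_identical(clip_negative(nonneg), nonneg)
  expect_identical(clip_negative(clip_negative(m)), clip_negative(m))
  bad <- m; bad[1] <- NaN
  expect_error(clip_negative(bad), "NaN")
})

test_that("Otsu separates a two-delta histogram and rejects constants", {
  v <- matrix(rep(c(0, 1), each = 128), 16, 16)
  thr <- otsu_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_equal(sum(v > thr), 128)
  expect_equal(sum(v <= thr), 128)
  expect_error(otsu_threshold(matrix(2, 4, 4)), "constant")
})

test_that("Otsu equals exhaustive inter-class variance search", {
  set.seed(21)
  for (rep in 1:12) {
    v <- matrix(c(rnorm(150, 0, 0.5), rnorm(106, 4, 1)), 16, 16)
    expect_equal(otsu_threshold(v), brute_otsu(v)$threshold,
                 tolerance = 1e-12)
  }
})

test_that("Otsu foreground contains planted well-separated peaks", {
  set.seed(8)
  ann <- separated_centers(10, 160, 160, min_sep = 25, margin = 13)
  dm <- build_density_map(ann, c(160, 160))
  thr <- otsu_threshold(dm$values)
  at_centers <- dm$values[cbind(round(ann$y) + 1, round(ann$x) + 1)]
  expect_true(all(at_centers > thr))
})

test_that("watershed splits merged peaks and labels partitions the mask", {
  # two unit-mass Gaussians 10 px apart fused into one Otsu component
  ann <- data.frame(x = c(30, 40), y = c(32, 32))
  dm <- build_density_map(ann, c(64, 64))
  mask <- dm$values > otsu_threshold(dm$values)
  expect_equal(max(tilmap:::.cc_label(matrix(as.integer(mask), 64, 64))), 1)
  lab <- split_components(mask, dm$values)
  expect_equal(lab$n, 2)
  expect_true(all(sort(unique(as.integer(lab$labels[lab$labels > 0]))) ==
                  1:2))
  expect_identical(lab$labels > 0, unname(mask))

  # one isolated blob stays whole; empty mask yields zero components
  one <- build_density_map(data.frame(x = 20, y = 20), c(64, 64))
  m1 <- one$values > otsu_threshold(one$values)
  expect_equal(split_components(m1, one$values)$n, 1)
  expect_equal(split_components(matrix(FALSE, 8, 8),
                                matrix(0, 8, 8))$n, 0)
})

test_that("labeling is monotone: watershed never merges mask components", {
  set.seed(13)
  for (rep in 1:5) {
    ann <- separated_centers(sample(3:12, 1), 96, 96, min_sep = 10)
    dm <- build_density_map(ann, c(96, 96))
    mask <- dm$values > otsu_threshold(dm$values)
    ncc <- max(tilmap:::.cc_label(matrix(as.integer(mask), 96, 96)))
    expect_gte(split_components(mask, dm$values)$n, ncc)
  }
})

test_that("centers of mass are density-weighted centroids", {
  # single-pixel component at x=10, y=20
  lab <- matrix(0L, 32, 32); lab[21, 11] <- 1L
  w <- matrix(1, 32, 32)
  com <- centers_of_mass(lab, w)
  expect_equal(com$x, 10); expect_equal(com$y, 20)

  # symmetric blob under uniform weights -> geometric center
  lab2 <- matrix(0L, 32, 32); lab2[10:14, 6:10] <- 1L
  com2 <- centers_of_mass(lab2, matrix(1, 32, 32))
  expect_equal(com2$x, 7); expect_equal(com2$y, 11)

  # asymmetric two-pixel component: 1 at (0,0), 3 at (4,0) -> (3, 0)
  lab3 <- matrix(0L, 8, 8); lab3[1, 1] <- 1L; lab3[1, 5] <- 1L
  w3 <- matrix(0, 8, 8); w3[1, 1] <- 1; w3[1, 5] <- 3
  com3 <- centers_of_mass(lab3, w3)
  expect_equal(com3$x, 3); expect_equal(com3$y, 0)
  expect_equal(com3$component_area, 2L)
})

test_that("detect recovers planted centers and degrades gracefully", {
  set.seed(77)
  ann <- separated_centers(25, 256, 256, min_sep = 20, margin = 13)
  dm <- build_density_map(ann, c(256, 256))
  p <- detect(dm)
  expect_equal(nrow(p), 25)
  mt <- match_detections(ann, p, threshold = 2)
  expect_equal(mt$tp, 25)

  expect_equal(nrow(detect(matrix(0, 32, 32))), 0)
  single <- build_density_map(data.frame(x = 16, y = 16), c(64, 64))
  expect_equal(nrow(detect(single)), 1)
  # negative-going background must be clipped before thresholding
  noisy <- single$values - 0.001
  expect_equal(nrow(detect(noisy)), 1)
})
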