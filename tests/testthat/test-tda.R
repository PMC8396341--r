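test_that("hexagon worked example: births, deaths, Betti values", {
  pd <- vr_persistence(hexagon_points(), maxdim = 1)
  h0 <- pd[pd$dimension == 0, ]
  expect_equal(nrow(h0), 6)  # one H0 feature per input point
  expect_equal(sum(is.infinite(h0$death)), 1)
  expect_equal(unname(h0$death[is.finite(h0$death)]), rep(1, 5))
  h1 <- pd[pd$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(3), tolerance = 1e-9)

  bc <- betti_curve(pd, grid = c(0.5, 1, 1.5, h1$death, 2))
  expect_identical(bc$H0, c(6L, 1L, 1L, 1L, 1L))
  expect_identical(bc$H1, c(0L, 1L, 1L, 0L, 0L))
})

test_that("degenerate clouds: single point, single edge", {
  one <- vr_persistence(matrix(c(0, 0), 1, 2))
  expect_identical(one$death, Inf)
  two <- vr_persistence(rbind(c(0, 0), c(3, 4)))
  expect_setequal(two$death, c(5, Inf))
  expect_false(any(two$dimension == 1))
  expect_error(vr_persistence(matrix(0, 1, 2), maxscale = -1), "positive")
})

test_that("finite H0 deaths equal the Euclidean MST edge lengths", {
  skip_if_not_installed("vegan")
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    pts <- matrix(runif(2 * n, 0, 10), n, 2)
    pd <- vr_persistence(pts, maxdim = 0)
    deaths <- sort(pd$death[is.finite(pd$death)])
    mst <- sort(vegan::spantree(dist(pts))$dist)
    expect_equal(deaths, mst, tolerance = 1e-8)
  }
})

test_that("diagrams match the full boundary-matrix reduction on tiny clouds", {
  set.seed(16)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(2 * n, 0, 4), n, 2)
    pd <- vr_persistence(pts, maxdim = 1)
    oracle <- brute_vr_persistence(pts)
    expect_identical(diagram_key(pd), diagram_key(oracle))
  }
})

test_that("diagram is invariant under input permutation", {
  set.seed(17)
  pts <- matrix(runif(24, 0, 5), 12, 2)
  pd <- vr_persistence(pts)
  for (rep in 1:5) {
    perm <- sample(12)
    expect_identical(diagram_key(vr_persistence(pts[perm, ])),
                     diagram_key(pd))
  }
})

test_that("Betti curves are consistent with their diagrams", {
  set.seed(18)
  pts <- matrix(runif(30, 0, 5), 15, 2)
  pd <- vr_persistence(pts)
  bc <- betti_curve(pd)
  # independent recount at every grid point
  for (k in 0:1) {
    feats <- pd[pd$dimension == k, ]
    recount <- sapply(bc$scale, function(r) {
      alive <- 0
      for (i in seq_len(nrow(feats)))
        if (feats$birth[i] <= r && r < feats$death[i]) alive <- alive + 1
      alive
    })
    expect_equal(bc[[paste0("H", k)]], as.integer(recount))
  }
  # H0 is non-increasing (all births at 0 for point clouds)
  expect_true(all(diff(bc$H0) <= 0))
  empty <- pd[0, ]
  bce <- betti_curve(empty, grid = c(0, 1, 2))
  expect_true(all(bce$H0 == 0) && all(bce$H1 == 0))
  expect_error(betti_curve(pd, grid = numeric(0)), "empty")
  expect_error(betti_curve(pd, grid = c(2, 1)), "increasing")
})

test_that("persistence diagrams round-trip through CSV with inf sentinels", {
  pd <- vr_persistence(hexagon_points())
  path <- withr::local_tempfile(fileext = ".csv")
  write_tda_csv(pd, path)
  expect_true(any(grepl("inf", readLines(path))))
  back <- read_persistence_csv(path)
  expect_identical(diagram_key(back), diagram_key(pd))
})

test_that("TwoNN closed form equals likelihood-grid maximization", {
  set.seed(19)
  for (rep in 1:5) {
    x <- matrix(runif(2 * 300), 300, 2)
    est <- twonn_id(x)
    mu <- sort(est$mu)[seq_len(est$n_used)]
    k <- est$n_total - est$n_used
    grid <- seq(0.05, 50, by = 0.001)
    # Pareto likelihood of the retained ratios, discarded tail right-censored
    ll <- vapply(grid, function(d)
      length(mu) * log(d) - (d + 1) * sum(log(mu)) -
        d * k * log(mu[length(mu)]), 0)
    expect_equal(est$id, grid[which.max(ll)], tolerance = 1e-2)
  }
})

test_that("TwoNN recovers known manifold dimensions", {
  set.seed(20)
  sq <- twonn_id(matrix(runif(2 * 2000), 2000, 2))
  expect_gt(sq$id, 1.8); expect_lt(sq$id, 2.2)
  line <- cbind(runif(500), rnorm(500, 0, 1e-4))
  li <- twonn_id(line)
  expect_gt(li$id, 0.8); expect_lt(li$id, 1.3)
})

test_that("TwoNN degenerate inputs: duplicates dropped, constants fatal", {
  set.seed(22)
  x <- matrix(runif(40), 20, 2)
  dup <- rbind(x, x[1:5, ])
  expect_warning(est <- twonn_id(dup), "duplicate")
  expect_equal(est$n_total, 20)
  expect_error(suppressWarnings(twonn_id(matrix(1, 30, 2))), "identical")
  expect_error(twonn_id(x[1:5, ]), "at least 10")
})

test_that("id_profile tabulates finite estimates for all six blocks", {
  set.seed(23)
  m <- build_model(unet_config("tiny", seed = 6))
  tiles <- lapply(1:40, function(i) generate_tile(64, 64, sample(0:12, 1),
                                                  seed = 900 + i))
  prof <- id_profile(m, tiles)
  expect_equal(nrow(prof), 6)
  expect_setequal(prof$block, unet_blocks())
  expect_true(all(is.finite(prof$id) & prof$id > 0))
})
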