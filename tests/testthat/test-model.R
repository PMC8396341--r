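test_that("shape contracts: H x W x 3 in, H x W x 1 out, five halvings", {
  m <- build_model(unet_config("tiny"))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fw <- tilmap:::unet_forward(m, x)
  expect_identical(dim(fw$out), c(64L, 64L, 1L))
  expect_identical(dim(fw$cache$enc5)[1:2], c(2L, 2L))  # 64 / 2^5
  expect_error(tilmap:::unet_forward(m, array(0, c(60, 64, 3))),
               "divisible")

  std <- unet_config("standard")
  expect_identical(std$dec_widths, c(256L, 128L, 64L, 32L, 16L))
  expect_error(unet_config(decoder_widths = c(64, 32, 16, 8)), "five")
  expect_error(unet_config(decoder_widths = c(64, 32, 32, 16, 8)),
               "decreasing")
})

test_that("final decoder block emits the last configured width", {
  m <- build_model(unet_config("tiny"))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- tilmap:::unet_forward(m, x)
  expect_identical(dim(fw$cache$dec5)[3], 4L)
  # head consumes those channels into a single identity-activated channel
  expect_identical(dim(m$params$head$w), c(4L, 1L))
})

test_that("tiny preset stays under 100k parameters and runs fast", {
  m <- build_model(unet_config("tiny"))
  n_par <- sum(unlist(rapply(m$params, length, how = "unlist")))
  expect_lt(n_par, 1e5)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3))
  elapsed <- system.time(tilmap:::unet_forward(m, x, keep_cache = FALSE))[3]
  expect_lt(elapsed, 1)
})

test_that("scSE preserves shape, attenuates, and has an identity limit", {
  set.seed(5)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  y <- scse_block(x, seed = 2)
  expect_identical(dim(y), dim(x))
  # both branches are sigmoid-bounded and combined by max, so attenuation
  for (s in 1:5) {
    xi <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
    yi <- scse_block(xi, seed = s)
    expect_true(all(abs(yi) <= abs(xi) + 1e-12))
  }
  # bias trick: saturate both sigmoids -> all weights 1 -> identity
  p <- tilmap:::init_scse(8L)
  p$cw2[] <- 0; p$cb2[] <- 40
  p$sw[] <- 0; p$sb <- 40
  expect_equal(tilmap:::scse_fw(x, p)$y, x, tolerance = 1e-12)
  expect_error(scse_block(array(0, c(4, 4)), seed = 1), "C >= 2")
})

test_that("analytic gradients match finite differences on every layer kind", {
  set.seed(11)
  m <- build_model(unet_config("tiny", seed = 3))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  target <- matrix(rnorm(32 * 32, sd = 0.1), 32, 32)
  loss_of <- function(mm)
    mean((tilmap:::unet_forward(mm, x, keep_cache = FALSE)$out[, , 1] -
          target)^2)
  fw <- tilmap:::unet_forward(m, x)
  resid <- fw$out[, , 1] - target
  dout <- array(2 * resid / length(resid), dim(fw$out))
  g <- tilmap:::unet_backward(m, fw$cache, dout)
  eps <- 1e-6
  checks <- list(c("stem", "w"), c("enc2", "w"), c("enc5", "b"),
                 c("dec1", "w"), c("dec5", "b"), c("head", "w"),
                 c("scse3", "cw1"), c("scse3", "sw"))
  for (ck in checks) {
    idx <- 2
    m2 <- m
    m2$params[[ck[1]]][[ck[2]]][idx] <- m2$params[[ck[1]]][[ck[2]]][idx] + eps
    num <- (loss_of(m2) - loss_of(m)) / eps
    expect_equal(g[[ck[1]]][[ck[2]]][idx], num, tolerance = 1e-3,
                 label = paste("grad", ck[1], ck[2]))
  }
})

test_that("plateau scheduler implements eta' = alpha * eta", {
  sch <- plateau_scheduler(lr = 1e-2, factor = 0.2, patience = 10)
  sch <- scheduler_step(sch, 1.0)  # establishes the best
  for (i in 1:11) sch <- scheduler_step(sch, 1.0)  # patience+1 flat epochs
  expect_equal(sch$lr, 2e-3, tolerance = 1e-15)
  expect_equal(sch$n_reductions, 1L)
  # improvement resets the counter
  sch2 <- plateau_scheduler(1e-2, 0.2, 3)
  sch2 <- scheduler_step(sch2, 1.0)
  for (v in c(1.0, 1.0, 0.5, 1.0, 1.0, 1.0)) sch2 <- scheduler_step(sch2, v)
  expect_equal(sch2$lr, 1e-2)
})

test_that("training reduces loss on a separable toy problem", {
  ts <- tiny_training_set(n_tiles = 8, size = 64, n_cells = 6)
  m <- build_model(unet_config("tiny", seed = 1))
  m <- train_model(m, ts$tiles[1:6], ts$targets[1:6],
                   ts$tiles[7:8], ts$targets[7:8], epochs = 8, seed = 2)
  h <- m$history
  expect_identical(names(h), c("epoch", "train_loss", "val_loss", "lr"))
  expect_lt(tail(h$val_loss, 1), 0.5 * h$val_loss[1])
  expect_error(train_model(m, list(), list(), list(), list()), "empty")
})

test_that("constant-zero targets drive predictions toward zero", {
  tiles <- lapply(1:4, function(i) generate_tile(64, 64, 5, seed = 400 + i))
  zeros <- lapply(1:4, function(i) matrix(0, 64, 64))
  m <- build_model(unet_config("tiny", seed = 9))
  initial <- mean(abs(predict_map(m, tiles[[1]])$values))
  m <- train_model(m, tiles, zeros, tiles[1], zeros[1], epochs = 25, seed = 3)
  final <- mean(abs(predict_map(m, tiles[[1]])$values))
  expect_lt(final, 1e-2 * initial)
})

test_that("feature extraction is deterministic, nonnegative, consistent", {
  m <- build_model(unet_config("tiny", seed = 4))
  tiles <- lapply(1:3, function(i) generate_tile(64, 64, 4, seed = 500 + i))
  fc <- extract_features(m, c(tiles, tiles[1]), "enc3")
  expect_identical(nrow(fc), 4L)
  # D = H_b * W_b * C_b of the tapped block: 8 x 8 x 16 at 1/8 resolution
  expect_identical(ncol(fc), 8L * 8L * 16L)
  expect_identical(attr(fc, "dim_block"), c(8L, 8L, 16L))
  expect_true(all(fc >= 0))                      # post-ReLU
  expect_identical(fc[1, ], fc[4, ])             # identical tiles
  expect_error(extract_features(m, tiles, "conv7"), "valid ids")
  # decoder taps are post-scSE and also nonnegative
  fd <- extract_features(m, tiles[1], "dec2")
  expect_true(all(fd >= 0))
})

test_that("checkpoints are written on cadence and reloadable", {
  ts <- tiny_training_set(n_tiles = 4, size = 64, n_cells = 3)
  dir <- withr::local_tempdir()
  m <- build_model(unet_config("tiny", seed = 2))
  m <- train_model(m, ts$tiles[1:3], ts$targets[1:3],
                   ts$tiles[4], ts$targets[4], epochs = 6, seed = 5,
                   checkpoint_dir = dir, checkpoint_every = 3)
  expect_setequal(list.files(dir), c("epoch_003.rds", "epoch_006.rds"))
  fc <- extract_features(m, ts$tiles[1], "dec1",
                         checkpoint = file.path(dir, "epoch_003.rds"))
  expect_identical(nrow(fc), 1L)
  expect_error(extract_features(m, ts$tiles[1], "dec1",
                                checkpoint = file.path(dir, "nope.rds")),
               "not found")
})
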