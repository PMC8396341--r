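test_that("gaussian kernel matches the closed form and its symmetries", {
  k <- gaussian_kernel(1, 7, normalize = FALSE)
  expect_equal(k[4, 4], 1 / (2 * pi), tolerance = 1e-12)
  # direct evaluation of G at a few integer offsets
  g <- function(x, y, s) exp(-(x^2 + y^2) / (2 * s^2)) / (2 * pi * s^2)
  expect_equal(k[4 + 2, 4 - 1], g(2, -1, 1), tolerance = 1e-12)

  for (par in list(c(1, 5), c(2.5, 13), c(4, 25))) {
    kk <- gaussian_kernel(par[1], par[2], normalize = FALSE)
    expect_equal(kk, kk[nrow(kk):1, ], tolerance = 0)      # y flip
    expect_equal(kk, kk[, ncol(kk):1], tolerance = 0)      # x flip
  }
  expect_equal(sum(gaussian_kernel(2, 13, normalize = TRUE)), 1,
               tolerance = 1e-12)
  expect_error(gaussian_kernel(2, 12), "odd")
  expect_error(gaussian_kernel(-1, 7), "positive")
})

test_that("density map conserves mass and peaks at the annotation", {
  empty <- build_density_map(data.frame(x = numeric(0), y = numeric(0)),
                             c(512, 512))
  expect_true(all(empty$values == 0))

  one <- build_density_map(data.frame(x = 256, y = 256), c(512, 512))
  expect_equal(sum(one$values), 1, tolerance = 1e-6)
  peak <- which(one$values == max(one$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(257, 257))  # row = y+1, col = x+1
})

test_that("density map equals the direct Gaussian sum (brute-force oracle)", {
  ann <- data.frame(x = c(30, 34), y = c(40, 40))  # 4 px apart
  dm <- build_density_map(ann, c(80, 80), d = 1, sigma = 4, l = 25)
  expect_equal(sum(dm$values), 2, tolerance = 1e-6)
  # brute-force double loop over the kernel support
  k <- gaussian_kernel(4, 25, normalize = TRUE)
  oracle <- matrix(0, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    for (a in seq_len(nrow(ann))) {
      dx <- (j - 1) - ann$x[a]; dy <- (i - 1) - ann$y[a]
      if (abs(dx) <= 12 && abs(dy) <= 12)
        oracle[i, j] <- oracle[i, j] + k[dy + 13, dx + 13]
    }
  }
  expect_equal(dm$values, oracle, tolerance = 1e-12)
})

test_that("mass additivity holds for interior centers across random draws", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(1:40, 1)
    ann <- data.frame(x = runif(n, 13, 114), y = runif(n, 13, 114))
    dm <- build_density_map(ann, c(128, 128), d = 2.5)
    expect_equal(sum(dm$values), 2.5 * n, tolerance = 1e-6 * 2.5 * n)
  }
})

test_that("translation equivariance and linearity", {
  ann <- data.frame(x = c(40, 60), y = c(50, 45))
  base <- build_density_map(ann, c(128, 128))
  shifted <- build_density_map(data.frame(x = ann$x + 7, y = ann$y + 3),
                               c(128, 128))
  expect_equal(shifted$values[(1 + 3):128, (1 + 7):128],
               base$values[1:(128 - 3), 1:(128 - 7)], tolerance = 1e-14)

  a1 <- data.frame(x = 30, y = 30); a2 <- data.frame(x = 90, y = 90)
  both <- build_density_map(rbind(a1, a2), c(128, 128))
  expect_equal(both$values,
               build_density_map(a1, c(128, 128))$values +
               build_density_map(a2, c(128, 128))$values,
               tolerance = 1e-14)
})

test_that("fractional annotations round half away from zero; OOB errors name the center", {
  frac <- build_density_map(data.frame(x = 10.5, y = 20.4), c(64, 64),
                            sigma = 1, l = 3)
  whole <- build_density_map(data.frame(x = 11, y = 20), c(64, 64),
                             sigma = 1, l = 3)
  expect_equal(frac$values, whole$values)
  expect_error(build_density_map(data.frame(x = 64, y = 5), c(64, 64)),
               "annotation 1 at \\(64, 5\\)")
  # coincident centers add
  two <- build_density_map(data.frame(x = c(5, 5), y = c(5, 5)), c(64, 64),
                           sigma = 1, l = 3)
  expect_equal(sum(two$values), 2, tolerance = 1e-12)
})

test_that("density maps round-trip through the text container", {
  dm <- build_density_map(data.frame(x = c(10, 20), y = c(12, 18)), c(40, 40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_density_map(dm, path, preview = TRUE)
  back <- read_density_map(path)
  expect_equal(back$values, dm$values, tolerance = 1e-15)
  expect_equal(back$sigma, dm$sigma)
  expect_true(file.exists(paste0(path, ".png")))
})
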