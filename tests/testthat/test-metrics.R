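test_that("matching handles identity, rejection, and empty sets", {
  pts <- data.frame(x = c(1, 5, 9), y = c(2, 2, 7))
  m <- match_detections(pts, pts)
  expect_equal(m$tp, 3); expect_equal(m$fp, 0); expect_equal(m$fn, 0)

  # sqrt(200) ~ 14.14 > 8: assignment found but rejected
  m2 <- match_detections(data.frame(x = 0, y = 0),
                         data.frame(x = 10, y = 10), threshold = 8)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))

  m3 <- match_detections(pts, pts[0, ])
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 0, 3))
  m4 <- match_detections(pts[0, ], pts)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 3, 0))
  expect_error(match_detections(pts, pts, threshold = 0), "positive")
})

test_that("assignment cost equals exhaustive permutation search", {
  set.seed(14)
  for (rep in 1:30) {
    nt <- sample(1:6, 1); np <- sample(1:6, 1)
    tm <- cbind(runif(nt, 0, 50), runif(nt, 0, 50))
    pm <- cbind(runif(np, 0, 50), runif(np, 0, 50))
    m <- match_detections(tm, pm, threshold = 1e9)  # accept everything
    expect_equal(sum(m$pairs$distance), brute_min_assignment(tm, pm),
                 tolerance = 1e-9)
  }
})

test_that("swapping truth and prediction swaps the error types", {
  set.seed(3)
  tm <- cbind(runif(5, 0, 30), runif(5, 0, 30))
  pm <- cbind(runif(8, 0, 30), runif(8, 0, 30))
  a <- match_detections(tm, pm)
  b <- match_detections(pm, tm)
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  sa <- detection_scores(a); sb <- detection_scores(b)
  expect_equal(unname(sa["precision"]), unname(sb["recall"]))
  expect_equal(unname(sa["recall"]), unname(sb["precision"]))
})

test_that("detection scores implement the harmonic mean with zero guards", {
  s <- detection_scores(list(tp = 3, fp = 1, fn = 0))
  expect_equal(unname(s), c(0.75, 1, 6 / 7), tolerance = 1e-12)
  expect_equal(unname(detection_scores(list(tp = 0, fp = 4, fn = 2))),
               c(0, 0, 0))
  for (v in c(0.25, 0.5, 1)) {  # P = R = v is a fixed point of F1
    tp <- v * 8; fp <- 8 - tp
    s <- detection_scores(list(tp = tp, fp = fp, fn = fp))
    expect_equal(unname(s["f1"]), v, tolerance = 1e-12)
  }
})

test_that("count binning reproduces the ordinal class table", {
  expect_identical(bin_count(c(0, 1, 5, 6, 10, 11, 20, 21, 50, 51, 200, 201)),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L))
  expect_identical(bin_count(1000), 6L)
  expect_error(bin_count(-1), "nonnegative")
})

test_that("classification metrics: identities and the printed MCC formula", {
  g <- c(0, 1, 2, 3, 4, 5, 6, 2, 2)
  perfect <- classification_metrics(g, g)
  expect_equal(unname(perfect), c(0, 0, 1, 1, 1))

  # fixed 3x3 confusion matrix vs direct evaluation of the triple sum
  cm <- matrix(c(2, 0, 1, 1, 3, 0, 0, 0, 2), 3, 3)  # [[2,1,0],[0,3,0],[1,0,2]]
  truth <- rep(0:2, times = rowSums(cm))
  pred <- unlist(lapply(1:3, function(a)
    rep(0:2, times = cm[a, ])))
  met <- classification_metrics(truth, pred, n_classes = 3)
  expect_equal(unname(met["mcc"]), brute_mcc(cm), tolerance = 1e-12)

  # degenerate predictor against balanced truth: MCC = 0
  g2 <- rep(c(0, 1), 20)
  expect_equal(unname(classification_metrics(g2, rep(1, 40))["mcc"]), 0)

  expect_error(classification_metrics(integer(0), integer(0)), "empty")
  expect_error(classification_metrics(c(0, 1), c(0, 7)), "class set")
})

test_that("MCC is invariant under relabeling; kappa behaves at the poles", {
  set.seed(9)
  g <- sample(0:6, 120, replace = TRUE)
  p <- ifelse(runif(120) < 0.6, g, sample(0:6, 120, replace = TRUE))
  base <- classification_metrics(g, p)
  perm <- sample(0:6)
  relab <- classification_metrics(perm[g + 1], perm[p + 1])
  expect_equal(unname(relab["mcc"]), unname(base["mcc"]), tolerance = 1e-12)

  expect_equal(unname(classification_metrics(g, g)["kappa"]), 1)
  # independent classifiers: K near 0 (Monte-Carlo tolerance)
  set.seed(10)
  g3 <- sample(0:6, 6000, replace = TRUE)
  p3 <- sample(0:6, 6000, replace = TRUE)
  expect_lt(abs(unname(classification_metrics(g3, p3)["kappa"])), 0.05)
  expect_lt(abs(unname(classification_metrics(g3, p3)["mcc"])), 0.05)
})

test_that("cv protocol is grouped, reproducible, and honest on nulls", {
  co <- generate_cohort(12, 20, seed = 8, width = 64, height = 64)
  # perfect oracle predictor reproduces the ground-truth counts
  oracle_factory <- function(train_man, cohort) {
    function(man) man$n_cells
  }
  cv <- cv_protocol(co, oracle_factory, repeats = 2, folds = 3, seed = 1)
  expect_true(all(cv$per_fold$acc == 1))
  expect_true(all(cv$summary$mean[cv$summary$metric %in%
                                    c("mcc", "kappa", "acc")] == 1))

  # reproducibility at fixed seed
  seen <- list()
  capture_factory <- function(train_man, cohort) {
    seen[[length(seen) + 1]] <<- sort(unique(train_man$slide_id))
    function(man) man$n_cells
  }
  cv1 <- cv_protocol(co, capture_factory, repeats = 1, folds = 3, seed = 2)
  cv2 <- cv_protocol(co, oracle_factory, repeats = 1, folds = 3, seed = 2)
  expect_identical(cv1$per_fold, cv2$per_fold)
  # no training fold may contain a held-out slide (grouping check)
  expect_true(all(lengths(seen) < length(unique(
    co$manifest$slide_id[co$manifest$split == "train"]))))

  # shuffled-label control hovers near zero MCC
  null_factory <- function(train_man, cohort) {
    function(man) sample(man$n_cells)
  }
  cvn <- cv_protocol(co, null_factory, repeats = 2, folds = 3, seed = 3)
  mcc_mean <- cvn$summary$mean[cvn$summary$metric == "mcc"]
  expect_lt(abs(mcc_mean), 0.15)

  expect_error(cv_protocol(co, oracle_factory, folds = 50), "folds")
  row <- format_cv_table(cv, "TR-CV")
  expect_identical(names(row), c("Subset", "MCC", "K", "ACC", "MAE", "MSE"))
})
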