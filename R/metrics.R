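as_points <- function(p) {
  if (is.data.frame(p)) cbind(p$x, p$y)
  else if (is.matrix(p)) p
  else if (length(p) == 0) matrix(numeric(0), 0, 2)
  else stop("points must be a data frame with x/y or a 2-column matrix",
            call. = FALSE)
}

#' Match detections to ground truth by optimal assignment
#'
#' Computes the minimum-total-Euclidean-distance assignment between ground
#' truth centers `T` and predicted centers `P` (Hungarian algorithm), then
#' rejects assigned pairs at distance `>= threshold`: accepted pairs are
#' true positives, unmatched truths false negatives, unmatched predictions
#' false positives. The default threshold of 8 px corresponds to the ~4 um
#' lymphocyte size at 0.5 um/pixel.
#'
#' @param truth,pred Data frames with columns `x`, `y` (or 2-column
#'   matrices).
#' @param threshold Acceptance threshold Theta in pixels (> 0); a match is
#'   accepted only when its distance is strictly lower.
#' @return An object of class `detection_match`: list with `pairs` (data
#'   frame `truth_idx`, `pred_idx`, `distance`), `tp`, `fp`, `fn`,
#'   `threshold`.
#' @export
match_detections <- function(truth, pred, threshold = 8) {
  assert_that(threshold > 0, "threshold must be positive")
  tm <- as_points(truth); pm <- as_points(pred)
  nt <- nrow(tm); np <- nrow(pm)
  pairs <- data.frame(truth_idx = integer(0), pred_idx = integer(0),
                      distance = numeric(0))
  if (nt > 0 && np > 0) {
    cost <- sqrt(outer(tm[, 1], pm[, 1], "-")^2 +
                 outer(tm[, 2], pm[, 2], "-")^2)
    if (nt <= np) {
      match <- .hungarian(cost)
      ti <- seq_len(nt); pi <- match
    } else {
      match <- .hungarian(t(cost))
      pi <- seq_len(np); ti <- match
    }
    d <- cost[cbind(ti, pi)]
    keep <- d < threshold
    pairs <- data.frame(truth_idx = ti[keep], pred_idx = pi[keep],
                        distance = d[keep])
  }
  tp <- nrow(pairs)
  structure(list(pairs = pairs, tp = tp, fp = np - tp, fn = nt - tp,
                 threshold = threshold, n_truth = nt, n_pred = np),
            class = "detection_match")
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf("<detection_match> TP=%d FP=%d FN=%d (theta=%g px)\n",
              x$tp, x$fp, x$fn, x$threshold))
  invisible(x)
}

#' Precision, recall and F1 of a detection match
#'
#' F1 is the harmonic mean `2PR/(P+R)`. All three scores are 0 when their
#' denominators vanish with no true positives.
#'
#' @param match A `detection_match`, or a list/vector with `tp`, `fp`, `fn`.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
detection_scores <- function(match) {
  if (is.list(match)) {
    tp <- match$tp; fp <- match$fp; fn <- match$fn
  } else {
    tp <- match[["tp"]]; fp <- match[["fp"]]; fn <- match[["fn"]]
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Bin a lymphocyte count into its ordinal class
#'
#' Classes 0--6 with boundaries 0, 1--5, 6--10, 11--20, 21--50, 51--200,
#' >200 (all boundaries inclusive).
#'
#' @param count Nonnegative integer count (vectorized).
#' @return Integer class in `0:6`.
#' @export
bin_count <- function(count) {
  assert_that(all(count >= 0), "counts must be nonnegative")
  breaks <- c(-Inf, 0, 5, 10, 20, 50, 200, Inf)
  as.integer(cut(count, breaks, labels = FALSE)) - 1L
}

confusion_matrix <- function(truth, pred, n_classes = 7) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm  # cm[a, b]: truth class a-1 predicted as class b-1
}

quadratic_kappa <- function(cm) {
  k <- nrow(cm)
  n <- sum(cm)
  w <- outer(0:(k - 1), 0:(k - 1), function(i, j) (i - j)^2 / (k - 1)^2)
  obs <- cm / n
  exp_ <- outer(rowSums(cm), colSums(cm)) / n^2
  denom <- sum(w * exp_)
  if (denom == 0) return(1)  # all mass on one agreeing cell
  1 - sum(w * obs) / denom
}

multiclass_mcc <- function(cm) {
  # covariance form of the multiclass Matthews correlation coefficient;
  # algebraically identical to the triple-sum confusion-matrix formula
  n <- sum(cm)
  correct <- sum(diag(cm))
  t_k <- rowSums(cm)  # truth occurrences per class
  p_k <- colSums(cm)  # predicted occurrences per class
  num <- correct * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Ordinal count-classification metrics
#'
#' Mean absolute error and mean squared error between class vectors,
#' accuracy (Kronecker-delta agreement), quadratically-weighted Cohen's
#' kappa, and the multiclass Matthews correlation coefficient.
#'
#' @param truth,pred Equal-length integer class vectors with entries in
#'   `0:(n_classes-1)`.
#' @param n_classes Size of the ordinal class set (default 7).
#' @return Named numeric vector `mae`, `mse`, `acc`, `kappa`, `mcc`.
#' @export
classification_metrics <- function(truth, pred, n_classes = 7) {
  assert_that(length(truth) > 0, "empty class vectors")
  assert_that(length(truth) == length(pred),
              "class vectors must have equal length")
  assert_that(all(truth %in% 0:(n_classes - 1)) &&
              all(pred %in% 0:(n_classes - 1)),
              "class labels must lie in the ordinal class set")
  cm <- confusion_matrix(truth, pred, n_classes)
  c(mae = mean(abs(truth - pred)),
    mse = mean((truth - pred)^2),
    acc = mean(truth == pred),
    kappa = quadratic_kappa(cm),
    mcc = multiclass_mcc(cm))
}

#' Repeated slide-grouped cross-validation of a count predictor
#'
#' Runs an `repeats x folds` cross-validation over the training slides of a
#' cohort, always assigning whole slides to folds (no tile-level leakage),
#' and reports the ordinal classification metrics per fold plus their mean
#' and standard deviation, mirroring the usual results-table layout
#' (Subset, MCC, K, ACC, MAE, MSE).
#'
#' @param cohort A [generate_cohort()] result.
#' @param predictor_factory Function `(train_manifest, cohort) -> function`
#'   where the returned function maps a manifest subset to predicted counts
#'   (one per row).
#' @param repeats,folds Resampling plan (default 4 x 5).
#' @param seed Seed for fold assignment.
#' @return List with `per_fold` (data.frame of metrics per repeat/fold) and
#'   `summary` (mean and sd per metric).
#' @export
cv_protocol <- function(cohort, predictor_factory, repeats = 4, folds = 5,
                        seed = 1) {
  man <- cohort$manifest[cohort$manifest$split == "train", ]
  slides <- unique(man$slide_id)
  assert_that(length(slides) >= folds, sprintf(
    "cannot form %d slide-grouped folds from %d training slides",
    folds, length(slides)))
  rows <- list()
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- setNames(rep_len(seq_len(folds), length(slides)),
                          sample(slides))
      for (f in seq_len(folds)) {
        hold <- names(fold_of)[fold_of == f]
        tr <- man[!man$slide_id %in% hold, ]
        te <- man[man$slide_id %in% hold, ]
        predictor <- predictor_factory(tr, cohort)
        pred_counts <- predictor(te)
        met <- classification_metrics(bin_count(te$n_cells),
                                      bin_count(pmax(round(pred_counts), 0)))
        rows[[length(rows) + 1]] <- data.frame(
          repeat_ = r, fold = f, t(met))
      }
    }
  })
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("mcc", "kappa", "acc", "mae", "mse")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), 0),
    sd = vapply(metric_cols, function(m) sd(per_fold[[m]]), 0),
    row.names = NULL)
  list(per_fold = per_fold, summary = summary)
}

#' Format a cross-validation summary as a results table row
#'
#' @param cv A [cv_protocol()] result.
#' @param subset Row label (e.g. `"TR-CV"`).
#' @return One-row data frame with `mean (sd)` strings per metric.
#' @export
format_cv_table <- function(cv, subset = "TR-CV") {
  s <- cv$summary
  fmt <- function(m) {
    i <- match(m, s$metric)
    sprintf("%.3f (%.3f)", s$mean[i], s$sd[i])
  }
  data.frame(Subset = subset, MCC = fmt("mcc"), K = fmt("kappa"),
             ACC = fmt("acc"), MAE = fmt("mae"), MSE = fmt("mse"))
}
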