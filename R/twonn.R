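#' TwoNN intrinsic-dimension estimate
#'
#' For each point the ratio \eqn{\mu_i = d_{i,2}/d_{i,1}} of its second to
#' first nearest-neighbor distance follows a Pareto law
#' \eqn{p(\mu; d) = d\,\mu^{-(d+1)}} when the data lie uniformly on a
#' `d`-dimensional manifold. The largest `discard_fraction` of the ratios
#' (the heavy tail most sensitive to density variation) is discarded; since
#' \eqn{\ln\mu} is exponential with rate `d`, the discarded tail enters the
#' likelihood as right-censored observations at the retention threshold, and
#' the maximum-likelihood estimate has the closed form
#' \eqn{\hat d = m / (\sum_{i \le m} \ln \mu_{(i)} + k \ln \mu_{(m)})} with
#' `m` retained and `k` censored ratios. (The naive truncated-sample formula
#' \eqn{m/\sum\ln\mu} ignores the censoring and overestimates `d` by roughly
#' `discard_fraction`.)
#'
#' @param points Numeric matrix (one point per row), data frame or
#'   `feature_cloud`. Duplicate rows are removed with a warning.
#' @param discard_fraction Fraction of the largest ratios to drop
#'   (default 0.1).
#' @return An object of class `id_estimate`: list with `id` (the estimate
#'   \eqn{\hat d}), `mu` (all ratios), `n_used`, `n_total`,
#'   `discard_fraction`.
#' @export
twonn_id <- function(points, discard_fraction = 0.1) {
  x <- unclass(as.matrix(points))
  n0 <- nrow(x)
  x <- unique(x)
  if (nrow(x) < n0)
    warning(sprintf("removed %d duplicate points before TwoNN estimation",
                    n0 - nrow(x)), call. = FALSE)
  n <- nrow(x)
  if (n < 2) stop("all points identical: intrinsic dimension undefined",
                  call. = FALSE)
  assert_that(n >= 10, "TwoNN needs at least 10 distinct points")
  assert_that(discard_fraction >= 0 && discard_fraction < 1,
              "discard_fraction must be in [0, 1)")
  D <- as.matrix(dist(x))
  diag(D) <- Inf
  mu <- vapply(seq_len(n), function(i) {
    d12 <- sort.int(D[i, ], partial = 1:2)[1:2]
    d12[2] / d12[1]
  }, 0)
  m <- n - floor(discard_fraction * n)
  retained <- sort(mu)[seq_len(m)]
  k <- n - m
  denom <- sum(log(retained)) + k * log(retained[m])
  assert_that(denom > 0, "degenerate neighbor ratios (all equal to 1)")
  structure(list(id = m / denom, mu = mu, n_used = m, n_total = n,
                 discard_fraction = discard_fraction),
            class = "id_estimate")
}

#' @export
print.id_estimate <- function(x, ...) {
  cat(sprintf("<id_estimate> d = %.3f (n = %d, %d used, discard %.0f%%)\n",
              x$id, x$n_total, x$n_used, 100 * x$discard_fraction))
  invisible(x)
}

#' Intrinsic-dimension profile across network blocks and checkpoints
#'
#' Estimates the TwoNN intrinsic dimension of the flattened activations of
#' each designated inner block at each training checkpoint, the raw
#' material for dimensionality-over-training profiles.
#'
#' @param model A `unet`.
#' @param tiles List of tiles to push through the network.
#' @param checkpoints Named list/vector mapping epoch (coercible to
#'   integer) to checkpoint path; `NULL` uses the model's current weights
#'   under epoch `NA`.
#' @param blocks Block ids (default all of [unet_blocks()]).
#' @param discard_fraction Passed to [twonn_id()].
#' @return Data frame `epoch`, `block`, `id`, `n`.
#' @export
id_profile <- function(model, tiles, checkpoints = NULL,
                       blocks = unet_blocks(), discard_fraction = 0.1) {
  if (is.null(checkpoints)) checkpoints <- list(`NA` = NULL)
  rows <- list()
  for (ep in names(checkpoints)) {
    ckpt <- checkpoints[[ep]]
    if (!is.null(ckpt) && !file.exists(ckpt))
      stop("checkpoint not found: ", ckpt, call. = FALSE)
    for (blk in blocks) {
      fc <- extract_features(model, tiles, blk, checkpoint = ckpt)
      est <- twonn_id(fc, discard_fraction)
      rows[[length(rows) + 1]] <- data.frame(
        epoch = suppressWarnings(as.integer(ep)), block = blk,
        id = est$id, n = est$n_used)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
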