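#' Reduce-on-plateau learning-rate scheduler
#'
#' Monitors a validation metric; after `patience` consecutive epochs without
#' improvement the learning rate is multiplied by `factor` (the
#' update \eqn{\eta_{t+1} = \alpha \eta_t} with \eqn{\alpha = 0.2}).
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative factor alpha applied on a plateau.
#' @param patience Number of non-improving epochs tolerated before reducing.
#' @return A scheduler state list; advance it with [scheduler_step()].
#' @export
plateau_scheduler <- function(lr = 1e-2, factor = 0.2, patience = 10) {
  list(lr = lr, factor = factor, patience = patience,
       best = Inf, bad_epochs = 0L, n_reductions = 0L)
}

#' @rdname plateau_scheduler
#' @param sched A scheduler state.
#' @param metric The epoch's validation metric (lower is better).
#' @return The updated scheduler state; `$lr` holds the current learning
#'   rate and `$reduced` whether this step triggered a reduction.
#' @export
scheduler_step <- function(sched, metric) {
  sched$reduced <- FALSE
  if (metric < sched$best) {
    sched$best <- metric
    sched$bad_epochs <- 0L
  } else {
    sched$bad_epochs <- sched$bad_epochs + 1L
    if (sched$bad_epochs > sched$patience) {
      sched$lr <- sched$factor * sched$lr
      sched$bad_epochs <- 0L
      sched$n_reductions <- sched$n_reductions + 1L
      sched$reduced <- TRUE
    }
  }
  sched
}

# Adam update, applied recursively over the nested parameter list.
adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- step(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- step(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

tile_input <- function(tile) {
  img <- if (inherits(tile, "annotated_tile")) tile$image else tile
  array(img / 255, dim(img))
}

target_matrix <- function(target) {
  if (inherits(target, "density_map")) target$values else target
}

mse_loss <- function(pred, target) {
  mean((pred - target)^2)
}

#' Train the density-regression network
#'
#' Plain stochastic gradient training with Adam, pixel-wise MSE loss between
#' predicted and target density maps, and a reduce-on-plateau learning-rate
#' schedule monitoring the validation MSE. Tile order is reshuffled each
#' epoch under the training seed, so a fixed seed reproduces the run.
#'
#' @param model An [build_model()] network.
#' @param tiles List of training tiles (`annotated_tile` or `H x W x 3`
#'   arrays, intensities 0--255).
#' @param targets List of matching targets (`density_map` or matrices).
#' @param val_tiles,val_targets Validation tiles/targets (held-out slides).
#' @param epochs Number of epochs.
#' @param seed Seed controlling shuffling.
#' @param checkpoint_dir If non-`NULL`, model snapshots are written there
#'   every `checkpoint_every` epochs (for the topology-over-training
#'   analyses) as `epoch_<n>.rds`.
#' @param checkpoint_every Checkpoint cadence in epochs (default 6).
#' @param verbose Print one line per epoch.
#' @return The model, with `$history` (data.frame `epoch`, `train_loss`,
#'   `val_loss`, `lr`) attached.
#' @export
train_model <- function(model, tiles, targets, val_tiles, val_targets,
                        epochs = 20, seed = 1, checkpoint_dir = NULL,
                        checkpoint_every = 6, verbose = FALSE) {
  assert_that(length(tiles) > 0, "empty training set")
  assert_that(length(tiles) == length(targets),
              "tiles and targets must have equal length")
  xs <- lapply(tiles, tile_input)
  ys <- lapply(targets, target_matrix)
  xv <- lapply(val_tiles, tile_input)
  yv <- lapply(val_targets, target_matrix)
  sched <- plateau_scheduler(model$config$lr, model$config$sched_factor,
                             model$config$sched_patience)
  opt <- adam_init(model$params)
  history <- data.frame()
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  val_loss <- function() {
    if (!length(xv)) return(NA_real_)
    mean(vapply(seq_along(xv), function(i) {
      mse_loss(unet_forward(model, xv[[i]], keep_cache = FALSE)$out[, , 1],
               yv[[i]])
    }, 0))
  }
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      order <- sample.int(length(xs))
      tr_loss <- 0
      for (i in order) {
        fw <- unet_forward(model, xs[[i]])
        resid <- fw$out[, , 1] - ys[[i]]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
        tr_loss <- tr_loss + loss
        dout <- array(2 * resid / length(resid), dim(fw$out))
        grads <- unet_backward(model, fw$cache, dout)
        upd <- adam_update(model$params, grads, opt, sched$lr)
        model$params <- upd$params
        opt <- upd$state
      }
      vl <- val_loss()
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tr_loss / length(xs), val_loss = vl,
        lr = sched$lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e  lr %.2e",
                        ep, tr_loss / length(xs), vl, sched$lr))
      if (is.finite(vl)) sched <- scheduler_step(sched, vl)
      if (!is.null(checkpoint_dir) && ep %% checkpoint_every == 0)
        saveRDS(model$params,
                file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
    }
  })
  model$history <- history
  model
}

#' Predict a density map for one tile
#'
#' @param model A (trained) `unet`.
#' @param tile An `annotated_tile` or `H x W x 3` array.
#' @return A `density_map` whose values are the raw network output (may be
#'   negative; [detect()] clips them).
#' @export
predict_map <- function(model, tile) {
  out <- unet_forward(model, tile_input(tile), keep_cache = FALSE)$out[, , 1]
  structure(list(values = out, d = NA_real_, sigma = NA_real_, l = NA_integer_),
            class = "density_map")
}

#' Extract flattened hidden-layer activations
#'
#' Runs each tile through the network and returns the post-activation
#' feature map of one of the six designated inner blocks, flattened into a
#' row vector (so entries are nonnegative: encoder taps are post-ReLU,
#' decoder taps post-scSE which preserves sign).
#'
#' @param model A `unet`.
#' @param tiles List of tiles.
#' @param block Block id, one of [unet_blocks()].
#' @param checkpoint Optional path to a checkpoint written by
#'   [train_model()]; its weights are used instead of the model's.
#' @return A `n x D` matrix of class `feature_cloud` with attributes
#'   `block` and `dim_block` (the `H x W x C` of the tapped block).
#' @export
extract_features <- function(model, tiles, block, checkpoint = NULL) {
  valid <- unet_blocks()
  if (!block %in% valid)
    stop("unknown block id '", block, "'; valid ids: ",
         paste(valid, collapse = ", "), call. = FALSE)
  if (!is.null(checkpoint)) {
    if (!file.exists(checkpoint))
      stop("checkpoint not found: ", checkpoint, call. = FALSE)
    model$params <- readRDS(checkpoint)
  }
  d_block <- NULL
  rows <- lapply(tiles, function(tl) {
    fw <- unet_forward(model, tile_input(tl))
    if (is.null(d_block)) d_block <<- dim(fw$cache[[block]])
    as.numeric(fw$cache[[block]])
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("feature_cloud", class(out)),
            block = block, dim_block = d_block)
}
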