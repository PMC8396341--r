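# Hand-rolled encoder-decoder density regressor. All tensors are H x W x C
# arrays; 3x3 convolutions, 2x2 max pooling and 2x bilinear upsampling run
# in compiled code (src/nn_ops.cpp), 1x1 convolutions and the scSE attention
# are plain matrix algebra here. Backpropagation is written out layer by
# layer; no autograd.

relu <- function(x) {
  x[x < 0] <- 0
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))

conv3 <- function(x, w, b) .conv2d_fw(x, w, b, 3L)
conv3_bw <- function(x, w, dy) .conv2d_bw(x, w, dy, 3L)

# 1x1 convolution as (H*W) x Cin %*% (Cin x Cout)
conv1 <- function(x, w, b) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3]) %*% w
  m <- sweep(m, 2, b, "+")
  array(m, c(d[1], d[2], ncol(w)))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

#' Network configuration for the density-regression U-Net
#'
#' @param preset `"tiny"` (thin five-stage encoder, < 100k parameters, for
#'   desk-scale training) or `"standard"` (decoder widths 256/128/64/32/16).
#' @param decoder_widths Five strictly decreasing channel widths; defaults
#'   depend on the preset (`standard`: `c(256,128,64,32,16)`).
#' @param scse Enable concurrent spatial/channel squeeze-and-excitation
#'   attention at the end of each decoder block (default `TRUE`).
#' @param lr Initial learning rate eta (default `1e-2`).
#' @param sched_factor Plateau scheduler factor alpha: on a plateau the new
#'   learning rate is `alpha * eta` (default `0.2`).
#' @param sched_patience Epochs without validation improvement before the
#'   learning rate is reduced (default `10`).
#' @param seed Seed for weight initialization.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(preset = c("tiny", "standard"), decoder_widths = NULL,
                         scse = TRUE, lr = 1e-2, sched_factor = 0.2,
                         sched_patience = 10, seed = 42) {
  preset <- match.arg(preset)
  enc <- switch(preset,
                tiny = c(6L, 8L, 12L, 16L, 24L, 32L),
                standard = c(32L, 48L, 96L, 160L, 288L, 448L))
  dec <- decoder_widths %||% switch(preset,
                                    tiny = c(24L, 16L, 12L, 8L, 4L),
                                    standard = c(256L, 128L, 64L, 32L, 16L))
  assert_that(length(dec) == 5, "decoder must have exactly five blocks")
  assert_that(all(diff(dec) < 0), "decoder widths must be strictly decreasing")
  structure(list(preset = preset, enc_widths = enc,
                 dec_widths = as.integer(dec), scse = scse, lr = lr,
                 sched_factor = sched_factor, sched_patience = sched_patience,
                 seed = seed),
            class = "unet_config")
}

init_conv <- function(k, cin, cout) {
  list(w = matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout))
}

init_scse <- function(c) {
  ch <- max(1L, c %/% 2L)
  list(cw1 = matrix(rnorm(ch * c, 0, sqrt(2 / c)), ch, c), cb1 = numeric(ch),
       cw2 = matrix(rnorm(c * ch, 0, sqrt(2 / ch)), c, ch), cb2 = numeric(c),
       sw = matrix(rnorm(c, 0, sqrt(1 / c)), c, 1), sb = 0)
}

#' Build the encoder-decoder density-regression network
#'
#' Five encoder stages each halve the spatial size; five decoder blocks each
#' upsample (non-trainable 2x bilinear), concatenate the symmetric encoder
#' feature, convolve, and apply scSE attention. The output head is a 1x1
#' convolution to one channel with identity activation, so predictions may be
#' negative (the postprocessor clips them).
#'
#' @param config An [unet_config()].
#' @return An object of class `unet` with the parameter set and config.
#' @export
build_model <- function(config = unet_config()) {
  e <- config$enc_widths; d <- config$dec_widths
  with_seed(config$seed, {
    params <- list(stem = init_conv(3, 3, e[1]))
    for (i in 1:5)
      params[[paste0("enc", i)]] <- init_conv(3, e[i], e[i + 1])
    skips <- e[5:1]  # decoder j concatenates encoder feature e[6-j]
    cin <- e[6]
    for (j in 1:5) {
      params[[paste0("dec", j)]] <- init_conv(3, cin + skips[j], d[j])
      if (config$scse)
        params[[paste0("scse", j)]] <- init_scse(d[j])
      cin <- d[j]
    }
    params$head <- list(w = matrix(rnorm(d[5], 0, sqrt(1 / d[5])), d[5], 1),
                        b = 0)
    structure(list(config = config, params = params), class = "unet")
  })
}

#' @export
print.unet <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf("<unet> preset '%s', decoder widths %s, %s parameters\n",
              x$config$preset, paste(x$config$dec_widths, collapse = "/"),
              format(np, big.mark = ",")))
  invisible(x)
}

#' Valid feature-tap block identifiers
#'
#' The six designated inner blocks around the bottleneck whose post-ReLU
#' activations feed the topological introspection suite.
#' @return Character vector of block ids.
#' @export
unet_blocks <- function() {
  c("enc3", "enc4", "enc5", "dec1", "dec2", "dec3")
}

# scSE attention forward. Returns output plus cache for backward.
scse_fw <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  z <- colMeans(xm)
  h_pre <- as.numeric(p$cw1 %*% z + p$cb1)
  h <- pmax(h_pre, 0)
  s <- sigmoid(as.numeric(p$cw2 %*% h + p$cb2))       # channel weights, [0,1]
  q <- sigmoid(as.numeric(xm %*% p$sw) + p$sb)        # spatial weights, [0,1]
  n <- d[1] * d[2]
  wmat <- pmax(matrix(q, n, d[3]), matrix(s, n, d[3], byrow = TRUE))
  # wmat[p, c] = max(q[p], s[c])
  y <- array(xm * wmat, d)
  list(y = y, cache = list(x = x, xm = xm, z = z, h_pre = h_pre, h = h,
                           s = s, q = q, wmat = wmat, dim = d))
}

scse_bw <- function(dy, p, cache) {
  d <- cache$dim
  dym <- matrix(dy, d[1] * d[2], d[3])
  dxm <- dym * cache$wmat
  g <- dym * cache$xm                      # gradient w.r.t. the weight matrix
  ch_mask <- matrix(cache$s, d[1] * d[2], d[3], byrow = TRUE) >= cache$q
  ds <- colSums(g * ch_mask)
  dq <- rowSums(g * !ch_mask)
  # channel branch
  ds_pre <- ds * cache$s * (1 - cache$s)
  dcw2 <- ds_pre %o% cache$h
  dcb2 <- ds_pre
  dh <- as.numeric(t(p$cw2) %*% ds_pre) * (cache$h_pre > 0)
  dcw1 <- dh %o% cache$z
  dcb1 <- dh
  dz <- as.numeric(t(p$cw1) %*% dh)
  dxm <- dxm + matrix(dz / (d[1] * d[2]), d[1] * d[2], d[3], byrow = TRUE)
  # spatial branch
  dm <- dq * cache$q * (1 - cache$q)
  dsw <- t(cache$xm) %*% dm
  dsb <- sum(dm)
  dxm <- dxm + dm %*% t(p$sw)
  list(dx = array(dxm, d),
       grads = list(cw1 = dcw1, cb1 = dcb1, cw2 = dcw2, cb2 = dcb2,
                    sw = dsw, sb = dsb))
}

#' Apply a concurrent spatial/channel squeeze-and-excitation block
#'
#' Channel branch: global average pool, bottleneck dense layer halving the
#' channel count, ReLU, dense restore, sigmoid. Spatial branch: 1x1
#' convolution to one channel, per-pixel sigmoid. Each output entry is the
#' input entry times the maximum of its channel weight and spatial weight,
#' so `|output| <= |input|` everywhere.
#'
#' @param x `H x W x C` array, `C >= 2`.
#' @param params Parameter list as produced inside [build_model()]; if
#'   omitted, a fresh random initialization for `C` channels (seeded from
#'   `seed`) is used.
#' @param seed Seed for the default random parameters.
#' @return `H x W x C` array.
#' @export
scse_block <- function(x, params = NULL, seed = 1) {
  d <- dim(x)
  assert_that(length(d) == 3 && d[3] >= 2, "scse_block needs an H x W x C array with C >= 2")
  if (is.null(params)) params <- with_seed(seed, init_scse(d[3]))
  scse_fw(x, params)$y
}

# Full forward pass; cache retains every intermediate needed for backward
# and for feature extraction.
unet_forward <- function(model, x, keep_cache = TRUE) {
  d <- dim(x)
  assert_that(length(d) == 3 && d[3] == 3, "input must be H x W x 3")
  assert_that(d[1] %% 32 == 0 && d[2] %% 32 == 0,
              "input spatial size must be divisible by 2^5 = 32")
  p <- model$params
  cache <- list(x = x)
  a <- conv3(x, p$stem$w, p$stem$b)
  e0 <- relu(a)
  cache$stem_pre <- a; cache$e0 <- e0
  enc <- list(e0)
  cur <- e0
  for (i in 1:5) {
    pool <- .maxpool2_fw(cur)
    nm <- paste0("enc", i)
    pre <- conv3(pool$y, p[[nm]]$w, p[[nm]]$b)
    cur <- relu(pre)
    cache[[paste0("pool", i)]] <- pool
    cache[[paste0(nm, "_pre")]] <- pre
    cache[[nm]] <- cur
    enc[[i + 1]] <- cur
  }
  skips <- enc[5:1]  # e4, e3, e2, e1, e0
  for (j in 1:5) {
    up <- .upsample2_fw(cur)
    catx <- cat_channels(up, skips[[j]])
    nm <- paste0("dec", j)
    pre <- conv3(catx, p[[nm]]$w, p[[nm]]$b)
    act <- relu(pre)
    cache[[paste0(nm, "_cat")]] <- catx
    cache[[paste0(nm, "_pre")]] <- pre
    if (model$config$scse) {
      sc <- scse_fw(act, p[[paste0("scse", j)]])
      cache[[paste0(nm, "_act")]] <- act
      cache[[paste0("scse", j)]] <- sc$cache
      cur <- sc$y
    } else {
      cur <- act
    }
    cache[[nm]] <- cur
  }
  out <- conv1(cur, p$head$w, p$head$b)
  cache$final <- cur
  if (keep_cache) list(out = out, cache = cache) else list(out = out)
}

unet_backward <- function(model, cache, dout) {
  p <- model$params
  grads <- list()
  d <- dim(cache$final)
  dm <- matrix(dout, d[1] * d[2], 1)
  fm <- matrix(cache$final, d[1] * d[2], d[3])
  grads$head <- list(w = t(fm) %*% dm, b = sum(dm))
  dcur <- array(dm %*% t(p$head$w), d)
  for (j in 5:1) {
    nm <- paste0("dec", j)
    if (model$config$scse) {
      sb <- scse_bw(dcur, p[[paste0("scse", j)]], cache[[paste0("scse", j)]])
      grads[[paste0("scse", j)]] <- sb$grads
      dcur <- sb$dx
    }
    dcur <- dcur * (cache[[paste0(nm, "_pre")]] > 0)
    cb <- conv3_bw(cache[[paste0(nm, "_cat")]], p[[nm]]$w, dcur)
    grads[[nm]] <- list(w = cb$dw, b = cb$db)
    dcat <- cb$dx
    # channel split: first the upsampled path, then the encoder skip
    # (decoder j concatenated encoder activation e_{5-j})
    skip_w <- model$config$enc_widths[6 - j]
    cup <- dim(dcat)[3] - skip_w
    dup <- dcat[, , seq_len(cup), drop = FALSE]
    cache[[paste0("dskip_e", 5 - j)]] <-
      dcat[, , cup + seq_len(skip_w), drop = FALSE]
    dcur <- .upsample2_bw(dup)
  }
  # encoder sweep: dcur is now the gradient at the bottleneck activation
  for (i in 5:1) {
    nm <- paste0("enc", i)
    if (i < 5) dcur <- dcur + cache[[paste0("dskip_e", i)]]
    dcur <- dcur * (cache[[paste0(nm, "_pre")]] > 0)
    pool <- cache[[paste0("pool", i)]]
    cb <- conv3_bw(pool$y, p[[nm]]$w, dcur)
    grads[[nm]] <- list(w = cb$dw, b = cb$db)
    din <- dim(if (i == 1) cache$e0 else cache[[paste0("enc", i - 1)]])
    dcur <- .maxpool2_bw(cb$dx, pool$argmax, din[1], din[2])
  }
  dcur <- dcur + (cache[["dskip_e0"]] %||% 0)
  dcur <- dcur * (cache$stem_pre > 0)
  cb <- conv3_bw(cache$x, p$stem$w, dcur)
  grads$stem <- list(w = cb$dw, b = cb$db)
  grads
}
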