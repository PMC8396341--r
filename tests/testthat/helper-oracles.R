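# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the package implementation it checks.

hexagon_points <- function() {
  cbind(cos(0:5 * pi / 3), sin(0:5 * pi / 3))
}

# Brute-force Vietoris-Rips persistence for tiny clouds (n <= 8): builds the
# FULL boundary matrix over vertices, edges and triangles in filtration
# order and runs the textbook left-to-right reduction, with no union-find
# shortcut. Returns a data.frame(dimension, birth, death).
brute_vr_persistence <- function(pts, digits = 12) {
  n <- nrow(pts)
  stopifnot(n <= 8)
  D <- signif(as.matrix(dist(pts)), digits)
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1]] <- list(v = i, f = 0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    simp[[length(simp) + 1]] <- list(v = c(i, j), f = D[i, j])
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    simp[[length(simp) + 1]] <- list(v = c(i, j, k),
                                     f = max(D[i, j], D[i, k], D[j, k]))
  dims <- vapply(simp, function(s) length(s$v) - 1L, 0L)
  fil <- vapply(simp, function(s) s$f, 0)
  lex <- vapply(simp, function(s) paste(sprintf("%02d", s$v), collapse = ""), "")
  ord <- order(fil, dims, lex)
  simp <- simp[ord]; dims <- dims[ord]; fil <- fil[ord]
  m <- length(simp)
  key <- vapply(simp, function(s) paste(sort(s$v), collapse = "-"), "")
  index_of <- setNames(seq_len(m), key)
  # boundary columns as sorted row-index vectors
  cols <- lapply(seq_len(m), function(c) {
    v <- simp[[c]]$v
    if (length(v) == 1) return(integer(0))
    faces <- utils::combn(v, length(v) - 1)
    sort(unname(index_of[apply(faces, 2, function(f)
      paste(sort(f), collapse = "-"))]))
  })
  low_of <- integer(m)  # row -> column having that low
  pairs <- list()
  for (c in seq_len(m)) {
    col <- cols[[c]]
    repeat {
      if (!length(col)) break
      low <- col[length(col)]
      if (low_of[low] == 0) break
      other <- cols[[low_of[low]]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    cols[[c]] <- col
    if (length(col)) {
      low <- col[length(col)]
      low_of[low] <- c
      pairs[[length(pairs) + 1]] <- c(low, c)
    }
  }
  paired <- unlist(lapply(pairs, identity))
  rows <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(dimension = dims[p[1]], birth = fil[p[1]], death = fil[p[2]])
  }))
  # unpaired simplices are essential classes
  unpaired <- setdiff(seq_len(m), c(vapply(pairs, `[`, 0, 1),
                                    vapply(pairs, `[`, 0, 2)))
  ess <- do.call(rbind, lapply(unpaired, function(s)
    data.frame(dimension = dims[s], birth = fil[s], death = Inf)))
  out <- rbind(rows, ess)
  out <- out[out$dimension <= 1 & (out$death > out$birth), ]
  out[order(out$dimension, out$birth, out$death), ]
}

# Canonical multiset representation of a diagram, for set comparison.
diagram_key <- function(pd, tol_digits = 9) {
  pd <- pd[pd$death > pd$birth, ]
  sort(sprintf("%d|%.9g|%.9g", pd$dimension, signif(pd$birth, tol_digits),
               signif(pd$death, tol_digits)))
}

# Exhaustive minimum-cost assignment by permutation search (|T|,|P| <= 6):
# returns the minimum total distance over all injective assignments of the
# smaller set into the larger.
brute_min_assignment <- function(tm, pm) {
  nt <- nrow(tm); np <- nrow(pm)
  cost <- sqrt(outer(tm[, 1], pm[, 1], "-")^2 + outer(tm[, 2], pm[, 2], "-")^2)
  if (nt > np) {
    cost <- t(cost)
    tmp <- nt; nt <- np; np <- tmp
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(np))) {
    tot <- sum(cost[cbind(seq_len(nt), p[seq_len(nt)])])
    if (tot < best) best <- tot
  }
  best
}

# Exhaustive Otsu: for each of the 255 interior bin edges, compute the
# between-class variance from first principles (explicit class masses and
# means over bin midpoints) and return the argmax edge.
brute_otsu <- function(v, bins = 256) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (t in 1:(bins - 1)) {
    c0 <- idx <= t; c1 <- !c0
    if (!any(c0) || !any(c1)) next
    w0 <- mean(c0); w1 <- mean(c1)
    mu0 <- mean(mids[idx[c0]]); mu1 <- mean(mids[idx[c1]])
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  list(threshold = edges[best_t + 1], between = best)
}

# Direct evaluation of the printed multiclass MCC triple-sum formula on a
# confusion matrix C (C[a, b] = truth a predicted b).
brute_mcc <- function(cm) {
  N <- nrow(cm)
  num <- 0
  for (k in 1:N) for (l in 1:N) for (m in 1:N)
    num <- num + cm[k, k] * cm[m, l] - cm[l, k] * cm[k, m]
  d1 <- 0
  for (k in 1:N) {
    a <- sum(cm[, k])
    b <- 0
    for (f in 1:N) for (g in 1:N) if (f != k) b <- b + cm[g, f]
    d1 <- d1 + a * b
  }
  d2 <- 0
  for (k in 1:N) {
    a <- sum(cm[k, ])
    b <- 0
    for (f in 1:N) for (g in 1:N) if (f != k) b <- b + cm[f, g]
    d2 <- d2 + a * b
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / (sqrt(d1) * sqrt(d2))
}

# Rejection sampler for well-separated centers inside a margin. Errors if
# the requested packing saturates rather than spinning forever.
separated_centers <- function(n, width, height, min_sep, margin = 0) {
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    cx <- runif(1, margin, width - 1 - margin)
    cy <- runif(1, margin, height - 1 - margin)
    if (!length(xs) || all((xs - cx)^2 + (ys - cy)^2 >= min_sep^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
    tries <- tries + 1
    if (tries > 20000 * n)
      stop("separated_centers: packing too dense for the requested area")
  }
  data.frame(x = xs, y = ys)
}

# Small rendered cohort shared by training-path tests.
tiny_training_set <- function(n_tiles = 8, size = 64, n_cells = 6,
                              seed = 100) {
  tiles <- lapply(seq_len(n_tiles), function(i)
    generate_tile(size, size, n_cells, seed = seed + i))
  targets <- lapply(tiles, build_density_map)
  list(tiles = tiles, targets = targets)
}
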