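#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that user session RNG is never disturbed.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Counter scheme expanding a master seed into per-item seeds, documented in
# the simulator: item i gets (master * 7919 + i) mod (2^31 - 1). The modulus
# keeps derived seeds inside R's 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + as.double(index)) %% 2147483647)
}

# Round half away from zero (VIA exports fractional point coordinates;
# base round() is banker's rounding, which is not what annotation tools do).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

assert_that <- function(ok, msg, call. = FALSE) {
  if (!isTRUE(ok)) stop(msg, call. = call.)
  invisible(TRUE)
}

# CRC-32 hash of a character scalar, as an 8-digit hex string. Used to tag
# log lines with a configuration fingerprint.
#' @keywords internal
#' @noRd
hash_string <- function(x) {
  v <- .crc32_raw(charToRaw(paste(x, collapse = "\n")))
  sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
}

log_stage <- function(stage, seed, config_hash = "-", ...) {
  extra <- paste(c(...), collapse = " ")
  message(sprintf("[%s] seed=%s config=%s %s", stage,
                  if (is.null(seed)) "-" else seed, config_hash, extra))
}
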