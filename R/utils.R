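# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 32-bit-safe seed derived from a master seed plus arbitrary
# labels (subject index, condition name, ...). Simple multiplicative hash;
# collisions are harmless (streams merely coincide) but rare.
derive_seed <- function(...) {
  parts <- as.character(unlist(list(...)))
  h <- 17
  for (p in parts) {
    for (v in utf8ToInt(p)) h <- (h * 131 + v) %% 2147483629
  }
  as.integer(h)
}

# Frequency grid of an n-point DFT sampled every `tr` seconds, folded to
# [0, Nyquist]: entry k is the physical frequency of DFT bin k (1-based).
dft_frequencies <- function(n, tr) {
  k <- 0:(n - 1)
  k <- pmin(k, n - k)
  k / (n * tr)
}

check_passband <- function(passband, tr) {
  if (length(passband) != 2 || !is.numeric(passband)) {
    stop("`passband` must be a numeric pair (low, high) in Hz.")
  }
  nyq <- 1 / (2 * tr)
  if (passband[1] >= passband[2]) {
    stop("Degenerate passband: low (", passband[1], ") >= high (", passband[2], ").")
  }
  if (passband[1] <= 0 || passband[2] >= nyq) {
    stop("Passband must lie strictly inside (0, Nyquist = ", nyq, " Hz).")
  }
  invisible(passband)
}
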