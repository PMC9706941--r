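# Shared internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  seed = NULL runs in the ambient stream.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

revcumsum <- function(x) rev(cumsum(rev(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Piecewise-constant hazard on [0, Inf): `breaks` are the interior cut
# points (ascending, possibly empty), `rates` has length(breaks) + 1.

# Cumulative hazard at times t (vectorised).
pch_cumhaz <- function(t, breaks, rates) {
  starts <- c(0, breaks)
  ends <- c(breaks, Inf)
  H <- numeric(length(t))
  for (k in seq_along(rates)) {
    dur <- pmin(t, ends[k]) - starts[k]
    dur[dur < 0] <- 0
    H <- H + rates[k] * dur
  }
  H
}

pch_survival <- function(t, breaks, rates) exp(-pch_cumhaz(t, breaks, rates))

# Inverse-transform sampler for per-subject piecewise-constant hazards.
# `rate_mat` is n x K (K pieces over common interior `breaks`); returns one
# latent time per row (Inf if the total hazard is exhausted first).
rpch <- function(rate_mat, breaks) {
  n <- nrow(rate_mat)
  K <- ncol(rate_mat)
  stopifnot(K == length(breaks) + 1L)
  starts <- c(0, breaks)
  widths <- c(diff(starts), Inf)
  E <- rexp(n)
  t_out <- rep(Inf, n)
  acc <- numeric(n)          # cumulative hazard consumed so far
  alive <- rep(TRUE, n)      # not yet assigned a time
  for (k in seq_len(K)) {
    r <- rate_mat[, k]
    inc <- r * widths[k]
    inc[r == 0] <- 0         # 0 * Inf in the open last piece
    hit <- alive & (acc + inc >= E) & r > 0
    t_out[hit] <- starts[k] + (E[hit] - acc[hit]) / r[hit]
    alive <- alive & !hit
    acc <- acc + inc
  }
  t_out
}

# Deterministic 32-bit FNV-1a hash of a character vector, as hex.  Used only
# to fingerprint configurations in reports; splits the 32-bit state into
# 16-bit halves so the modular multiply stays exact in doubles.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b)  # xor touches the low byte only
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  # hex-format the 32-bit value from its two 16-bit halves
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
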