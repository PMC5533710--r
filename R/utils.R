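# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centred moving average with reflect padding; width coerced to odd.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < 2L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  half <- min(half, n - 1L)
  width <- 2L * half + 1L
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  cs <- cumsum(c(0, padded))
  (cs[(width + 1L):(width + n)] - cs[1:n]) / width
}

# Piecewise-constant rolling quantile: quantile per block of `win` samples,
# linearly interpolated between block centres. Cheap stand-in for a true
# rolling quantile at the resolutions the detectors need.
rolling_level <- function(x, win, prob) {
  n <- length(x)
  win <- max(2L, min(as.integer(win), n))
  starts <- seq(1L, n, by = win)
  centres <- pmin(starts + (win - 1L) / 2, n)
  levels <- vapply(starts, function(s) {
    stats::quantile(x[s:min(s + win - 1L, n)], probs = prob, names = FALSE)
  }, numeric(1))
  if (length(levels) == 1L) return(rep(levels, n))
  stats::approx(centres, levels, xout = seq_len(n), rule = 2)$y
}

# Strict interior local extrema (sign change of the first difference).
local_minima <- function(x) {
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1          # treat flats as rising so plateau start wins
  which(diff(s) == 2) + 1L
}

local_maxima <- function(x) local_minima(-x)

# Prominence of a local minimum at index i within [lo, hi]: height of the
# lower flanking barrier above the minimum.
min_prominence <- function(x, i, lo, hi) {
  left <- max(x[lo:i])
  right <- max(x[i:hi])
  min(left, right) - x[i]
}

# Analytic-signal magnitude via FFT (one-sided spectrum doubling).
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Run `expr` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed stream, kept below 2^31 - 1.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647) * 48271 + 1009 * i) %% 2147483647L
}

# Truncated normal draws by rejection with a clamp fallback.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 50L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  pmin(pmax(out, lower), upper)
}

ms_to_samples <- function(ms, fs) round(ms * fs / 1000)

idx_to_ms <- function(idx, fs) (idx - 1) * 1000 / fs

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", what, "` must be a single positive finite number."))
  }
}
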