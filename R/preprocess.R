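#' Band-pass filter specification
#'
#' @param kind `"butterworth_bandpass"` or `"fft_bandpass"`.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth prototype order (2, 4 or 8); the -3 dB points of
#'   a single causal pass sit at the band edges.
#' @param zero_phase Apply forward-backward for zero group delay (default);
#'   timing-critical fiducial work is incompatible with uncorrected IIR delay.
#' @return A `gcg_filter_spec` list.
#' @export
filter_spec <- function(kind = c("butterworth_bandpass", "fft_bandpass"),
                        low_hz, high_hz, order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!order %in% c(2, 4, 8)) abort("`order` must be one of 2, 4, 8.")
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 ||
      high_hz <= low_hz) {
    abort("Parameter error: need 0 < low_hz < high_hz.")
  }
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = order, zero_phase = zero_phase),
            class = "gcg_filter_spec")
}

# Reflect-pad by `pad` samples each side; callers trim with trim_pad().
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  list(x = c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)]), pad = pad)
}

# Digital Butterworth band-pass as second-order sections: analog prototype
# poles, band-pass transformation, bilinear mapping, conjugate poles paired
# into biquads with one zero each at z = +1 and z = -1, gain normalised at
# the geometric band centre. The cascaded form stays numerically linear
# where the single 2N-order transfer function is ill-conditioned for narrow
# normalised bands.
butter_bandpass_sos <- function(fs, low_hz, high_hz, order) {
  wl <- tan(pi * low_hz / fs)
  wh <- tan(pi * high_hz / fs)
  w0sq <- wl * wh
  bw <- wh - wl
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k - 1 + order) / (2 * order))
  s_poles <- c()
  for (p in proto) {
    disc <- sqrt((bw * p)^2 - 4 * w0sq)
    s_poles <- c(s_poles, (bw * p + disc) / 2, (bw * p - disc) / 2)
  }
  z_poles <- (1 + s_poles) / (1 - s_poles)
  up <- z_poles[Im(z_poles) > 1e-12]
  re <- z_poles[abs(Im(z_poles)) <= 1e-12]
  sections <- list()
  for (p in up) {
    sections[[length(sections) + 1L]] <-
      list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2))
  }
  if (length(re) > 0) {
    re <- Re(re)
    for (i in seq(1, length(re), by = 2)) {
      sections[[length(sections) + 1L]] <-
        list(b = c(1, 0, -1),
             a = c(1, -(re[i] + re[i + 1]), re[i] * re[i + 1]))
    }
  }
  wc <- 2 * atan(sqrt(w0sq))
  z <- exp(1i * wc)
  h <- prod(vapply(sections, function(s) {
    (s$b[1] + s$b[2] / z + s$b[3] / z^2) /
      (s$a[1] + s$a[2] / z + s$a[3] / z^2)
  }, complex(1)))
  list(sections = sections, gain = 1 / Mod(h))
}

apply_sos <- function(sos, x) {
  y <- x
  for (s in sos$sections) {
    y <- as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), y))
  }
  sos$gain * y
}

#' Butterworth band-pass filter
#'
#' Digital Butterworth band-pass of the given prototype order (-3 dB at the
#' band edges per causal pass), implemented as cascaded second-order
#' sections and applied over a 1 s reflect-padded copy of the signal,
#' forward-backward when `zero_phase` so symmetric pulses keep their
#' extremum location.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param low_hz,high_hz Band edges, Hz (must satisfy `high_hz < fs/2`).
#' @param order Prototype order (2, 4 or 8).
#' @param zero_phase Forward-backward application (default TRUE).
#' @return Filtered series, same length as `x`.
#' @export
butterworth_bandpass <- function(x, fs, low_hz = 1, high_hz = 20,
                                 order = 4, zero_phase = TRUE) {
  stopifnot_scalar_pos(fs, "fs")
  spec <- filter_spec("butterworth_bandpass", low_hz, high_hz, order,
                      zero_phase)
  if (high_hz >= fs / 2) abort("Parameter error: high_hz must be < fs/2.")
  if (length(x) <= 3 * order) abort("Signal too short for the filter order.")
  sos <- butter_bandpass_sos(fs, low_hz, high_hz, order)
  p <- reflect_pad(x, round(fs))
  y <- apply_sos(sos, p$x)
  if (zero_phase) y <- rev(apply_sos(sos, rev(y)))
  y[(p$pad + 1L):(p$pad + length(x))]
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Closed-form magnitude of the digital design at frequency `f_hz`, using the
#' bilinear-transform frequency mapping and the band-pass prototype
#' transformation; squared when `zero_phase` (two passes).
#'
#' @inheritParams butterworth_bandpass
#' @param f_hz Frequency at which to evaluate, Hz.
#' @return Gain (linear scale).
#' @export
butterworth_gain <- function(f_hz, fs, low_hz = 1, high_hz = 20, order = 4,
                             zero_phase = TRUE) {
  warp <- function(f) tan(pi * f / fs)
  wl <- warp(low_hz); wh <- warp(high_hz); w <- warp(f_hz)
  q <- (w^2 - wl * wh) / (w * (wh - wl))
  g <- 1 / sqrt(1 + q^(2 * order))
  if (zero_phase) g^2 else g
}

#' FFT band-pass filter
#'
#' Multiplies the spectrum by a raised-cosine band mask: unity inside
#' `[low_hz, high_hz]`, zero outside `[low_hz*(1-w), high_hz*(1+w)]` with
#' cosine tapers across the relative transition width `w`.
#'
#' @param x Numeric series (length >= 16).
#' @param fs Sampling rate, Hz.
#' @param low_hz,high_hz Pass-band edges, Hz.
#' @param trans_frac Relative transition width (default 0.1).
#' @return Filtered series, same length as `x`.
#' @export
fft_bandpass <- function(x, fs, low_hz = 0.5, high_hz = 45,
                         trans_frac = 0.1) {
  stopifnot_scalar_pos(fs, "fs")
  if (length(x) < 16) abort("Signal too short (need >= 16 samples).")
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 ||
      high_hz <= low_hz || high_hz >= fs / 2) {
    abort("Parameter error: need 0 < low_hz < high_hz < fs/2.")
  }
  p <- reflect_pad(x, round(fs))
  n <- length(p$x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided magnitude axis
  mask <- fft_band_mask(f, low_hz, high_hz, trans_frac)
  y <- Re(stats::fft(stats::fft(p$x) * mask, inverse = TRUE) / n)
  y[(p$pad + 1L):(p$pad + length(x))]
}

fft_band_mask <- function(f, low, high, w) {
  lo0 <- low * (1 - w); hi1 <- high * (1 + w)
  mask <- numeric(length(f))
  mask[f >= low & f <= high] <- 1
  ramp_up <- f > lo0 & f < low
  mask[ramp_up] <- 0.5 * (1 - cos(pi * (f[ramp_up] - lo0) / (low - lo0)))
  ramp_dn <- f > high & f < hi1
  mask[ramp_dn] <- 0.5 * (1 + cos(pi * (f[ramp_dn] - high) / (hi1 - high)))
  mask
}

#' Preprocess a recording with the standard acquisition chain
#'
#' Gyroscope channels get a 1-20 Hz Butterworth band-pass, accelerometer
#' channels 4-45 Hz, the ECG a 0.5-45 Hz FFT band-pass; all zero-phase by
#' default and overridable.
#'
#' @param rec A `gcg_recording`.
#' @param gyro_band,acc_band,ecg_band Two-element band edges, Hz.
#' @param order Butterworth prototype order.
#' @param zero_phase Forward-backward application.
#' @return A filtered `gcg_recording`.
#' @export
preprocess_recording <- function(rec, gyro_band = c(1, 20),
                                 acc_band = c(4, 45),
                                 ecg_band = c(0.5, 45),
                                 order = 4, zero_phase = TRUE) {
  fs <- rec_fs(rec)
  out <- rec
  for (nm in intersect(c("gyro_x", "gyro_y", "gyro_z"), names(rec))) {
    out[[nm]] <- butterworth_bandpass(rec[[nm]], fs, gyro_band[1],
                                      gyro_band[2], order, zero_phase)
  }
  for (nm in intersect(c("acc_x", "acc_y", "acc_z"), names(rec))) {
    out[[nm]] <- butterworth_bandpass(rec[[nm]], fs, acc_band[1],
                                      acc_band[2], order, zero_phase)
  }
  out$ecg <- fft_bandpass(rec$ecg, fs, ecg_band[1], ecg_band[2])
  out
}
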