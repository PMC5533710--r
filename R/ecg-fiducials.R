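#' Detect ECG R peaks
#'
#' Squared-derivative envelope detector: the first difference of the filtered
#' ECG is squared, smoothed (120 ms moving average), and peaks above an
#' adaptive threshold (0.4 x the rolling 95th percentile over 2 s) are kept
#' with a 250 ms refractory period. Each envelope peak is refined to the ECG
#' maximum within +/-40 ms.
#'
#' @param ecg Filtered ECG series, mV.
#' @param fs Sampling rate, Hz (>= 200).
#' @param threshold_frac Fraction of the rolling 95th percentile used as
#'   threshold.
#' @param refractory_s Minimum spacing between detections, s.
#' @return Strictly increasing integer sample indices of R peaks.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.4,
                           refractory_s = 0.25) {
  if (fs < 200) abort("`fs` must be at least 200 Hz.")
  if (length(ecg) < 2 * fs) abort("Signal shorter than 2 s.")
  env <- moving_average(c(0, diff(ecg))^2, round(0.12 * fs))
  if (max(env) <= 0) return(integer(0))
  thr <- threshold_frac * rolling_level(env, round(2 * fs), 0.95)
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr[cand]]
  cand <- enforce_refractory(cand, env[cand], round(refractory_s * fs))
  half <- as.integer(round(0.04 * fs))
  n <- length(ecg)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  enforce_refractory(refined, ecg[refined], round(refractory_s * fs))
}

# Greedy refractory: keep candidates in decreasing strength order, discarding
# any within `gap` samples of an already-kept one.
enforce_refractory <- function(idx, strength, gap) {
  if (length(idx) == 0L) return(integer(0))
  ord <- order(strength, decreasing = TRUE)
  kept <- integer(0)
  for (i in idx[ord]) {
    if (all(abs(i - kept) > gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Locate the Q wave before an R peak
#'
#' Deepest sufficiently prominent local minimum in the 50 ms window before
#' the R peak; when the window contains no local minimum (e.g. a monotone
#' ramp) a fixed 33 ms fallback offset is used. Returns `NA` when the window
#' would run off the start of the record.
#'
#' @param ecg Filtered ECG series.
#' @param r_idx Index of a detected R peak.
#' @param fs Sampling rate, Hz.
#' @return Integer index of the Q trough, or `NA_integer_`.
#' @export
locate_q_wave <- function(ecg, r_idx, fs) {
  win <- round(0.05 * fs)
  lo <- r_idx - win
  if (lo < 1L || r_idx > length(ecg)) return(NA_integer_)
  seg <- ecg[lo:(r_idx - 1L)]
  mins <- local_minima(seg)
  if (length(mins) > 0L) {
    span <- diff(range(seg))
    prom <- vapply(mins, function(i) min_prominence(seg, i, 1L, length(seg)),
                   numeric(1))
    mins <- mins[prom >= 0.1 * span]
  }
  if (length(mins) == 0L) {
    fb <- r_idx - round(0.033 * fs)
    return(if (fb >= 1L) as.integer(fb) else NA_integer_)
  }
  as.integer(lo + mins[which.min(seg[mins])] - 1L)
}

#' Locate the T peak after an R peak
#'
#' Maximum of the ECG in the 150-450 ms window after the R peak (earliest
#' sample on ties); `NA` when the window is truncated by the record end.
#'
#' @inheritParams locate_q_wave
#' @return Integer index of the T peak, or `NA_integer_`.
#' @export
locate_t_peak <- function(ecg, r_idx, fs) {
  lo <- r_idx + round(0.15 * fs)
  hi <- r_idx + round(0.45 * fs)
  if (hi > length(ecg) || lo < 1L) return(NA_integer_)
  as.integer(lo + which.max(ecg[lo:hi]) - 1L)
}

#' ECG fiducial points for a recording
#'
#' Runs [detect_r_peaks()], then locates the Q trough and T peak for every
#' beat.
#'
#' @param rec A (preprocessed) `gcg_recording`.
#' @param ... Passed to [detect_r_peaks()].
#' @return Tibble with columns `beat`, `r_idx`, `q_idx`, `t_idx` (indices;
#'   `NA` where a point could not be located).
#' @export
ecg_fiducials <- function(rec, ...) {
  fs <- rec_fs(rec)
  r <- detect_r_peaks(rec$ecg, fs, ...)
  tibble(
    beat = seq_along(r),
    r_idx = r,
    q_idx = vapply(r, function(i) locate_q_wave(rec$ecg, i, fs), integer(1)),
    t_idx = vapply(r, function(i) locate_t_peak(rec$ecg, i, fs), integer(1))
  )
}
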