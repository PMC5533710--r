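#' Hilbert envelope of a signal
#'
#' Magnitude of the analytic signal (one-sided spectrum doubling via FFT),
#' optionally smoothed with a centred moving average.
#'
#' @param x Numeric series (length >= 16).
#' @param fs Sampling rate, Hz; required for smoothing.
#' @param smooth_ms Moving-average width in ms (0 disables smoothing).
#' @return Nonnegative envelope series, same length as `x`.
#' @export
hilbert_envelope <- function(x, fs = NULL, smooth_ms = 100) {
  if (length(x) < 16) abort("Signal too short (need >= 16 samples).")
  env <- analytic_envelope(x)
  if (!is.null(fs) && smooth_ms > 0) {
    env <- moving_average(env, round(smooth_ms / 1000 * fs))
  }
  env
}

#' Beat-detector configuration
#'
#' @param threshold_frac Fraction of the rolling 95th-percentile envelope
#'   level used as detection threshold.
#' @param level_window_s Window for the rolling envelope level, s.
#' @param refractory_s Minimum beat spacing, s (0.4 s caps detectable
#'   heart rate at 150 bpm).
#' @param smooth_ms Envelope smoothing, ms.
#' @param refine_ms Half-width of the g_J refinement search around each
#'   envelope peak, ms.
#' @param amp_gate_frac Amplitude-consistency gate: refined anchors whose
#'   y-axis amplitude falls below this fraction of the median anchor
#'   amplitude are discarded (rejects diastolic-wave false positives).
#' @return A list of detector settings.
#' @export
beat_config <- function(threshold_frac = 0.5, level_window_s = 3,
                        refractory_s = 0.4, smooth_ms = 100,
                        refine_ms = 60, amp_gate_frac = 0.55) {
  list(threshold_frac = threshold_frac, level_window_s = level_window_s,
       refractory_s = refractory_s, smooth_ms = smooth_ms,
       refine_ms = refine_ms, amp_gate_frac = amp_gate_frac)
}

#' ECG-free heartbeat detection on the gyroscope y-axis
#'
#' Peaks of the smoothed Hilbert envelope above an adaptive threshold
#' (`threshold_frac` x rolling 95th-percentile level), with a refractory
#' period; each detection is refined to the y-axis maximum within
#' `refine_ms`, i.e. the g_J (aortic-opening) candidate.
#'
#' @param gyro_y Preprocessed y-axis angular velocity, dps.
#' @param fs Sampling rate, Hz.
#' @param cfg Settings from [beat_config()].
#' @return Strictly increasing integer sample indices of beat anchors.
#' @export
detect_beats_gcg <- function(gyro_y, fs, cfg = beat_config()) {
  if (length(gyro_y) < 2 * fs) abort("Signal shorter than 2 s.")
  env <- hilbert_envelope(gyro_y, fs, cfg$smooth_ms)
  if (max(env) <= 0) return(integer(0))
  thr <- cfg$threshold_frac *
    rolling_level(env, round(cfg$level_window_s * fs), 0.95)
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr[cand]]
  gap <- round(cfg$refractory_s * fs)
  cand <- enforce_refractory(cand, env[cand], gap)
  half <- as.integer(round(cfg$refine_ms / 1000 * fs))
  n <- length(gyro_y)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(gyro_y[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  refined <- enforce_refractory(refined, gyro_y[refined], gap)
  if (length(refined) > 2L) {
    gate <- cfg$amp_gate_frac * stats::median(gyro_y[refined])
    refined <- refined[gyro_y[refined] >= gate]
  }
  refined
}

#' Segment a recording into per-beat windows
#'
#' Cuts equal-length slices of every channel around each anchor; anchors
#' whose window would overrun the record edges are dropped (count retained
#' in the result).
#'
#' @param rec A `gcg_recording`.
#' @param anchors Integer sample indices (e.g. R peaks or GCG beat anchors).
#' @param window `c(pre_ms, post_ms)` extent of each slice around its anchor.
#' @return A `gcg_beat_segments` object: per-channel matrices (beats x
#'   samples), kept anchors, the window, and `n_dropped`.
#' @export
segment_beats <- function(rec, anchors, window = c(200, 600)) {
  if (length(anchors) == 0L) abort("Empty anchor list.")
  fs <- rec_fs(rec)
  pre <- round(window[1] / 1000 * fs)
  post <- round(window[2] / 1000 * fs)
  n <- nrow(rec)
  keep <- anchors - pre >= 1L & anchors + post <= n
  kept <- anchors[keep]
  if (length(kept) == 0L) abort("All anchors fall too close to the record edges.")
  offs <- -pre:post
  chans <- rec_channels(rec)
  segs <- lapply(stats::setNames(chans, chans), function(nm) {
    m <- vapply(kept, function(a) rec[[nm]][a + offs], numeric(length(offs)))
    t(m)
  })
  structure(list(anchors = kept, n_dropped = sum(!keep), pre = pre,
                 post = post, fs = fs, window = window, segments = segs),
            class = "gcg_beat_segments")
}

#' @export
print.gcg_beat_segments <- function(x, ...) {
  cat(sprintf(
    "<gcg_beat_segments> %d beats x %d samples (%g ms pre, %g ms post), %d dropped\n",
    length(x$anchors), x$pre + x$post + 1, x$window[1], x$window[2],
    x$n_dropped))
  invisible(x)
}

#' Ensemble-average beat morphology
#'
#' Pointwise mean and SD across beats for every channel.
#'
#' @param segs A `gcg_beat_segments` object with at least two beats.
#' @return A `gcg_ensemble` tibble: `channel`, `offset` (samples relative to
#'   anchor), `t_offset` (s), `mean`, `sd`.
#' @export
ensemble_average <- function(segs) {
  if (!inherits(segs, "gcg_beat_segments")) {
    abort("`segs` must come from segment_beats().")
  }
  if (length(segs$anchors) < 2L) abort("Need at least 2 segments to average.")
  offs <- -segs$pre:segs$post
  out <- purrr::map(names(segs$segments), function(nm) {
    m <- segs$segments[[nm]]
    tibble(channel = nm, offset = offs, t_offset = offs / segs$fs,
           mean = colMeans(m), sd = apply(m, 2, sd))
  })
  out <- bind_rows(out)
  class(out) <- c("gcg_ensemble", class(out))
  out
}
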