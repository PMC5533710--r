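#' Annotation search windows
#'
#' Search windows (ms) for the GCG fiducial points, centred on normative
#' healthy-adult event timings and roughly +/- 3 population SDs wide. All
#' windows are relative: `g_j` to the R peak; `g_i` and `spv` to the located
#' g_J; the x-axis wedge peak to the ECG T peak (or R + `kx_default_ms` when
#' no T is available); `g_k`/`g_l` to the wedge peak; `dpv` to g_L.
#'
#' @param g_j Window around R for the dominant y-axis peak, ms.
#' @param g_i Window before g_J for the mitral-closure notch, ms.
#' @param spv Window after g_J for the systolic peak-velocity lobe, ms.
#' @param kx_default_ms Fallback wedge-search centre after R, ms.
#' @param kx_half Half-width of the wedge-peak search, ms.
#' @param g_k,g_l Windows before/after the wedge peak for the aortic-closure
#'   and mitral-opening notches, ms.
#' @param dpv Window after g_L for the diastolic peak-velocity dip, ms.
#' @param spv_smooth_ms Moving-average width applied before the SPV argmax
#'   (the lobe is broad, not a sharp peak), ms.
#' @param prominence_frac Minimal prominence of an accepted local minimum,
#'   as a fraction of the local window span; rejects noise dimples.
#' @param gj_frac g_J is the earliest local maximum in its window reaching
#'   this fraction of the window maximum: the aortic-opening peak comes
#'   first even when the later systolic peak-velocity lobe rivals it in
#'   amplitude.
#' @return An `gcg_annotation_config` list.
#' @export
annotation_config <- function(g_j = c(-20, 120), g_i = c(-80, 0),
                              spv = c(0, 120), kx_default_ms = 360,
                              kx_half = 120, g_k = c(-80, 0),
                              g_l = c(0, 120), dpv = c(0, 120),
                              spv_smooth_ms = 50, prominence_frac = 0.15,
                              gj_frac = 0.35) {
  structure(list(g_j = g_j, g_i = g_i, spv = spv,
                 kx_default_ms = kx_default_ms, kx_half = kx_half,
                 g_k = g_k, g_l = g_l, dpv = dpv,
                 spv_smooth_ms = spv_smooth_ms,
                 prominence_frac = prominence_frac, gj_frac = gj_frac),
            class = "gcg_annotation_config")
}

# Earliest local maximum in [lo, hi] reaching frac * window maximum; falls
# back to the interior argmax when no interior local maximum qualifies.
earliest_dominant_max <- function(x, lo, hi, frac) {
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (hi - lo < 2L) return(NA_integer_)
  seg <- x[lo:hi]
  cands <- local_maxima(seg)
  cands <- cands[seg[cands] >= frac * max(seg)]
  if (length(cands) == 0L) return(interior_argmax(x, lo, hi))
  as.integer(lo + cands[1L] - 1L)
}

# Interior argmax within [lo, hi]; NA when the extremum touches a bound.
interior_argmax <- function(x, lo, hi, require_interior = TRUE) {
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (hi - lo < 2L) return(NA_integer_)
  i <- lo + which.max(x[lo:hi]) - 1L
  if (require_interior && (i == lo || i == hi)) return(NA_integer_)
  as.integer(i)
}

# Prominence-filtered local minima of x restricted to [lo, hi] (absolute).
prominent_minima <- function(x, lo, hi, frac) {
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (hi - lo < 2L) return(integer(0))
  seg <- x[lo:hi]
  mins <- local_minima(seg)
  if (length(mins) == 0L) return(integer(0))
  span <- diff(range(seg))
  if (span <= 0) return(integer(0))
  prom <- vapply(mins, function(i) min_prominence(seg, i, 1L, length(seg)),
                 numeric(1))
  as.integer(lo + mins[prom >= frac * span] - 1L)
}

#' Annotate the GCG fiducial points of one beat
#'
#' Locates, on the beat's channel slices: g_J (dominant y-axis maximum near
#' R, aortic opening), g_I (last prominent y-axis minimum before g_J, mitral
#' closure), SPV (maximum of the smoothed y-axis after g_J), the x-axis
#' wedge peak around the T wave with its flanking notches g_K (aortic
#' closure) and g_L (mitral opening), DPV (y-axis minimum after g_L) and the
#' maximal angular displacement (argmax of the detrended running integral of
#' the y-axis after Q). A fiducial whose extremum is not strictly interior
#' to its search window is reported absent (`NA`), never raised.
#'
#' @param seg Named list with numeric `gyro_y` and `gyro_x` slices of one
#'   beat (equal length).
#' @param r_idx Index of the R peak within the slices.
#' @param fs Sampling rate, Hz.
#' @param cfg Windows from [annotation_config()].
#' @param q_idx,t_idx Optional ECG Q/T indices within the slices.
#' @return One-row tibble with integer columns `g_i`, `g_j`, `spv`, `g_k`,
#'   `g_l`, `dpv`, `max_ang_disp` (indices into the slices; `NA` = absent).
#' @export
annotate_beat <- function(seg, r_idx, fs, cfg = annotation_config(),
                          q_idx = NA_integer_, t_idx = NA_integer_) {
  y <- seg$gyro_y
  x <- seg$gyro_x
  if (is.null(y) || is.null(x) || length(y) != length(x)) {
    abort("`seg` must contain equal-length `gyro_y` and `gyro_x` slices.")
  }
  smp <- function(ms) round(ms / 1000 * fs)
  need <- r_idx + smp(cfg$g_j[2])
  if (length(y) < need || r_idx + smp(cfg$g_j[1]) < 1L) {
    abort("Segment too short for the configured windows.")
  }

  g_j <- earliest_dominant_max(y, r_idx + smp(cfg$g_j[1]),
                               r_idx + smp(cfg$g_j[2]), cfg$gj_frac)

  g_i <- NA_integer_
  if (!is.na(g_j)) {
    mins <- prominent_minima(y, g_j + smp(cfg$g_i[1]), g_j - 1L,
                             cfg$prominence_frac)
    if (length(mins) > 0L) g_i <- mins[length(mins)]
  }

  spv <- NA_integer_
  if (!is.na(g_j)) {
    ys <- moving_average(y, smp(cfg$spv_smooth_ms))
    spv <- interior_argmax(ys, g_j + 1L, g_j + smp(cfg$spv[2]))
  }

  kx_centre <- if (!is.na(t_idx)) t_idx else r_idx + smp(cfg$kx_default_ms)
  wedge <- interior_argmax(x, kx_centre - smp(cfg$kx_half),
                           kx_centre + smp(cfg$kx_half))
  g_k <- g_l <- NA_integer_
  if (!is.na(wedge)) {
    before <- prominent_minima(x, wedge + smp(cfg$g_k[1]), wedge - 1L,
                               cfg$prominence_frac)
    if (length(before) > 0L) g_k <- before[length(before)]
    after <- prominent_minima(x, wedge + 1L, wedge + smp(cfg$g_l[2]),
                              cfg$prominence_frac)
    if (length(after) > 0L) g_l <- after[1L]
  }

  dpv <- NA_integer_
  if (!is.na(g_l)) {
    dpv <- interior_argmax(-y, g_l + 1L, g_l + smp(cfg$dpv[2]))
  }

  disp <- angular_displacement(y, fs)
  anchor <- if (!is.na(q_idx)) q_idx else r_idx
  mad_idx <- locate_max_ang_disp(disp, c(1L, length(y)), anchor)

  tibble(g_i = g_i, g_j = g_j, spv = spv, g_k = g_k, g_l = g_l,
         dpv = dpv, max_ang_disp = mad_idx)
}

#' Angular displacement from angular velocity
#'
#' Cumulative trapezoidal integral of the gyroscope y-axis; with the input
#' in degrees/s the result is in degrees.
#'
#' @param gyro_y Angular-velocity series, dps.
#' @param fs Sampling rate, Hz.
#' @return Displacement series (degrees), same length.
#' @export
angular_displacement <- function(gyro_y, fs) {
  stopifnot_scalar_pos(fs, "fs")
  if (length(gyro_y) < 2L) return(rep(0, length(gyro_y)))
  pracma::cumtrapz(gyro_y)[, 1] / fs
}

#' Locate the maximal angular displacement of a beat
#'
#' Linearly detrends the displacement over the beat bounds, then takes the
#' argmax strictly after the Q index (earliest sample on ties). The detrend
#' makes the maximum well defined: raw integration of a band-passed signal
#' drifts.
#'
#' @param disp Displacement series (e.g. from [angular_displacement()]).
#' @param bounds Two-element integer vector, beat bounds within `disp`.
#' @param q_idx Q index within `disp`; the search covers `(q_idx, bounds[2]]`.
#' @return Integer index of the maximum, or `NA_integer_` if the window is
#'   empty.
#' @export
locate_max_ang_disp <- function(disp, bounds, q_idx) {
  lo <- max(1L, bounds[1]); hi <- min(length(disp), bounds[2])
  if (hi <= lo) return(NA_integer_)
  seg <- detrend_linear(disp[lo:hi])
  if (diff(range(seg)) == 0) return(NA_integer_)  # flat: maximum undefined
  from <- max(q_idx - lo + 2L, 1L)
  if (from > length(seg)) return(NA_integer_)
  as.integer(lo + from - 2L + which.max(seg[from:length(seg)]))
}

#' Annotate every beat of a recording
#'
#' Segments the recording around the ECG R peaks (window 200 ms before to
#' 600 ms after) and runs [annotate_beat()] on each slice.
#'
#' @param rec A preprocessed `gcg_recording`.
#' @param ecg Tibble from [ecg_fiducials()] (columns `beat`, `r_idx`,
#'   `q_idx`, `t_idx`).
#' @param cfg Windows from [annotation_config()].
#' @param window Segmentation window `c(pre_ms, post_ms)`.
#' @return Tibble with one row per annotated beat: `beat`, `r_idx`, `q_idx`
#'   and absolute indices `g_i`, `g_j`, `spv`, `g_k`, `g_l`, `dpv`,
#'   `max_ang_disp` (`NA` = absent).
#' @export
annotate_recording <- function(rec, ecg, cfg = annotation_config(),
                               window = c(200, 600)) {
  fs <- rec_fs(rec)
  segs <- segment_beats(rec, ecg$r_idx, window)
  kept <- match(segs$anchors, ecg$r_idx)
  pre <- segs$pre
  rows <- purrr::map(seq_along(segs$anchors), function(j) {
    i <- kept[j]
    a <- segs$anchors[j]
    rel <- function(idx) if (is.na(idx)) NA_integer_ else idx - a + pre + 1L
    ann <- annotate_beat(
      list(gyro_y = segs$segments$gyro_y[j, ],
           gyro_x = segs$segments$gyro_x[j, ]),
      r_idx = pre + 1L, fs = fs, cfg = cfg,
      q_idx = rel(ecg$q_idx[i]), t_idx = rel(ecg$t_idx[i]))
    ann_abs <- ann %>% mutate(across(
      all_of(c("g_i", "g_j", "spv", "g_k", "g_l", "dpv", "max_ang_disp")),
      ~ .x + a - pre - 1L))
    dplyr::bind_cols(tibble(beat = ecg$beat[i], r_idx = a,
                            q_idx = ecg$q_idx[i]), ann_abs)
  })
  bind_rows(rows)
}
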