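#' Per-beat cardiac time intervals from fiducial points
#'
#' Converts matched ECG and GCG fiducials into intervals (ms): R-to-event
#' times, PEP (Q to g_J, aortic opening), LVET (g_J to g_K), QS2 (Q to g_K,
#' aortic closure; `qs2 = pep + lvet` holds exactly by construction), IVCT
#' (g_I to g_J), IVRT (g_K to g_L), and the Q-to-peak-velocity /
#' Q-to-maximal-displacement delays. Any interval with a missing endpoint is
#' absent (`NA`). Heart rate is 60/RR from adjacent R anchors, assigned to
#' the later beat.
#'
#' Note on QS2: the g_K notch is interpreted as aortic closure, giving QS2
#' its standard electromechanical-systole meaning; `qs2_endpoint = "avo"`
#' instead returns Q-to-g_J for users who want the literal alternative.
#'
#' @param gcg Tibble from [annotate_recording()].
#' @param ecg Tibble from [ecg_fiducials()].
#' @param fs Sampling rate, Hz.
#' @param qs2_endpoint `"avc"` (default; Q to g_K) or `"avo"` (Q to g_J).
#' @return Tibble, one row per matched beat, intervals in ms plus `hr` in
#'   bpm.
#' @export
compute_intervals <- function(gcg, ecg, fs, qs2_endpoint = c("avc", "avo")) {
  qs2_endpoint <- match.arg(qs2_endpoint)
  stopifnot_scalar_pos(fs, "fs")
  df <- inner_join(ecg, gcg, by = c("beat", "r_idx"),
                   suffix = c("", ".gcg"))
  if ("q_idx.gcg" %in% names(df)) df$q_idx.gcg <- NULL
  if (nrow(df) == 0L) abort("Anchor mismatch: no common beats.")
  k <- 1000 / fs
  ms <- function(a, b) (a - b) * k
  hr_tbl <- heart_rate(ecg$r_idx, fs)
  df <- left_join(df, tibble(beat = ecg$beat[-1], hr = hr_tbl$hr), by = "beat")
  pep <- ms(df$g_j, df$q_idx)
  lvet <- ms(df$g_k, df$g_j)
  tibble(
    beat = df$beat,
    r_mvc = ms(df$g_i, df$r_idx),
    r_avo = ms(df$g_j, df$r_idx),
    r_avc = ms(df$g_k, df$r_idx),
    r_mvo = ms(df$g_l, df$r_idx),
    ivct = ms(df$g_j, df$g_i),
    ivrt = ms(df$g_l, df$g_k),
    lvet = lvet,
    pep = pep,
    qs2 = if (qs2_endpoint == "avc") pep + lvet else pep,
    q_spv = ms(df$spv, df$q_idx),
    q_dpv = ms(df$dpv, df$q_idx),
    q_max_ang_disp = ms(df$max_ang_disp, df$q_idx),
    hr = df$hr
  )
}

#' Instantaneous heart rate from beat anchors
#'
#' @param anchors Strictly increasing sample indices.
#' @param fs Sampling rate, Hz.
#' @return Tibble with `beat` (index of the later anchor, starting at 2) and
#'   `hr` in bpm; empty for fewer than two anchors.
#' @export
heart_rate <- function(anchors, fs) {
  stopifnot_scalar_pos(fs, "fs")
  if (length(anchors) < 2L) return(tibble(beat = integer(0), hr = numeric(0)))
  rr <- diff(anchors) / fs
  tibble(beat = seq_along(anchors)[-1], hr = 60 / rr)
}

#' Cohort summary of per-beat intervals
#'
#' Two-stage summary matching subject-level reporting: per-subject means are
#' computed first, then the cohort mean and sample SD of those means. Absent
#' values are excluded, with counts reported.
#'
#' @param records Tibble of per-beat intervals with a `subject` column.
#' @param vars Interval columns to summarise (default: all standard ones
#'   present).
#' @return Tibble with `metric`, `mean`, `sd`, `n_subjects`, `n_beats`.
#' @export
summarize_cohort <- function(records, vars = NULL) {
  if (!"subject" %in% names(records)) {
    abort("`records` must contain a `subject` column.")
  }
  if (nrow(records) == 0L) abort("`records` is empty.")
  vars <- vars %||% intersect(interval_cols, names(records))
  out <- purrr::map(vars, function(v) {
    per <- records %>%
      group_by(.data$subject) %>%
      summarise(m = mean(.data[[v]], na.rm = TRUE),
                nb = sum(!is.na(.data[[v]])), .groups = "drop") %>%
      filter(.data$nb > 0L)
    tibble(metric = v,
           mean = if (nrow(per) > 0L) mean(per$m) else NA_real_,
           sd = if (nrow(per) > 1L) sd(per$m)
                else if (nrow(per) == 1L) 0 else NA_real_,
           n_subjects = nrow(per), n_beats = sum(per$nb))
  })
  bind_rows(out)
}
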