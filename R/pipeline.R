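#' Full GCG processing pipeline for one recording
#'
#' Convenience wrapper: preprocess, detect ECG fiducials, annotate the GCG
#' beats and compute per-beat intervals.
#'
#' @param rec A raw `gcg_recording`.
#' @param preprocess Apply [preprocess_recording()] first (default TRUE).
#' @param annotate_cfg Windows from [annotation_config()].
#' @return List with `recording` (preprocessed), `ecg`, `fiducials` and
#'   `intervals` tibbles.
#' @export
process_recording <- function(rec, preprocess = TRUE,
                              annotate_cfg = annotation_config()) {
  fs <- rec_fs(rec)
  pp <- if (preprocess) preprocess_recording(rec) else rec
  ef <- ecg_fiducials(pp)
  gf <- annotate_recording(pp, ef, annotate_cfg)
  iv <- compute_intervals(gf, ef, fs)
  list(recording = pp, ecg = ef, fiducials = gf, intervals = iv)
}

#' Ground-truth per-beat intervals
#'
#' Converts simulator truth event times into the same interval table the
#' pipeline produces, for direct agreement comparison.
#'
#' @param truth Truth object from [simulate_subject()].
#' @return Tibble of per-beat reference intervals, ms.
#' @export
truth_intervals <- function(truth) {
  b <- truth$beats
  ms <- function(a, z) (a - z) * 1000
  rr <- c(NA_real_, diff(b$t_r))
  tibble(
    beat = b$beat,
    r_mvc = ms(b$t_mvc, b$t_r),
    r_avo = ms(b$t_ao, b$t_r),
    r_avc = ms(b$t_ac, b$t_r),
    r_mvo = ms(b$t_mvo, b$t_r),
    ivct = ms(b$t_ao, b$t_mvc),
    ivrt = ms(b$t_mvo, b$t_ac),
    lvet = ms(b$t_ac, b$t_ao),
    pep = ms(b$t_ao, b$t_q),
    qs2 = ms(b$t_ac, b$t_q),
    q_spv = ms(b$t_spv, b$t_q),
    q_dpv = ms(b$t_dpv, b$t_q),
    q_max_ang_disp = ms(b$t_max_disp, b$t_q),
    hr = 60 / rr
  )
}

#' Run the pipeline over a simulated cohort
#'
#' @param cohort Output of [simulate_cohort()].
#' @param ... Passed to [process_recording()].
#' @return Tibble of per-beat intervals across subjects, with a `subject`
#'   column.
#' @export
process_cohort <- function(cohort, ...) {
  rows <- purrr::imap(cohort, function(subj, i) {
    iv <- process_recording(subj$recording, ...)$intervals
    iv$subject <- i
    iv
  })
  bind_rows(rows)
}
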