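#' Build a multichannel chest-motion recording
#'
#' A recording is a tibble with one row per sample and columns `t` (seconds),
#' `ecg` (mV), `gyro_x`, `gyro_y`, `gyro_z` (degrees/s) and optionally
#' `acc_x`, `acc_y`, `acc_z` (g). The sampling rate, start time and channel
#' units travel as attributes. Axis convention: x points laterally left to
#' right, y from head to foot, z from back to front.
#'
#' @param ecg ECG channel in millivolts.
#' @param gyro_x,gyro_y,gyro_z Angular-velocity channels in degrees per second.
#' @param acc_x,acc_y,acc_z Optional accelerometer channels in g.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Start time in seconds.
#' @param units Named character vector of channel-family units.
#' @return A `gcg_recording` tibble.
#' @export
recording <- function(ecg, gyro_x, gyro_y, gyro_z,
                      acc_x = NULL, acc_y = NULL, acc_z = NULL,
                      fs, t0 = 0,
                      units = c(ecg = "mV", gyro = "dps", acc = "g")) {
  stopifnot_scalar_pos(fs, "fs")
  chans <- list(ecg = ecg, gyro_x = gyro_x, gyro_y = gyro_y, gyro_z = gyro_z)
  acc <- list(acc_x = acc_x, acc_y = acc_y, acc_z = acc_z)
  acc_present <- !vapply(acc, is.null, logical(1))
  if (any(acc_present) && !all(acc_present)) {
    abort("Accelerometer channels must be supplied all together or not at all.")
  }
  if (all(acc_present)) chans <- c(chans, acc)
  n <- unique(lengths(chans))
  if (length(n) != 1L) abort("All channels must have identical length.")
  if (n == 0L) abort("Recording must contain at least one sample.")
  for (nm in names(chans)) {
    if (!all(is.finite(chans[[nm]]))) {
      abort(paste0("Channel `", nm, "` contains non-finite samples."))
    }
  }
  out <- as_tibble(c(list(t = t0 + (seq_len(n) - 1) / fs), chans))
  new_recording(out, fs = fs, t0 = t0, units = units)
}

new_recording <- function(df, fs, t0, units) {
  attr(df, "fs") <- fs
  attr(df, "t0") <- t0
  attr(df, "units") <- units
  class(df) <- unique(c("gcg_recording", class(df)))
  df
}

#' Sampling rate of a recording
#' @param rec A `gcg_recording`.
#' @return Sampling rate in Hz.
#' @export
rec_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (is.null(fs)) abort("Object carries no `fs` attribute; not a recording?")
  fs
}

rec_channels <- function(rec) setdiff(names(rec), "t")

has_acc <- function(rec) all(c("acc_x", "acc_y", "acc_z") %in% names(rec))

#' @export
print.gcg_recording <- function(x, ...) {
  cat(sprintf("<gcg_recording> %d samples @ %g Hz (%.1f s), channels: %s\n",
              nrow(x), rec_fs(x), nrow(x) / rec_fs(x),
              paste(rec_channels(x), collapse = ", ")))
  NextMethod()
}

required_cols <- c("t", "ecg", "gyro_x", "gyro_y", "gyro_z")
acc_cols <- c("acc_x", "acc_y", "acc_z")

#' Read a recording from delimited text
#'
#' The on-disk format is comma-separated UTF-8 with two leading comment lines,
#' `# fs_hz=<rate>` and `# units=ecg:mV,gyro:dps,acc:g`, followed by a header
#' row `t,ecg,gyro_x,gyro_y,gyro_z[,acc_x,acc_y,acc_z]`.
#'
#' @param path File path.
#' @return A `gcg_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  head_lines <- readLines(path, n = 10L)
  meta <- grep("^#", head_lines, value = TRUE)
  fs_line <- grep("^#\\s*fs_hz=", meta, value = TRUE)
  if (length(fs_line) == 0L) abort("Header error: missing `# fs_hz=` line.")
  fs <- suppressWarnings(as.numeric(sub("^#\\s*fs_hz=", "", fs_line[1])))
  if (!is.finite(fs) || fs <= 0) abort("Header error: fs must be > 0.")
  units <- c(ecg = "mV", gyro = "dps", acc = "g")
  units_line <- grep("^#\\s*units=", meta, value = TRUE)
  if (length(units_line) > 0L) {
    pairs <- strsplit(sub("^#\\s*units=", "", units_line[1]), ",")[[1]]
    kv <- strsplit(pairs, ":")
    units <- stats::setNames(vapply(kv, `[`, character(1), 2),
                             vapply(kv, `[`, character(1), 1))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0("Format error: missing column(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  have_acc <- acc_cols %in% names(df)
  if (any(have_acc) && !all(have_acc)) {
    abort("Format error: accelerometer columns must be all present or absent.")
  }
  keep <- c(required_cols, if (all(have_acc)) acc_cols)
  df <- df[keep]
  for (nm in setdiff(keep, "t")) {
    if (!all(is.finite(df[[nm]]))) {
      abort(paste0("Data error: non-finite values in `", nm, "`."))
    }
  }
  t0 <- if (nrow(df) > 0L) df$t[1] else 0
  new_recording(as_tibble(df), fs = fs, t0 = t0, units = units)
}

#' Write a recording to delimited text
#'
#' @param rec A `gcg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  fs <- rec_fs(rec)
  units <- attr(rec, "units") %||% c(ecg = "mV", gyro = "dps", acc = "g")
  con <- tryCatch(file(path, open = "wt"), error = function(e) {
    abort(paste0("I/O error: cannot open `", path, "` for writing."))
  })
  writeLines(c(
    sprintf("# fs_hz=%.10g", fs),
    paste0("# units=", paste(names(units), units, sep = ":", collapse = ","))
  ), con)
  close(con)
  readr::write_csv(as_tibble(unclass(rec)), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

interval_cols <- c("r_mvc", "r_avo", "r_avc", "r_mvo", "ivct", "ivrt",
                   "qs2", "lvet", "pep", "q_spv", "q_dpv",
                   "q_max_ang_disp", "hr")

#' Write per-beat cardiac time intervals to TSV
#'
#' One row per beat; interval columns in milliseconds rounded to one decimal,
#' heart rate in bpm.
#'
#' @param records Tibble of per-beat intervals (from [compute_intervals()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort("`records` must be a nonempty data frame of per-beat intervals.")
  }
  out <- as_tibble(records)
  num <- intersect(interval_cols, names(out))
  out[num] <- lapply(out[num], function(x) round(x, 1))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-beat cardiac time intervals from TSV
#' @param path File path written by [write_intervals()].
#' @return Tibble of per-beat intervals.
#' @export
read_intervals <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write simulator ground truth to JSON
#'
#' @param truth Ground-truth object from [simulate_subject()]: a list with
#'   `mean_hr` (bpm) and `beats`, a tibble of per-beat event times in seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_groundtruth <- function(truth, path) {
  jsonlite::write_json(
    list(mean_hr = truth$mean_hr, beats = as.data.frame(truth$beats)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulator ground truth from JSON
#' @param path File path written by [write_groundtruth()].
#' @return List with `mean_hr` and `beats` tibble.
#' @export
read_groundtruth <- function(path) {
  raw <- jsonlite::fromJSON(path)
  truth <- list(mean_hr = raw$mean_hr, beats = as_tibble(raw$beats))
  validate_groundtruth(truth)
  truth
}

validate_groundtruth <- function(truth) {
  b <- truth$beats
  ord <- c("t_q", "t_r", "t_mvc", "t_ao", "t_spv", "t_ac", "t_mvo", "t_dpv")
  missing <- setdiff(ord, names(b))
  if (length(missing) > 0L) {
    abort(paste0("Ground truth lacks column(s) ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(b[ord])
  if (nrow(m) > 0L && any(t(apply(m, 1, diff)) < 0)) {
    abort("Ground-truth event order violated within a beat.")
  }
  invisible(truth)
}
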