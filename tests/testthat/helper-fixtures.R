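# Shared fixtures: everything is generated in code at test time.

idx_of <- function(t, fs) round(t * fs) + 1L

# A deterministic, noise-free, jitter-free subject: the cleanest possible
# recording for exactness checks.
noise_free_params <- function(seed = 7, ...) {
  subject_params(noise_sd = 0, ecg_noise_sd = 0, acc_noise_sd = 0,
                 resp_depth = 0, hr_sd_within = 0, delay_jitter_sd = 0,
                 seed = seed, ...)
}

sine_wave <- function(freq, fs, dur, amp = 1) {
  amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)
}

# Steady-state amplitude of a (near-)sinusoid at a known frequency,
# estimated by projection onto the complex exponential over whole cycles.
tone_amplitude <- function(x, freq, fs) {
  n <- length(x)
  cycles <- floor(freq * n / fs)
  m <- round(cycles * fs / freq)
  t <- (0:(m - 1)) / fs
  2 * Mod(mean(x[1:m] * exp(-2i * pi * freq * t)))
}

tiny_recording <- function(n = 2400, fs = 800, seed = 1) {
  set.seed(seed)
  recording(ecg = rnorm(n), gyro_x = rnorm(n), gyro_y = rnorm(n),
            gyro_z = rnorm(n), acc_x = rnorm(n), acc_y = rnorm(n),
            acc_z = rnorm(n), fs = fs)
}

# Match detected beats to the nearest truth beat.
match_beats <- function(det_idx, truth_times, fs) {
  vapply(det_idx, function(i) which.min(abs(idx_of(truth_times, fs) - i)),
         integer(1))
}

default_population_zero_sd <- function() {
  tibble::tibble(
    param = c("hr", "q_r", "r_avo", "ivct", "lvet", "ivrt",
              "ao_spv", "mvo_dpv", "r_maxdisp"),
    mean = c(59, 33, 49, 29, 310, 68, 52, 7, 338),
    sd = 0)
}

interval_cols_for_test <- function() {
  c("r_mvc", "r_avo", "r_avc", "r_mvo", "ivct", "ivrt", "qs2", "lvet",
    "pep", "q_spv", "q_dpv", "q_max_ang_disp")
}

# Brute-force references for the paired statistics, written from the
# textbook formulas with no shared code with the package implementation.
bf_r2 <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  (sxy / sqrt(sxx * syy))^2
}
bf_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))
bf_ba <- function(x, y) {
  d <- x - y
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias, sd = s, lo = bias - 1.96 * s, hi = bias + 1.96 * s,
       rpc = 1.96 * s, cv = 100 * s / (sum(c(x, y)) / (2 * n)))
}
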