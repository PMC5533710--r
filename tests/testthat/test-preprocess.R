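test_that("band-pass passes the passband and rejects DC", {
  fs <- 800
  x <- sine_wave(10, fs, 10)
  y <- butterworth_bandpass(x, fs, 1, 20, 4, zero_phase = TRUE)
  expect_equal(tone_amplitude(y[2000:6000], 10, fs), 1, tolerance = 0.02)

  z <- butterworth_bandpass(rep(2.5, 4000), fs, 1, 20, 4)
  expect_lt(abs(mean(z)), 1e-3 * 2.5)
})

test_that("stopband attenuation matches the analytic magnitude response", {
  # closed-form digital Butterworth band-pass magnitude via the bilinear
  # frequency mapping -- computed here, independent of the filtering path
  fs <- 800
  analytic_gain <- function(f, lo, hi, ord) {
    w <- tan(pi * f / fs); wl <- tan(pi * lo / fs); wh <- tan(pi * hi / fs)
    q <- (w^2 - wl * wh) / (w * (wh - wl))
    1 / sqrt(1 + q^(2 * ord))
  }
  for (f in c(5, 10, 50, 100)) {
    x <- sine_wave(f, fs, 12)
    y <- butterworth_bandpass(x, fs, 1, 20, 4, zero_phase = FALSE)
    meas <- tone_amplitude(y[3000:9000], f, fs)
    expect_equal(meas, analytic_gain(f, 1, 20, 4), tolerance = 0.05 *
                   max(analytic_gain(f, 1, 20, 4), meas))
  }
})

test_that("band edges reject invalid parameters", {
  expect_error(butterworth_bandpass(rnorm(100), 800, 1, 500), "Nyquist|fs/2")
  expect_error(butterworth_bandpass(rnorm(10), 800, 1, 20), "short")
  expect_error(filter_spec("butterworth_bandpass", 20, 1), "low_hz")
  expect_error(fft_bandpass(rnorm(100), 800, 45, 0.5), "Parameter")
})

test_that("FFT band-pass suppresses the stopband and keeps the passband", {
  fs <- 800
  x60 <- sine_wave(60, fs, 6)
  y60 <- fft_bandpass(x60, fs, 0.5, 45)
  core <- (fs + 1):(5 * fs)   # away from the reflection edges
  expect_lt(sqrt(mean(y60[core]^2)), 0.01 * sqrt(mean(x60[core]^2)))

  x10 <- sine_wave(10, fs, 6)
  y10 <- fft_bandpass(x10, fs, 0.5, 45)
  expect_equal(sqrt(mean(y10[800:4000]^2)), sqrt(mean(x10[800:4000]^2)),
               tolerance = 0.02)
})

test_that("the FFT filter realises its raised-cosine mask", {
  # spectral comparison on an impulse: away from the transition bands the
  # output spectrum must equal the mask computed independently here
  fs <- 800; n <- 4096
  x <- numeric(n); x[n / 2] <- 1
  y <- fft_bandpass(x, fs, 0.5, 45, trans_frac = 0.1)
  spec <- Mod(fft(y))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  pass <- f >= 1 & f <= 40
  stop_band <- f >= 55 & f <= 350
  expect_lt(max(abs(spec[pass] - 1)), 0.05)
  expect_lt(max(spec[stop_band]), 0.01)
})

test_that("preprocessing keeps zeros, tolerates missing acc, stays linear", {
  fs <- 800
  zero <- recording(ecg = numeric(4000), gyro_x = numeric(4000),
                    gyro_y = numeric(4000), gyro_z = numeric(4000), fs = fs)
  out <- preprocess_recording(zero)
  expect_true(all(out$gyro_y == 0) && all(out$ecg == 0))
  expect_false("acc_x" %in% names(out))

  set.seed(1)
  x <- rnorm(4000); y <- rnorm(4000)
  lhs <- butterworth_bandpass(2 * x - 3 * y, fs, 1, 20)
  rhs <- 2 * butterworth_bandpass(x, fs, 1, 20) -
    3 * butterworth_bandpass(y, fs, 1, 20)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("zero-phase filtering preserves symmetric pulse extrema exactly", {
  fs <- 800
  t <- (0:(8 * fs - 1)) / fs
  for (sg in c(0.012, 0.02, 0.04)) {
    x <- exp(-(t - 4)^2 / (2 * sg^2))
    y <- butterworth_bandpass(x, fs, 1, 20, 4, zero_phase = TRUE)
    expect_equal(which.max(y), which.max(x))
  }
})

test_that("a second pass of the acquisition band barely moves g_J", {
  sim <- simulate_subject(noise_free_params(seed = 6), duration = 8, fs = 800)
  pp1 <- preprocess_recording(sim$recording)
  pp2 <- preprocess_recording(pp1)
  tr <- sim$truth$beats
  r <- idx_of(tr$t_ao[4], 800)
  w <- (r - 20):(r + 20)
  expect_lte(abs(which.max(pp2$gyro_y[w]) - which.max(pp1$gyro_y[w])), 2)
})
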