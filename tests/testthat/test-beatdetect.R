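test_that("the Hilbert envelope recovers amplitudes and modulation", {
  fs <- 800
  x <- sine_wave(5, fs, 6, amp = 2)
  env <- hilbert_envelope(x)
  core <- env[800:4000]
  expect_lt(max(abs(core - 2)) / 2, 0.02)

  expect_true(all(hilbert_envelope(numeric(64)) == 0))

  # AM tone: envelope must track the slow modulation a(t)
  t <- (0:(6 * fs - 1)) / fs
  a <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  x2 <- a * sin(2 * pi * 20 * t)
  env2 <- hilbert_envelope(x2)
  sel <- 800:4000
  expect_lt(sqrt(mean((env2[sel] - a[sel])^2)) / sqrt(mean(a[sel]^2)), 0.03)

  # sign invariance
  expect_equal(hilbert_envelope(-x2), hilbert_envelope(x2), tolerance = 1e-12)
})

test_that("GCG beat detection recovers beats and their timing", {
  fs <- 800
  sim <- simulate_subject(subject_params(seed = 14), duration = 60, fs = fs)
  pp <- preprocess_recording(sim$recording)
  a <- detect_beats_gcg(pp$gyro_y, fs)
  tr <- sim$truth$beats
  expect_lte(abs(length(a) - nrow(tr)), 1)
  m <- match_beats(a, tr$t_ao, fs)
  err_ms <- abs(a - idx_of(tr$t_ao, fs)[m]) * 1000 / fs
  expect_lte(median(err_ms), 10)

  expect_length(detect_beats_gcg(numeric(3 * fs), fs), 0)
  expect_error(detect_beats_gcg(numeric(100), fs), "2 s")
})

test_that("beat-detected heart rate matches truth on clean recordings", {
  fs <- 800
  sim <- simulate_subject(noise_free_params(seed = 15), duration = 60,
                          fs = fs)
  pp <- preprocess_recording(sim$recording)
  a <- detect_beats_gcg(pp$gyro_y, fs)
  hr <- mean(heart_rate(a, fs)$hr)
  expect_lt(abs(hr - sim$truth$mean_hr), 1)
})

test_that("segmentation cuts equal windows and drops edge anchors", {
  fs <- 800
  rec <- tiny_recording(n = 12 * fs, seed = 2)
  anchors <- as.integer(seq(2 * fs, 10 * fs, by = 0.8 * fs))
  segs <- segment_beats(rec, anchors, window = c(200, 600))
  expect_equal(length(segs$anchors), length(anchors))
  expect_equal(ncol(segs$segments$gyro_y), 0.8 * fs + 1)
  expect_equal(segs$n_dropped, 0)

  segs2 <- segment_beats(rec, c(10L, anchors), window = c(200, 600))
  expect_equal(segs2$n_dropped, 1)
  expect_error(segment_beats(rec, integer(0)), "anchor")
})

test_that("segments of a noise-free periodic signal are identical", {
  sim <- simulate_subject(noise_free_params(seed = 5, mean_hr = 60),
                          duration = 12, fs = 800)
  r <- idx_of(sim$truth$beats$t_r, 800)
  segs <- segment_beats(sim$recording, r[2:10], window = c(200, 600))
  m <- segs$segments$gyro_y
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-9)
})

test_that("ensemble averaging reduces noise like 1/sqrt(m)", {
  fs <- 800
  rec <- tiny_recording(n = 6 * fs, seed = 3)
  anchors <- as.integer(seq(1 * fs, 5 * fs, by = 0.5 * fs))
  segs <- segment_beats(rec, anchors, window = c(100, 100))
  ens <- ensemble_average(segs)
  expect_s3_class(ens, "gcg_ensemble")

  # identical segments: mean equals the segment, sd is zero
  segs_id <- segs
  for (nm in names(segs_id$segments)) {
    segs_id$segments[[nm]] <- matrix(rep(segs$segments[[nm]][1, ], 3),
                                     nrow = 3, byrow = TRUE)
  }
  ens_id <- ensemble_average(segs_id)
  expect_true(all(ens_id$sd == 0))

  # template + iid noise over m = 100 beats: residual RMS ~ sigma / sqrt(m)
  set.seed(42)
  len <- segs$pre + segs$post + 1L
  tmpl <- sin(seq(0, 2 * pi, length.out = len))
  sigma <- 0.8; m <- 100
  noisy <- matrix(rep(tmpl, each = m), nrow = m) +
    matrix(rnorm(m * len, 0, sigma), nrow = m)
  segs_mc <- segs
  segs_mc$anchors <- seq_len(m) * 300L
  segs_mc$segments <- list(gyro_y = noisy)
  ens_mc <- ensemble_average(segs_mc)
  rms <- sqrt(mean((ens_mc$mean - tmpl)^2))
  expect_lt(abs(rms - sigma / sqrt(m)) / (sigma / sqrt(m)), 0.3)

  # linearity: averaging +x and -x cancels
  segs_pm <- segs
  segs_pm$segments <- list(gyro_y = rbind(tmpl, -tmpl))
  segs_pm$anchors <- c(300L, 600L)
  expect_true(all(abs(ensemble_average(segs_pm)$mean) < 1e-12))

  segs_one <- segs
  segs_one$anchors <- segs$anchors[1]
  segs_one$segments <- lapply(segs$segments, function(m) m[1, , drop = FALSE])
  expect_error(ensemble_average(segs_one), "2 segments")
})
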