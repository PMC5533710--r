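test_that("the y-axis template peaks at the aortic-opening offset", {
  # R-to-AO of 49 ms at 800 Hz is sample 39 after the R sample
  b <- beat_template(c(r_mvc = 0.020, r_avo = 0.049), fs = 800)
  r <- attr(b, "r_index")
  expect_lte(abs((which.max(b$gyro_y) - r) - 39), 1)
})

test_that("template extrema sit on their generating events", {
  fs <- 800
  b <- beat_template(fs = fs)
  r <- attr(b, "r_index")
  smp <- function(ms) round(ms / 1000 * fs)
  apex <- r + smp(393)
  win_ac <- (apex - smp(120)):apex
  win_mvo <- apex:(apex + smp(120))
  ac <- win_ac[which.min(b$gyro_x[win_ac])] - r
  mvo <- win_mvo[which.min(b$gyro_x[win_mvo])] - r
  expect_lte(abs(ac - smp(359)), 1)
  expect_lte(abs(mvo - smp(427)), 1)
  win_mvc <- (r - smp(10)):(r + smp(45))
  mvc <- win_mvc[which.min(b$gyro_y[win_mvc])] - r
  expect_lte(abs(mvc - smp(20)), 3)  # band-limit residual, < 4 ms
})

test_that("zero amplitude gives an all-zero template and bad order errors", {
  b <- beat_template(fs = 800, waveform = waveform_params(amp_scale = 0))
  expect_true(all(b$gyro_y == 0) && all(b$gyro_x == 0) && all(b$ecg == 0))
  expect_error(beat_template(c(r_mvc = 0.05, r_avo = 0.02)), "order")
})

test_that("beat count follows the configured heart rate", {
  sim <- simulate_subject(
    subject_params(mean_hr = 60, hr_sd_within = 0, seed = 1),
    duration = 10, fs = 800)
  expect_true(nrow(sim$truth$beats) %in% c(10, 11))
})

test_that("a noise-free subject is exactly periodic between beats", {
  sim <- simulate_subject(noise_free_params(seed = 2, mean_hr = 60),
                          duration = 8, fs = 800)
  tr <- sim$truth$beats
  fs <- 800
  r <- idx_of(tr$t_r, fs)
  w <- -150:600
  for (ch in c("ecg", "gyro_y", "gyro_x")) {
    a <- sim$recording[[ch]][r[3] + w]
    b <- sim$recording[[ch]][r[4] + w]
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("simulation is deterministic given the seed and noise leaves truth alone", {
  p <- subject_params(seed = 9)
  s1 <- simulate_subject(p, duration = 6, fs = 800)
  s2 <- simulate_subject(p, duration = 6, fs = 800)
  expect_identical(s1$recording$gyro_y, s2$recording$gyro_y)
  expect_identical(s1$recording$ecg, s2$recording$ecg)

  quiet <- subject_params(seed = 9, noise_sd = 0, ecg_noise_sd = 0,
                          acc_noise_sd = 0)
  s3 <- simulate_subject(quiet, duration = 6, fs = 800)
  expect_equal(as.data.frame(s3$truth$beats), as.data.frame(s1$truth$beats),
               tolerance = 1e-12)
})

test_that("ground-truth event order holds for every generated beat", {
  ord <- c("t_q", "t_r", "t_mvc", "t_ao", "t_spv", "t_ac", "t_mvo", "t_dpv")
  for (seed in c(1, 5, 23)) {
    sim <- simulate_subject(subject_params(seed = seed), duration = 8,
                            fs = 800)
    m <- as.matrix(sim$truth$beats[ord])
    expect_true(all(apply(m, 1, function(row) all(diff(row) >= 0))))
  }
})

test_that("a degenerate population collapses to identical subjects", {
  pop <- default_population_zero_sd()
  cp <- cohort_params(n_subjects = 9, population = pop, duration = 5,
                      seed = 4)
  subj <- sample_subject_params(cp)
  expect_equal(length(unique(round(subj$r_avo, 9))), 1)
  expect_equal(length(unique(round(subj$mean_hr, 9))), 1)
})

test_that("cohort heart-rate draws recover the population mean", {
  # population HR 59 +/- 12, n = 9: mean within 3 * 12 / sqrt(9)
  subj <- sample_subject_params(cohort_params(seed = 8))
  expect_lt(abs(mean(subj$mean_hr) - 59), 3 * 12 / sqrt(9))
})

test_that("subject-parameter draws converge to the configured means", {
  subj <- sample_subject_params(cohort_params(seed = 31), n = 800)
  expect_lt(abs(mean(subj$r_avo) - 49), 3 * 10 / sqrt(800) + 0.2)
  expect_lt(abs(mean(subj$r_avc - subj$r_avo) - 310), 3 * 26 / sqrt(800))
  expect_lt(abs(mean(subj$mean_hr) - 59), 3 * 12 / sqrt(800) + 0.3)
})
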