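test_that("noise-free beats are annotated exactly at the truth samples", {
  fs <- 800
  sim <- simulate_subject(noise_free_params(seed = 7), duration = 20,
                          fs = fs)
  pp <- preprocess_recording(sim$recording)
  ef <- ecg_fiducials(pp)
  gf <- annotate_recording(pp, ef)
  tr <- sim$truth$beats
  m <- match_beats(gf$r_idx, tr$t_r, fs)
  err <- function(det, t_ev) abs(det - idx_of(t_ev, fs)[m])
  expect_lte(max(err(gf$g_i, tr$t_mvc)), 1)
  expect_lte(max(err(gf$g_j, tr$t_ao)), 1)
  expect_lte(max(err(gf$spv, tr$t_spv)), 1)
  expect_lte(max(err(gf$g_k, tr$t_ac)), 1)
  expect_lte(max(err(gf$g_l, tr$t_mvo)), 1)
  expect_lte(max(err(gf$dpv, tr$t_dpv)), 1)
  expect_lte(max(err(gf$max_ang_disp, tr$t_max_disp)), 2)

  # R-to-g_J around the normative 49 ms aortic-opening delay
  expect_lte(max(abs((gf$g_j - gf$r_idx) - round(0.049 * fs))), 1)
})

test_that("all-zero gyro channels yield absent fiducials", {
  fs <- 800
  seg <- list(gyro_y = numeric(641), gyro_x = numeric(641))
  ann <- annotate_beat(seg, r_idx = 161L, fs = fs, q_idx = 135L)
  expect_true(all(is.na(unlist(ann))))
})

test_that("angular displacement integrates, detrends and locates maxima", {
  fs <- 800
  expect_true(all(angular_displacement(numeric(100), fs) == 0))

  n <- 2 * fs
  disp_const <- angular_displacement(rep(3, n), fs)
  expect_equal(disp_const[n], 3 * (n - 1) / fs, tolerance = 1e-9)

  # single positive Gaussian lobe: detrended maximum where the lobe equals
  # its own mean rate -- computed from the closed-form Gaussian CDF
  t <- (0:(n - 1)) / fs
  centre <- 1; sg <- 0.05
  lobe <- exp(-(t - centre)^2 / (2 * sg^2))
  disp <- angular_displacement(lobe, fs)
  cdf <- pnorm(t, centre, sg) * sg * sqrt(2 * pi)
  oracle <- which.max(stats::resid(stats::lm(cdf ~ t)))
  got <- locate_max_ang_disp(disp, c(1L, n), q_idx = 2L)
  expect_lte(abs(got - oracle), 1)

  # monotone (convex) displacement peaks at the end after detrending
  expect_equal(locate_max_ang_disp((seq_len(100) / 10)^2, c(1L, 100L), 5L),
               100L)
  two_max <- c(0, 1, 0, 1, 0)
  expect_equal(which.max(two_max), 2L)  # earliest-tie convention of which.max
  expect_true(is.na(locate_max_ang_disp(rep(1, 50), c(1L, 50L), 2L)))
})

test_that("fiducial ordering holds whenever all points are detected", {
  fs <- 800
  sim <- simulate_subject(subject_params(seed = 18), duration = 30, fs = fs)
  pp <- preprocess_recording(sim$recording)
  gf <- annotate_recording(pp, ecg_fiducials(pp))
  full <- stats::complete.cases(gf[c("g_i", "g_j", "spv", "g_k", "g_l",
                                     "dpv")])
  m <- as.matrix(gf[full, c("g_i", "g_j", "spv", "g_k", "g_l", "dpv")])
  expect_gt(sum(full), 10)
  expect_true(all(apply(m, 1, function(r) all(diff(r) >= 0))))
})

test_that("annotation is invariant under uniform amplitude scaling", {
  fs <- 800
  sim <- simulate_subject(subject_params(seed = 19), duration = 15, fs = fs)
  pp <- preprocess_recording(sim$recording)
  ef <- ecg_fiducials(pp)
  gf1 <- annotate_recording(pp, ef)
  scaled <- pp
  for (ch in c("gyro_x", "gyro_y", "gyro_z")) {
    scaled[[ch]] <- 3.7 * scaled[[ch]]
  }
  gf2 <- annotate_recording(scaled, ef)
  expect_identical(as.data.frame(gf1), as.data.frame(gf2))
})

test_that("fiducial errors stay below 10 ms at the default noise level", {
  fs <- 800
  sim <- simulate_subject(subject_params(seed = 25), duration = 220,
                          fs = fs)
  pp <- preprocess_recording(sim$recording)
  gf <- annotate_recording(pp, ecg_fiducials(pp))
  tr <- sim$truth$beats
  expect_gte(nrow(gf), 200)
  m <- match_beats(gf$r_idx, tr$t_r, fs)
  med_ms <- function(det, t_ev) {
    median(abs(det - idx_of(t_ev, fs)[m]) * 1000 / fs, na.rm = TRUE)
  }
  expect_lte(med_ms(gf$g_i, tr$t_mvc), 10)
  expect_lte(med_ms(gf$g_j, tr$t_ao), 10)
  expect_lte(med_ms(gf$spv, tr$t_spv), 10)
  expect_lte(med_ms(gf$g_k, tr$t_ac), 10)
  expect_lte(med_ms(gf$g_l, tr$t_mvo), 10)
  expect_lte(med_ms(gf$dpv, tr$t_dpv), 10)
  expect_lte(med_ms(gf$max_ang_disp, tr$t_max_disp), 10)
})
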