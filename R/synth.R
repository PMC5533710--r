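#' Waveform geometry of the synthetic beat
#'
#' Pulse atoms are Gaussians (and one Gaussian-derivative slow wave), so every
#' extremum of the clean template sits analytically at its generating event
#' time and the simulator's ground truth is exact by construction. Amplitudes
#' are degrees/s for gyroscope atoms (a few dps, the scale seen on the chest),
#' mV for ECG and g for the accelerometer; widths are Gaussian sigmas in
#' seconds.
#'
#' @param amp_scale Multiplier applied to every atom amplitude (0 gives an
#'   all-zero template).
#' @param gi_amp Depth of the mitral-closure dip (g_I), dps.
#' @param gj_amp Amplitude of the dominant systolic y-axis peak (aortic
#'   opening, g_J), dps.
#' @param spv_amp Amplitude of the broad systolic peak-velocity lobe, dps.
#' @param dpv_amp Depth of the diastolic peak-velocity dip, dps.
#' @param wedge_amp Amplitude of the x-axis wedge (the up-down wave around
#'   the second heart sound); its flanking notches are 0.446 x as deep.
#' @param disp_amp Amplitude of the slow angular-displacement wave, degrees;
#'   its time-derivative is added to the y-axis so the integrated signal
#'   peaks at the maximal-displacement event.
#' @param disp_sd Sigma of the slow displacement wave, seconds.
#' @return A list of atom definitions used by [beat_template()] and the
#'   simulator.
#' @export
waveform_params <- function(amp_scale = 1, gi_amp = 1.5, gj_amp = 4.0,
                            spv_amp = 4.0, dpv_amp = 1.6, wedge_amp = 2.2,
                            disp_amp = 0.05, disp_sd = 0.015) {
  list(
    amp_scale = amp_scale,
    ecg = list(q = c(-0.15, 0.006), r = c(1.0, 0.008), s = c(-0.25, 0.006),
               t = c(0.30, 0.030)),
    y = list(gi_amp = gi_amp, gj_amp = gj_amp,
             spv = c(spv_amp, 0.026), dpv = c(-dpv_amp, 0.012),
             interdip = c(-2.4, 0.010), plateau = c(1.0, 0.055),
             ao_spike = c(1.2, 0.006)),
    disp = c(disp_amp, disp_sd),
    recoil_lag = 0.15, recoil_sd = 0.12,
    x = list(sys1 = c(-2.0, 0.009), sys2 = c(2.4, 0.010),
             sys3 = c(-1.6, 0.009), wedge_amp = wedge_amp),
    z = list(c(0.8, 0.010), c(-0.4, 0.008), c(-0.5, 0.008), c(0.3, 0.012)),
    acc = list(ao = c(0.030, 0.005), ac = c(0.015, 0.005),
               mvc = c(-0.010, 0.005)),
    # Equivalent-Gaussian SD (s) of the 1-20 Hz acquisition low-pass:
    # gyroscope atoms are generated as deconvolved pre-images under this
    # kernel so the band-limited waveform carries the designed geometry.
    # The wedge complex sees a slightly smaller equivalent kernel.
    presharpen = 0.012, ij_presharpen = 0.013, wedge_presharpen = 0.012,
    # amplitude calibration for the pre-sharpened dip-peak wavelet: the
    # Butterworth band is not exactly the Gaussian kernel, and the residual
    # mismatch inflates the recovered amplitude by ~1.3x
    ij_amp_cal = 0.72,
    # placement trim for the SPV atom: the lobe is broad, so its smoothed
    # peak (how SPV is defined) sits slightly right of the atom centre
    spv_shift = -0.006
  )
}

gauss <- function(tt, centre, sd) exp(-((tt - centre)^2) / (2 * sd^2))

# Derivative of disp_amp * gauss(tt, centre, sd): slow angular-velocity wave
# whose running integral peaks exactly at `centre`.
gauss_deriv <- function(tt, centre, sd, amp) {
  -amp * (tt - centre) / sd^2 * gauss(tt, centre, sd)
}

# Asymmetric dip-peak wavelet f(z) = alpha (z + r) exp(-z^2/2): one local
# minimum and one local maximum whose positions and amplitudes are solved in
# closed form, so the g_I dip and g_J peak land exactly on their events.
# The stationary points are the roots of z^2 + r z - 1 = 0.
ij_wavelet_geometry <- function(dip_amp, peak_amp) {
  target <- -dip_amp / peak_amp
  ratio <- function(r) {
    disc <- sqrt(r^2 + 4)
    z_p <- (-r + disc) / 2
    z_d <- (-r - disc) / 2
    ((z_d + r) * exp(-z_d^2 / 2)) / ((z_p + r) * exp(-z_p^2 / 2))
  }
  r <- stats::uniroot(function(r) ratio(r) - target, c(0, 6),
                      tol = 1e-12)$root
  disc <- sqrt(r^2 + 4)
  z_p <- (-r + disc) / 2
  z_d <- (-r - disc) / 2
  list(r = r, z_p = z_p, z_d = z_d)
}

# Evaluate the dip-peak wavelet with dip at t_dip and peak at t_peak.
# `presharp` deconvolves a Gaussian kernel of that SD from the atom (the
# family is closed under Gaussian convolution), so that after the
# acquisition low-pass the waveform regains exactly the designed geometry.
ij_wavelet <- function(tt, t_dip, t_peak, dip_amp, peak_amp, presharp = 0) {
  geo <- ij_wavelet_geometry(dip_amp, peak_amp)
  sdv <- (t_peak - t_dip) / (geo$z_p - geo$z_d)
  m <- t_peak - sdv * geo$z_p
  alpha <- peak_amp * exp(geo$z_p^2 / 2) / (geo$z_p + geo$r)
  r <- geo$r
  if (presharp > 0) {
    # cap the kernel for narrow complexes so the pre-image stays
    # well-conditioned (at most ~2.3x amplitude inflation)
    presharp <- min(presharp, 0.8 * sdv)
    sd0 <- sqrt(max(sdv^2 - presharp^2, (sdv / 4)^2))
    r <- r * sd0 / sdv
    alpha <- alpha * sdv^2 / sd0^2
    sdv <- sd0
  }
  z <- (tt - m) / sdv
  w <- alpha * (z + r) * exp(-z^2 / 2)
  # net area of the wavelet = alpha * r * sd * sqrt(2*pi)
  attr(w, "area") <- alpha * r * sdv * sqrt(2 * pi)
  w
}

# Inverted Ricker wedge: central peak at the midpoint of [t1, t2] with the
# two flanking minima exactly at t1 and t2 (stationary points at 0, +-sqrt 3),
# optionally pre-sharpened against the acquisition low-pass.
ricker_wedge <- function(tt, t1, t2, amp, presharp = 0) {
  sdv <- (t2 - t1) / (2 * sqrt(3))
  if (presharp > 0) {
    presharp <- min(presharp, 0.8 * sdv)
    sd0 <- sqrt(max(sdv^2 - presharp^2, (sdv / 4)^2))
    amp <- amp * (sdv / sd0)^3
    sdv <- sd0
    # minima of the smoothed wedge stay at t1, t2; evaluate the pre-image
    z <- (tt - (t1 + t2) / 2) / sdv
    return(amp * (1 - z^2) * exp(-z^2 / 2))
  }
  z <- (tt - (t1 + t2) / 2) / sdv
  amp * (1 - z^2) * exp(-z^2 / 2)
}

default_delays_ms <- c(q_r = 33, r_mvc = 20, r_avo = 49, r_avc = 359,
                       r_mvo = 427, r_spv = 101, r_dpv = 434,
                       r_maxdisp = 338)

# Evaluate all channel templates at times tt (seconds relative to the R peak)
# for one beat with event offsets ev (seconds relative to R; q is negative).
# Gyroscope atoms are evaluated as pre-images of their designed shapes under
# a Gaussian kernel of SD wf$presharpen, so the 1-20 Hz acquisition band
# returns them with the designed extrema placement.
template_eval <- function(tt, ev, wf) {
  s <- wf$amp_scale
  atom0 <- function(def, centre) s * def[1] * gauss(tt, centre, def[2])
  ecg <- atom0(wf$ecg$q, -ev$q) + atom0(wf$ecg$r, 0) +
    atom0(wf$ecg$s, 0.025) + atom0(wf$ecg$t, ev$ac - 0.045)
  if (s == 0) {
    zero <- numeric(length(tt))
    return(list(ecg = ecg, gyro_x = zero, gyro_y = zero, gyro_z = zero,
                acc_x = zero, acc_y = zero, acc_z = zero))
  }
  ps <- wf$presharpen
  sharp_sd <- function(sd) {
    eff <- min(ps, 0.8 * sd)
    sqrt(max(sd^2 - eff^2, (sd / 4)^2))
  }
  atom <- function(def, centre) {
    sd0 <- sharp_sd(def[2])
    # (narrow atoms are capped inside sharp_sd)
    s * def[1] * (def[2] / sd0) * gauss(tt, centre, sd0)
  }
  ij <- ij_wavelet(tt, ev$mvc, ev$ao, s * wf$ij_amp_cal * wf$y$gi_amp,
                   s * wf$ij_amp_cal * wf$y$gj_amp,
                   presharp = wf$ij_presharpen)
  # Late-systolic plateau lobe: sustained low positive angular velocity
  # between SPV and the maximal displacement, so the integrated signal keeps
  # rising until the displacement maximum (the myocardium keeps shortening
  # until end-systole).
  t_plat <- (ev$spv + ev$maxdisp) / 2
  # Diastolic recoil lobe: broad negative pulse cancelling the net area of
  # the y-axis components, so each beat's angular displacement returns to
  # baseline (zero net rotation per cycle) and peaks at the maximal
  # displacement event. Pre-sharpening preserves atom areas.
  net <- attr(ij, "area") + s * (wf$y$spv[1] * wf$y$spv[2] +
                                   wf$y$dpv[1] * wf$y$dpv[2] +
                                   wf$y$interdip[1] * wf$y$interdip[2] +
                                   wf$y$plateau[1] * wf$y$plateau[2] +
                                   wf$y$ao_spike[1] * wf$y$ao_spike[2]) * sqrt(2 * pi)
  rec_amp <- -net / (wf$recoil_sd * sqrt(2 * pi))
  y <- as.numeric(ij) + atom(wf$y$spv, ev$spv + wf$spv_shift) +
    atom(wf$y$ao_spike, ev$ao) + atom(wf$y$dpv, ev$dpv) +
    atom(wf$y$interdip, (ev$ao + ev$spv) / 2) +
    atom(wf$y$plateau, t_plat) +
    rec_amp * gauss(tt, ev$dpv + wf$recoil_lag, wf$recoil_sd) +
    # the slow displacement wave is already in-band and antisymmetric, so
    # it is not pre-sharpened: its integral peaks exactly at the event
    gauss_deriv(tt, ev$maxdisp, wf$disp[2], s * wf$disp[1])
  x <- atom(wf$x$sys1, 0.005) + atom(wf$x$sys2, 0.032) +
    atom(wf$x$sys3, 0.060) +
    s * ricker_wedge(tt, ev$ac, ev$mvo, wf$x$wedge_amp,
                     presharp = wf$wedge_presharpen)
  z <- atom(wf$z[[1]], ev$ao + 0.010) + atom(wf$z[[2]], ev$mvc) +
    atom(wf$z[[3]], ev$ac + 0.005) + atom(wf$z[[4]], ev$mvo + 0.010)
  acc_z <- atom0(wf$acc$ao, ev$ao) + atom0(wf$acc$ac, ev$ac) +
    atom0(wf$acc$mvc, ev$mvc)
  acc_x <- 0.35 * (atom0(wf$acc$ao, ev$ao + 0.004) +
                     atom0(wf$acc$ac, ev$ac + 0.004))
  acc_y <- 0.25 * (atom0(wf$acc$ao, ev$ao - 0.003) +
                     atom0(wf$acc$ac, ev$ac - 0.003))
  list(ecg = ecg, gyro_x = x, gyro_y = y, gyro_z = z,
       acc_x = acc_x, acc_y = acc_y, acc_z = acc_z)
}

offsets_to_events <- function(offsets) {
  d <- default_delays_ms / 1000
  get <- function(nm) unname(if (nm %in% names(offsets)) offsets[[nm]] else d[[nm]])
  list(q = get("q_r"), mvc = get("r_mvc"), ao = get("r_avo"),
       ac = get("r_avc"), mvo = get("r_mvo"), spv = get("r_spv"),
       dpv = get("r_dpv"), maxdisp = get("r_maxdisp"))
}

check_event_order <- function(ev) {
  ord <- c(-ev$q, 0, ev$mvc, ev$ao, ev$spv, ev$ac, ev$mvo, ev$dpv)
  if (any(diff(ord) < 0)) {
    abort("Parameter error: event offsets violate the cardiac event order.")
  }
}

#' Clean single-beat waveform template
#'
#' Evaluates the per-axis pulse templates for one beat on a regular grid.
#' Event offsets are seconds relative to the R peak (`q_r` is the positive
#' Q-to-R interval); unspecified events take the package's normative healthy
#' adult defaults.
#'
#' @param event_offsets Named numeric vector (seconds): any of `q_r`, `r_mvc`,
#'   `r_avo`, `r_avc`, `r_mvo`, `r_spv`, `r_dpv`, `r_maxdisp`.
#' @param fs Sampling rate in Hz.
#' @param waveform Atom definitions from [waveform_params()].
#' @param band_limited Return the waveform as seen through the acquisition
#'   band (gyro 1-20 Hz, accelerometer 4-45 Hz); this is the domain in which
#'   the fiducial extrema sit exactly on their events. `FALSE` returns the
#'   raw atom pre-images.
#' @return A tibble with `t` (seconds relative to R) and one column per
#'   channel; attribute `r_index` marks the sample at t = 0.
#' @export
beat_template <- function(event_offsets = NULL, fs = 800,
                          waveform = waveform_params(),
                          band_limited = TRUE) {
  stopifnot_scalar_pos(fs, "fs")
  ev <- offsets_to_events(event_offsets %||% numeric(0))
  check_event_order(ev)
  t_max <- max(unlist(ev)) + 0.65
  tt <- seq(-0.3, t_max, by = 1 / fs)
  ch <- template_eval(tt, ev, waveform)
  if (band_limited && waveform$amp_scale != 0) {
    for (nm in c("gyro_x", "gyro_y", "gyro_z")) {
      ch[[nm]] <- butterworth_bandpass(ch[[nm]], fs, 1, 20, 4,
                                       zero_phase = TRUE)
    }
    for (nm in c("acc_x", "acc_y", "acc_z")) {
      ch[[nm]] <- butterworth_bandpass(ch[[nm]], fs, 4, 45, 4,
                                       zero_phase = TRUE)
    }
  }
  out <- as_tibble(c(list(t = tt), ch))
  attr(out, "r_index") <- which.min(abs(tt))
  out
}

#' Per-subject simulation parameters
#'
#' Event-delay means default to normative healthy-adult systolic
#' time-interval statistics (R-to-mitral-closure 20 ms, R-to-aortic-opening
#' 49 ms, R-to-aortic-closure 359 ms, R-to-mitral-opening 427 ms, Q-to-R
#' 33 ms, and so on); beat-to-beat variability enters through the RR interval
#' and small jitter on the delay increments.
#'
#' @param mean_hr Subject mean heart rate, bpm.
#' @param hr_sd_within Beat-to-beat SD of instantaneous heart rate, bpm.
#' @param delays_ms Named vector of event-delay means in ms: `q_r`, `r_mvc`,
#'   `r_avo`, `r_avc`, `r_mvo`, `r_spv`, `r_dpv`, `r_maxdisp`.
#' @param delay_jitter_sd Beat-to-beat SD (ms) applied to the delay
#'   increments within a subject.
#' @param noise_sd Additive white-noise SD on the gyroscope channels, dps.
#'   The default places the dominant systolic peak 10 dB (amplitude ratio
#'   3.16) above the noise.
#' @param ecg_noise_sd Additive white-noise SD on the ECG channel, mV.
#' @param acc_noise_sd Additive white-noise SD on the accelerometer, g.
#' @param resp_rate Respiration rate, breaths/min.
#' @param resp_depth Multiplicative amplitude-modulation depth in [0, 1).
#' @param include_acc Simulate the three accelerometer channels as well.
#' @param waveform Atom geometry from [waveform_params()].
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return A `gcg_subject_params` list.
#' @export
subject_params <- function(mean_hr = 59, hr_sd_within = 2,
                           delays_ms = default_delays_ms,
                           delay_jitter_sd = 3,
                           noise_sd = 4.0 / 10^(10 / 20),
                           ecg_noise_sd = 0.10,
                           acc_noise_sd = 0.008,
                           resp_rate = 15, resp_depth = 0.2,
                           include_acc = TRUE,
                           waveform = waveform_params(),
                           seed = 1L) {
  d <- default_delays_ms
  d[names(delays_ms)] <- delays_ms
  if (mean_hr <= 0) abort("`mean_hr` must be positive.")
  if (noise_sd < 0 || ecg_noise_sd < 0 || acc_noise_sd < 0) {
    abort("Noise SDs must be nonnegative.")
  }
  if (resp_depth < 0 || resp_depth >= 1) abort("`resp_depth` must lie in [0, 1).")
  ev <- offsets_to_events(d / 1000)
  check_event_order(ev)
  structure(list(
    mean_hr = mean_hr, hr_sd_within = hr_sd_within, delays_ms = d,
    delay_jitter_sd = delay_jitter_sd, noise_sd = noise_sd,
    ecg_noise_sd = ecg_noise_sd, acc_noise_sd = acc_noise_sd,
    resp_rate = resp_rate, resp_depth = resp_depth,
    include_acc = include_acc, waveform = waveform, seed = as.integer(seed)
  ), class = "gcg_subject_params")
}

detrend_linear <- function(v) {
  n <- length(v)
  if (n < 3L) return(v - mean(v))
  tc <- seq_len(n) - (n + 1) / 2
  v - mean(v) - sum(tc * v) / sum(tc^2) * tc
}

# Ground-truth maximal-displacement time for one beat: argmax of the linearly
# detrended running integral of the clean y-axis over the annotation window.
truth_maxdisp <- function(y_clean, fs, r_idx, q_idx, n) {
  lo <- max(1L, r_idx - round(0.2 * fs))
  hi <- min(n, r_idx + round(0.6 * fs))
  seg <- y_clean[lo:hi]
  disp <- detrend_linear(pracma::cumtrapz(seg)[, 1] / fs)
  from <- max(q_idx - lo + 2L, 2L)
  lo + from - 2L + which.max(disp[from:length(disp)])
}

#' Simulate one subject's recording with ground truth
#'
#' Generates coupled ECG + three-axis gyroscope (+ optional accelerometer)
#' signals as a train of per-beat pulse templates with RR-interval
#' variability, within-subject event-delay jitter, multiplicative respiratory
#' amplitude modulation of the motion channels, and additive white noise.
#' Ground truth records the exact pre-noise event times of every beat.
#'
#' @param params A [subject_params()] object.
#' @param duration Recording length in seconds (>= 5).
#' @param fs Sampling rate in Hz (>= 200).
#' @return A list with `recording` (a [recording()]) and `truth` (list with
#'   `mean_hr` and a per-beat `beats` tibble of event times in seconds).
#' @export
simulate_subject <- function(params, duration = 60, fs = 800) {
  if (!inherits(params, "gcg_subject_params")) {
    abort("`params` must come from subject_params().")
  }
  if (duration < 5) abort("`duration` must be at least 5 s.")
  if (fs < 200) abort("`fs` must be at least 200 Hz.")
  with_local_seed(params$seed, simulate_subject_impl(params, duration, fs))
}

simulate_subject_impl <- function(p, duration, fs) {
  n <- round(duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  d <- p$delays_ms / 1000
  jit <- p$delay_jitter_sd / 1000

  # Beat anchors: RR = 60 / N(mean_hr, hr_sd_within), RR truncated > 300 ms.
  t_r <- numeric(0)
  cur <- 0.5
  while (cur <= duration - 0.5) {
    t_r <- c(t_r, cur)
    hr_b <- rnorm(1, p$mean_hr, p$hr_sd_within)
    rr <- max(60 / max(hr_b, 1e-3), 0.3)
    cur <- cur + rr
  }
  nb <- length(t_r)
  if (nb == 0L) abort("Duration too short to place any beat.")

  jn <- function(m) rnorm(nb, 0, jit) + m
  mvc <- pmax(jn(d[["r_mvc"]]), 0.006)
  ivct <- pmax(jn(d[["r_avo"]] - d[["r_mvc"]]), 0.006)
  lvet <- pmax(jn(d[["r_avc"]] - d[["r_avo"]]), 0.1)
  ivrt <- pmax(jn(d[["r_mvo"]] - d[["r_avc"]]), 0.02)
  ao_spv <- pmax(jn(d[["r_spv"]] - d[["r_avo"]]), 0.005)
  mvo_dpv <- pmax(jn(d[["r_dpv"]] - d[["r_mvo"]]), 0.0025)
  ao <- mvc + ivct
  ac <- ao + lvet
  mvo <- ac + ivrt
  spv <- ao + ao_spv
  dpv <- mvo + mvo_dpv
  maxd <- pmin(pmax(jn(d[["r_maxdisp"]]), spv + 0.05), dpv - 0.05)

  chans <- c("ecg", "gyro_x", "gyro_y", "gyro_z",
             if (p$include_acc) c("acc_x", "acc_y", "acc_z"))
  sig <- lapply(stats::setNames(chans, chans), function(.) numeric(n))

  for (k in seq_len(nb)) {
    ev <- list(q = d[["q_r"]], mvc = mvc[k], ao = ao[k], ac = ac[k],
               mvo = mvo[k], spv = spv[k], dpv = dpv[k], maxdisp = maxd[k])
    i1 <- max(1L, floor((t_r[k] - 0.30) * fs) + 1L)
    i2 <- min(n, ceiling((t_r[k] + 1.20) * fs) + 1L)
    tt <- tgrid[i1:i2] - t_r[k]
    tmpl <- template_eval(tt, ev, p$waveform)
    for (nm in chans) sig[[nm]][i1:i2] <- sig[[nm]][i1:i2] + tmpl[[nm]]
  }

  # Exact per-beat event times: nominal event offsets refined to the actual
  # extrema of the clean (pre-noise, pre-modulation) waveform in the 1-20 Hz
  # acquisition band, the domain in which the fiducial morphology is
  # defined. Thanks to the placement calibration these coincide with the
  # nominal offsets to within a sample.
  q_idx <- pmax(1L, round((t_r - d[["q_r"]]) * fs) + 1L)
  r_idx <- round(t_r * fs) + 1L
  y_bl <- butterworth_bandpass(sig$gyro_y, fs, 1, 20, 4, zero_phase = TRUE)
  x_bl <- butterworth_bandpass(sig$gyro_x, fs, 1, 20, 4, zero_phase = TRUE)
  # SPV is a broad lobe: its time is defined on the 50 ms-smoothed signal
  bl <- list(gyro_y = y_bl, gyro_x = x_bl,
             gyro_y_smooth = moving_average(y_bl, round(0.05 * fs)))
  refine <- function(ch, t_nom, type, half_ms = 10) {
    h <- round(half_ms / 1000 * fs)
    vapply(t_nom, function(tn) {
      i0 <- round(tn * fs) + 1L
      lo <- max(1L, i0 - h); hi <- min(n, i0 + h)
      seg <- if (type == "max") bl[[ch]][lo:hi] else -bl[[ch]][lo:hi]
      (lo + which.max(seg) - 2L) / fs
    }, numeric(1))
  }
  t_mvc <- refine("gyro_y", t_r + mvc, "min")
  t_ao <- refine("gyro_y", t_r + ao, "max")
  t_spv <- refine("gyro_y_smooth", t_r + spv, "max", 15)
  t_ac <- refine("gyro_x", t_r + ac, "min")
  t_mvo <- refine("gyro_x", t_r + mvo, "min")
  t_dpv <- refine("gyro_y", t_r + dpv, "min")
  t_dpv <- pmax(t_dpv, t_mvo)
  t_maxdisp <- vapply(seq_len(nb), function(k) {
    idx <- truth_maxdisp(y_bl, fs, r_idx[k], q_idx[k], n)
    (idx - 1) / fs
  }, numeric(1))

  truth <- list(
    mean_hr = if (nb > 1) mean(60 / diff(t_r)) else NA_real_,
    beats = tibble(
      beat = seq_len(nb),
      t_q = t_r - d[["q_r"]], t_r = t_r, t_mvc = t_mvc,
      t_ao = t_ao, t_ac = t_ac, t_mvo = t_mvo,
      t_spv = t_spv, t_dpv = t_dpv, t_max_disp = t_maxdisp
    )
  )

  # Respiratory amplitude modulation on motion channels, then white noise.
  resp <- 1 + p$resp_depth * sin(2 * pi * p$resp_rate / 60 * tgrid)
  for (nm in setdiff(chans, "ecg")) sig[[nm]] <- sig[[nm]] * resp
  if (p$noise_sd > 0) {
    for (nm in c("gyro_x", "gyro_y", "gyro_z")) {
      sig[[nm]] <- sig[[nm]] + rnorm(n, 0, p$noise_sd)
    }
  }
  if (p$ecg_noise_sd > 0) sig$ecg <- sig$ecg + rnorm(n, 0, p$ecg_noise_sd)
  if (p$include_acc && p$acc_noise_sd > 0) {
    for (nm in c("acc_x", "acc_y", "acc_z")) {
      sig[[nm]] <- sig[[nm]] + rnorm(n, 0, p$acc_noise_sd)
    }
  }

  rec <- recording(ecg = sig$ecg, gyro_x = sig$gyro_x, gyro_y = sig$gyro_y,
                   gyro_z = sig$gyro_z,
                   acc_x = sig$acc_x, acc_y = sig$acc_y, acc_z = sig$acc_z,
                   fs = fs)
  list(recording = rec, truth = truth)
}

#' Cohort-level simulation parameters
#'
#' Subject-level delay means are drawn as ordered physiological increments
#' (R-to-MVC, then IVCT, LVET, IVRT, the AO-to-SPV and MVO-to-DPV gaps), each
#' with its own population mean and SD, so that every subject satisfies the
#' cardiac event order while the marginal means match the configured values.
#'
#' @param n_subjects Number of subjects (>= 1); default 9.
#' @param population Tibble with columns `param`, `mean`, `sd` overriding any
#'   of: `hr`, `q_r`, `r_avo`, `ivct`, `lvet`, `ivrt`, `ao_spv`, `mvo_dpv`,
#'   `r_maxdisp` (ms except `hr` in bpm).
#' @param duration Per-subject recording length, s.
#' @param fs Sampling rate, Hz.
#' @param noise_sd,resp_depth Passed to every subject's [subject_params()].
#' @param seed Cohort seed; per-subject seeds derive deterministically from it.
#' @return A `gcg_cohort_params` list.
#' @export
cohort_params <- function(n_subjects = 9, population = NULL,
                          duration = 60, fs = 800,
                          noise_sd = 4.0 / 10^(10 / 20),
                          resp_depth = 0.2, seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  pop <- default_population()
  if (!is.null(population)) {
    for (i in seq_len(nrow(population))) {
      j <- match(population$param[i], pop$param)
      if (is.na(j)) abort(paste0("Unknown population parameter: ",
                                 population$param[i]))
      pop$mean[j] <- population$mean[i]
      pop$sd[j] <- population$sd[i]
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), population = pop,
                 duration = duration, fs = fs, noise_sd = noise_sd,
                 resp_depth = resp_depth, seed = as.integer(seed)),
            class = "gcg_cohort_params")
}

# Population (mean, sd) of the subject-level means, with physiological
# floors. R-to-AO is drawn directly (so the pre-ejection period inherits its
# reported spread); R-to-MVC follows as r_avo - ivct. ao_spv sd is chosen so
# the marginal R-to-SPV SD is 20 ms given the 10 ms R-to-AO SD; mvo_dpv is a
# small ordered gap placing DPV 7 ms after MVO.
default_population <- function() {
  tibble(
    param = c("hr", "q_r", "r_avo", "ivct", "lvet", "ivrt",
              "ao_spv", "mvo_dpv", "r_maxdisp"),
    mean = c(59, 33, 49, 29, 310, 68, 52, 7, 338),
    sd = c(12, 0, 10, 12, 26, 14, 17.3, 2.5, 31.9),
    lower = c(35, 20, 28, 10, 200, 25, 15, 2, 150),
    upper = c(150, 60, 85, 80, 450, 130, 130, 20, 520)
  )
}

#' Draw subject-level parameters for a cohort
#'
#' @param cohort A [cohort_params()] object.
#' @param n Number of subjects to draw (defaults to `cohort$n_subjects`).
#' @return Tibble, one row per subject, with the drawn HR and delay means
#'   (ms) plus the derived per-event delays.
#' @export
sample_subject_params <- function(cohort, n = NULL) {
  if (!inherits(cohort, "gcg_cohort_params")) {
    abort("`cohort` must come from cohort_params().")
  }
  n <- n %||% cohort$n_subjects
  pop <- cohort$population
  with_local_seed(cohort$seed, {
    draw <- function(par) {
      i <- match(par, pop$param)
      rnorm_trunc(n, pop$mean[i], pop$sd[i], pop$lower[i], pop$upper[i])
    }
    hr <- draw("hr"); q_r <- draw("q_r"); r_avo <- draw("r_avo")
    ivct <- draw("ivct"); lvet <- draw("lvet"); ivrt <- draw("ivrt")
    ao_spv <- draw("ao_spv"); mvo_dpv <- draw("mvo_dpv")
    r_maxdisp <- draw("r_maxdisp")
    ivct <- pmin(ivct, r_avo - 6)      # mitral closure stays after R
    r_mvc <- r_avo - ivct
    r_avc <- r_avo + lvet
    r_mvo <- r_avc + ivrt
    r_spv <- r_avo + ao_spv
    r_dpv <- r_mvo + mvo_dpv
    r_maxdisp <- pmin(pmax(r_maxdisp, r_spv + 50), r_dpv - 50)
    tibble(subject = seq_len(n), mean_hr = hr, q_r = q_r, r_mvc = r_mvc,
           r_avo = r_avo, r_avc = r_avc, r_mvo = r_mvo, r_spv = r_spv,
           r_dpv = r_dpv, r_maxdisp = r_maxdisp,
           seed = vapply(seq_len(n), function(i) child_seed(cohort$seed, i),
                         integer(1)))
  })
}

#' Simulate a cohort of subjects
#'
#' @param cohort A [cohort_params()] object.
#' @return A list of per-subject results, each a list with `recording`,
#'   `truth` and `params`; the drawn subject table is attached as attribute
#'   `subjects`.
#' @export
simulate_cohort <- function(cohort) {
  subjects <- sample_subject_params(cohort)
  out <- purrr::map(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    sp <- subject_params(
      mean_hr = s$mean_hr,
      delays_ms = c(q_r = s$q_r, r_mvc = s$r_mvc, r_avo = s$r_avo,
                    r_avc = s$r_avc, r_mvo = s$r_mvo, r_spv = s$r_spv,
                    r_dpv = s$r_dpv, r_maxdisp = s$r_maxdisp),
      noise_sd = cohort$noise_sd, resp_depth = cohort$resp_depth,
      seed = s$seed)
    c(simulate_subject(sp, duration = cohort$duration, fs = cohort$fs),
      list(params = sp))
  })
  attr(out, "subjects") <- subjects
  out
}
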