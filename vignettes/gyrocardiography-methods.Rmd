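---
title: "Methods: simulating and annotating gyrocardiography signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and annotating gyrocardiography signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyrocardio)
```

## The measurement model

Gyrocardiography measures chest angular velocity in degrees per second on
three axes (x: left→right, y: head→foot, z: back→front). During each
cardiac cycle the y-axis shows a sharp downward notch at mitral valve
closure (g_I) followed by the dominant upward peak at aortic valve opening
(g_J), a broad systolic peak-velocity lobe (SPV), and a V-shaped diastolic
dip (DPV). The x-axis shows a lower-amplitude up–down wedge around the
second heart sound whose two flanking notches mark aortic closure (g_K)
and mitral opening (g_L). With the ECG Q and R waves as electrical
references, the package computes per beat:
R-to-event times for the four valve events, IVCT = g_J − g_I,
LVET = g_K − g_J, IVRT = g_L − g_K, PEP = g_J − Q, QS2 = PEP + LVET
(exact by construction), the Q-to-SPV/DPV delays, and the Q-to-maximum of
the integrated y-axis (angular displacement). All indices are 1-based
sample positions; times are seconds internally and milliseconds in every
report.

How the heart's rotation transfers to the chest surface is not mechanistic
knowledge we rely on anywhere: the simulator below is phenomenological by
design, and the annotator only assumes the morphological conventions
above.

## The synthetic-data generator

`simulate_subject()` builds each beat from analytic pulse atoms placed at
the beat's event times:

* the g_I→g_J complex is a single asymmetric dip–peak wavelet
  `α (z + r) exp(−z²/2)`; its two stationary points (the roots of
  `z² + r z − 1`) are solved in closed form so dip and peak sit exactly on
  MVC and AO with the configured amplitudes (defaults −1.5 and +4 dps);
* the g_K/wedge/g_L complex on the x-axis is an inverted Ricker wavelet,
  whose side minima fall exactly at aortic closure and mitral opening;
* SPV (default 4 dps, σ 26 ms), an inter-lobe dip between g_J and SPV,
  DPV (−1.6 dps, σ 12 ms) and a narrow AO spike are Gaussian atoms;
* a slow Gaussian-derivative wave adds the late-systolic angular
  displacement: its running integral peaks exactly at the configured
  maximal-displacement time (default R + 338 ms, i.e. Q + 371 ms);
* a sustained low-velocity plateau lobe keeps the displacement rising
  until end-systole, and a broad diastolic recoil lobe cancels the net
  area of all y-axis atoms, so each cycle returns the chest to its
  baseline orientation (zero net rotation per beat);
* the ECG is a Q/R/S/T Gaussian train (R dominant, T centred 45 ms before
  aortic closure), and optional accelerometer channels carry small
  AO/AC-locked pulses.

Beat anchors follow RR = 60/N(HR, hr_sd_within) with RR truncated above
300 ms; event delays jitter beat-to-beat on their physiological increments
(3 ms SD by default) so the event order can never invert; respiration
multiplies the motion channels by `1 + depth·sin(2π·rate/60·t)` (depth
0.2, 15 breaths/min); white Gaussian noise is added last. The default
noise SD places the systolic peak 10 dB above the noise floor in
amplitude. Everything is deterministic given the seed.

### The acquisition band defines the waveform

The acquisition chain band-limits the gyroscope to 1–20 Hz, and the
fiducial morphology (where "the" dip or notch lies) is only meaningful in
that band: a 29 ms dip-to-peak transition is a ~17 Hz structure, so naive
sharp atoms would move by several samples once filtered. The generator
therefore evaluates every gyroscope atom as the analytic *pre-image* of
its designed shape under an equivalent-Gaussian kernel of the low-pass
(all atom families used are closed under Gaussian convolution); the kernel
SDs (12–13 ms) and one wavelet amplitude factor are fixed calibration
constants of the geometry. Ground truth is then defined as the extrema of
the *band-limited* noise-free waveform, refined numerically per beat —
exact by construction, and coincident with the configured event times to
within a sample. One consequence worth knowing: subjects drawn with
IVCT below ~25 ms are physically unresolvable in a 1–20 Hz band, so the
recovered cohort IVCT runs a few milliseconds above the configured mean —
the same compression a band-limited instrument shows against an
echocardiographic reference.

### Cohort draws

`simulate_cohort()` draws subject-level means as ordered physiological
increments: heart rate (59 ± 12 bpm), Q→R fixed at 33 ms, R→AO directly
from its reported distribution (49 ± 10 ms) so that PEP inherits the
reported spread, then IVCT (29 ± 12), LVET (310 ± 26), IVRT (68 ± 14), the
AO→SPV gap (52 ± 17.3, giving R→SPV a 20 ms marginal SD) and the MVO→DPV
gap (7 ± 2.5), with truncation at physiological floors. Drawing the
R-to-event times independently at their printed SDs would invert the event
order for roughly half the subjects (e.g. DPV before MVO); the increment
construction preserves the marginal means exactly while guaranteeing the
order. Per-subject seeds derive deterministically from the cohort seed.

### What the generator does not emulate

Pathological morphologies (arrhythmia, valvular disease), motion
artefacts, sensor drift and axis cross-talk, inter-subject waveform-shape
variability (only timings, amplitudes and rates vary), and any
biomechanical chest-transfer model. Passing tests on these simulations
therefore demonstrate that the pipeline recovers what it is designed to
recover under the stated signal model — not that it is robust to every
failure mode of real chest recordings.

## Preprocessing

Gyroscope channels get a 1–20 Hz Butterworth band-pass of prototype order
4 (−3 dB at the edges per causal pass), accelerometer channels 4–45 Hz,
the ECG a 0.5–45 Hz FFT filter with raised-cosine transitions of 10%
relative width. The Butterworth is implemented as cascaded second-order
sections — the single 8-pole transfer function is numerically
ill-conditioned at these narrow normalised bands — and applied
forward–backward by default: millisecond-level timing is incompatible
with uncorrected IIR group delay, and zero-phase filtering provably keeps
the extremum of any symmetric pulse in place. A causal mode remains
available (`zero_phase = FALSE`). Signals are reflect-padded by 1 s before
filtering and trimmed after.

## Detection and annotation

*ECG.* R peaks are local maxima of a 120 ms-smoothed squared-derivative
envelope above 0.4× a rolling 95th-percentile level (2 s window), with a
250 ms refractory period and refinement to the ECG maximum within ±40 ms.
The Q trough is the deepest sufficiently prominent local minimum within
50 ms before R (fallback: a fixed 33 ms offset when the window is
monotone); the T peak is the maximum in R + [150, 450] ms.

*GCG beats.* The y-axis Hilbert envelope (analytic-signal magnitude,
100 ms moving average) is thresholded at 0.5× a rolling 95th-percentile
level over 3 s; peaks obey a 400 ms refractory period (capping detectable
heart rate at 150 bpm and rejecting late-diastolic waves), are refined to
the y-axis maximum within ±60 ms (the g_J candidate), and finally pass an
amplitude-consistency gate at 0.55× the median anchor amplitude. All of
these constants live in `beat_config()`.

*Fiducials.* Search windows are centred on normative timings and about
±3 population SDs wide (`annotation_config()`). g_J is the *earliest*
local maximum reaching 35% of the window maximum — the aortic-opening
peak comes first even when the later SPV lobe rivals it in amplitude, so a
blind argmax would jump windows; g_I is the last prominent local minimum
before g_J; SPV is the argmax of the 50 ms-smoothed y-axis after g_J (the
wave is broad, not a sharp peak); the wedge peak is searched ±120 ms
around the T peak (fallback R + 360 ms), with g_K/g_L the prominent minima
immediately before and after it; DPV is the y-minimum within 120 ms after
g_L. Local minima must clear a prominence of 15% of the local span, which
rejects noise dimples. Everywhere in the package ties resolve to the
earliest sample, and an extremum that lands on a window boundary is
reported absent rather than trusted.

*Angular displacement.* The y-axis is integrated by cumulative trapezoids
and linearly detrended per beat before taking the argmax after Q — raw
integration of a band-passed signal drifts, and detrending makes the
maximum well defined. A perfectly flat detrended segment has no defined
maximum and is reported absent.

## Intervals and summaries

`compute_intervals()` converts matched fiducials to milliseconds;
composite intervals are built so the identities
`qs2 = pep + lvet` and `ivct + lvet + ivrt = r_mvo − r_mvc` hold exactly,
and any interval with a missing endpoint is absent rather than guessed.
The QS2 endpoint is g_K interpreted as aortic closure — the standard
electromechanical-systole definition; an alternative literal endpoint is
selectable via `qs2_endpoint`. Cohort summaries are two-stage (subject
means first, then mean and sample SD across subjects), matching how
small-cohort physiology is reported.

## Agreement statistics

`pearson_r2()`, `rmse()` and `bland_altman()` implement the paired-method
statistics: bias = mean difference, 95% limits of agreement =
bias ± 1.96·SD, reproducibility coefficient = 1.96·SD, and coefficient of
variation = 100·SD over the overall mean of both methods' observations.
Sample (n−1) SDs are used throughout — appropriate at cohort sizes of
nine. Zero-variance inputs yield an absent r²; a zero overall mean yields
an absent CV.

## Problem sizes and tolerances

The validation suite runs a 9-subject cohort of 60 s recordings at 800 Hz
(the full end-to-end recovery), a 220 s single subject for the noisy
fiducial-accuracy checks (≥200 beats), and seconds-scale property tests
elsewhere; cohort means are required to land within three standard errors
of the generator's between-subject distribution, noise-free fiducials
within one sample of truth (two for the displacement maximum), and the
statistics agree with independent brute-force formulas to 1e-9.

## Known limitations

The simulator's shape parameters are fixed per cohort, so waveform-shape
variability between subjects is understated; the displacement wave and
plateau lobes are a minimal construction that produces a single
well-defined displacement maximum, not a fitted myocardial strain curve;
SPV timing carries a few milliseconds of definition-dependent offset
because a broad lobe's "time" depends on the smoothing convention; and
agreement statistics assume independent beats (no repeated-measures
correction of the limits of agreement).
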