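# gyrocardio

Gyrocardiography (GCG) records the angular velocity of the chest wall with
a MEMS gyroscope taped to the sternum. Because the heart's contraction
twists the thorax, the three rotation axes (x: left→right, y: head→foot,
z: back→front) carry repeatable waveforms whose extrema coincide with
mechanical cardiac events: on the y-axis a sharp dip (g_I, mitral valve
closure) followed by the dominant systolic peak (g_J, aortic valve
opening), and on the x-axis an up–down wedge around the second heart sound
whose flanking notches (g_K, g_L) mark aortic closure and mitral opening.
From these fiducials, together with the ECG Q and R waves, the classic
systolic time intervals follow:

- PEP = t(g_J) − t(Q) (pre-ejection period)
- LVET = t(g_K) − t(g_J) (left-ventricular ejection time)
- QS2 = PEP + LVET (total electromechanical systole)
- IVCT = t(g_J) − t(g_I), IVRT = t(g_L) − t(g_K)

The y-axis also shows broad systolic and diastolic peak-velocity waves
(SPV, DPV), and the running integral of the y-axis — the *angular
displacement* — peaks at end-systole, an analogue of the time to maximal
myocardial strain.

`gyrocardio` is a toolkit for this analysis chain, written for signal-
processing researchers working on wearable cardiac monitoring:

* a **simulator** of coupled ECG + 3-axis gyroscope (+ accelerometer)
  recordings with exact per-beat ground truth, parameterised by normative
  healthy-adult interval statistics (HR 59 ± 12 bpm, PEP 82 ± 10 ms,
  LVET 310 ± 26 ms, …);
* **preprocessing** that mirrors a typical acquisition chain (1–20 Hz
  zero-phase Butterworth on the gyroscope, 4–45 Hz on the accelerometer,
  0.5–45 Hz FFT band-pass on the ECG);
* **beat detection** on the gyroscope y-axis alone via a smoothed Hilbert
  envelope with an adaptive threshold — no ECG needed for heart rate;
* **fiducial annotation** (g_I, g_J, g_K, g_L, SPV, DPV, maximal angular
  displacement) and per-beat **interval computation**;
* **agreement statistics** against a reference method: Pearson r², RMSE,
  and Bland–Altman bias, 95% limits of agreement, reproducibility
  coefficient and coefficient of variation, with `tidy()`/`glance()`/
  `autoplot()` methods.

Everything takes and returns tibbles, so pipelines compose with the pipe.

## Worked example

Simulate one subject, run the pipeline, and compare against the
simulator's ground truth:

```r
library(gyrocardio)
library(dplyr)

sim <- simulate_subject(subject_params(seed = 1), duration = 60, fs = 800)
res <- process_recording(sim$recording)

res$intervals |> select(beat, pep, lvet, qs2, ivct, ivrt, hr) |> head(4)
#>    beat   pep  lvet   qs2  ivct  ivrt    hr
#> 1     1  82.5  315   398.  33.8  70    NA
#> 2     2  87.5  314.  401.  30    65    57.7
#> 3     3  80    315   395   33.8  66.2  59.4
#> 4     4  87.5  304.  391.  32.5  70    57.3

ref <- truth_intervals(sim$truth)
agreement_report(ref, res$intervals, vars = c("pep", "lvet", "qs2")) |>
  select(metric, n, r2, rmse, bias, loa_low, loa_high)
#>   metric     n    r2  rmse   bias loa_low loa_high
#> 1 pep       59 0.780  1.93  0.515   -3.16     4.19
#> 2 lvet      59 0.811  1.75 -0.381   -3.76     3.00
#> 3 qs2       59 0.850  2.14  0.133   -4.08     4.35
```

Each row of `res$intervals` is one heartbeat; `pep = 82.5` means the
estimated pre-ejection period of that beat is 82.5 ms. The agreement table
says the pipeline recovers per-beat PEP with an RMSE of about 2 ms and a
bias of half a millisecond against ground truth, with 95% of beat-level
differences inside roughly ±4 ms.

A cohort goes the same way:

```r
coh <- simulate_cohort(cohort_params(n_subjects = 9, seed = 1))
iv  <- process_cohort(coh)
summarize_cohort(iv)   # two-stage mean ± SD across subjects
```

A thin command-line front end over the same functions lives at
`inst/cli/gcg.R` (`simulate`, `preprocess`, `detect`, `annotate`,
`intervals`, `agreement`).

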