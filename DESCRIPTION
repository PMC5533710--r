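Package: gyrocardio
Title: Gyrocardiography Signal Processing and Cardiac Time Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Processing of chest-worn inertial (gyrocardiography, GCG) and
    ECG recordings into per-beat cardiac fiducial points and systolic time
    intervals. Includes a phenomenological simulator of coupled ECG and
    six-axis chest-motion signals with exact per-beat ground truth,
    channel-specific band-pass preprocessing, Hilbert-envelope heartbeat
    detection, annotation of the GCG fiducial points (g_I, g_J, g_K, g_L,
    systolic and diastolic peak velocity, maximal angular displacement),
    computation of PEP, LVET, QS2, IVCT and IVRT, and paired-method
    agreement statistics (Pearson r squared, RMSE, Bland-Altman limits of
    agreement).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
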