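Package: attenscan
Title: Attention-Modulated Scanning Access from a Single-Channel EEG Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing attention-based computer access with a
    single-channel (Fp1) consumer EEG headset: synthetic session generation
    emulating an alternating attention/non-attention trial protocol,
    Savitzky-Golay residual screening of raw 512 Hz epochs for blink, EMG
    and motion artifacts, trial-level attentional metrics (successful score,
    initial and sustained times), per-subject Wilcoxon rank-sum band
    statistics, linear discriminant classification of attentional state with
    stratified k-fold cross-validation, and estimation of the optimal dwell
    time, scanning period and Wolpaw information transfer rate for a
    scanning communication board.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
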