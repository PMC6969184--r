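Package: upcallr
Title: Deep-Network Detection of Right Whale Upcalls in Passive Acoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting North Atlantic right whale
    upcalls in low-frequency passive acoustic recordings with small deep
    neural networks. Audio streams and Raven-style selection tables are read
    and written in standard formats; 2 s clips are converted to normalized
    40x40 spectrogram patches; labeled training sets are built from analyst
    annotations with random negatives, waveform-shift augmentation and
    hard-negative mining; a LeNet-style convolutional network and a
    Conv1D+GRU recurrent network are trained with class-weighted
    cross-entropy and Adam; continuous audio is scored with a 2 s sliding
    window advanced every 0.1 s followed by non-maximum suppression; and
    detections are evaluated with precision-recall curves, average
    precision, false positives per hour and analyst-workload estimates.
    A seeded synthetic-soundscape generator (upsweeping tonal calls plus
    upsweep-like confounders in colored band-limited noise at controlled
    SNR) makes every stage testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
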