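Package: fpcgbench
Title: Synthetic Fetal Phonocardiography Denoising and Heart-Sound
    Detection Benchmark
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates annotated synthetic fetal phonocardiogram (fPCG)
    recordings with controlled interference (maternal heart sounds,
    movement artifacts, white Gaussian noise and high-pass-filtered
    ambient noise) mixed at exact target signal-to-noise ratios, denoises
    them with eight single-channel algorithms (Savitzky-Golay, FIR
    band-pass, adaptive and maximal-overlap wavelet thresholding,
    variational mode decomposition and the EMD/EEMD/CEEMDAN family),
    detects and labels fetal S1/S2 heart sounds with a Hilbert-envelope
    threshold procedure, and scores filtering quality by detection
    accuracy, SNR improvement and heart-interval error, including a
    nonparametric statistical comparison of the algorithms
    (Kruskal-Wallis, Dunn post hoc with Benjamini-Hochberg adjustment,
    Wilcoxon signed-rank on accuracy ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
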