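# fpcgbench

Fetal phonocardiography (fPCG) — listening to fetal heart sounds through a
sensor on the maternal abdomen — is a cheap, passive alternative to Doppler
ultrasound for monitoring fetal heart activity. The recorded signal,
however, is buried under maternal heart sounds, movement artifacts,
broadband sensor noise and ambient sound, so the practical question is
which single-channel denoising algorithm best recovers the fetal S1 and S2
sounds. `fpcgbench` implements a complete, reproducible benchmarking study
of eight such algorithms on synthetic recordings with known ground truth.

The package is aimed at biomedical-signal-processing researchers who want
to compare fPCG filtering methods under controlled, regenerable conditions
rather than on unshareable clinical recordings.

## What is inside

* **Synthetic data** — fetal heart-sound trains built from
  Gaussian-modulated sinusoids $s(t) = A\,e^{-(t-t_0)^2/2\sigma^2}
  \sin 2\pi f (t-t_0)$ (140 bpm, S1/S2 amplitude ratio 1.7, carriers
  36.89 / 55.18 Hz, 140 ms S1–S2 spacing), maternal heart sounds (70 bpm,
  ratio 1.54, 16.93 / 30.44 Hz, 331 ms), movement-artifact pulses
  (0.5–1.5 s, band-limited), white Gaussian noise, and Butterworth
  high-passed ambient noise — mixed at an exact target SNR
  $\mathrm{SNR} = 10\log_{10}\big(\sum m_\mathrm{ref}^2 /
  \sum (m_\mathrm{in}-m_\mathrm{ref})^2\big)$.
* **Filter bank** — Savitzky–Golay, FIR band-pass (20–110 Hz), adaptive
  wavelet thresholding, MODWT thresholding, VMD, EMD, EEMD and CEEMDAN,
  behind one `filter_config()` / `apply_filter()` interface. The wavelet
  and mode decompositions are implemented in the package.
* **Detection** — Hilbert-envelope S1/S2 detector: low-pass smoothing,
  threshold at 0.4 × envelope maximum, 100 ms minimum-interval
  deduplication, restoration of sub-threshold sounds, and
  systole/diastole-based labelling.
* **Evaluation** — detection accuracy
  $\mathrm{ACC} = 100\,\mathrm{TP}/(\mathrm{TP+FP+FN})$ with ±50 ms
  matching, SNR improvement ($\mathrm{SNR_{out}} - \mathrm{SNR_{in}}$),
  and the mean absolute S1–S1 interval error $\overline{|\Delta T_i|}$.
* **Benchmark** — 2 records × 15 interference scenarios × 8 algorithms,
  with the per-scenario reference settings built in and an
  ACC-maximizing grid search.
* **Statistics** — median/IQR descriptives, Shapiro–Wilk gate,
  Kruskal–Wallis, Dunn post hoc with Benjamini–Hochberg adjustment,
  homogeneous subgroups, and Wilcoxon signed-rank tests on low/high-noise
  accuracy ratios.

## Worked example

```r
library(fpcgbench)

ref   <- generate_fetal_pcg(duration_s = 60, fs = 1000, seed = 1)
noise <- generate_gaussian_noise(60, fs = 1000, seed = 11)
noisy <- mix_at_snr(ref, list(noise), target_snr_db = -1.20)

cfg  <- filter_config("CEEMDAN", N = 10, Nstd = 0.4, imf_selection = c(2, 3))
filt <- apply_filter(noisy$samples, cfg, fs = 1000)
det  <- detect_heart_sounds(filt, fs = 1000)
evaluate_cell(ref, noisy$samples, filt, det)
#> <fpcg_evaluation> ACC S1 100.00%, ACC S2 100.00%, SNR in -1.20 dB,
#>   out 5.32 dB (improvement 6.52 dB), interval error 2.09 ms
```

The printed report says: every S1 and S2 sound was recovered within
±50 ms (ACC 100%), the filter raised the SNR by about 6.5 dB relative to
the clean reference, and the beat-to-beat S1 interval — the quantity
behind fetal-heart-rate estimation — is reproduced to within about 2 ms.

A full benchmark table and its statistical comparison:

```r
bench <- run_benchmark(build_scenarios(), duration_s = 60)
stats_report(bench, "acc_s1")
```

A thin command-line wrapper is included at `inst/cli/fpcg`
(`fpcg simulate`, `filter`, `detect`, `evaluate`, `benchmark`, `stats`).

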