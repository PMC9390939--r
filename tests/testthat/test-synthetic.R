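test_that("fetal generator produces the expected beat structure", {
  ref <- ref20()
  s1 <- ref$events[ref$events$label == "S1", ]
  s2 <- ref$events[ref$events$label == "S2", ]
  # floor(duration * rate / 60) beats
  expect_equal(nrow(s1), floor(20 * 140 / 60))
  # consecutive S1 onsets exactly one beat period apart
  expect_equal(diff(s1$time_s), rep(60 / 140, nrow(s1) - 1), tolerance = 1e-12)
  # S2 follows its S1 by exactly 140 ms
  expect_equal(s2$time_s - s1$time_s[seq_len(nrow(s2))],
               rep(0.140, nrow(s2)), tolerance = 1e-12)
  # labels alternate S1, S2, S1, ...
  expect_true(all(ref$events$label == rep(c("S1", "S2"),
                                          length.out = nrow(ref$events))))
  expect_length(ref$samples, 20000)
})

test_that("empty and invalid generator inputs are handled", {
  empty <- generate_fetal_pcg(duration_s = 0)
  expect_length(empty$samples, 0)
  expect_equal(nrow(empty$events), 0)
  expect_error(generate_fetal_pcg(fs = 100), "carrier")
  expect_error(heart_sound_params(140, 500, 1.7, 36.89, 55.18),
               "beat period")
})

test_that("heart sounds are Gaussian-modulated sinusoids at their carriers", {
  ref <- ref20()
  s1 <- ref$events$time_s[ref$events$label == "S1"]
  s2 <- ref$events$time_s[ref$events$label == "S2"]
  # the analytic spectrum of a Gaussian-modulated sinusoid is centered on
  # its carrier: an excised sound's periodogram peak recovers the carrier
  idx <- function(t) round(t * 1000) + 1
  seg1 <- ref$samples[idx(s1[4] - 0.1):idx(s1[4] + 0.1)]
  expect_lt(abs(spectral_peak_hz(seg1, 1000) - 36.89), 0.25)
  seg2 <- ref$samples[idx(s2[4] - 0.1):idx(s2[4] + 0.1)]
  expect_lt(abs(spectral_peak_hz(seg2, 1000) - 55.18), 0.25)
  # envelope peak ratio at annotations equals the configured S1/S2 ratio
  env <- compute_envelope(ref$samples)
  expect_equal(median(env[idx(s1)]) / median(env[idx(s2)]), 1.7,
               tolerance = 0.01)
  # envelope matches the generating Gaussian peak; the carriers sit only
  # ~2.3 periods inside the pulse sigma, so the analytic-signal magnitude
  # carries a small negative bias -- allow 3%
  expect_equal(median(env[idx(s1)]), 1, tolerance = 0.03)
})

test_that("maternal generator matches its parameter set and band", {
  m <- maternal60()
  s1 <- m$events[m$events$label == "S1", ]
  s2 <- m$events[m$events$label == "S2", ]
  expect_equal(nrow(s1), floor(60 * 70 / 60))
  expect_equal(s2$time_s - s1$time_s[seq_len(nrow(s2))],
               rep(0.331, nrow(s2)), tolerance = 1e-12)
  # >95% of power in the 10-40 Hz maternal band (periodogram integration)
  p <- Mod(fft(m$samples))^2
  f <- (seq_along(p) - 1) / 60
  half <- f <= 500
  expect_gt(sum(p[half & f >= 10 & f <= 40]) / sum(p[half]), 0.95)
})

test_that("movement artifacts are seeded, non-overlapping, band-limited pulses", {
  spec <- movement_spec(pulse_rate_hz = 0.3)
  a <- generate_movement_artifacts(spec, 40, 1000, seed = 5)
  b <- generate_movement_artifacts(spec, 40, 1000, seed = 5)
  expect_identical(a$samples, b$samples)
  p <- a$params$pulses
  expect_true(all(p$duration_s >= 0.5 & p$duration_s <= 1.5))
  starts <- p$center_s - p$duration_s / 2
  ends <- p$center_s + p$duration_s / 2
  expect_true(all(starts[-1] >= ends[-nrow(p)]))
  # maternal-type pulses are band-limited to 0-100 Hz: less than 1% of
  # power above 110 Hz
  mt <- which(p$type == "maternal")
  if (length(mt)) {
    k <- mt[1]
    seg <- a$samples[round(starts[k] * 1000):round(ends[k] * 1000)]
    pw <- Mod(fft(seg))^2
    f <- (seq_along(pw) - 1) / (length(seg) / 1000)
    half <- f <= 500
    expect_lt(sum(pw[half & f > 110]) / sum(pw[half]), 0.01)
  }
  expect_error(generate_movement_artifacts(movement_spec(pulse_rate_hz = 2),
                                           10, 1000, 1),
               "overlap")
})

test_that("gaussian noise is white and seeded", {
  g <- gauss20()
  n <- length(g$samples)
  expect_lt(abs(mean(g$samples)), 3 / sqrt(n))
  # flat PSD: equal power in equal-width bands within 10%
  p1 <- band_power(g$samples, 0, 100)
  p2 <- band_power(g$samples, 100, 200)
  expect_lt(abs(p1 - p2) / p2, 0.10)
  expect_identical(generate_gaussian_noise(20, 1000, 42)$samples, g$samples)
})

test_that("ambient noise matches a causal 5th-order Butterworth high-pass", {
  a <- generate_ambient_noise(120, 1000, seed = 3)
  expect_identical(generate_ambient_noise(120, 1000, 3)$samples, a$samples)
  # measured 50 vs 200 Hz attenuation matches the analytic magnitude
  # response 10*log10((1+(50/100)^-10)/(1+(200/100)^-10)) ~= 30.07 dB
  att <- 10 * log10(band_power(a$samples, 195, 205) /
                    band_power(a$samples, 45, 55))
  expect_lt(abs(att - 30.07), 1.5)
  # -3 dB point at 100 +/- 2 Hz from the output/input PSD ratio
  set.seed(3)
  white <- rnorm(120000)
  ratio_db <- function(f) {
    10 * log10(band_power(a$samples, f - 2, f + 2) /
               band_power(white, f - 2, f + 2))
  }
  fgrid <- seq(90, 110, by = 0.5)
  r <- vapply(fgrid, ratio_db, numeric(1))
  ref_db <- 10 * log10(band_power(a$samples, 240, 260) /
                       band_power(white, 240, 260))
  f3 <- fgrid[which.min(abs(r - (ref_db - 3)))]
  expect_lt(abs(f3 - 100), 2)
})

test_that("mix_at_snr achieves the target SNR exactly and superposes", {
  ref <- ref20()
  g <- gauss20()
  for (target in c(0, -0.53, -3.56, -10.76)) {
    mixed <- mix_at_snr(ref, list(g), target)
    expect_lt(abs(mixed$params$snr_in_db - target), 1e-6)
    # annotations carried through unchanged
    expect_identical(mixed$events, ref$events)
    # mixture minus the scaled noise recovers the reference
    expect_equal(mixed$samples - mixed$params$noise_samples, ref$samples,
                 tolerance = 1e-12)
  }
  # at 0 dB the scaled noise power equals the reference power
  m0 <- mix_at_snr(ref, list(g), 0)
  expect_equal(mean(m0$params$noise_samples^2), mean(ref$samples^2),
               tolerance = 1e-9)
  # lowering the target by 20 dB scales the noise amplitude by x10
  m20 <- mix_at_snr(ref, list(g), -20)
  expect_equal(m20$params$noise_samples / m0$params$noise_samples,
               rep(10, length(ref$samples)), tolerance = 1e-9)
  expect_error(mix_at_snr(ref, list(annotated_signal(numeric(20000), 1000)),
                          0), "zero power")
})

test_that("multi-kind mixtures honor the component weights", {
  ref <- ref20()
  g1 <- gauss20()
  g2 <- generate_ambient_noise(20, 1000, seed = 9)
  mixed <- mix_at_snr(ref, list(g1, g2), -1.45, weights = c(0.5, 0.5))
  expect_lt(abs(mixed$params$snr_in_db + 1.45), 1e-6)
})
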