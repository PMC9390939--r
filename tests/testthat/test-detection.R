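test_that("envelope computation matches the analytic-signal magnitude", {
  t <- (0:1999) / 1000
  x <- 0.8 * sin(2 * pi * 50 * t)
  env <- compute_envelope(x)
  expect_true(all(env >= 0))
  expect_equal(env[200:1800], rep(0.8, 1601), tolerance = 0.01)
  # Gaussian-modulated sinusoid: envelope recovers the generating Gaussian
  sigma <- 0.01
  g <- exp(-(t - 1)^2 / (2 * sigma^2)) * sin(2 * pi * 60 * (t - 1))
  eg <- compute_envelope(g)
  expect_equal(max(eg), 1, tolerance = 0.02)
  expect_equal(which.max(eg), 1001, tolerance = 2)
})

test_that("envelope smoothing is zero-phase with unit DC gain", {
  env <- rep(1, 1000)
  sm <- smooth_envelope(env, 1000, 20)
  expect_lt(max(abs(sm - 1)), 1e-3)          # DC gain 1 (small edge error)
  expect_lt(max(abs(sm[100:900] - 1)), 1e-4) # interior essentially exact
  # 200 Hz ripple on a 20 Hz smoother attenuated by >= 40 dB
  t <- (0:4999) / 1000
  ripple <- sin(2 * pi * 200 * t)
  out <- smooth_envelope(ripple, 1000, 20)
  expect_lt(max(abs(out[1000:4000])), 10^(-40 / 20))
  expect_length(out, 5000)
  expect_error(smooth_envelope(env, 1000, 600), "cutoff")
})

test_that("thresholding keeps local maxima above the fractional threshold", {
  # two bumps: 1.0 and 0.39 of max -> only the first passes at 0.4
  t <- (0:1999) / 1000
  env <- exp(-(t - 0.5)^2 / (2 * 0.02^2)) +
    0.39 * exp(-(t - 1.5)^2 / (2 * 0.02^2))
  tr <- threshold_candidates(env, 1000)
  expect_equal(tr$times, 0.5, tolerance = 1e-3)
  # at a 0.3 threshold both survive
  tr2 <- threshold_candidates(env, 1000, threshold_frac = 0.3)
  expect_length(tr2$times, 2)
  # flat envelope: no candidates
  expect_length(threshold_candidates(rep(1, 100), 1000)$times, 0)
})

test_that("deduplication keeps the per-cluster amplitude argmax", {
  tr <- structure(list(times = c(0.50, 0.55), amplitudes = c(1.0, 0.7),
                       labels = NULL), class = "peak_train")
  out <- deduplicate_peaks(tr, 100)
  expect_equal(out$times, 0.50)
  # random trains: result equals the transitive-closure cluster argmax
  # computed independently
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    times <- sort(runif(n, 0, 2))
    amps <- runif(n)
    tr <- structure(list(times = times, amplitudes = amps, labels = NULL),
                    class = "peak_train")
    out <- deduplicate_peaks(tr, 100)
    # oracle: group by chaining the <100 ms relation, keep each group's max
    grp <- cumsum(c(TRUE, diff(times) >= 0.1))
    keep <- unlist(lapply(split(seq_len(n), grp),
                          function(ix) ix[which.max(amps[ix])]))
    expect_equal(out$times, times[sort(keep)])
    # no two retained peaks closer than the minimum interval
    if (length(out$times) > 1) expect_true(all(diff(out$times) >= 0.1))
    # idempotent
    expect_equal(deduplicate_peaks(out, 100)$times, out$times)
  }
})

test_that("restoration inserts envelope bumps only in over-long gaps", {
  fs <- 1000
  t <- (0:1999) / fs
  # peaks every 0.29 s, one missing at 1.17 -> 0.60 s gap with a bump
  peak_times <- c(0.29, 0.58, 0.87, 1.47, 1.76)
  env <- rowSums(vapply(c(peak_times, 1.17), function(tc)
    0.6 * exp(-(t - tc)^2 / (2 * 0.02^2)), numeric(length(t))))
  tr <- structure(list(times = peak_times, amplitudes = rep(0.6, 5),
                       labels = NULL), class = "peak_train")
  out <- restore_missed_peaks(tr, env, fs)
  expect_length(out$times, 6)
  expect_equal(out$times[4], 1.17, tolerance = 2e-3)
  # a train whose gaps are all within the limit is a fixed point
  tr2 <- structure(list(times = c(0.29, 0.58, 0.87), amplitudes = rep(1, 3),
                        labels = NULL), class = "peak_train")
  expect_equal(restore_missed_peaks(tr2, env, fs)$times, tr2$times)
  # restoration never removes peaks
  expect_true(all(peak_times %in% out$times))
  expect_warning(restore_missed_peaks(
    structure(list(times = 0.5, amplitudes = 1, labels = NULL),
              class = "peak_train"), env, fs), "fewer than 2")
})

test_that("S1/S2 labels orient on the diastole and alternate", {
  # alternating 140 / 288 ms gaps starting with S1
  s1 <- seq(0, by = 0.428, length.out = 6)
  times <- sort(c(s1, s1 + 0.140))
  tr <- structure(list(times = times, amplitudes = rep(c(1, 0.6), 6),
                       labels = NULL), class = "peak_train")
  lab <- classify_s1_s2(tr)
  expect_equal(lab$labels, rep(c("S1", "S2"), 6))
  # no two consecutive identical labels
  expect_true(all(lab$labels[-1] != lab$labels[-length(lab$labels)]))
  expect_error(classify_s1_s2(
    structure(list(times = c(0, 1), amplitudes = c(1, 1), labels = NULL),
              class = "peak_train")), "3 peaks")
})

test_that("full detection recovers every annotation on clean signals", {
  ref <- ref20()
  det <- detect_heart_sounds(ref)
  ev <- evaluate_cell(ref, ref$samples, ref$samples, det)
  expect_equal(ev$acc_s1, 100)
  expect_equal(ev$acc_s2, 100)
  expect_equal(ev$mean_interval_error_ms, 0, tolerance = 1.0)
  # 20 s at 140 bpm: 46 S1 + 46 S2 labelled events
  expect_equal(sum(det$final$labels == "S1"), 46)
  expect_equal(sum(det$final$labels == "S2"), 46)
  # stage containment: deduplicated within candidates, within restored
  expect_true(all(det$deduplicated$times %in% det$candidates$times))
  expect_true(all(det$deduplicated$times %in% det$restored$times))
  expect_identical(det$final$times, det$restored$times)
  # all-zero input: flagged empty result
  det0 <- detect_heart_sounds(numeric(1000), fs = 1000)
  expect_true(det0$no_peaks)
  expect_length(det0$final$times, 0)
})

test_that("clean-signal detection is perfect across rates and jitter seeds", {
  for (bpm in c(110, 135, 160)) {
    for (seed in 1:3) {
      p <- fetal_params(rate_bpm = bpm, jitter_ms = 5)
      ref <- generate_fetal_pcg(p, duration_s = 15, fs = 1000, seed = seed)
      det <- detect_heart_sounds(ref)
      ev <- evaluate_cell(ref, ref$samples, ref$samples, det)
      expect_equal(ev$acc_s1, 100,
                   label = sprintf("S1 ACC at %d bpm seed %d", bpm, seed))
      expect_equal(ev$acc_s2, 100,
                   label = sprintf("S2 ACC at %d bpm seed %d", bpm, seed))
    }
  }
})
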