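test_that("event matching counts TP/FP/FN within the tolerance window", {
  ref <- seq(0.5, 5, by = 0.5)
  m <- match_events(ref, ref)
  expect_equal(c(m$TP, m$FP, m$FN), c(10, 0, 0))
  # shift beyond tolerance: nothing matches
  m2 <- match_events(ref + 0.060, ref, tolerance_ms = 50)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0, 10, 10))
  # within tolerance: everything matches
  m3 <- match_events(ref + 0.040, ref, tolerance_ms = 50)
  expect_equal(m3$TP, 10)
  # TP + FN always equals the reference count
  expect_equal(m2$TP + m2$FN, length(ref))
})

test_that("greedy matching equals optimal bipartite matching on small cases", {
  # oracle: maximum bipartite matching size by exhaustive assignment
  max_matching <- function(det, ref, tol) {
    best <- 0
    recurse <- function(d, used_r, count) {
      best <<- max(best, count)
      if (d > length(det)) return()
      recurse(d + 1, used_r, count)             # leave d unmatched
      for (r in seq_along(ref)) {
        if (!used_r[r] && abs(det[d] - ref[r]) <= tol) {
          used_r[r] <- TRUE
          recurse(d + 1, used_r, count + 1)
          used_r[r] <- FALSE
        }
      }
    }
    recurse(1, logical(length(ref)), 0)
    best
  }
  # reference events separated by more than twice the tolerance (the
  # physiological regime: heart sounds sit >= 100 ms apart while the window
  # is +/-50 ms), detections scrambled by jitter, deletions and insertions
  set.seed(17)
  for (rep in 1:25) {
    ref <- cumsum(runif(sample(3:6, 1), 0.25, 0.6))
    keep <- runif(length(ref)) > 0.3
    jit <- runif(sum(keep), -0.12, 0.12)
    extra <- runif(sample(0:2, 1), 0, max(ref))
    det <- sort(c(ref[keep] + jit, extra))
    m <- match_events(det, ref, tolerance_ms = 100)
    expect_equal(m$TP, max_matching(det, ref, 0.1),
                 label = sprintf("rep %d greedy vs optimal", rep))
  }
})

test_that("tolerance monotonicity: larger windows never lose matches", {
  set.seed(23)
  det <- sort(runif(20, 0, 10))
  ref <- sort(runif(20, 0, 10))
  tps <- vapply(c(10, 25, 50, 100, 200),
                function(tol) match_events(det, ref, tol)$TP, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("accuracy implements TP/(TP+FP+FN) in percent", {
  expect_equal(accuracy(list(TP = 9, FP = 1, FN = 2)), 75)
  expect_equal(accuracy(list(TP = 0, FP = 5, FN = 5)), 0)
  expect_equal(accuracy(list(TP = 700, FP = 0, FN = 0)), 100)
  expect_true(is.na(accuracy(list(TP = 0, FP = 0, FN = 0))))
})

test_that("SNR follows its closed-form identities", {
  set.seed(3)
  ref <- rnorm(1000)
  res <- rnorm(1000)
  # residual power equal to reference power -> 0 dB
  res0 <- res * sqrt(sum(ref^2) / sum(res^2))
  expect_equal(snr_db(ref, ref + res0), 0, tolerance = 1e-10)
  # scaling the residual x10 lowers SNR by exactly 20 dB
  expect_equal(snr_db(ref, ref + res) - snr_db(ref, ref + 10 * res), 20,
               tolerance = 1e-10)
  # other = -reference: residual -2 ref, power x4 -> -6.02 dB
  expect_equal(snr_db(ref, -ref), 10 * log10(1 / 4), tolerance = 1e-10)
  # zero residual: capped and flagged
  capped <- snr_db(ref, ref)
  expect_equal(as.numeric(capped), 300)
  expect_true(attr(capped, "capped"))
  # strictly decreasing in residual power
  expect_gt(snr_db(ref, ref + 0.5 * res), snr_db(ref, ref + res))
})

test_that("SNR improvement is the out-minus-in difference", {
  set.seed(4)
  ref <- rnorm(500); noise <- rnorm(500)
  expect_equal(snr_improvement(ref, ref + noise, ref + noise), 0)
  # halving the residual amplitude gains 6.02 dB
  expect_equal(snr_improvement(ref, ref + noise, ref + noise / 2),
               20 * log10(2), tolerance = 1e-10)
  expect_gt(snr_improvement(ref, ref + noise, ref + 0.1 * noise), 0)
})

test_that("interval error is shift invariant and averages |interval diffs|", {
  s1 <- seq(0.5, 10, by = 0.42857)
  expect_equal(mean_interval_error(s1, s1), 0)
  # a uniform shift leaves all intervals unchanged
  expect_equal(mean_interval_error(s1 + 0.030, s1), 0, tolerance = 1e-9)
  # alternating +/-2 ms jitter: every interval differs by 4 ms
  jit <- s1 + rep(c(0.002, -0.002), length.out = length(s1))
  expect_equal(mean_interval_error(jit, s1), 4, tolerance = 1e-9)
  # fewer than 2 matches: missing value
  expect_true(is.na(mean_interval_error(numeric(0), s1)))
  expect_true(is.na(mean_interval_error(s1[1], s1)))
})

test_that("evaluate_cell binds the metrics consistently", {
  ref <- ref20()
  det <- detect_heart_sounds(ref)
  ev <- evaluate_cell(ref, ref$samples, ref$samples, det)
  expect_equal(ev$acc_s1, 100)
  expect_equal(ev$acc_s2, 100)
  expect_equal(ev$snr_improvement_db, ev$snr_out_db - ev$snr_in_db)
  expect_equal(ev$counts_s1$TP + ev$counts_s1$FN,
               sum(ref$events$label == "S1"))
  # a noisy-input cell keeps the identity too
  noisy <- mix_at_snr(ref, list(gauss20()), -1.2)
  y <- apply_filter(noisy$samples, reference_setting("r01_03", "FIR"),
                    fs = 1000)
  ev2 <- evaluate_cell(ref, noisy$samples, y, detect_heart_sounds(y, 1000))
  expect_equal(ev2$snr_improvement_db, ev2$snr_out_db - ev2$snr_in_db)
  expect_true(ev2$acc_s1 >= 0 && ev2$acc_s1 <= 100)
})
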