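# Scoring of a filtered signal against the clean reference: event matching
# with a +/-50 ms window, detection accuracy, SNR in/out/improvement, and the
# mean absolute error of the S1-S1 heart interval.

#' Match detected events against reference events
#'
#' One-to-one greedy nearest matching: candidate (detected, reference) pairs
#' within `tolerance_ms` are accepted in order of increasing absolute time
#' difference (ties resolved toward the earlier reference event). Unmatched
#' detections count as false positives, unmatched reference events as false
#' negatives.
#'
#' @param detected_times numeric vector of detected event times (s), sorted.
#' @param reference_times numeric vector of reference event times (s), sorted.
#' @param tolerance_ms matching window half-width (ms); default 50.
#' @return A list of class `match_counts` with elements `TP`, `FP`, `FN`,
#'   `tolerance_ms` and `pairs` (matrix of matched index pairs).
#' @export
match_events <- function(detected_times, reference_times, tolerance_ms = 50) {
  stopifnot(tolerance_ms > 0)
  nd <- length(detected_times); nr <- length(reference_times)
  pairs <- NULL
  if (nd > 0 && nr > 0) {
    cand <- expand.grid(d = seq_len(nd), r = seq_len(nr))
    cand$dt <- abs(detected_times[cand$d] - reference_times[cand$r])
    cand <- cand[cand$dt <= tolerance_ms / 1000, , drop = FALSE]
    cand <- cand[order(cand$dt, cand$r), , drop = FALSE]
    used_d <- logical(nd); used_r <- logical(nr)
    keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!used_d[cand$d[i]] && !used_r[cand$r[i]]) {
        used_d[cand$d[i]] <- TRUE
        used_r[cand$r[i]] <- TRUE
        keep <- c(keep, i)
      }
    }
    pairs <- as.matrix(cand[keep, c("d", "r"), drop = FALSE])
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(TP = tp, FP = nd - tp, FN = nr - tp,
                 tolerance_ms = tolerance_ms, pairs = pairs),
            class = "match_counts")
}

#' Detection accuracy
#'
#' `ACC = 100 * TP / (TP + FP + FN)` in percent.
#'
#' @param counts a `match_counts` object from [match_events()], or a list
#'   with elements `TP`, `FP`, `FN`.
#' @return Accuracy in percent, or `NA` when all counts are zero.
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$FP + counts$FN
  if (tot == 0) return(NA_real_)
  100 * counts$TP / tot
}

#' Signal-to-noise ratio against a reference
#'
#' `10 log10( sum(ref^2) / sum((other - ref)^2) )` in dB. When `other`
#' equals the reference exactly the value is capped (default +300 dB) and
#' flagged via the `"capped"` attribute.
#'
#' @param reference clean reference waveform.
#' @param other waveform to score (noisy input or filtered output).
#' @param cap_db cap applied when the residual is exactly zero.
#' @return SNR in dB.
#' @export
snr_db <- function(reference, other, cap_db = 300) {
  stopifnot(length(reference) == length(other))
  p_ref <- sum(reference^2)
  if (p_ref == 0) stop("reference signal is identically zero")
  p_res <- sum((other - reference)^2)
  if (p_res == 0)
    return(structure(cap_db, capped = TRUE))
  10 * log10(p_ref / p_res)
}

#' SNR improvement achieved by a filter
#'
#' Difference between the output SNR (filtered vs reference) and the input
#' SNR (noisy input vs reference), in dB.
#'
#' @param reference clean reference waveform.
#' @param input noisy input waveform.
#' @param filtered filtered waveform.
#' @return SNR improvement in dB.
#' @export
snr_improvement <- function(reference, input, filtered) {
  as.numeric(snr_db(reference, filtered)) - as.numeric(snr_db(reference, input))
}

#' Mean absolute heart-interval error
#'
#' Compares consecutive S1-to-S1 intervals of the detections with those of
#' the reference, over matched beats only: reference beats that were matched
#' within tolerance define the interval sequence, and the mean of
#' `|T_i_detected - T_i_reference|` is returned in milliseconds. Consecutive
#' here means consecutive among matched beats, so a missed beat drops the
#' two intervals it participates in rather than corrupting them.
#'
#' @param detected_s1_times detected S1 times (s).
#' @param reference_s1_times reference S1 times (s).
#' @param tolerance_ms matching window for pairing detections to beats (ms).
#' @return Mean absolute interval error in ms, or `NA` when fewer than two
#'   beats were matched.
#' @export
mean_interval_error <- function(detected_s1_times, reference_s1_times,
                                tolerance_ms = 50) {
  m <- match_events(detected_s1_times, reference_s1_times, tolerance_ms)
  if (m$TP < 2) return(NA_real_)
  ord <- order(m$pairs[, "r"])
  rp <- m$pairs[ord, , drop = FALSE]
  dt_det <- diff(detected_s1_times[rp[, "d"]])
  dt_ref <- diff(reference_s1_times[rp[, "r"]])
  mean(abs(dt_det - dt_ref)) * 1000
}

#' Score one benchmark cell
#'
#' Binds the three evaluation metrics into a single report for one
#' (reference, noisy input, filtered output, detection) combination:
#' S1 and S2 detection accuracy at +/-50 ms, input/output SNR and the SNR
#' improvement, and the mean S1-S1 interval error.
#'
#' @param reference clean [annotated_signal()] with ground-truth events.
#' @param noisy noisy input waveform (numeric vector or `fpcg_signal`).
#' @param filtered filtered waveform (numeric vector or `fpcg_signal`).
#' @param detection a `fpcg_detection` from [detect_heart_sounds()].
#' @param tolerance_ms matching window (ms).
#' @return A list of class `fpcg_evaluation` with fields `acc_s1`, `acc_s2`,
#'   `snr_in_db`, `snr_out_db`, `snr_improvement_db`,
#'   `mean_interval_error_ms` and the per-sound `match_counts`.
#' @export
evaluate_cell <- function(reference, noisy, filtered, detection,
                          tolerance_ms = 50) {
  stopifnot(inherits(reference, "fpcg_signal"))
  x_in <- if (inherits(noisy, "fpcg_signal")) noisy$samples else noisy
  x_out <- if (inherits(filtered, "fpcg_signal")) filtered$samples else filtered
  final <- detection$final
  ref_s1 <- reference$events$time_s[reference$events$label == "S1"]
  ref_s2 <- reference$events$time_s[reference$events$label == "S2"]
  det_s1 <- final$times[final$labels == "S1"]
  det_s2 <- final$times[final$labels == "S2"]
  m1 <- match_events(det_s1, ref_s1, tolerance_ms)
  m2 <- match_events(det_s2, ref_s2, tolerance_ms)
  snr_in <- as.numeric(snr_db(reference$samples, x_in))
  snr_out <- as.numeric(snr_db(reference$samples, x_out))
  structure(list(acc_s1 = accuracy(m1), acc_s2 = accuracy(m2),
                 snr_in_db = snr_in, snr_out_db = snr_out,
                 snr_improvement_db = snr_out - snr_in,
                 mean_interval_error_ms =
                   mean_interval_error(det_s1, ref_s1, tolerance_ms),
                 counts_s1 = m1, counts_s2 = m2,
                 tolerance_ms = tolerance_ms),
            class = "fpcg_evaluation")
}

#' @export
print.fpcg_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<fpcg_evaluation> ACC S1 %.2f%%, ACC S2 %.2f%%, ",
                     "SNR in %.2f dB, out %.2f dB (improvement %.2f dB), ",
                     "interval error %.2f ms\n"),
              x$acc_s1, x$acc_s2, x$snr_in_db, x$snr_out_db,
              x$snr_improvement_db, x$mean_interval_error_ms))
  invisible(x)
}
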