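# S1/S2 heart-sound detection: Hilbert envelope -> low-pass smoothing ->
# amplitude threshold -> minimum-interval deduplication -> restoration of
# sub-threshold sounds -> systole/diastole-based S1/S2 labelling.

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Envelope of a waveform via the Hilbert transform
#'
#' Magnitude of the analytic signal; nonnegative, same length as the input.
#'
#' @param x numeric waveform, length >= 2.
#' @return Envelope waveform.
#' @export
compute_envelope <- function(x) {
  stopifnot(length(x) >= 2)
  Mod(analytic_signal(x))
}

#' Smooth an envelope with a zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), so the
#' envelope peaks stay time-aligned.
#'
#' @param env envelope waveform.
#' @param fs sampling frequency (Hz).
#' @param cutoff_hz low-pass cutoff; default 20 Hz passes the beat-scale
#'   envelope while removing carrier ripple.
#' @return Smoothed envelope, same length.
#' @export
smooth_envelope <- function(env, fs, cutoff_hz = 20) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), "low")
  n <- length(env)
  # reflect the ends before filtering so the filter transient dies in the
  # padding instead of distorting the envelope near the record edges
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  if (pad > 0) {
    ext <- c(rev(env[seq_len(pad) + 1L]), env,
             rev(env[n - seq_len(pad)]))
    out <- as.numeric(signal::filtfilt(bf, ext))
    out[pad + seq_len(n)]
  } else {
    as.numeric(signal::filtfilt(bf, env))
  }
}

peak_train <- function(times, amplitudes, labels = NULL) {
  structure(list(times = times, amplitudes = amplitudes, labels = labels),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d peaks", length(x$times)))
  if (!is.null(x$labels))
    cat(sprintf(" (%d S1, %d S2)", sum(x$labels == "S1"),
                sum(x$labels == "S2")))
  cat("\n")
  invisible(x)
}

local_maxima <- function(env) {
  n <- length(env)
  if (n < 3) return(integer(0))
  which(env[2:(n - 1)] > env[1:(n - 2)] & env[2:(n - 1)] >= env[3:n]) + 1L
}

#' Threshold the envelope to find candidate heart sounds
#'
#' Keeps every local maximum of the envelope whose value exceeds
#' `threshold_frac` times the maximal envelope amplitude.
#'
#' @param env (smoothed) envelope waveform.
#' @param fs sampling frequency (Hz).
#' @param threshold_frac fraction of the envelope maximum; default 0.4.
#' @return A `peak_train` of candidates (empty for a flat envelope).
#' @export
threshold_candidates <- function(env, fs, threshold_frac = 0.4) {
  stopifnot(length(env) > 0, threshold_frac > 0, threshold_frac < 1)
  idx <- local_maxima(env)
  thr <- threshold_frac * max(env)
  idx <- idx[env[idx] > thr]
  train <- peak_train((idx - 1L) / fs, env[idx])
  attr(train, "threshold_value") <- thr
  train
}

#' Remove extra peaks closer than a minimum interval
#'
#' Peaks linked by gaps shorter than `min_interval_ms` are grouped
#' (transitive closure of the too-close relation) and only the
#' highest-amplitude peak of each group is retained. Retained peaks are
#' therefore never closer than the minimum interval, and the operation is
#' idempotent.
#'
#' @param train a `peak_train`, sorted by time.
#' @param min_interval_ms minimum allowed inter-peak interval (ms);
#'   default 100.
#' @return Deduplicated `peak_train`.
#' @export
deduplicate_peaks <- function(train, min_interval_ms = 100) {
  n <- length(train$times)
  if (n <= 1) return(train)
  close_gap <- diff(train$times) < min_interval_ms / 1000
  cluster <- cumsum(c(TRUE, !close_gap))
  keep <- vapply(split(seq_len(n), cluster), function(ix) {
    ix[which.max(train$amplitudes[ix])]
  }, integer(1))
  keep <- sort(unname(keep))
  peak_train(train$times[keep], train$amplitudes[keep])
}

#' Restore heart sounds lost below the threshold
#'
#' The shortest inter-peak interval of the deduplicated train defines a
#' limit of twice its value. Every gap longer than that limit is searched
#' for the highest envelope *local maximum* strictly inside the gap -- the
#' best sub-threshold sound candidate, since heart sounds always produce an
#' envelope bump -- and that peak is inserted. Candidates closer than
#' `min_interval_ms` to either flanking peak are excluded, so restored
#' peaks respect the same minimum interval as detected ones. The scan
#' repeats until no gap exceeds the limit or no candidate exists, capped at
#' 10 passes. Candidates must also rise above `amp_floor`: a true heart
#' sound, even when suppressed below the detection threshold, still makes a
#' clear envelope bump, whereas smoothing ripple and the noise floor do not.
#'
#' @param train a deduplicated `peak_train` with >= 2 peaks (returned
#'   unchanged, with a warning, otherwise).
#' @param env the envelope the peaks were detected on.
#' @param fs sampling frequency (Hz).
#' @param min_interval_ms margin kept between a restored peak and the gap's
#'   flanking peaks (ms).
#' @param amp_floor minimum envelope amplitude of a restoration candidate
#'   (envelope units); default 25% of the envelope maximum.
#' @return `peak_train` including restored peaks.
#' @export
restore_missed_peaks <- function(train, env, fs, min_interval_ms = 100,
                                 amp_floor = 0.25 * max(env)) {
  if (length(train$times) < 2) {
    warning("fewer than 2 peaks; nothing to restore")
    return(train)
  }
  limit <- 2 * min(diff(train$times))
  margin <- min_interval_ms / 1000
  locmax <- local_maxima(env)
  locmax <- locmax[env[locmax] > amp_floor]
  for (pass in seq_len(10)) {
    inserted <- FALSE
    j <- 1L
    while (j < length(train$times)) {
      if (train$times[j + 1] - train$times[j] > limit) {
        t_lo <- train$times[j] + margin
        t_hi <- train$times[j + 1] - margin
        cand <- locmax[(locmax - 1L) / fs > t_lo & (locmax - 1L) / fs < t_hi]
        if (length(cand)) {
          k <- cand[which.max(env[cand])]
          train <- peak_train(append(train$times, (k - 1L) / fs, after = j),
                              append(train$amplitudes, env[k], after = j))
          inserted <- TRUE
          next  # recheck the left sub-gap at the same j
        }
      }
      j <- j + 1L
    }
    if (!inserted) break
  }
  train
}

#' Label peaks as S1 or S2
#'
#' The systolic (S1 to S2) interval is physiologically shorter than the
#' diastolic (S2 to next S1) interval, so a long inter-peak interval must
#' be a diastole: the peak before it is labelled S2 and the peak after it
#' S1. The longest interval (earliest on ties) provides the primary
#' orientation; every other gap on the diastolic side of the midpoint
#' between the lower- and upper-quartile gap lengths anchors the same rule,
#' and the remaining peaks are labelled in sequence, alternating between
#' anchors. Re-anchoring at each diastole keeps an occasional spurious or
#' missed peak from cascading through the rest of the recording.
#'
#' @param train a `peak_train` with >= 3 peaks.
#' @return The train with `labels` filled in.
#' @export
classify_s1_s2 <- function(train) {
  n <- length(train$times)
  if (n < 3) stop("at least 3 peaks are required to orient S1/S2 labels")
  gaps <- diff(train$times)
  thr <- mean(quantile(gaps, c(0.25, 0.75), names = FALSE))
  anchors <- which(gaps > thr)
  if (length(anchors)) {
    # gaps much longer than the typical diastole indicate a missed sound,
    # not a diastole; do not anchor on them
    d_typ <- median(gaps[anchors])
    anchors <- anchors[gaps[anchors] < 1.25 * d_typ]
  }
  if (!length(anchors)) anchors <- which.max(gaps)  # earliest on ties
  labels <- rep(NA_character_, n)
  labels[anchors] <- "S2"
  labels[anchors + 1L] <- "S1"
  flip <- c(S1 = "S2", S2 = "S1")
  # propagate outward from the anchors, nearest anchor first, so a spurious
  # or missed peak perturbs labels only up to the adjacent diastole
  while (anyNA(labels)) {
    nxt <- labels
    progress <- FALSE
    for (i in which(is.na(labels))) {
      left <- if (i > 1) labels[i - 1] else NA_character_
      right <- if (i < n) labels[i + 1] else NA_character_
      cand <- c(if (!is.na(left)) flip[[left]],
                if (!is.na(right)) flip[[right]])
      if (!length(cand)) next
      if (length(cand) == 2 && cand[1] != cand[2]) {
        # equidistant between conflicting anchors (an inserted or lost peak
        # sits in between): decide by amplitude, S1 sounds being larger
        a1 <- median(train$amplitudes[which(labels == "S1")])
        a2 <- median(train$amplitudes[which(labels == "S2")])
        cand <- if (is.na(a1) || is.na(a2)) cand[1]
                else if (abs(train$amplitudes[i] - a1) <=
                         abs(train$amplitudes[i] - a2)) "S1" else "S2"
      }
      nxt[i] <- cand[1]
      progress <- TRUE
    }
    if (!progress) break
    labels <- nxt
  }
  peak_train(train$times, train$amplitudes, labels)
}

#' Detect and label fetal S1/S2 heart sounds
#'
#' Runs the full detection chain on a (filtered) PCG waveform: Hilbert
#' envelope, low-pass smoothing, amplitude thresholding at a fraction of
#' the envelope maximum, minimum-interval deduplication, restoration of
#' sub-threshold sounds in over-long gaps, and S1/S2 labelling from the
#' systole/diastole asymmetry. All intermediates are retained.
#'
#' @param x numeric waveform (or `fpcg_signal`).
#' @param fs sampling frequency (Hz); taken from `x` if it is an
#'   `fpcg_signal`.
#' @param threshold_frac amplitude threshold as a fraction of the envelope
#'   maximum (default 0.4).
#' @param min_interval_ms minimum inter-peak interval (default 100 ms).
#' @param envelope_lpf_hz envelope smoothing cutoff (default 20 Hz).
#' @param restore_floor_frac amplitude floor for restored peaks, as a
#'   fraction of the smoothed-envelope maximum (default 0.25).
#' @return An object of class `fpcg_detection`: raw and smoothed envelopes,
#'   threshold value, the candidate/deduplicated/restored trains and the
#'   final labelled `peak_train` (`$final`). For input without detectable
#'   peaks the result is empty and flagged `no_peaks`.
#' @export
detect_heart_sounds <- function(x, fs = NULL, threshold_frac = 0.4,
                                min_interval_ms = 100, envelope_lpf_hz = 20,
                                restore_floor_frac = 0.25) {
  if (inherits(x, "fpcg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  stopifnot(length(x) > 0, !is.null(fs))
  empty <- peak_train(numeric(0), numeric(0), character(0))
  if (all(x == 0)) {
    return(structure(list(final = empty, no_peaks = TRUE),
                     class = "fpcg_detection"))
  }
  raw_env <- compute_envelope(x)
  sm_env <- smooth_envelope(raw_env, fs, envelope_lpf_hz)
  candidates <- threshold_candidates(sm_env, fs, threshold_frac)
  if (length(candidates$times) == 0) {
    return(structure(list(raw_envelope = raw_env, smoothed_envelope = sm_env,
                          final = empty, no_peaks = TRUE),
                     class = "fpcg_detection"))
  }
  dedup <- deduplicate_peaks(candidates, min_interval_ms)
  restored <- if (length(dedup$times) >= 2)
    restore_missed_peaks(dedup, sm_env, fs, min_interval_ms,
                         restore_floor_frac * max(sm_env))
  else dedup
  final <- if (length(restored$times) >= 3) classify_s1_s2(restored)
           else peak_train(restored$times, restored$amplitudes,
                           rep(NA_character_, length(restored$times)))
  structure(list(raw_envelope = raw_env, smoothed_envelope = sm_env,
                 threshold_value = attr(candidates, "threshold_value"),
                 candidates = candidates, deduplicated = dedup,
                 restored = restored, final = final, no_peaks = FALSE),
            class = "fpcg_detection")
}

#' @export
print.fpcg_detection <- function(x, ...) {
  if (isTRUE(x$no_peaks)) {
    cat("<fpcg_detection> no peaks detected\n")
  } else {
    cat(sprintf(paste0("<fpcg_detection> %d candidates -> %d deduplicated ",
                       "-> %d restored; final: "),
                length(x$candidates$times), length(x$deduplicated$times),
                length(x$restored$times)))
    print(x$final)
  }
  invisible(x)
}
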