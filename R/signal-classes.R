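#' Heart-sound generator parameters
#'
#' Bundles the parameters of a Gaussian-modulated-sinusoid heart-sound train:
#' beat rate, S1-to-S2 onset spacing, S1/S2 peak-envelope amplitude ratio,
#' the two carrier frequencies and the effective sound durations (the width
#' of the Gaussian envelope at -40 dB relative to its peak).
#'
#' @param rate_bpm beat rate in beats per minute.
#' @param s1_s2_interval_ms S1-onset to S2-onset spacing within a beat (ms);
#'   must be shorter than the beat period.
#' @param amp_ratio_s1_s2 ratio of the S1 peak envelope to the S2 peak
#'   envelope (dimensionless, > 0).
#' @param f_s1_hz,f_s2_hz carrier frequencies of S1 and S2 (Hz).
#' @param s1_duration_ms,s2_duration_ms effective sound durations (ms),
#'   defined as the -40 dB width of the Gaussian envelope.
#' @param base_amplitude peak envelope of S1 (arbitrary units).
#' @param jitter_ms standard deviation of Gaussian jitter applied to beat
#'   onsets (ms); 0 gives a strictly periodic train.
#' @return An object of class `heart_sound_params`.
#' @seealso [fetal_params()], [maternal_params()], [generate_fetal_pcg()]
#' @export
heart_sound_params <- function(rate_bpm, s1_s2_interval_ms, amp_ratio_s1_s2,
                               f_s1_hz, f_s2_hz,
                               s1_duration_ms = 60, s2_duration_ms = 40,
                               base_amplitude = 1, jitter_ms = 0) {
  stopifnot(rate_bpm > 0, amp_ratio_s1_s2 > 0,
            f_s1_hz > 0, f_s2_hz > 0,
            s1_duration_ms > 0, s2_duration_ms > 0, jitter_ms >= 0)
  if (s1_s2_interval_ms >= 60000 / rate_bpm)
    stop("s1_s2_interval_ms must be shorter than the beat period (",
         round(60000 / rate_bpm, 1), " ms at ", rate_bpm, " bpm)")
  structure(list(rate_bpm = rate_bpm,
                 s1_s2_interval_ms = s1_s2_interval_ms,
                 amp_ratio_s1_s2 = amp_ratio_s1_s2,
                 f_s1_hz = f_s1_hz, f_s2_hz = f_s2_hz,
                 s1_duration_ms = s1_duration_ms,
                 s2_duration_ms = s2_duration_ms,
                 base_amplitude = base_amplitude,
                 jitter_ms = jitter_ms),
            class = "heart_sound_params")
}

#' Default fetal heart-sound parameters
#'
#' 140 bpm, 140 ms S1-S2 spacing, S1/S2 amplitude ratio 1.7, carriers at
#' 36.89 Hz (S1) and 55.18 Hz (S2) -- a term fetus.
#'
#' @param ... overrides passed to [heart_sound_params()].
#' @return A `heart_sound_params` object.
#' @export
fetal_params <- function(...) {
  defaults <- list(rate_bpm = 140, s1_s2_interval_ms = 140,
                   amp_ratio_s1_s2 = 1.7, f_s1_hz = 36.89, f_s2_hz = 55.18,
                   s1_duration_ms = 60, s2_duration_ms = 40)
  do.call(heart_sound_params, modifyList(defaults, list(...)))
}

#' Default maternal heart-sound parameters
#'
#' 70 bpm, 331 ms S1-S2 spacing, amplitude ratio 1.54, carriers at 16.93 Hz
#' (S1) and 30.44 Hz (S2); the train occupies the 10-40 Hz band.
#'
#' @param ... overrides passed to [heart_sound_params()].
#' @return A `heart_sound_params` object.
#' @export
maternal_params <- function(...) {
  defaults <- list(rate_bpm = 70, s1_s2_interval_ms = 331,
                   amp_ratio_s1_s2 = 1.54, f_s1_hz = 16.93, f_s2_hz = 30.44,
                   s1_duration_ms = 180, s2_duration_ms = 120)
  do.call(heart_sound_params, modifyList(defaults, list(...)))
}

#' Annotated waveform
#'
#' A sampled waveform plus ground-truth event annotations and the parameters
#' it was generated with. The central data container of the package.
#'
#' @param samples numeric amplitude vector (arbitrary units).
#' @param fs sampling frequency (Hz).
#' @param events data frame with columns `time_s` (strictly increasing) and
#'   `label` (`"S1"`/`"S2"`); may have zero rows.
#' @param params generation parameters (a `heart_sound_params`, a noise
#'   spec list, or `NULL`).
#' @param seed integer seed the realization was drawn with, or `NA`.
#' @return An object of class `fpcg_signal`.
#' @export
annotated_signal <- function(samples, fs, events = empty_events(),
                             params = NULL, seed = NA_integer_) {
  stopifnot(is.numeric(samples), fs > 0)
  events <- as.data.frame(events)
  if (nrow(events)) {
    stopifnot(all(diff(events$time_s) > 0),
              all(events$label %in% c("S1", "S2")),
              all(events$time_s >= 0),
              all(events$time_s <= length(samples) / fs))
  }
  structure(list(samples = as.numeric(samples), fs = fs, events = events,
                 params = params, seed = seed),
            class = "fpcg_signal")
}

#' @export
print.fpcg_signal <- function(x, ...) {
  cat(sprintf("<fpcg_signal> %d samples @ %g Hz (%.3f s), %d annotated events\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              nrow(x$events)))
  if (nrow(x$events))
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(table(x$events$label)),
                              as.integer(table(x$events$label))),
                      collapse = ", ")))
  invisible(x)
}

#' @export
print.heart_sound_params <- function(x, ...) {
  cat(sprintf(paste0("<heart_sound_params> %g bpm, S1-S2 %g ms, ",
                     "S1/S2 ratio %g, carriers %g/%g Hz\n"),
              x$rate_bpm, x$s1_s2_interval_ms, x$amp_ratio_s1_s2,
              x$f_s1_hz, x$f_s2_hz))
  invisible(x)
}

empty_events <- function() {
  data.frame(time_s = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Duration of an annotated signal in seconds
#' @param x an `fpcg_signal`.
#' @return Length of the waveform in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$fs
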