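# Synthetic fPCG reference signals and the four interference generators.
# Heart sounds are Gaussian-modulated sinusoids; the Gaussian sigma is set so
# that the envelope falls to -40 dB of its peak at +/- duration/2.

gauss_sigma_s <- function(duration_ms) {
  # exp(-(d/2)^2 / (2 sigma^2)) = 10^(-40/20)  =>  sigma = d / (2 sqrt(2 ln 100))
  (duration_ms / 1000) / (2 * sqrt(2 * log(100)))
}

add_gauss_pulse <- function(samples, fs, t0, amp, f_hz, duration_ms,
                            carrier = TRUE) {
  sigma <- gauss_sigma_s(duration_ms)
  n <- length(samples)
  i0 <- max(1L, floor((t0 - 5 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((t0 + 5 * sigma) * fs) + 1L)
  if (i0 > n || i1 < 1L || i0 > i1) return(samples)
  t <- (seq.int(i0, i1) - 1L) / fs
  w <- amp * exp(-(t - t0)^2 / (2 * sigma^2))
  if (carrier) w <- w * sin(2 * pi * f_hz * (t - t0))
  samples[i0:i1] <- samples[i0:i1] + w
  samples
}

generate_heart_train <- function(params, duration_s, fs, seed, label_prefix,
                                 start_offset_s = NULL) {
  stopifnot(inherits(params, "heart_sound_params"))
  if (fs <= 0) stop("fs must be positive")
  if (duration_s < 0) stop("duration_s must be nonnegative")
  fmax <- max(params$f_s1_hz, params$f_s2_hz)
  if (fs < 4 * fmax)
    stop("fs = ", fs, " Hz violates the sampling requirement fs >= 4 x max ",
         "carrier frequency (", 4 * fmax, " Hz)")
  n <- round(duration_s * fs)
  samples <- numeric(n)
  if (n == 0)
    return(annotated_signal(samples, fs, params = params, seed = seed))

  period <- 60 / params$rate_bpm
  n_beats <- floor(duration_s * params$rate_bpm / 60)
  if (n_beats == 0)
    return(annotated_signal(samples, fs, params = params, seed = seed))
  # the first sound starts clear of the recording edge so no pulse is
  # truncated (a cut first S1 would bias its envelope peak and amplitude)
  if (is.null(start_offset_s))
    start_offset_s <- 1.5 * params$s1_duration_ms / 1000
  onsets <- start_offset_s + (seq_len(n_beats) - 1L) * period
  onsets <- onsets[onsets <= duration_s]
  n_beats <- length(onsets)
  if (n_beats == 0)
    return(annotated_signal(samples, fs, params = params, seed = seed))
  if (params$jitter_ms > 0) {
    if (!is.na(seed)) set.seed(seed)
    onsets <- onsets + rnorm(n_beats, 0, params$jitter_ms / 1000)
    onsets <- pmin(pmax(onsets, 0), duration_s)
    onsets <- sort(onsets)
  }
  s2_times <- onsets + params$s1_s2_interval_ms / 1000
  keep2 <- s2_times <= duration_s
  a_s1 <- params$base_amplitude
  a_s2 <- params$base_amplitude / params$amp_ratio_s1_s2
  for (k in seq_len(n_beats)) {
    samples <- add_gauss_pulse(samples, fs, onsets[k], a_s1,
                               params$f_s1_hz, params$s1_duration_ms)
    if (keep2[k])
      samples <- add_gauss_pulse(samples, fs, s2_times[k], a_s2,
                                 params$f_s2_hz, params$s2_duration_ms)
  }
  times <- c(onsets, s2_times[keep2])
  labels <- c(rep("S1", n_beats), rep("S2", sum(keep2)))
  ord <- order(times)
  events <- data.frame(time_s = times[ord], label = labels[ord],
                       stringsAsFactors = FALSE)
  annotated_signal(samples, fs, events, params = params, seed = seed)
}

#' Generate a reference fetal phonocardiogram
#'
#' Synthesizes a fetal heart-sound train in which every S1 and S2 sound is a
#' Gaussian-modulated sinusoid at its carrier frequency, centered on its
#' annotated time. Beats are spaced `60/rate_bpm` seconds apart; S2 follows
#' S1 by `s1_s2_interval_ms`; the S1 peak envelope is `amp_ratio_s1_s2`
#' times the S2 peak envelope.
#'
#' @param params a [heart_sound_params()]; defaults to [fetal_params()]
#'   (140 bpm, ratio 1.7, 36.89/55.18 Hz, 140 ms spacing).
#' @param duration_s signal length in seconds (>= 0).
#' @param fs sampling frequency in Hz; must be at least four times the
#'   highest carrier frequency.
#' @param seed integer seed (only consumed when `jitter_ms > 0`).
#' @param start_offset_s onset time of the first beat; default
#'   `1.5 * s1_duration` keeps the first sound clear of the recording edge.
#' @return An [annotated_signal()] with S1/S2 ground-truth events.
#' @examples
#' ref <- generate_fetal_pcg(duration_s = 10)
#' table(ref$events$label)
#' @export
generate_fetal_pcg <- function(params = fetal_params(), duration_s = 300,
                               fs = 1000, seed = 1L, start_offset_s = NULL) {
  generate_heart_train(params, duration_s, fs, seed, "f", start_offset_s)
}

#' Generate a maternal heart-sound interference train
#'
#' Same construction as [generate_fetal_pcg()] with the maternal parameter
#' set (70 bpm, amplitude ratio 1.54, carriers 16.93/30.44 Hz, 331 ms S1-S2
#' spacing); the result occupies the 10-40 Hz band typical of maternal heart
#' sounds picked up on the abdomen.
#'
#' @inheritParams generate_fetal_pcg
#' @return An [annotated_signal()].
#' @export
generate_maternal_hs <- function(params = maternal_params(), duration_s = 300,
                                 fs = 1000, seed = 1L, start_offset_s = NULL) {
  generate_heart_train(params, duration_s, fs, seed, "m", start_offset_s)
}

#' Movement-artifact noise specification
#'
#' @param pulse_rate_hz mean pulse rate (pulses per second). The default of
#'   0.2 (one pulse every 5 s on average) reflects intermittent maternal and
#'   fetal movement.
#' @param amplitude fixed peak amplitude of every pulse.
#' @return A list of class `noise_spec`.
#' @export
movement_spec <- function(pulse_rate_hz = 0.2, amplitude = 1) {
  stopifnot(pulse_rate_hz > 0, amplitude > 0)
  structure(list(kind = "movement", pulse_rate_hz = pulse_rate_hz,
                 amplitude = amplitude), class = "noise_spec")
}

#' Generate random movement-artifact pulses
#'
#' Movement of maternal limbs or the fetus shows up in abdominal recordings
#' as random pulses of fixed amplitude lasting 0.5-1.5 s. Each pulse is a
#' Gaussian-windowed burst of band-limited noise: fetal-type pulses are
#' limited to 0-25 Hz, maternal-type to 0-100 Hz, drawn with equal
#' probability. Pulses never overlap.
#'
#' @param spec a [movement_spec()].
#' @param duration_s signal length (s).
#' @param fs sampling frequency (Hz), > 200.
#' @param seed integer seed; identical seeds give identical output.
#' @return An [annotated_signal()] (no events); `params$pulses` records the
#'   center, duration and type of each emitted pulse.
#' @export
generate_movement_artifacts <- function(spec = movement_spec(),
                                        duration_s = 300, fs = 1000,
                                        seed = 1L) {
  stopifnot(inherits(spec, "noise_spec"), spec$kind == "movement")
  if (fs <= 200) stop("fs must exceed 200 Hz for movement artifacts")
  n <- round(duration_s * fs)
  if (n == 0) return(annotated_signal(numeric(0), fs, params = spec,
                                      seed = seed))
  n_pulses <- max(1L, round(duration_s * spec$pulse_rate_hz))
  if (n_pulses * 1.5 > duration_s)
    stop("pulse rate too high: ", n_pulses, " pulses of up to 1.5 s cannot ",
         "be placed without overlap in ", duration_s, " s")
  set.seed(seed)
  durs <- runif(n_pulses, 0.5, 1.5)
  # place pulses without overlap: draw gaps from the free time budget
  free <- duration_s - sum(durs)
  gaps <- runif(n_pulses + 1L)
  gaps <- gaps / sum(gaps) * free
  starts <- cumsum(gaps[seq_len(n_pulses)]) + cumsum(c(0, durs[-n_pulses]))
  types <- sample(c("fetal", "maternal"), n_pulses, replace = TRUE)
  samples <- numeric(n)
  pulse_band <- c(fetal = 25, maternal = 100)
  for (k in seq_len(n_pulses)) {
    m <- round(durs[k] * fs)
    noise <- rnorm(m + 2L * fs)            # pad for filter settling
    bf <- signal::butter(6, pulse_band[[types[k]]] / (fs / 2), "low")
    noise <- signal::filtfilt(bf, noise)
    noise <- noise[fs + seq_len(m)]
    sigma <- gauss_sigma_s(durs[k] * 1000)
    t <- (seq_len(m) - 1L) / fs - durs[k] / 2
    pulse <- noise * exp(-t^2 / (2 * sigma^2))
    pulse <- pulse / max(abs(pulse)) * spec$amplitude
    i0 <- floor(starts[k] * fs) + 1L
    idx <- i0:min(n, i0 + m - 1L)
    samples[idx] <- samples[idx] + pulse[seq_along(idx)]
  }
  spec$pulses <- data.frame(center_s = starts + durs / 2, duration_s = durs,
                            type = types, stringsAsFactors = FALSE)
  annotated_signal(samples, fs, params = spec, seed = seed)
}

#' Generate white Gaussian noise
#'
#' Zero-mean i.i.d. normal samples (unit variance): equal power in any two
#' bands of equal width. Surrogate for womb contractions, breathing,
#' digestive sounds and transducer quantization noise.
#'
#' @param duration_s signal length (s).
#' @param fs sampling frequency (Hz).
#' @param seed integer seed.
#' @return An [annotated_signal()] (no events).
#' @export
generate_gaussian_noise <- function(duration_s = 300, fs = 1000, seed = 1L) {
  stopifnot(fs > 0, duration_s >= 0)
  set.seed(seed)
  samples <- rnorm(round(duration_s * fs))
  annotated_signal(samples, fs,
                   params = structure(list(kind = "gaussian"),
                                      class = "noise_spec"),
                   seed = seed)
}

#' Generate ambient broadband noise
#'
#' White Gaussian noise passed through a causal fifth-order Butterworth
#' high-pass filter with a 100 Hz cutoff: the broadband interference caused
#' by speech, coughing, closing doors and similar ambient sources.
#'
#' @param duration_s signal length (s).
#' @param fs sampling frequency (Hz), > 2 x cutoff.
#' @param seed integer seed.
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param order filter order.
#' @return An [annotated_signal()] (no events).
#' @export
generate_ambient_noise <- function(duration_s = 300, fs = 1000, seed = 1L,
                                   cutoff_hz = 100, order = 5) {
  stopifnot(fs > 2 * cutoff_hz, duration_s >= 0)
  set.seed(seed)
  white <- rnorm(round(duration_s * fs))
  bf <- signal::butter(order, cutoff_hz / (fs / 2), "high")
  samples <- as.numeric(signal::filter(bf, white))
  annotated_signal(samples, fs,
                   params = structure(list(kind = "ambient",
                                           cutoff_hz = cutoff_hz,
                                           order = order),
                                      class = "noise_spec"),
                   seed = seed)
}

#' Mix a reference signal with interference at an exact target SNR
#'
#' Combines one or more interference signals (each first normalized to unit
#' power and weighted by its share of the combined noise power), then scales
#' the combination so that the input SNR -- ten times the log10 ratio of the
#' reference power to the power of the added noise -- equals
#' `target_snr_db` to within 1e-6 dB. Reference annotations are carried
#' through unchanged.
#'
#' @param ref the clean reference [annotated_signal()].
#' @param noises list of interference `fpcg_signal`s, same `fs` and length
#'   as `ref`.
#' @param target_snr_db target input SNR in dB.
#' @param weights relative power fractions of the noise components before
#'   global scaling; positive, summing to 1. Default: equal shares.
#' @return An [annotated_signal()] whose `params` holds the achieved SNR
#'   (`snr_in_db`) and the scaled combined noise (`noise_samples`), so that
#'   `samples - noise_samples` recovers the reference.
#' @export
mix_at_snr <- function(ref, noises, target_snr_db,
                       weights = rep(1 / length(noises), length(noises))) {
  stopifnot(inherits(ref, "fpcg_signal"), length(noises) >= 1,
            length(weights) == length(noises), all(weights > 0),
            abs(sum(weights) - 1) < 1e-9)
  p_ref <- mean(ref$samples^2)
  if (p_ref == 0) stop("reference signal has zero power")
  combined <- numeric(length(ref$samples))
  for (k in seq_along(noises)) {
    nk <- noises[[k]]
    stopifnot(inherits(nk, "fpcg_signal"))
    if (nk$fs != ref$fs || length(nk$samples) != length(ref$samples))
      stop("noise ", k, " does not match the reference fs/length")
    p_k <- mean(nk$samples^2)
    if (p_k == 0) stop("noise ", k, " has zero power")
    combined <- combined + sqrt(weights[k] / p_k) * nk$samples
  }
  p_comb <- mean(combined^2)
  g <- sqrt(p_ref / (p_comb * 10^(target_snr_db / 10)))
  noise_scaled <- g * combined
  out <- annotated_signal(ref$samples + noise_scaled, ref$fs, ref$events,
                          params = list(kind = "mixture",
                                        target_snr_db = target_snr_db,
                                        weights = weights,
                                        noise_samples = noise_scaled),
                          seed = ref$seed)
  out$params$snr_in_db <- snr_db(ref$samples, out$samples)
  out
}
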