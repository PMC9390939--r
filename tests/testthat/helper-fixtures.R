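# Shared fixtures, built once per test run. Short durations keep the suite
# fast; the generators are deterministic given (params, duration, fs, seed).

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (is.null(cache[[name]])) cache[[name]] <- build()
    cache[[name]]
  }
})

ref20 <- function() fix("ref20", function()
  generate_fetal_pcg(duration_s = 20, fs = 1000, seed = 1))

maternal60 <- function() fix("maternal60", function()
  generate_maternal_hs(duration_s = 60, fs = 1000, seed = 1))

gauss20 <- function() fix("gauss20", function()
  generate_gaussian_noise(20, fs = 1000, seed = 42))

# average periodogram power of `x` (fs = 1000) in a frequency band
band_power <- function(x, f_lo, f_hi, fs = 1000) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(51, 51),
                          plot = FALSE, taper = 0)
  mean(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi])
}

# zero-padded periodogram peak frequency of a signal segment
spectral_peak_hz <- function(seg, fs, nfft = 2^17) {
  z <- c(seg, numeric(nfft - length(seg)))
  p <- Mod(stats::fft(z))[seq_len(nfft / 2)]
  (which.max(p) - 1) * fs / nfft
}
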