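# Savitzky-Golay smoothing and linear-phase FIR band-pass filtering.

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing. Classical S-G requires an odd
#' window; even requested lengths are rounded up to the next odd integer
#' (the value actually used is attached as attribute `"window_used"`).
#'
#' @param x numeric waveform.
#' @param window_length window length in samples (rounded up to odd).
#' @param poly_order polynomial order, < window length.
#' @return Smoothed waveform, same length as input.
#' @export
savgol_smooth <- function(x, window_length, poly_order) {
  w <- as.integer(window_length)
  if (w %% 2 == 0) w <- w + 1L
  if (poly_order >= w)
    stop("poly_order (", poly_order, ") must be smaller than the window (",
         w, ")")
  if (w > length(x)) stop("window longer than the signal")
  out <- as.numeric(signal::sgolayfilt(x, p = poly_order, n = w))
  attr(out, "window_used") <- w
  out
}

#' Linear-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass design at the given order, applied with
#' group-delay compensation (a shift of `order/2` samples) so the output is
#' time-aligned with the input. The benchmark default band is 20-110 Hz,
#' bracketing the fetal S1/S2 carriers.
#'
#' @param x numeric waveform.
#' @param fs sampling frequency (Hz).
#' @param filter_order FIR order (number of taps minus one).
#' @param band numeric length-2 vector, passband edges in Hz, inside
#'   (0, fs/2).
#' @return Filtered waveform, same length as input.
#' @export
fir_bandpass <- function(x, fs, filter_order, band = c(20, 110)) {
  stopifnot(filter_order >= 1, length(band) == 2)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band edges must satisfy 0 < low < high < fs/2")
  # fir1 needs an even order for a band-pass (odd-length symmetric impulse
  # response); bump odd orders by one and compensate the exact delay.
  ord <- as.integer(filter_order)
  if (ord %% 2 == 1) ord <- ord + 1L
  h <- signal::fir1(ord, band / (fs / 2), type = "pass")
  n <- length(x)
  delay <- ord / 2
  y <- as.numeric(stats::filter(c(x, numeric(delay)), h, method = "convolution",
                                sides = 1))
  y <- y[(delay + 1):(delay + n)]
  y[is.na(y)] <- 0
  y
}
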