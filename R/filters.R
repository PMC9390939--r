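# Uniform dispatch over the eight denoising algorithms.

.algorithms <- c("SG", "FIR", "AWT", "MODWT", "VMD", "EMD", "EEMD", "CEEMDAN")

#' Configuration for one denoising algorithm
#'
#' Validates and bundles the parameters of one of the eight algorithms so
#' that [apply_filter()] can dispatch uniformly.
#'
#' @param algorithm one of `"SG"`, `"FIR"`, `"AWT"`, `"MODWT"`, `"VMD"`,
#'   `"EMD"`, `"EEMD"`, `"CEEMDAN"`.
#' @param window_length,poly_order SG: window (samples) and polynomial
#'   order (order < window).
#' @param filter_order,band FIR: order and passband in Hz.
#' @param wavelet,levels AWT/MODWT: wavelet name and decomposition levels.
#' @param N,Nstd,seed EEMD/CEEMDAN: ensemble trials (>= 1), added-noise
#'   standard deviation as a fraction of the signal's (>= 0), seed.
#' @param imf_selection VMD/EMD/EEMD/CEEMDAN: 1-based indices of the modes
#'   summed into the filtered signal.
#' @param n_modes,bandwidth_alpha,tau,tol VMD hyperparameters.
#' @param max_imfs,sift_tolerance EMD-family sifting controls.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(algorithm,
                          window_length = NULL, poly_order = NULL,
                          filter_order = NULL, band = c(20, 110),
                          wavelet = NULL, levels = NULL,
                          N = NULL, Nstd = NULL, seed = 1L,
                          imf_selection = NULL,
                          n_modes = 5, bandwidth_alpha = 2000, tau = 0,
                          tol = 1e-7,
                          max_imfs = 10, sift_tolerance = 0.3) {
  if (!algorithm %in% .algorithms)
    stop("unknown algorithm '", algorithm, "'; expected one of: ",
         paste(.algorithms, collapse = ", "))
  cfg <- switch(algorithm,
    SG = {
      stopifnot(!is.null(window_length), !is.null(poly_order),
                poly_order >= 0, poly_order < window_length)
      list(window_length = window_length, poly_order = poly_order)
    },
    FIR = {
      stopifnot(!is.null(filter_order), filter_order >= 1,
                length(band) == 2, band[1] > 0, band[1] < band[2])
      list(filter_order = filter_order, band = band)
    },
    AWT = ,
    MODWT = {
      stopifnot(!is.null(wavelet), !is.null(levels), levels >= 1)
      wavelet_filters(wavelet)   # validates the name
      list(wavelet = wavelet, levels = levels)
    },
    VMD = {
      stopifnot(n_modes >= 1)
      sel <- if (is.null(imf_selection)) seq_len(n_modes) else imf_selection
      stopifnot(length(sel) >= 1, all(sel >= 1))
      list(n_modes = n_modes, bandwidth_alpha = bandwidth_alpha, tau = tau,
           tol = tol, imf_selection = sel)
    },
    EMD = {
      stopifnot(!is.null(imf_selection), all(imf_selection >= 1))
      list(imf_selection = imf_selection, max_imfs = max_imfs,
           sift_tolerance = sift_tolerance)
    },
    EEMD = ,
    CEEMDAN = {
      stopifnot(!is.null(N), N >= 1, !is.null(Nstd), Nstd >= 0,
                !is.null(imf_selection), all(imf_selection >= 1))
      list(N = N, Nstd = Nstd, seed = seed, imf_selection = imf_selection,
           max_imfs = max_imfs, sift_tolerance = sift_tolerance)
    })
  structure(c(list(algorithm = algorithm), cfg), class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  flat <- x[setdiff(names(x), "algorithm")]
  cat(sprintf("<filter_config> %s: %s\n", x$algorithm,
              paste(names(flat),
                    vapply(flat, function(v) paste(v, collapse = "+"),
                           character(1)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Apply a configured denoising algorithm
#'
#' Dispatches to the matching filter; the decomposition methods compose
#' decomposition and IMF-selection reconstruction. A missing mode index in
#' the selection (the decomposition produced fewer modes than requested)
#' contributes nothing rather than failing, since the number of extractable
#' IMFs depends on the signal.
#'
#' @param x numeric waveform (or `fpcg_signal`).
#' @param config a [filter_config()].
#' @param fs sampling frequency (Hz); taken from `x` when it is an
#'   `fpcg_signal`.
#' @return Filtered waveform, same length as the input.
#' @export
apply_filter <- function(x, config, fs = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (inherits(x, "fpcg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs) && config$algorithm %in% c("FIR", "AWT", "MODWT", "VMD"))
    stop("fs is required for ", config$algorithm)
  select_modes <- function(dec, sel) {
    sel <- sel[sel <= length(dec$modes)]
    if (!length(sel)) return(numeric(length(x)))
    reconstruct_from_imfs(dec, sel)
  }
  switch(config$algorithm,
    SG = savgol_smooth(x, config$window_length, config$poly_order),
    FIR = fir_bandpass(x, fs, config$filter_order, config$band),
    AWT = awt_denoise(x, fs, config$wavelet, config$levels),
    MODWT = modwt_denoise(x, fs, config$wavelet, config$levels),
    VMD = {
      dec <- vmd_decompose(x, fs, config$n_modes, config$bandwidth_alpha,
                           config$tau, config$tol)
      select_modes(dec, config$imf_selection)
    },
    EMD = select_modes(emd_decompose(x, config$max_imfs,
                                     config$sift_tolerance),
                       config$imf_selection),
    EEMD = select_modes(eemd_decompose(x, config$N, config$Nstd, config$seed,
                                       config$max_imfs,
                                       config$sift_tolerance),
                        config$imf_selection),
    CEEMDAN = select_modes(ceemdan_decompose(x, config$N, config$Nstd,
                                             config$seed, config$max_imfs,
                                             config$sift_tolerance),
                           config$imf_selection))
}
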