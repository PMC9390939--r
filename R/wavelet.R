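# Orthogonal discrete wavelet transform (periodized), maximal-overlap DWT,
# and the two wavelet denoisers built on them. Filter coefficients for the
# Daubechies/symlet/coiflet families live in wavelet-coefs.R.

wavelet_filters <- function(wavelet) {
  h <- .wavelet_lowpass[[wavelet]]
  if (is.null(h))
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.wavelet_lowpass), collapse = ", "))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature-mirror highpass
  list(h = h, g = g, L = L)
}

# one level of the periodized orthogonal DWT; n must be even
dwt_step <- function(x, f) {
  n <- length(x)
  n2 <- n / 2
  k <- seq_len(n2) - 1L
  a <- numeric(n2); d <- numeric(n2)
  for (m in seq_len(f$L) - 1L) {
    idx <- (2L * k + 1L - m) %% n + 1L
    a <- a + f$h[m + 1L] * x[idx]
    d <- d + f$g[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, f) {
  n2 <- length(a)
  n <- 2L * n2
  k <- seq_len(n2) - 1L
  x <- numeric(n)
  for (m in seq_len(f$L) - 1L) {
    idx <- (2L * k + 1L - m) %% n + 1L
    x[idx] <- x[idx] + f$h[m + 1L] * a + f$g[m + 1L] * d
  }
  x
}

#' Discrete wavelet transform (periodized, orthogonal)
#'
#' @param x numeric waveform; internally reflection-padded to a multiple of
#'   `2^levels`.
#' @param wavelet wavelet name (`db3`-`db6`, `sym3`-`sym6`, `coif3`-`coif5`).
#' @param levels number of decomposition levels.
#' @return List with `approx` (deepest approximation), `details` (list,
#'   level 1 = finest), and bookkeeping for [idwt()].
#' @export
dwt <- function(x, wavelet, levels) {
  stopifnot(levels >= 1)
  f <- wavelet_filters(wavelet)
  n0 <- length(x)
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  if (pad > 0) x <- c(x, rev(x)[seq_len(pad)])
  if (length(x) / block < 1)
    stop("signal too short for ", levels, " decomposition levels")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, f)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = wavelet, levels = levels,
       n = n0)
}

#' Inverse of [dwt()]
#' @param w result of [dwt()] (coefficients may have been modified).
#' @return Reconstructed waveform of the original length.
#' @export
idwt <- function(w) {
  f <- wavelet_filters(w$wavelet)
  a <- w$approx
  for (j in rev(seq_len(w$levels))) {
    a <- idwt_step(a, w$details[[j]], f)
  }
  a[seq_len(w$n)]
}

#' Maximal-overlap discrete wavelet transform
#'
#' Undecimated transform: coefficients at every level have the input length.
#' Boundaries are handled by reflection padding before the circular
#' transform.
#'
#' @inheritParams dwt
#' @return List with `smooth` (deepest scaling coefficients), `details`
#'   (list, level 1 = finest) and bookkeeping for [imodwt()].
#' @export
modwt <- function(x, wavelet, levels) {
  stopifnot(levels >= 1)
  f <- wavelet_filters(wavelet)
  ht <- f$h / sqrt(2)
  gt <- f$g / sqrt(2)
  n0 <- length(x)
  x <- c(x, rev(x))                    # reflection boundary
  n <- length(x)
  details <- vector("list", levels)
  v <- x
  t0 <- seq_len(n) - 1L
  for (j in seq_len(levels)) {
    stride <- 2^(j - 1L)
    wj <- numeric(n); vj <- numeric(n)
    for (m in seq_len(f$L) - 1L) {
      idx <- (t0 - stride * m) %% n + 1L
      wj <- wj + gt[m + 1L] * v[idx]
      vj <- vj + ht[m + 1L] * v[idx]
    }
    details[[j]] <- wj
    v <- vj
  }
  list(smooth = v, details = details, wavelet = wavelet, levels = levels,
       n = n0)
}

#' Inverse of [modwt()]
#' @param w result of [modwt()] (coefficients may have been modified).
#' @return Reconstructed waveform of the original length.
#' @export
imodwt <- function(w) {
  f <- wavelet_filters(w$wavelet)
  ht <- f$h / sqrt(2)
  gt <- f$g / sqrt(2)
  n <- 2L * w$n
  v <- w$smooth
  t0 <- seq_len(n) - 1L
  for (j in rev(seq_len(w$levels))) {
    stride <- 2^(j - 1L)
    vm <- numeric(n)
    for (m in seq_len(f$L) - 1L) {
      idx <- (t0 + stride * m) %% n + 1L
      vm <- vm + ht[m + 1L] * v[idx] + gt[m + 1L] * w$details[[j]][idx]
    }
    v <- vm
  }
  v[seq_len(w$n)]
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Adaptive wavelet-threshold denoising
#'
#' Orthogonal DWT to `levels`, then soft thresholding of every detail
#' coefficient with a locally adapted universal threshold: the noise level
#' sigma is estimated in a moving window (default 1 s, 50% overlap) from the
#' median absolute deviation of the finest-level details, interpolated to
#' each coefficient's time position, and the threshold is
#' `sigma(t) * sqrt(2 log n)`. This tracks interference whose power changes
#' over the recording.
#'
#' @param x numeric waveform.
#' @param fs sampling frequency (Hz).
#' @param wavelet wavelet name.
#' @param levels decomposition levels.
#' @param window_s moving-window length for the noise estimate (s).
#' @param threshold_scale multiplier on the universal threshold; 0 disables
#'   thresholding (perfect reconstruction).
#' @return Denoised waveform, same length.
#' @export
awt_denoise <- function(x, fs, wavelet, levels, window_s = 1,
                        threshold_scale = 1) {
  w <- dwt(x, wavelet, levels)
  n <- length(x)
  if (threshold_scale > 0) {
    d1 <- w$details[[1]]
    n1 <- length(d1)
    # windowed MAD sigma estimate on the finest details (coef rate fs/2)
    win <- max(4L, round(window_s * fs / 2))
    hop <- max(2L, win %/% 2L)
    starts <- seq(1L, max(1L, n1 - win + 1L), by = hop)
    centers <- pmin(starts + win / 2, n1)
    sig <- vapply(starts, function(s) {
      seg <- d1[s:min(n1, s + win - 1L)]
      mad(seg)
    }, numeric(1))
    sig_fun <- if (length(sig) > 1)
      function(pos01) approx(centers / n1, sig, xout = pos01, rule = 2)$y
    else function(pos01) rep(sig, length(pos01))
    lambda0 <- sqrt(2 * log(n)) * threshold_scale
    for (j in seq_len(levels)) {
      dj <- w$details[[j]]
      pos01 <- (seq_along(dj) - 0.5) / length(dj)
      w$details[[j]] <- soft_threshold(dj, lambda0 * sig_fun(pos01))
    }
  }
  idwt(w)
}

#' MODWT denoising
#'
#' Maximal-overlap DWT to `levels`, universal soft threshold per level
#' (`sigma_j * sqrt(2 log n)` with `sigma_j` the MAD estimate from that
#' level's coefficients), inverse transform.
#'
#' @inheritParams awt_denoise
#' @return Denoised waveform, same length.
#' @export
modwt_denoise <- function(x, fs, wavelet, levels, threshold_scale = 1) {
  w <- modwt(x, wavelet, levels)
  if (threshold_scale > 0) {
    n <- length(x)
    for (j in seq_len(levels)) {
      lambda <- mad(w$details[[j]]) * sqrt(2 * log(n)) * threshold_scale
      w$details[[j]] <- soft_threshold(w$details[[j]], lambda)
    }
  }
  imodwt(w)
}
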