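# Empirical mode decomposition and its noise-assisted ensemble variants.
# Sifting uses cubic-spline upper/lower envelopes through the local extrema
# (endpoints mirrored), with the classical standard-deviation stop criterion.

imf_set <- function(modes, residue, method) {
  structure(list(modes = modes, residue = residue, method = method),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %s: %d IMFs + residue (length %d)\n",
              x$method, length(x$modes), length(x$residue)))
  invisible(x)
}

find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus count once
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  chg <- which(s[nz[-length(nz)]] != s[nz[-1]])
  idx <- nz[chg] + 1L
  types <- s[nz[chg]]                   # +1 -> maximum, -1 -> minimum
  list(max = idx[types > 0], min = idx[types < 0])
}

# cubic-spline envelope through extrema, endpoints handled by mirroring the
# two nearest extrema beyond each boundary
spline_envelope <- function(x, idx) {
  n <- length(x)
  t <- idx; v <- x[idx]
  k <- length(idx)
  if (k >= 2) {
    t <- c(2 - t[2], 2 - t[1], t, 2 * n - t[k], 2 * n - t[k - 1])
    v <- c(v[2], v[1], v, v[k], v[k - 1])
  }
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  keep <- !duplicated(t)
  spline(t[keep], v[keep], xout = seq_len(n), method = "fmm")$y
}

sift_one_imf <- function(x, sd_tol = 0.2, max_sifts = 50) {
  h <- x
  for (s in seq_len(max_sifts)) {
    ex <- find_extrema(h)
    if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
    upper <- spline_envelope(h, ex$max)
    lower <- spline_envelope(h, ex$min)
    m <- (upper + lower) / 2
    h_new <- h - m
    sd_crit <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
    h <- h_new
    if (sd_crit < sd_tol) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a waveform into intrinsic mode functions (IMFs) by iterative
#' sifting: cubic-spline upper and lower envelopes through the local
#' extrema, subtraction of their mean, repeated until the normalized squared
#' mean falls below `sift_tolerance`. Extraction stops when the residue is
#' monotone/constant (fewer than two maxima or minima) or `max_imfs` is
#' reached. The sum of all IMFs plus the residue reconstructs the input
#' exactly.
#'
#' @param x numeric waveform.
#' @param max_imfs maximum number of IMFs (default 10).
#' @param sift_tolerance standard-deviation stop criterion (default 0.3).
#' @return An `imf_set` (constant input gives zero IMFs, residue = input).
#' @export
emd_decompose <- function(x, max_imfs = 10, sift_tolerance = 0.3) {
  residue <- x
  modes <- list()
  for (k in seq_len(max_imfs)) {
    imf <- sift_one_imf(residue, sift_tolerance)
    if (is.null(imf)) break
    modes[[k]] <- imf
    residue <- residue - imf
  }
  imf_set(modes, residue, "EMD")
}

pad_modes <- function(modes, n_target, n_samples) {
  while (length(modes) < n_target) modes[[length(modes) + 1L]] <-
      numeric(n_samples)
  modes
}

#' Ensemble empirical mode decomposition
#'
#' Averages, index by index, the EMDs of `N` copies of the input perturbed
#' with white Gaussian noise of standard deviation `Nstd` times the input's
#' standard deviation. The added noise populates the full spectrum, so each
#' trial's sifting splits signal components consistently across the
#' ensemble and mode mixing is reduced.
#'
#' @param x numeric waveform.
#' @param N number of ensemble trials (>= 1).
#' @param Nstd noise standard deviation as a fraction of `sd(x)`; 0 reduces
#'   to plain EMD.
#' @param seed integer seed; identical seeds give identical output.
#' @param max_imfs maximum number of IMFs per trial.
#' @param sift_tolerance sifting stop criterion.
#' @return An `imf_set` with the ensemble-averaged modes and residue.
#' @export
eemd_decompose <- function(x, N, Nstd, seed = 1L, max_imfs = 10,
                           sift_tolerance = 0.3) {
  stopifnot(N >= 1, Nstd >= 0)
  if (Nstd == 0) {
    out <- emd_decompose(x, max_imfs, sift_tolerance)
    out$method <- "EEMD"
    return(out)
  }
  set.seed(seed)
  eps <- Nstd * sd(x)
  n <- length(x)
  acc_modes <- list()
  acc_res <- numeric(n)
  for (trial in seq_len(N)) {
    dec <- emd_decompose(x + eps * rnorm(n), max_imfs, sift_tolerance)
    k <- max(length(acc_modes), length(dec$modes))
    acc_modes <- pad_modes(acc_modes, k, n)
    dm <- pad_modes(dec$modes, k, n)
    for (j in seq_len(k)) acc_modes[[j]] <- acc_modes[[j]] + dm[[j]]
    acc_res <- acc_res + dec$residue
  }
  imf_set(lapply(acc_modes, function(m) m / N), acc_res / N, "EEMD")
}

#' Complete ensemble EMD with adaptive noise
#'
#' Extracts IMFs sequentially: at every stage, paired positive and negative
#' realizations of scaled EMD modes of the noise are added to the current
#' residue, the first IMF of each perturbed copy is sifted out, and the
#' stage IMF is the ensemble average. Each IMF is subtracted from the
#' running residue before the next stage, so the sum of modes plus the
#' final residue reconstructs the input exactly.
#'
#' @param x numeric waveform.
#' @param N number of noise realizations; each is used with both signs,
#'   giving a 2N-member ensemble per stage.
#' @param Nstd noise amplitude as a fraction of the standard deviation of
#'   the current residue; 0 reduces to plain EMD.
#' @param seed integer seed.
#' @param max_imfs maximum number of IMFs.
#' @param sift_tolerance sifting stop criterion.
#' @return An `imf_set`.
#' @export
ceemdan_decompose <- function(x, N, Nstd, seed = 1L, max_imfs = 10,
                              sift_tolerance = 0.3) {
  stopifnot(N >= 1, Nstd >= 0)
  if (Nstd == 0) {
    out <- emd_decompose(x, max_imfs, sift_tolerance)
    out$method <- "CEEMDAN"
    return(out)
  }
  set.seed(seed)
  n <- length(x)
  noise_dec <- vector("list", N)
  for (i in seq_len(N)) {
    w <- rnorm(n)
    noise_dec[[i]] <- list(raw = w,
                           modes = emd_decompose(w, max_imfs,
                                                 sift_tolerance)$modes)
  }
  modes <- list()
  residue <- x
  for (k in seq_len(max_imfs)) {
    eps <- Nstd * sd(residue)
    if (!is.finite(eps) || eps == 0) break
    acc <- numeric(n)
    got <- 0L
    for (i in seq_len(N)) {
      pk <- if (k == 1L) noise_dec[[i]]$raw
            else if (length(noise_dec[[i]]$modes) >= k - 1L)
              noise_dec[[i]]$modes[[k - 1L]]
            else numeric(n)
      for (sgn in c(1, -1)) {
        imf <- sift_one_imf(residue + sgn * eps * pk, sift_tolerance)
        if (!is.null(imf)) {
          acc <- acc + imf
          got <- got + 1L
        }
      }
    }
    if (got == 0L) break
    modes[[k]] <- acc / got
    residue <- residue - modes[[k]]
    ex <- find_extrema(residue)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
  }
  imf_set(modes, residue, "CEEMDAN")
}

#' Reconstruct a waveform from selected IMFs
#'
#' Elementwise sum of the selected modes (optionally plus the residue).
#'
#' @param imfset an `imf_set`.
#' @param imf_selection 1-based indices of the modes to sum; must be
#'   nonempty and within range.
#' @param include_residue add the residue to the sum (default `FALSE`).
#' @return Reconstructed waveform.
#' @export
reconstruct_from_imfs <- function(imfset, imf_selection,
                                  include_residue = FALSE) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imf_selection) == 0) stop("imf_selection must be nonempty")
  imf_selection <- as.integer(imf_selection)
  if (any(imf_selection < 1) || any(imf_selection > length(imfset$modes)))
    stop("imf_selection out of range: decomposition has ",
         length(imfset$modes), " modes")
  out <- Reduce(`+`, imfset$modes[imf_selection])
  if (include_residue) out <- out + imfset$residue
  out
}
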