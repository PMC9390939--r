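# Minimal RIFF/WAVE reader and writer: mono, PCM 16/24/32-bit or IEEE
# float32. Integer encodings are normalized to [-1, 1] on read.

#' Write a waveform as a mono WAV file
#'
#' @param x numeric waveform (or `fpcg_signal`).
#' @param path output file path.
#' @param fs sampling frequency (Hz); taken from `x` if it is an
#'   `fpcg_signal`.
#' @param format `"float32"` (default, lossless for doubles up to float
#'   precision) or `"pcm16"` (samples clipped to [-1, 1] and quantized).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(x, "fpcg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  stopifnot(!is.null(fs), fs > 0)
  n <- length(x)
  bits <- if (format == "float32") 32L else 16L
  bytes_per <- bits %/% 8L
  audio_fmt <- if (format == "float32") 3L else 1L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Accepts PCM 16/24/32-bit (normalized to [-1, 1]) or IEEE float32.
#' Multichannel or malformed files are rejected.
#'
#' @param path WAV file path.
#' @return An [annotated_signal()] with empty events.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  audio_fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      if (is.null(audio_fmt)) stop("data chunk before fmt chunk in ", path)
      if (channels != 1) stop("only mono WAV is supported (file has ",
                              channels, " channels)")
      n <- sz %/% (bits %/% 8L)
      x <- if (audio_fmt == 3L && bits == 32L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else if (audio_fmt == 1L && bits == 16L) {
        readBin(con, integer(), n = n, size = 2, signed = TRUE,
                endian = "little") / 32768
      } else if (audio_fmt == 1L && bits == 32L) {
        readBin(con, integer(), n = n, size = 4, endian = "little") /
          2147483648
      } else if (audio_fmt == 1L && bits == 24L) {
        raw3 <- readBin(con, raw(), n = 3L * n)
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop("unsupported WAV encoding (format ", audio_fmt, ", ", bits,
             " bits)")
      }
      return(annotated_signal(x, fs))
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2L))
    }
  }
}
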