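#' Construct an audio signal
#'
#' Container for a mono vascular-sound waveform. Samples are dimensionless
#' amplitudes (nominally in \[-1, 1\]); the sampling rate must be at least
#' 3000 Hz so that the 1500 Hz upper band edge of the analysis filters is
#' resolvable.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sampling_rate Sampling rate in Hz, >= 3000.
#' @return An object of class `audio_signal` with elements `samples`,
#'   `sampling_rate` and `duration` (seconds).
#' @examples
#' s <- audio_signal(sin(2 * pi * 200 * seq(0, 5, by = 1/4000)), 4000)
#' s$duration
#' @export
audio_signal <- function(samples, sampling_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("audio signal contains non-finite samples", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate < 3000)
    stop("`sampling_rate` must be a single value >= 3000 Hz ",
         "(needed to resolve the 1500 Hz band edge)", call. = FALSE)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         duration = length(samples) / sampling_rate),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %.3f s @ %g Hz (%d samples)>\n",
              x$duration, x$sampling_rate, length(x$samples)))
  invisible(x)
}

is_audio_signal <- function(x) inherits(x, "audio_signal")

#' Resample an audio signal
#'
#' Fourier-domain resampling to a new rate (truncation or zero-padding of the
#' spectrum). Used to align all recordings to the 4000 Hz analysis rate so
#' that spectrogram bins coincide across devices.
#'
#' @param signal An [audio_signal()].
#' @param rate Target sampling rate in Hz.
#' @return An `audio_signal` at the target rate.
#' @export
resample_signal <- function(signal, rate = 4000) {
  stopifnot(is_audio_signal(signal))
  if (signal$sampling_rate == rate) return(signal)
  n <- length(signal$samples)
  m <- max(2L, round(n * rate / signal$sampling_rate))
  X <- stats::fft(signal$samples)
  Y <- complex(m)
  # keep the lower half-spectrum common to both lengths, mirror for conjugate
  # symmetry; scale preserves amplitude (not energy)
  k <- min(floor(n / 2), floor(m / 2))
  Y[1] <- X[1]
  if (k >= 1) {
    Y[2:(k + 1)] <- X[2:(k + 1)]
    Y[(m - k + 1):m] <- X[(n - k + 1):n]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  audio_signal(y, rate)
}

#' Read a mono WAV file
#'
#' Supports PCM 16/24-bit and IEEE float 32-bit mono files. Stereo files are
#' rejected: pre-mix to mono before scoring.
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format    = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels  = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate      = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits      = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  if (fmt$channels != 1L)
    stop("stereo/multichannel WAV not supported; pre-mix to mono: ", path,
         call. = FALSE)
  samples <- switch(
    as.character(fmt$bits),
    "16" = {
      if (fmt$format != 1L) stop("unsupported 16-bit format code", call. = FALSE)
      readBin(data_raw, "integer", length(data_raw) / 2L, 2L, signed = TRUE,
              endian = "little") / 32768
    },
    "24" = {
      if (fmt$format != 1L) stop("unsupported 24-bit format code", call. = FALSE)
      b <- as.integer(data_raw)
      n <- length(b) %/% 3L
      v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] +
        65536 * b[seq(3, 3 * n, 3)]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$format != 3L)
        stop("32-bit WAV must be IEEE float (format 3)", call. = FALSE)
      readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
    },
    stop("unsupported WAV bit depth: ", fmt$bits, call. = FALSE)
  )
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bits Bit depth: 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16) {
  stopifnot(is_audio_signal(signal), bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(signal$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(signal$sampling_rate), con, 4, endian = "little")
  writeBin(as.integer(signal$sampling_rate * bytes_per), con, 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    v <- as.integer(round(pmax(-1, pmin(1, signal$samples)) * 32767))
    writeBin(v, con, 2, endian = "little")
  } else {
    writeBin(signal$samples, con, 4, endian = "little")
  }
  invisible(path)
}
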