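#' Short-time Fourier magnitude spectrogram
#'
#' Frames the signal with a Hann window and returns the one-sided magnitude
#' spectrogram. Defaults (256 ms window, 50% overlap) give a frequency
#' resolution of ~3.9 Hz — fine enough to place the 50 Hz lower band edge —
#' and >= 12 frames on a 3 s minimum recording.
#'
#' @param signal An [audio_signal()].
#' @param window_s Window length in seconds.
#' @param overlap Overlap fraction in \[0, 1).
#' @return A `spectral_power` object: `frame_times` (s, frame centers),
#'   `frequencies` (Hz), `magnitude` (frequency x time, nonnegative),
#'   `band_power` (filled after [band_power()]), plus windowing metadata.
#' @export
compute_spectrogram <- function(signal, window_s = 0.256, overlap = 0.5) {
  stopifnot(is_audio_signal(signal))
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  fs <- signal$sampling_rate
  n_win <- round(window_s * fs)
  x <- signal$samples
  if (length(x) < n_win)
    stop(sprintf("signal too short for analysis: %.3f s < %.3f s window",
                 signal$duration, window_s), call. = FALSE)
  hop <- max(1L, round(n_win * (1 - overlap)))
  starts <- seq(1L, length(x) - n_win + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_win) - 1) / (n_win - 1))
  nb <- floor(n_win / 2) + 1L
  mag <- matrix(0, nrow = nb, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + n_win - 1L)] * w
    mag[, j] <- Mod(stats::fft(seg))[1:nb]
  }
  structure(
    list(frame_times = (starts - 1 + n_win / 2) / fs,
         frequencies = (0:(nb - 1L)) * fs / n_win,
         magnitude = mag,
         band_power = NA_real_,
         window_samples = n_win,
         hop_samples = hop,
         window_ssq = sum(w^2),
         sampling_rate = fs),
    class = "spectral_power"
  )
}

#' @export
print.spectral_power <- function(x, ...) {
  cat(sprintf(
    "<spectral_power: %d freq bins x %d frames, df = %.2f Hz, band_power = %s>\n",
    nrow(x$magnitude), ncol(x$magnitude), x$frequencies[2] - x$frequencies[1],
    format(x$band_power)))
  invisible(x)
}

#' Band-pass and low-pass weighting of a spectrogram
#'
#' Applies the analysis filter chain as frequency-domain weights: a brick-wall
#' band-pass over \[`bandpass_low`, `bandpass_high`\] Hz followed by a 4th-order
#' Butterworth low-pass magnitude response with -3 dB at `lowpass_cutoff` Hz.
#' The net pass band at defaults is ~50-300 Hz, the range where fistula bruit
#' energy concentrates.
#'
#' @param spec A `spectral_power` from [compute_spectrogram()].
#' @param bandpass_low,bandpass_high Band-pass edges in Hz.
#' @param lowpass_cutoff Low-pass -3 dB frequency in Hz.
#' @param lowpass_order Butterworth order of the low-pass weight.
#' @return The spectrogram with filtered magnitudes.
#' @export
apply_band_filters <- function(spec, bandpass_low = 50, bandpass_high = 1500,
                               lowpass_cutoff = 300, lowpass_order = 4) {
  stopifnot(inherits(spec, "spectral_power"))
  nyquist <- spec$sampling_rate / 2
  if (!(0 < bandpass_low && bandpass_low < lowpass_cutoff &&
        lowpass_cutoff <= bandpass_high && bandpass_high < nyquist))
    stop("filter cutoffs must satisfy 0 < band_low < lowpass <= band_high < Nyquist",
         call. = FALSE)
  f <- spec$frequencies
  w <- as.numeric(f >= bandpass_low & f <= bandpass_high) /
    sqrt(1 + (f / lowpass_cutoff)^(2 * lowpass_order))
  spec$magnitude <- spec$magnitude * w
  spec$filter <- list(band = c(bandpass_low, bandpass_high),
                      lowpass = lowpass_cutoff, order = lowpass_order)
  spec
}

#' Time-averaged band power of a spectrogram
#'
#' Mean over frames of the frequency-integrated rectified magnitude
#' (magnitude convention: doubling the input amplitude doubles the power).
#'
#' @param spec A `spectral_power`.
#' @return Nonnegative scalar, also stored in `spec$band_power` by
#'   [compute_hvsi()].
#' @export
band_power <- function(spec) {
  stopifnot(inherits(spec, "spectral_power"))
  if (ncol(spec$magnitude) == 0L || nrow(spec$magnitude) == 0L)
    stop("empty spectrogram", call. = FALSE)
  df <- spec$frequencies[2] - spec$frequencies[1]
  mean(colSums(spec$magnitude) * df)
}
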