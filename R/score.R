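#' Analysis configuration
#'
#' Assembles the full analysis configuration, optionally merging a YAML file
#' over the defaults. Defaults: 256 ms Hann window with 50% overlap, 50-1500 Hz
#' band-pass then 300 Hz low-pass, 5 s analysis window after a 0.25 s onset
#' trim, resampling to 4000 Hz, and the packaged `default-v1` calibration.
#'
#' @param path Optional YAML file; keys mirror the defaults
#'   (`stft$window_s`, `stft$overlap`, `filter$band`, `filter$lowpass`,
#'   `calibration$p_min`/`p_max`/`id`, `analysis_window_s`, `onset_trim_s`,
#'   `target_rate`).
#' @param ... Named overrides applied after the file (e.g. `analysis_window_s = 4`).
#' @return A nested list of settings.
#' @export
hvsi_config <- function(path = NULL, ...) {
  cfg <- list(
    stft = list(window_s = 0.256, overlap = 0.5),
    filter = list(band = c(50, 1500), lowpass = 300, order = 4),
    calibration = hvsi_calibration(),
    analysis_window_s = 5,
    onset_trim_s = 0.25,
    target_rate = 4000
  )
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  cfg
}

#' Default score calibration
#'
#' The normalization constants mapping band power to the 0-999 index. The
#' `default-v1` constants were fitted once (scripts/calibrate.R) so that the
#' simulator's reference scenario spans the observed verification-cohort range:
#' a bruit at flow volume 160 mL/min scores ~41 and one at 3025 mL/min
#' saturates at 999.
#'
#' @param p_min,p_max Band powers mapped to index 0 and 999.
#' @param id Identifier recorded in every result for provenance.
#' @return A calibration list.
#' @export
hvsi_calibration <- function(p_min = .hvsi_default_cal$p_min,
                             p_max = .hvsi_default_cal$p_max,
                             id = .hvsi_default_cal$id) {
  if (!is.numeric(p_min) || !is.numeric(p_max) || !(p_min > 0) ||
      !(p_max > p_min))
    stop("invalid calibration: need 0 < p_min < p_max", call. = FALSE)
  list(p_min = p_min, p_max = p_max, id = id)
}

#' Normalize band power to the 0-999 index
#'
#' Logarithmic affine map with clipping:
#' `round(999 * clip((log10(p) - log10(p_min)) / (log10(p_max) - log10(p_min)), 0, 1))`
#' with round-half-up. Zero power maps to index 0 (silence), by convention.
#'
#' @param power Nonnegative band power (vectorized).
#' @param calibration A [hvsi_calibration()].
#' @return Integer index in \[0, 999\], monotone nondecreasing in `power`.
#' @export
normalize_to_index <- function(power, calibration = hvsi_calibration()) {
  if (any(!is.finite(power)) || any(power < 0))
    stop("`power` must be finite and nonnegative", call. = FALSE)
  calibration <- hvsi_calibration(calibration$p_min, calibration$p_max,
                                  calibration$id)
  frac <- (log10(pmax(power, .Machine$double.xmin)) - log10(calibration$p_min)) /
    (log10(calibration$p_max) - log10(calibration$p_min))
  frac[power == 0] <- 0
  as.integer(floor(999 * pmin(pmax(frac, 0), 1) + 0.5))
}

# fixed analysis epoch: first 5 s after a 0.25 s onset trim when the recording
# is long enough; recordings of 3 s and up are analyzed whole
trim_analysis_window <- function(signal, analysis_window_s = 5,
                                 onset_trim_s = 0.25) {
  if (signal$duration < 3)
    stop(sprintf("recording too short: %.2f s < 3 s minimum", signal$duration),
         call. = FALSE)
  fs <- signal$sampling_rate
  if (signal$duration >= analysis_window_s + onset_trim_s) {
    i0 <- round(onset_trim_s * fs) + 1L
    audio_signal(signal$samples[i0:(i0 + round(analysis_window_s * fs) - 1L)],
                 fs)
  } else signal
}

#' Compute the HVSI score for one or more recordings
#'
#' The full scoring chain per replicate: resample to the analysis rate, trim to
#' the analysis epoch, magnitude spectrogram, band-pass + low-pass weighting,
#' time-averaged rectified band power, logarithmic normalization to 0-999. The
#' clinical protocol records three replicates and averages; 1-3 are accepted.
#'
#' @param recordings An [audio_signal()] or list of 1-3 of them.
#' @param config A [hvsi_config()].
#' @return An `hvsi_result`: `replicate_scores` (integers in \[0, 999\]),
#'   `mean_score`, `band_power_per_replicate`, `calibration_id`.
#' @examples
#' rec <- simulate_bruit(bruit_scenario(flow_volume = 800, seed = 1))
#' compute_hvsi(rec)
#' @export
compute_hvsi <- function(recordings, config = hvsi_config()) {
  if (is_audio_signal(recordings)) recordings <- list(recordings)
  if (!is.list(recordings) || !length(recordings) %in% 1:3)
    stop("`recordings` must be 1-3 audio signals (3 is the standard protocol)",
         call. = FALSE)
  powers <- vapply(seq_along(recordings), function(i) {
    sig <- recordings[[i]]
    if (!is_audio_signal(sig))
      stop("replicate ", i, " is not an audio_signal", call. = FALSE)
    tryCatch({
      sig <- resample_signal(sig, config$target_rate)
      sig <- trim_analysis_window(sig, config$analysis_window_s,
                                  config$onset_trim_s)
      spec <- compute_spectrogram(sig, config$stft$window_s,
                                  config$stft$overlap)
      spec <- apply_band_filters(spec, config$filter$band[1],
                                 config$filter$band[2], config$filter$lowpass,
                                 config$filter$order)
      band_power(spec)
    }, error = function(e) {
      stop("replicate ", i, ": ", conditionMessage(e), call. = FALSE)
    })
  }, numeric(1))
  scores <- normalize_to_index(powers, config$calibration)
  structure(
    list(replicate_scores = scores,
         mean_score = mean(scores),
         band_power_per_replicate = powers,
         calibration_id = config$calibration$id),
    class = "hvsi_result"
  )
}

#' @export
print.hvsi_result <- function(x, ...) {
  cat(sprintf("HVSI %.1f (replicates: %s; calibration %s)\n", x$mean_score,
              paste(x$replicate_scores, collapse = ", "), x$calibration_id))
  invisible(x)
}
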