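test_that("audio_signal enforces its invariants", {
  expect_error(audio_signal(c(1, NA, 0), 4000), "non-finite")
  expect_error(audio_signal(c(1, Inf), 4000), "non-finite")
  expect_error(audio_signal(rnorm(100), 2000), "3000 Hz")
  s <- audio_signal(rnorm(8000), 4000)
  expect_equal(s$duration, 2)
})

test_that("spectrogram localizes a pure tone and meets resolution contracts", {
  spec <- compute_spectrogram(tone(200))
  expect_lte(spec$frequencies[2] - spec$frequencies[1], 10)
  expect_gte(ncol(spec$magnitude), 10)
  peak_bins <- apply(spec$magnitude, 2, which.max)
  expect_true(all(abs(spec$frequencies[peak_bins] - 200) <
                    spec$frequencies[2]))
  expect_true(all(spec$magnitude >= 0))
})

test_that("zero signal gives an identically zero spectrogram and band power", {
  spec <- compute_spectrogram(audio_signal(rep(0, 20000), 4000))
  expect_true(all(spec$magnitude == 0))
  expect_identical(band_power(spec), 0)
})

test_that("spectrogram errors on too-short input and bad overlap", {
  expect_error(compute_spectrogram(audio_signal(rnorm(500), 4000)),
               "too short")
  expect_error(compute_spectrogram(tone(200), overlap = 1), "overlap")
})

test_that("white-noise spectral energy matches the time-domain sum within 1%", {
  set.seed(42)
  x <- rnorm(80000)  # 20 s at 4 kHz
  sig <- audio_signal(x, 4000)
  spec <- compute_spectrogram(sig)
  # reconstruct full-spectrum energy from the one-sided magnitudes and undo
  # the FFT scaling: per frame, sum|X_k|^2 / N = windowed time-domain energy
  n_fft <- spec$window_samples
  full <- 2 * colSums(spec$magnitude^2) - spec$magnitude[1, ]^2 -
    spec$magnitude[nrow(spec$magnitude), ]^2
  spectral_energy <- sum(full) / n_fft
  # expected windowed energy for white noise: mean power x window ssq x frames
  covered <- (ncol(spec$magnitude) - 1) * spec$hop_samples + n_fft
  expected <- mean(x[1:covered]^2) * spec$window_ssq * ncol(spec$magnitude)
  expect_lt(abs(spectral_energy / expected - 1), 0.01)
})

test_that("band filters preserve the pass band and attenuate stop bands", {
  p_pass <- band_power(apply_band_filters(compute_spectrogram(tone(200))))
  p_raw <- band_power(compute_spectrogram(tone(200)))
  expect_lt(abs(p_pass / p_raw - 1), 0.05)

  # 1000 Hz tone: attenuation equals the 4th-order Butterworth magnitude
  # weight evaluated at 1000 Hz
  p1000 <- band_power(apply_band_filters(compute_spectrogram(tone(1000))))
  p1000_raw <- band_power(compute_spectrogram(tone(1000)))
  w1000 <- 1 / sqrt(1 + (1000 / 300)^8)
  expect_lt(abs(p1000 / p1000_raw / w1000 - 1), 0.10)

  # 20 Hz tone: below the band-pass, essentially removed
  p20 <- band_power(apply_band_filters(compute_spectrogram(tone(20))))
  p20_raw <- band_power(compute_spectrogram(tone(20)))
  expect_lt(p20 / p20_raw, 0.01)
})

test_that("filter cutoff ordering is validated", {
  spec <- compute_spectrogram(tone(200))
  expect_error(apply_band_filters(spec, bandpass_low = 400,
                                  lowpass_cutoff = 300), "cutoffs")
  expect_error(apply_band_filters(spec, bandpass_high = 3000), "cutoffs")
})

test_that("band power is the mean frequency-integrated magnitude", {
  # hand-built 3 x 2 spectrogram, df = 10 Hz:
  # frame sums 10*(1+2+3) = 60 and 10*(4+5+6) = 150; mean = 105
  spec <- structure(list(frame_times = c(0, 1), frequencies = c(0, 10, 20),
                         magnitude = matrix(1:6, nrow = 3),
                         sampling_rate = 4000),
                    class = "spectral_power")
  expect_equal(band_power(spec), 105)
  spec$magnitude <- spec$magnitude[, 0, drop = FALSE]
  expect_error(band_power(spec), "empty")
})

test_that("band power scales linearly with input amplitude", {
  s1 <- tone(200, amp = 0.3)
  s2 <- tone(200, amp = 0.6)
  p1 <- band_power(apply_band_filters(compute_spectrogram(s1)))
  p2 <- band_power(apply_band_filters(compute_spectrogram(s2)))
  expect_equal(p2 / p1, 2, tolerance = 1e-10)
})

test_that("normalization maps powers to the 0-999 index as specified", {
  cal <- hvsi_calibration(p_min = 10, p_max = 1000, id = "test")
  expect_identical(normalize_to_index(10, cal), 0L)
  expect_identical(normalize_to_index(1000, cal), 999L)
  # log-midpoint: raw value 499.5 rounds half-up to 500
  expect_identical(normalize_to_index(sqrt(10 * 1000), cal), 500L)
  expect_identical(normalize_to_index(5000, cal), 999L)  # clipped
  expect_identical(normalize_to_index(1, cal), 0L)       # clipped
  expect_identical(normalize_to_index(0, cal), 0L)       # silence convention
  expect_error(normalize_to_index(-1, cal), "nonnegative")
  expect_error(hvsi_calibration(p_min = 5, p_max = 5), "calibration")
})

test_that("normalization is monotone nondecreasing in power", {
  cal <- hvsi_calibration(p_min = 2, p_max = 777, id = "test")
  p <- sort(c(0, exp(seq(log(0.1), log(5000), length.out = 200))))
  idx <- normalize_to_index(p, cal)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= 0 & idx <= 999))
})

test_that("compute_hvsi chains the pipeline and averages replicates", {
  rec <- simulate_bruit(bruit_scenario(flow_volume = 800, seed = 3))
  one <- compute_hvsi(rec)
  three <- compute_hvsi(list(rec, rec, rec))
  expect_identical(three$replicate_scores, rep(one$replicate_scores, 3))
  expect_equal(three$mean_score, one$mean_score)
  expect_equal(three$mean_score, mean(three$replicate_scores))
  expect_identical(three$calibration_id, "default-v1")
  expect_true(all(three$replicate_scores == floor(three$replicate_scores)))
})

test_that("compute_hvsi is deterministic and identifies bad replicates", {
  rec <- simulate_bruit(bruit_scenario(flow_volume = 500, seed = 9))
  expect_identical(compute_hvsi(rec)$mean_score, compute_hvsi(rec)$mean_score)
  short <- audio_signal(rnorm(4000), 4000)  # 1 s < 3 s minimum
  expect_error(compute_hvsi(list(rec, short)), "replicate 2")
  expect_error(compute_hvsi(list()), "1-3")
})

test_that("high-flow bruit outscores low-flow bruit (Table 2 extremes)", {
  hi <- compute_hvsi(lapply(1:3, function(s)
    simulate_bruit(bruit_scenario(3000, seed = s))))
  lo <- compute_hvsi(lapply(1:3, function(s)
    simulate_bruit(bruit_scenario(160, seed = s))))
  expect_gt(hi$mean_score, lo$mean_score)
})

test_that("scaling input amplitude never decreases the score", {
  base <- simulate_bruit(bruit_scenario(600, seed = 4))
  scores <- vapply(c(0.25, 0.5, 1, 2, 4), function(k)
    compute_hvsi(audio_signal(base$samples * k,
                              base$sampling_rate))$mean_score,
    numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("YAML config merges over defaults", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("stft:", "  window_s: 0.128", "analysis_window_s: 4"), tf)
  cfg <- hvsi_config(tf)
  expect_equal(cfg$stft$window_s, 0.128)
  expect_equal(cfg$stft$overlap, 0.5)   # default retained
  expect_equal(cfg$analysis_window_s, 4)
  cfg2 <- hvsi_config(onset_trim_s = 0)
  expect_equal(cfg2$onset_trim_s, 0)
})
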