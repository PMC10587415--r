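test_that("band-pass removes DC and respiration, keeps in-band tones", {
  fs <- 1000
  t <- seq(0, 60, by = 1 / fs)
  band <- c(1.25, 15)
  # DC offset is eliminated
  y0 <- bandpass_filter(rep(2.5, length(t)), fs, band)
  expect_lt(max(abs(y0)), 1e-6)
  y0b <- bandpass_filter(rep(2.5, length(t)) + sin(2 * pi * 3 * t), fs, band)
  expect_lt(abs(mean(y0b[t > 20 & t < 40])), 1e-3)
  # 0.25 Hz respiration tone: attenuation agrees with the analytic
  # Butterworth magnitude (two passes); compare on the middle stretch
  mid <- t > 20 & t < 40
  x <- sin(2 * pi * 0.25 * t)
  y <- bandpass_filter(x, fs, band)
  att <- max(abs(y[mid])) / 1
  att_analytic <- butterworth_bandpass_gain(0.25, band, order = 6, passes = 2)
  expect_lt(att, 1e-3)
  expect_lt(abs(log10(att) - log10(att_analytic)), 1)
  # 5 Hz in-band tone preserved within 5%
  x5 <- sin(2 * pi * 5 * t)
  y5 <- bandpass_filter(x5, fs, band)
  expect_equal(max(abs(y5[mid])), 1, tolerance = 0.05)
  expect_error(bandpass_filter(x5, fs, c(0, 15)), "band")
  expect_error(bandpass_filter(x5, fs, c(1.25, 600)), "band")
})

test_that("attenuation at half the low cutoff is at least 20 dB", {
  fs <- 500
  t <- seq(0, 80, by = 1 / fs)
  for (band in list(c(0.7, 40), c(1.25, 15))) {
    x <- sin(2 * pi * (band[1] / 2) * t)
    y <- bandpass_filter(x, fs, band)
    expect_lt(20 * log10(max(abs(y[t > 30 & t < 50]))), -20)
  }
})

test_that("zero-phase filtering preserves a symmetric pulse's center", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  center <- 10
  x <- exp(-(t - center)^2 / (2 * 0.05^2))
  y <- bandpass_filter(x, fs, c(1.25, 15))
  expect_lt(abs(t[which.max(y)] - center), 1 / fs + 1e-9)
})

test_that("R peaks are recovered on synthetic ECG, clean and noisy", {
  spec <- synthetic_spec(HR = 75, n_beats = 60, jitter_sd = 0.02, seed = 11)
  e <- synth_ecg(spec)
  ecgf <- bandpass_filter(e$ecg, e$fs, c(0.7, 40))
  idx <- detect_r_peaks(ecgf, e$fs)
  expect_length(idx, 60)
  expect_lt(max(abs((idx - 1) / e$fs - e$r_times)), 0.010)
  # flat signal: no detections
  expect_warning(empty <- detect_r_peaks(numeric(5000), 1000), "no R peaks")
  expect_length(empty, 0)
  # additive noise at 0.2 x R amplitude: perfect sensitivity and precision
  set.seed(7)
  noisy <- bandpass_filter(e$ecg + rnorm(length(e$ecg), 0, 0.2), e$fs,
                           c(0.7, 40))
  idx_n <- detect_r_peaks(noisy, e$fs)
  matched <- vapply(e$r_times,
                    function(rt) min(abs((idx_n - 1) / e$fs - rt)) < 0.05,
                    logical(1))
  expect_true(all(matched))          # sensitivity 1.0
  expect_length(idx_n, 60)           # precision 1.0
})

test_that("segmentation yields one beat per RR interval", {
  fs <- 500
  r_idx <- seq(1, by = 400, length.out = 61)   # 61 R peaks, RR = 0.8 s
  tpl <- bcg_template(fs)
  bcg <- numeric(max(r_idx) + 400)
  for (s in r_idx) bcg[s:(s + length(tpl) - 1)] <- tpl
  ens <- segment_beats(bcg, r_idx, fs)
  expect_equal(nrow(ens$beats), 60)
  expect_true(all(ens$ok))
  # identical template at every R: every row equals the template
  expect_equal(max(abs(sweep(ens$beats, 2, tpl))), 0)
  # window longer than RR: beats flagged, not padded
  ens2 <- segment_beats(bcg, r_idx, fs, window = c(0, 0.9))
  expect_true(all(!ens2$ok))
  expect_equal(ncol(ens2$beats), round(0.9 * fs))
  expect_error(segment_beats(bcg, r_idx[1], fs), "2 R peaks")
})

test_that("ensemble mean reduces noise at the standard-error rate", {
  fs <- 500
  tpl <- bcg_template(fs)
  n <- 60; sigma <- 0.3
  set.seed(123)
  beats <- matrix(rep(tpl, each = n) + rnorm(n * length(tpl), 0, sigma),
                  nrow = n)
  ens <- structure(list(beats = beats, fs = fs, window = c(0, 0.7),
                        ok = rep(TRUE, n), r_idx = seq_len(n)),
                   class = "beat_ensemble")
  m <- ensemble_average(ens)
  expect_lt(sqrt(mean((m - tpl)^2)), 3 * sigma / sqrt(n))
  # identical beats: mean equals the beat; opposite pair: zero
  ens$beats <- matrix(rep(tpl, each = 4), nrow = 4)
  expect_equal(ensemble_average(structure(modifyList(ens, list(ok = rep(TRUE, 4))),
                                          class = "beat_ensemble")), tpl)
  pairs <- structure(list(beats = rbind(tpl, -tpl), fs = fs,
                          window = c(0, 0.7), ok = c(TRUE, TRUE)),
                     class = "beat_ensemble")
  expect_equal(ensemble_average(pairs), tpl * 0)
})

test_that("waveform comparison metrics behave on constructed cases", {
  fs <- 1000
  tpl <- bcg_template(fs)
  same <- compare_waveforms(tpl, tpl, fs)
  expect_equal(same$systolic$rmse, 0)
  expect_equal(same$full$r, 1)
  scaled <- compare_waveforms(2 * tpl, tpl, fs)
  expect_equal(scaled$full$r, 1)
  expect_gt(scaled$full$rmse, 0)
  shifted <- compare_waveforms(c(numeric(30), tpl[1:(length(tpl) - 30)]),
                               tpl, fs)
  expect_equal(shifted$systolic$peak_offset_s, 0.030, tolerance = 1e-6)
  expect_error(compare_waveforms(tpl, tpl[-1], fs), "common grid")
})
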