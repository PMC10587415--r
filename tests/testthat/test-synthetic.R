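test_that("synthetic ECG has exact RR spacing without jitter", {
  spec <- synthetic_spec(HR = 75, n_beats = 10, jitter_sd = 0, seed = 1)
  e <- synth_ecg(spec)
  expect_equal(diff(e$r_times), rep(0.8, 9))
  specf <- synthetic_spec(HR = 78.75, n_beats = 10, jitter_sd = 0, seed = 1)
  expect_equal(diff(synth_ecg(specf)$r_times), rep(60 / 78.75, 9))
})

test_that("generation is reproducible from the seed alone", {
  spec <- synthetic_spec(HR = 75, n_beats = 20, jitter_sd = 0.02, seed = 99)
  e1 <- synth_ecg(spec); e2 <- synth_ecg(spec)
  expect_identical(e1$ecg, e2$ecg)
  b1 <- synth_bcg(spec, e1$r_times, e1$t)
  b2 <- synth_bcg(spec, e2$r_times, e2$t)
  expect_identical(b1, b2)
  # and does not disturb the caller's RNG stream
  set.seed(5); x1 <- rnorm(3)
  set.seed(5); invisible(synth_ecg(spec)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("RR jitter has the requested dispersion", {
  spec <- synthetic_spec(HR = 75, n_beats = 200, jitter_sd = 0.02, seed = 42)
  e <- synth_ecg(spec)
  expect_equal(sd(diff(e$r_times)), 0.02, tolerance = 0.2)
})

test_that("noiseless BCG recovers the template exactly at true R times", {
  spec <- synthetic_spec(HR = 75, n_beats = 12, jitter_sd = 0,
                         noise_sd = 0, resp_amp = 0, seed = 3)
  e <- synth_ecg(spec)
  bcg <- synth_bcg(spec, e$r_times, e$t)
  ens <- segment_beats(bcg, round(e$r_times * spec$fs) + 1L, spec$fs)
  expect_equal(max(abs(sweep(ens$beats, 2, spec$template))), 0)
})

test_that("band-pass filtering crushes the respiration component", {
  spec <- synthetic_spec(HR = 75, n_beats = 30, jitter_sd = 0,
                         noise_sd = 0, resp_amp = 5, seed = 8)
  e <- synth_ecg(spec)
  bcg <- synth_bcg(spec, e$r_times, e$t)
  filtered <- bandpass_filter(bcg, spec$fs, c(1.25, 15))
  clean <- synth_bcg(modifyList(spec, list(resp_amp = 0)), e$r_times, e$t)
  mid <- e$t > 5 & e$t < max(e$t) - 5
  resid <- filtered[mid] - bandpass_filter(clean, spec$fs, c(1.25, 15))[mid]
  expect_lt(mean(resid^2), 0.01 * mean(clean[mid]^2))
})

test_that("ensemble-mean amplitude is linear in template amplitude", {
  mk <- function(amp) {
    spec <- synthetic_spec(HR = 75, n_beats = 40, jitter_sd = 0.01,
                           template = bcg_template(1000, amplitude = amp),
                           noise_sd = 0.1, seed = 21)
    e <- synth_ecg(spec)
    bcg <- synth_bcg(spec, e$r_times, e$t)
    ens <- segment_beats(bandpass_filter(bcg, spec$fs, c(1.25, 15)),
                         round(e$r_times * spec$fs) + 1L, spec$fs)
    m <- ensemble_average(ens)
    diff(range(m))
  }
  expect_equal(mk(2) / mk(1), 2, tolerance = 0.05)
})

test_that("full pipeline recovers HR, template shape and amplitude", {
  spec <- synthetic_spec(HR = 75, n_beats = 60, jitter_sd = 0.02,
                         noise_sd = 0.3, seed = 17)
  e <- synth_ecg(spec)
  bcg <- synth_bcg(spec, e$r_times, e$t)
  ecgf <- bandpass_filter(e$ecg, spec$fs, c(0.7, 40))
  bcgf <- bandpass_filter(bcg, spec$fs, c(1.25, 15))
  idx <- detect_r_peaks(ecgf, spec$fs)
  hr_est <- 60 / mean(diff((idx - 1) / spec$fs))
  expect_equal(hr_est, 75, tolerance = 0.01)
  ens <- segment_beats(bcgf, idx, spec$fs)
  m <- ensemble_average(ens)
  tpl_f <- bandpass_filter(spec$template, spec$fs, c(1.25, 15))
  expect_gt(cor(m, tpl_f), 0.98)
  expect_equal(diff(range(m)), diff(range(tpl_f)), tolerance = 0.05)
})

test_that("spec validation enforces its invariants", {
  expect_error(synthetic_spec(HR = 75), "seed")
  expect_error(synthetic_spec(HR = 75, fs = 50, seed = 1), "fs")
  expect_error(synthetic_spec(HR = 75, jitter_sd = 0.2, seed = 1), "jitter")
})

test_that("fixtures carry model templates and reproduce byte-identically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  tpl <- bandpass_filter(bcg_template(1000, amplitude = 2e5), 1000,
                         c(1.25, 15))
  fx1 <- make_fixture("female", seed = 7, dir = dir1, n_beats = 20,
                      template = tpl)
  fx2 <- make_fixture("female", seed = 7, dir = dir2, n_beats = 20,
                      template = tpl)
  expect_identical(readLines(fx1$recording), readLines(fx2$recording))
  truth <- jsonlite::read_json(fx1$truth, simplifyVector = TRUE)
  expect_equal(truth$HR, 78.75)
  expect_equal(mean(diff(truth$r_times)), 60 / 78.75, tolerance = 0.02)
  rec <- read.csv(fx1$recording)
  expect_named(rec, c("time_s", "ecg", "bcg"))
})

test_that("pipeline recovers the model male/female amplitude ratio", {
  fs <- 1000
  mk_tpl <- function(version) {
    b <- bcg_waveform(sim_version(version), scale = shared_cal()$bcg_scale)
    keep <- b$t <= 0.7
    tpl <- approx(b$t[keep], b$F[keep], rule = 2,
                  xout = seq(0, 0.7 - 1 / fs, by = 1 / fs))$y
    tpl - tpl[1]
  }
  recover <- function(version, tpl, seed) {
    fx <- make_fixture(version, seed = seed, dir = withr::local_tempdir(),
                       n_beats = 40, template = tpl)
    rec <- read.csv(fx$recording)
    idx <- detect_r_peaks(bandpass_filter(rec$ecg, fs, c(0.7, 40)), fs)
    m <- ensemble_average(
      segment_beats(bandpass_filter(rec$bcg, fs, c(1.25, 15)), idx, fs))
    diff(range(m))
  }
  tpl_m <- mk_tpl("idealized_male"); tpl_f <- mk_tpl("idealized_female")
  ratio_model <- diff(range(tpl_f)) / diff(range(tpl_m))
  ratio_rec <- recover("female", tpl_f, 31) / recover("male", tpl_m, 32)
  expect_equal(ratio_rec, ratio_model, tolerance = 0.08)
})
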