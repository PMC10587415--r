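# run code under a local RNG stream without touching the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic ECG+BCG recording
#'
#' Defines the ground-truth structure of a synthetic paired recording:
#' heart rate with i.i.d. Gaussian RR jitter, number of beats, sampling
#' rate, the per-beat BCG template, additive white noise (as a fraction of
#' the template peak-to-peak), and a respiration sinusoid. A seed is
#' mandatory; all randomness flows from it.
#'
#' @param HR heart rate (beats/min).
#' @param n_beats number of beats.
#' @param fs sampling rate (Hz), at least 100.
#' @param jitter_sd RR jitter standard deviation (s), below 0.1 RR.
#' @param template numeric vector, the per-beat BCG template sampled at
#'   `fs`; default a parametric tri-phasic wavelet ([bcg_template()]).
#' @param noise_sd BCG noise standard deviation as a fraction of the
#'   template peak-to-peak, default 0.3.
#' @param resp_hz respiration frequency (Hz), default 0.25.
#' @param resp_amp respiration amplitude as a fraction of the template
#'   peak-to-peak, default 1.
#' @param seed integer seed (mandatory).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(HR = 75, n_beats = 60, fs = 1000, jitter_sd = 0.02,
                           template = NULL, noise_sd = 0.3, resp_hz = 0.25,
                           resp_amp = 1, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("`seed` is mandatory for reproducibility", call. = FALSE)
  if (fs < 100) stop("`fs` must be at least 100 Hz", call. = FALSE)
  rr <- cycle_length_from_hr(HR)
  if (jitter_sd >= 0.1 * rr)
    stop("`jitter_sd` must be below 0.1 * RR", call. = FALSE)
  if (is.null(template)) template <- bcg_template(fs)
  if (length(template) > rr * fs)
    stop("template longer than the RR interval", call. = FALSE)
  structure(list(HR = HR, RR = rr, n_beats = as.integer(n_beats), fs = fs,
                 jitter_sd = jitter_sd, template = template,
                 noise_sd = noise_sd, resp_hz = resp_hz,
                 resp_amp = resp_amp, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Parametric tri-phasic BCG beat template
#'
#' A smooth stand-in for a single BCG beat: negative I wave, dominant
#' positive J wave, negative K wave, modelled as three Gaussian lobes in
#' the systolic phase.
#'
#' @param fs sampling rate (Hz).
#' @param duration template length (s), default 0.7.
#' @param amplitude J-wave amplitude (arbitrary units).
#' @return numeric vector of length `duration * fs`.
#' @export
bcg_template <- function(fs, duration = 0.7, amplitude = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  g <- function(mu, sd) exp(-(t - mu)^2 / (2 * sd^2))
  amplitude * (-0.5 * g(0.10, 0.02) + 1.0 * g(0.16, 0.025) -
                 0.6 * g(0.23, 0.03) + 0.15 * g(0.35, 0.05))
}

#' Synthesize an ECG channel with known R-peak times
#'
#' Narrow Gaussian QRS pulses at R times given by cumulative jittered RR
#' intervals, plus respiratory baseline wander (added before any
#' filtering).
#'
#' @param spec a `synthetic_spec`.
#' @return list with `t` (s), `ecg`, `r_times` (s), `fs`.
#' @export
synth_ecg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    rr <- spec$RR + stats::rnorm(spec$n_beats, 0, spec$jitter_sd)
    r_times <- 0.5 * spec$RR + cumsum(c(0, rr[-spec$n_beats]))
    dur <- r_times[spec$n_beats] + spec$RR
    t <- seq(0, dur, by = 1 / spec$fs)
    ecg <- 0.15 * sin(2 * pi * spec$resp_hz * t)
    for (rt in r_times)
      ecg <- ecg + exp(-(t - rt)^2 / (2 * 0.008^2))
    list(t = t, ecg = ecg, r_times = r_times, fs = spec$fs)
  })
}

#' Synthesize a BCG channel from a beat template
#'
#' Inserts the ground-truth template at each R time, then adds white
#' Gaussian noise and a respiration sinusoid (both scaled to the template
#' peak-to-peak amplitude as specified).
#'
#' @param spec a `synthetic_spec`.
#' @param r_times true R-peak times (s), from [synth_ecg()].
#' @param t time grid (s) of the recording.
#' @return numeric vector, the BCG channel on `t`.
#' @export
synth_bcg <- function(spec, r_times, t) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p2p <- diff(range(spec$template))
  ntpl <- length(spec$template)
  bcg <- numeric(length(t))
  fs <- spec$fs
  for (rt in r_times) {
    s <- round(rt * fs) + 1L
    e <- min(s + ntpl - 1L, length(bcg))
    if (s <= length(bcg))
      bcg[s:e] <- bcg[s:e] + spec$template[seq_len(e - s + 1L)]
  }
  with_seed(spec$seed + 1L, {
    bcg + spec$resp_amp * p2p * sin(2 * pi * spec$resp_hz * t) +
      stats::rnorm(length(t), 0, spec$noise_sd * p2p)
  })
}

#' Write a synthetic paired recording to disk
#'
#' Generates a male- or female-profile recording (heart rate 75 or 78.75
#' beats/min; BCG beat template taken from the corresponding calibrated
#' model simulation) and writes a CSV recording plus a ground-truth JSON
#' sidecar.
#'
#' @param profile `"male"` or `"female"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param n_beats number of beats, default 60.
#' @param fs sampling rate (Hz), default 1000.
#' @param shared shared parameter set for the model template, default the
#'   frozen calibrated set.
#' @param template optional pre-computed template (skips the simulation).
#' @return invisibly, list with paths `recording` and `truth`, plus the
#'   spec used.
#' @export
make_fixture <- function(profile = c("male", "female"), seed, dir = tempdir(),
                         n_beats = 60, fs = 1000, shared = calibrated_params(),
                         template = NULL) {
  profile <- match.arg(profile)
  version <- paste0("idealized_", profile)
  if (is.null(template)) {
    sim <- simulate_circuit(cv_config(version, shared))
    b <- bcg_waveform(sim, scale = shared$bcg_scale)
    keep <- b$t <= 0.7
    template <- stats::approx(b$t[keep], b$F[keep], rule = 2,
                              xout = seq(0, min(0.7, max(b$t[keep])),
                                         by = 1 / fs))$y
    template <- template - template[1]
  }
  spec <- synthetic_spec(HR = if (profile == "male") 75 else 78.75,
                         n_beats = n_beats, fs = fs, template = template,
                         seed = seed)
  e <- synth_ecg(spec)
  bcg <- synth_bcg(spec, e$r_times, e$t)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, paste0("recording_", profile, ".csv"))
  truth_path <- file.path(dir, paste0("truth_", profile, ".json"))
  utils::write.csv(data.frame(time_s = e$t, ecg = e$ecg, bcg = bcg),
                   rec_path, row.names = FALSE)
  jsonlite::write_json(
    list(profile = profile, HR = spec$HR, fs = fs, seed = seed,
         r_times = e$r_times, template = spec$template),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(recording = rec_path, truth = truth_path, spec = spec))
}
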