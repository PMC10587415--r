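#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters a signal with a Butterworth design of the stated
#' overall order (an even number; the analog low-pass prototype has
#' `order/2` poles, which the band-pass transform doubles). The filter is
#' applied forward-backward ([signal::filtfilt()]), so the net response is
#' the squared magnitude with zero phase shift: timing of peaks is
#' preserved, which beat-ensemble comparisons rely on.
#'
#' Defaults match the recording pipeline: ECG band 0.7-40 Hz, BCG band
#' 1.25-15 Hz, order 6.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band length-2 numeric, band edges (Hz), inside `(0, fs/2)`.
#' @param order overall band-pass order (even), default 6.
#' @return filtered signal, same length.
#' @export
bandpass_filter <- function(x, fs, band, order = 6) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("`band` must satisfy 0 < low < high < fs/2", call. = FALSE)
  if (order %% 2 != 0 || order < 2)
    stop("`order` must be a positive even number", call. = FALSE)
  bf <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  # the mean is deep in the stop band; removing it first shortens the
  # start/end transients of the forward-backward pass
  signal::filtfilt(bf, x - mean(x))
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Magnitude of the analog Butterworth band-pass prototype of the given
#' overall order at frequency `f`; with `passes = 2` the squared response
#' of a forward-backward application. Used as an independent check of the
#' digital filter's attenuation.
#'
#' @param f frequency (Hz), vectorized.
#' @param band band edges (Hz).
#' @param order overall band-pass order (even).
#' @param passes number of filter passes (2 = zero-phase application).
#' @return magnitude response in `[0, 1]`.
#' @export
butterworth_bandpass_gain <- function(f, band, order = 6, passes = 1) {
  n <- order / 2
  x <- (f^2 - band[1] * band[2]) / (f * (band[2] - band[1]))
  (1 / sqrt(1 + x^(2 * n)))^passes
}

#' Detect R peaks in a filtered ECG
#'
#' Adaptive-threshold local-maximum detector: candidate samples exceed a
#' fraction of a high quantile of the signal, are local maxima, and are
#' separated by a refractory period (strongest peak wins within the
#' refractory window).
#'
#' @param ecg filtered ECG signal.
#' @param fs sampling rate (Hz).
#' @param refractory minimum peak separation (s), default 0.3.
#' @param threshold_frac threshold as a fraction of the 99th percentile of
#'   the positive signal, default 0.4.
#' @return integer vector of R-peak sample indices (possibly empty, with a
#'   warning when nothing is found).
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.3, threshold_frac = 0.4) {
  n <- length(ecg)
  if (n < 3L || max(ecg) <= 0 || stats::sd(ecg) == 0) {
    warning("no R peaks found", call. = FALSE)
    return(integer(0))
  }
  thr <- threshold_frac * stats::quantile(ecg, 0.99, names = FALSE)
  if (thr <= 0) {
    warning("no R peaks found", call. = FALSE)
    return(integer(0))
  }
  mid <- 2:(n - 1)
  cand <- mid[ecg[mid] >= thr & ecg[mid] >= ecg[mid - 1] &
                ecg[mid] >= ecg[mid + 1]]
  if (length(cand) == 0L) {
    warning("no R peaks found", call. = FALSE)
    return(integer(0))
  }
  gap <- round(refractory * fs)
  # greedy by amplitude: strongest candidates first, suppress neighbours
  ord <- cand[order(ecg[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0L || all(abs(taken - i) >= gap))
      taken <- c(taken, i)
  }
  sort(taken)
}

#' Segment a BCG signal into beats at ECG R peaks
#'
#' Cuts one fixed-length window per R-to-R interval (the last R peak
#' anchors no beat). Beats whose window runs past the end of the recording
#' are dropped; beats whose window is longer than their own RR interval
#' are kept but flagged (the window then overlaps the next beat).
#'
#' @param bcg filtered BCG signal.
#' @param r_idx R-peak sample indices (ascending).
#' @param fs sampling rate (Hz).
#' @param window beat window relative to the R peak (s), default
#'   `c(0, 0.7)`.
#' @return object of class `beat_ensemble`: list with `beats`
#'   (n_beats x window-length matrix), `fs`, `window`, `ok` (per-beat
#'   quality flag: window fits inside the beat's RR interval), `r_idx`.
#' @export
segment_beats <- function(bcg, r_idx, fs, window = c(0, 0.7)) {
  if (length(r_idx) < 2L)
    stop("cannot segment: need at least 2 R peaks", call. = FALSE)
  len <- round((window[2] - window[1]) * fs)
  off <- round(window[1] * fs)
  starts <- r_idx[-length(r_idx)] + off
  rr <- diff(r_idx)
  inside <- starts >= 1 & (starts + len - 1) <= length(bcg)
  starts <- starts[inside]
  beats <- t(vapply(starts, function(s) bcg[s:(s + len - 1)],
                    numeric(len)))
  structure(list(beats = beats, fs = fs, window = window,
                 ok = rr[inside] >= len + off,
                 r_idx = r_idx[-length(r_idx)][inside]),
            class = "beat_ensemble")
}

#' @export
print.beat_ensemble <- function(x, ...) {
  cat(sprintf("<beat_ensemble> %d beats x %d samples (%.2f s window), %d flagged\n",
              nrow(x$beats), ncol(x$beats), diff(x$window), sum(!x$ok)))
  invisible(x)
}

#' Ensemble-mean beat
#'
#' Pointwise arithmetic mean of the quality-passing beats of an ensemble.
#'
#' @param ens a `beat_ensemble`.
#' @param use_flagged include flagged beats too (default FALSE).
#' @return numeric vector, the mean beat.
#' @export
ensemble_average <- function(ens, use_flagged = FALSE) {
  stopifnot(inherits(ens, "beat_ensemble"))
  rows <- if (use_flagged) rep(TRUE, nrow(ens$beats)) else ens$ok
  if (!any(rows)) stop("no usable beats", call. = FALSE)
  colMeans(ens$beats[rows, , drop = FALSE])
}

#' Compare a model-predicted beat with a measured ensemble-mean beat
#'
#' Both beats must be sampled on a common grid and expressed in the same
#' units. Agreement metrics are reported separately for the systolic
#' window (default 0-0.3 s) and the full window, since model fidelity is
#' systole-specific.
#'
#' @param model_beat numeric vector.
#' @param measured_beat numeric vector, same length.
#' @param fs sampling rate (Hz).
#' @param systolic systolic window (s), default `c(0, 0.3)`.
#' @return list with elements `systolic` and `full`, each containing
#'   `rmse`, `r` (Pearson), `peak_offset_s` (model peak time minus
#'   measured peak time within the window).
#' @export
compare_waveforms <- function(model_beat, measured_beat, fs,
                              systolic = c(0, 0.3)) {
  if (length(model_beat) != length(measured_beat))
    stop("beats must be resampled to a common grid", call. = FALSE)
  t <- (seq_along(model_beat) - 1) / fs
  one <- function(idx) {
    a <- model_beat[idx]; b <- measured_beat[idx]
    list(rmse = sqrt(mean((a - b)^2)),
         r = if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
             else stats::cor(a, b),
         peak_offset_s = t[idx][which.max(a)] - t[idx][which.max(b)])
  }
  list(systolic = one(which(t >= systolic[1] & t <= systolic[2])),
       full = one(seq_along(t)))
}
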