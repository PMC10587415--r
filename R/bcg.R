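#' Default head-to-foot compartment coordinates
#'
#' Body-centered centroid coordinate (cm, cranial positive) of each
#' compartment's blood volume, used to convert simulated volume
#' redistribution into center-of-mass motion. Only relative amplitudes and
#' timings of the synthesized force are model claims; the absolute scale is
#' absorbed by a single global position-scale factor calibrated to the male
#' amplitude anchor.
#'
#' The ventricles, pulmonary compartments and the venous pool drain and
#' fill through vessels that meet at the heart, so they share near-heart
#' coordinates (their mutual transfers move blood over a short lever);
#' the arterial segments carry their anatomical centroids, and the
#' microcirculatory beds sit at the centroids of the regions they perfuse.
#'
#' @return named numeric vector over the 14 model compartments (cm).
#' @export
default_y_pos <- function() {
  c(lv = 10, asc_aorta = 12, aortic_arch = 14, carotid = 40,
    thoracic_aorta = 0, abdominal_aorta = -12, iliac = -25,
    upper_micro = 45, lower_micro = -60, sys_veins = 8,
    rv = 10, pulm_artery = 10, pulm_micro = 10, pulm_veins = 10)
}

#' Center-of-mass displacement from compartment volumes
#'
#' `y_cm(t) = (rho_b / M_body) * sum_j y_j * V_j(t)`, reported mean-centered
#' (the additive constant is irrelevant to the force).
#'
#' @param V matrix of compartment volumes (mL), one column per compartment.
#' @param y_pos named numeric vector of compartment coordinates (cm);
#'   names must match `colnames(V)`.
#' @param rho blood density (g/cm^3).
#' @param M_body body mass (g).
#' @return numeric vector, mean-centered displacement (cm).
#' @export
center_of_mass_displacement <- function(V, y_pos, rho = 1.05, M_body = 75e3) {
  if (M_body <= 0) stop("`M_body` must be positive", call. = FALSE)
  if (is.null(colnames(V)) || !setequal(colnames(V), names(y_pos)))
    stop("compartment names of `V` and `y_pos` must match", call. = FALSE)
  y <- drop(V[, names(y_pos), drop = FALSE] %*% y_pos) * rho / M_body
  y - mean(y)
}

#' Body force from center-of-mass motion
#'
#' `F(t) = M_body * d2 y_cm / dt2`, estimated on a uniform grid by a
#' five-point central second-difference stencil after light zero-phase
#' low-pass smoothing (Butterworth, default cutoff 25 Hz) to suppress
#' differentiation noise. With `y_cm` in cm, `M_body` in g and `dt` in s
#' the force is in dyne.
#'
#' @param y_cm uniformly sampled displacement (cm).
#' @param dt sampling interval (s).
#' @param M_body body mass (g).
#' @param smooth_hz low-pass cutoff (Hz); `NULL` disables smoothing.
#' @return numeric vector of force (dyne), same length as `y_cm` (stencil
#'   edges filled by one-sided copies).
#' @export
bcg_force <- function(y_cm, dt, M_body = 75e3, smooth_hz = 25) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive scalar (uniform sampling)", call. = FALSE)
  y <- y_cm - mean(y_cm)   # additive level is irrelevant to d2/dt2
  if (!is.null(smooth_hz)) {
    fs <- 1 / dt
    bf <- signal::butter(4, smooth_hz / (fs / 2), type = "low")
    y <- signal::filtfilt(bf, y)
  }
  n <- length(y)
  if (n < 5L) stop("need at least 5 samples", call. = FALSE)
  d2 <- numeric(n)
  idx <- 3:(n - 2)
  d2[idx] <- (-y[idx - 2] + 16 * y[idx - 1] - 30 * y[idx] +
                16 * y[idx + 1] - y[idx + 2]) / (12 * dt^2)
  d2[1:2] <- d2[3]
  d2[(n - 1):n] <- d2[n - 2]
  M_body * d2
}

#' Amplitude and systolic peak timing of a BCG cycle
#'
#' Amplitude is defined peak-to-valley within the systolic window
#' (default 0-0.3 s after cycle start); the systolic peak time is the
#' argmax of the force in that window.
#'
#' @param F force over one cycle (dyne).
#' @param t time within the cycle (s), starting at 0.
#' @param window systolic window (s), default `c(0, 0.3)`.
#' @return named numeric vector `c(amplitude, systolic_peak_time)`.
#' @export
bcg_features <- function(F, t, window = c(0, 0.3)) {
  if (window[2] > max(t) + 1e-9)
    stop("systolic window exceeds cycle length", call. = FALSE)
  w <- t >= window[1] & t <= window[2]
  Fw <- F[w]
  c(amplitude = max(Fw) - min(Fw),
    systolic_peak_time = t[w][which.max(Fw)])
}

#' Synthesize the BCG waveform from a simulation
#'
#' Converts the simulated per-compartment volume waveforms into the
#' ballistocardiogram force: the blood-volume center of mass is formed from
#' the compartment centroid coordinates, differentiated twice, and scaled
#' by body mass. The body mass cancels exactly (displacement carries 1/M,
#' force carries M), so the waveform depends only on blood density, the
#' coordinates, and the simulated volumes. The second derivative is
#' evaluated over the last three simulated cycles so filter edge effects
#' stay outside the reported final cycle.
#'
#' The force is reported in the measurement band of the recording chain
#' (zero-phase Butterworth band-pass, default 1.25-15 Hz): measured BCGs
#' only exist behind that filter, so model-to-measurement comparisons and
#' amplitude features are formed on the same footing. Set `band = NULL`
#' for the raw (25 Hz low-pass smoothed) force.
#'
#' @param sim a `cvsim` object (needs at least 3 cycles).
#' @param y_pos compartment coordinates (cm), default [default_y_pos()].
#' @param scale global position-scale factor (the BCG calibration factor).
#' @param M_body body mass (g); cancels, kept for interface symmetry.
#' @param window systolic window for features (s).
#' @param band measurement band (Hz) applied to the force, default
#'   `c(1.25, 15)`; `NULL` to disable.
#' @return object of class `bcg_waveform`: list with `t` (s, from cycle
#'   start), `F` (dyne), `dt`, `Tc`, `amplitude` (dyne),
#'   `systolic_peak_time` (s), `window`, `version`.
#' @export
bcg_waveform <- function(sim, y_pos = default_y_pos(), scale = 1,
                         M_body = 75e3, window = c(0, 0.3),
                         band = c(1.25, 15)) {
  stopifnot(inherits(sim, "cvsim"))
  if (sim$n_cycles < 3L) stop("need at least 3 simulated cycles", call. = FALSE)
  tail3 <- sim$t >= (sim$n_cycles - 3) * sim$Tc - 1e-9
  V3 <- sim$V[tail3, , drop = FALSE]
  y_cm <- center_of_mass_displacement(V3, y_pos * scale, M_body = M_body)
  F3 <- bcg_force(y_cm, sim$dt, M_body = M_body)
  if (!is.null(band)) F3 <- bandpass_filter(F3, 1 / sim$dt, band)
  t3 <- sim$t[tail3]
  lc <- t3 >= (sim$n_cycles - 1) * sim$Tc - 1e-9
  t <- t3[lc] - (sim$n_cycles - 1) * sim$Tc
  F <- F3[lc]
  feats <- bcg_features(F, t, window)
  structure(list(t = t, F = F, dt = sim$dt, Tc = sim$Tc,
                 amplitude = feats[["amplitude"]],
                 systolic_peak_time = feats[["systolic_peak_time"]],
                 window = window, version = sim$config$version),
            class = "bcg_waveform")
}

#' @export
print.bcg_waveform <- function(x, ...) {
  cat(sprintf("<bcg_waveform> %s: amplitude %.3g x 10^5 dyne, systolic peak at %.0f ms\n",
              x$version, x$amplitude / 1e5, 1000 * x$systolic_peak_time))
  invisible(x)
}

#' Convert force between dyne and newton
#'
#' `1 N = 1e5 dyne`.
#' @param x numeric vector.
#' @return converted vector.
#' @export
dyne_to_newton <- function(x) x / 1e5

#' @rdname dyne_to_newton
#' @export
newton_to_dyne <- function(x) x * 1e5
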