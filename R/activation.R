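#' Ventricular activation waveform
#'
#' Periodic, dimensionless activation gating ventricular contraction.
#' Within each cardiac period `Tc` the ventricle is active for `T_act`
#' seconds, over which the activation rises smoothly from 0 to 1 and back:
#' `a(t) = sin^2(pi * t / T_act)` for `0 <= t mod Tc <= T_act`, and 0
#' otherwise. The waveform is continuous, bounded in `[0, 1]`, and attains
#' its single maximum of 1 at mid-activation.
#'
#' Within each cardiac period `Tc` the ventricle is active for `T_act`
#' seconds. Contraction is faster than relaxation, as in the ventricular
#' pressure upstroke/decay asymmetry: the activation rises as
#' `sin^2(pi t / (2 t_p))` to its single maximum of 1 at
#' `t_p = rise_frac * T_act` and decays as
#' `cos^2(pi (t - t_p) / (2 (T_act - t_p)))` back to 0 at `T_act`,
#' remaining 0 for the rest of the period. The waveform is continuously
#' differentiable, bounded in `[0, 1]`, and periodic. With
#' `rise_frac = 0.5` it reduces to the symmetric `sin^2(pi t / T_act)`.
#'
#' @param t numeric vector of times (s). May be negative; the waveform is
#'   periodic with period `Tc`.
#' @param Tc cardiac period (s), positive scalar.
#' @param T_act active duration (s), positive scalar strictly less than `Tc`.
#' @param rise_frac fraction of `T_act` spent contracting (default 0.4;
#'   relaxation takes the remaining 60%).
#' @return numeric vector of activation values in `[0, 1]`.
#' @examples
#' activation_waveform(c(0, 0.132, 0.33, 0.5), Tc = 0.8, T_act = 0.33)
#' @export
activation_waveform <- function(t, Tc, T_act, rise_frac = 0.4) {
  if (!is.numeric(Tc) || length(Tc) != 1L || !is.finite(Tc) || Tc <= 0)
    stop("`Tc` must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(T_act) || length(T_act) != 1L || !is.finite(T_act) ||
      T_act <= 0 || T_act >= Tc)
    stop("`T_act` must satisfy 0 < T_act < Tc", call. = FALSE)
  if (rise_frac <= 0 || rise_frac >= 1)
    stop("`rise_frac` must lie in (0, 1)", call. = FALSE)
  tm <- t %% Tc
  tp <- rise_frac * T_act
  a <- numeric(length(t))
  up <- tm <= tp
  dn <- tm > tp & tm <= T_act
  a[up] <- sin(pi * tm[up] / (2 * tp))^2
  a[dn] <- cos(pi * (tm[dn] - tp) / (2 * (T_act - tp)))^2
  a
}

#' Default active duration of the ventricular pressure generator
#'
#' Systole shortens less than proportionally as the heart rate rises; the
#' default used throughout the package is `T_act = 0.3 * Tc + 0.06` s,
#' capped below half the cardiac period (0.30 s at 75 beats/min, so the
#' systolic deceleration peak of the BCG falls inside the 0-0.3 s window).
#'
#' @param Tc cardiac period (s).
#' @return active duration (s).
#' @export
default_t_act <- function(Tc) {
  pmin(0.3 * Tc + 0.06, 0.499 * Tc)
}

#' Time-varying ventricular elastance
#'
#' Instantaneous ventricular stiffness (pressure per unit volume), varying
#' between its diastolic floor `E_D` and systolic ceiling `E_D + E_S` as the
#' activation waveform cycles: `E(t) = E_D + E_S * a(t)`.
#'
#' @param t numeric vector of times (s).
#' @param E_D diastolic elastance (mmHg/mL), positive.
#' @param E_S activation-scaled elastance amplitude (mmHg/mL), positive.
#' @param Tc cardiac period (s).
#' @param T_act active duration (s); defaults to [default_t_act()].
#' @return numeric vector of elastances (mmHg/mL) in `[E_D, E_D + E_S]`.
#' @examples
#' ventricular_elastance(0.165, E_D = 0.04, E_S = 1.375, Tc = 0.8, T_act = 0.33)
#' @export
ventricular_elastance <- function(t, E_D, E_S, Tc, T_act = default_t_act(Tc)) {
  if (!is.numeric(E_D) || E_D <= 0 || !is.numeric(E_S) || E_S <= 0)
    stop("elastance parameters must be positive", call. = FALSE)
  E_D + E_S * activation_waveform(t, Tc, T_act)
}

#' Cardiac period from heart rate
#'
#' @param HR heart rate (beats/min), positive.
#' @return cardiac period `Tc = 60 / HR` (s).
#' @examples
#' cycle_length_from_hr(75)     # 0.8 s
#' cycle_length_from_hr(78.75)  # female preset
#' @export
cycle_length_from_hr <- function(HR) {
  if (!is.numeric(HR) || any(!is.finite(HR)) || any(HR <= 0))
    stop("`HR` must be positive (beats/min)", call. = FALSE)
  60 / HR
}
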