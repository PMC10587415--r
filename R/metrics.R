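#' End-diastolic and end-systolic volume from a volume waveform
#'
#' Operational definitions used throughout: EDV is the maximum and ESV the
#' minimum of the simulated ventricular volume over one full cycle.
#'
#' @param V numeric vector, ventricular volume (mL) over one full cycle.
#' @return named numeric vector `c(EDV, ESV)` (mL).
#' @export
ventricular_volumes <- function(V) {
  if (length(V) < 10L || any(!is.finite(V)))
    stop("need at least 10 finite volume samples covering one cycle",
         call. = FALSE)
  c(EDV = max(V), ESV = min(V))
}

#' Stroke volume, cardiac output, ejection fraction
#'
#' `SV = EDV - ESV` (mL), `CO = HR * SV` (L/min), `EF = SV / EDV`
#' (fraction).
#'
#' @param EDV end-diastolic volume (mL).
#' @param ESV end-systolic volume (mL), with `0 < ESV < EDV`.
#' @param HR heart rate (beats/min).
#' @return named numeric vector `c(SV, CO, EF)`.
#' @export
stroke_metrics <- function(EDV, ESV, HR) {
  if (!is.finite(EDV) || !is.finite(ESV) || EDV <= ESV || ESV <= 0)
    stop("require 0 < ESV < EDV", call. = FALSE)
  SV <- unname(EDV - ESV)
  c(SV = SV, CO = unname(HR) * SV / 1000, EF = SV / unname(EDV))
}

#' End-systolic pressure from a pressure waveform
#'
#' The maximum simulated ventricular pressure over the cycle, used as the
#' operational end-systolic pressure for the elastance indexes.
#'
#' @param P numeric vector, ventricular pressure (mmHg) over one cycle.
#' @return ESP (mmHg).
#' @export
esp_from_pressure <- function(P) {
  if (length(P) < 10L || any(!is.finite(P)))
    stop("need at least 10 finite pressure samples covering one cycle",
         call. = FALSE)
  max(P)
}

#' Arterial and end-systolic elastance, and ventricular-arterial coupling
#'
#' `Ea = ESP / SV`, `Ees = ESP / ESV`; the coupling index is `Ea / Ees`
#' (VAC) for the left ventricle and `Ees / Ea` (RV-PA coupling) for the
#' right. Under these definitions VAC is algebraically `ESV / SV`.
#'
#' @param ESP end-systolic pressure (mmHg), positive.
#' @param SV stroke volume (mL), positive.
#' @param ESV end-systolic volume (mL), positive.
#' @param side `"left"` or `"right"`.
#' @return named numeric vector `c(Ea, Ees, coupling)`.
#' @export
elastance_indexes <- function(ESP, SV, ESV, side = c("left", "right")) {
  side <- match.arg(side)
  if (any(c(ESP, SV, ESV) <= 0) || any(!is.finite(c(ESP, SV, ESV))))
    stop("ESP, SV, ESV must be positive and finite", call. = FALSE)
  Ea <- ESP / SV
  Ees <- ESP / ESV
  c(Ea = Ea, Ees = Ees,
    coupling = if (side == "left") Ea / Ees else Ees / Ea)
}

#' Percent difference of a female value relative to male
#'
#' Sign convention: positive when the female value is lower,
#' `(male - female) / male * 100`.
#'
#' @param male_value reference (non-zero).
#' @param female_value comparison value.
#' @return percent difference.
#' @export
percent_difference <- function(male_value, female_value) {
  if (any(male_value == 0)) stop("male reference value must be non-zero",
                                 call. = FALSE)
  (male_value - female_value) / male_value * 100
}

#' All per-ventricle metrics from a simulation
#'
#' Computes EDV, ESV, SV, CO, EF, ESP, Ea, Ees and the coupling index for
#' one ventricle on the last simulated cycle.
#'
#' @param sim a `cvsim` object.
#' @param side `"left"` or `"right"`.
#' @return object of class `cardiac_metrics` (named list).
#' @export
cardiac_metrics <- function(sim, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(sim, "cvsim"))
  comp <- if (side == "left") "lv" else "rv"
  lc <- sim$last_cycle
  vv <- ventricular_volumes(sim$V[lc, comp])
  sm <- stroke_metrics(vv[["EDV"]], vv[["ESV"]], sim$config$HR)
  ESP <- esp_from_pressure(sim$P[lc, comp])
  ei <- elastance_indexes(ESP, sm[["SV"]], vv[["ESV"]], side)
  structure(c(as.list(vv), as.list(sm), list(ESP = ESP), as.list(ei),
              list(side = side, HR = sim$config$HR,
                   version = sim$config$version)),
            class = "cardiac_metrics")
}

#' @export
print.cardiac_metrics <- function(x, ...) {
  cat(sprintf("<cardiac_metrics> %s ventricle (%s)\n", x$side, x$version))
  cat(sprintf("  EDV %.1f mL  ESV %.1f mL  SV %.1f mL  CO %.1f L/min  EF %.1f%%\n",
              x$EDV, x$ESV, x$SV, x$CO, 100 * x$EF))
  cat(sprintf("  ESP %.1f mmHg  Ea %.2f  Ees %.2f  %s %.2f\n",
              x$ESP, x$Ea, x$Ees,
              if (x$side == "left") "VAC (Ea/Ees)" else "RV-PA (Ees/Ea)",
              x$coupling))
  invisible(x)
}
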