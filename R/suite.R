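# Clinical literature reference values (population means) used only for
# labelled comparison columns in the report tables.
.CLINICAL <- data.frame(
  parameter = c("LV_EDV_mL", "LV_ESV_mL", "LV_SV_mL", "LV_CO_L_min",
                "LV_EF_pct", "LV_Ees", "LV_Ea", "LV_VAC",
                "RV_EDV_mL", "RV_ESV_mL", "RV_SV_mL", "RV_CO_L_min",
                "RV_EF_pct", "RV_Ees", "RV_Ea", "RV_PAC",
                "BCG_amplitude_1e5_dyne"),
  male_clinical = c(168.4, 78.6, 89.8, 5.6, 53.7, 1.74, 1.20, 0.69,
                    157.9, 80.9, 95.0, 5.6, 57.0, 0.7, 0.5, 1.4, 2.26),
  female_clinical = c(124.0, 53.5, 69.3, 4.9, 57.2, 2.13, 1.45, 0.68,
                      132.5, 65.2, 74.0, 4.4, 60.0, 0.8, 0.6, 1.7, 1.21))

metrics_row <- function(sim, shared) {
  ml <- cardiac_metrics(sim, "left")
  mr <- cardiac_metrics(sim, "right")
  b <- bcg_waveform(sim, scale = shared$bcg_scale)
  data.frame(
    version = sim$config$version, HR = sim$config$HR,
    LV_EDV_mL = ml$EDV, LV_ESV_mL = ml$ESV, LV_SV_mL = ml$SV,
    LV_CO_L_min = ml$CO, LV_EF_pct = 100 * ml$EF, LV_ESP_mmHg = ml$ESP,
    LV_Ees = ml$Ees, LV_Ea = ml$Ea, LV_VAC = ml$coupling,
    RV_EDV_mL = mr$EDV, RV_ESV_mL = mr$ESV, RV_SV_mL = mr$SV,
    RV_CO_L_min = mr$CO, RV_EF_pct = 100 * mr$EF, RV_ESP_mmHg = mr$ESP,
    RV_Ees = mr$Ees, RV_Ea = mr$Ea, RV_PAC = mr$coupling,
    BCG_amplitude_1e5_dyne = b$amplitude / 1e5,
    BCG_peak_time_s = b$systolic_peak_time)
}

#' Run all eight model versions
#'
#' Simulates every model version under the shared calibrated parameter set
#' and collects the per-ventricle metrics and BCG features of each.
#'
#' @param shared shared parameter set, default [calibrated_params()].
#' @param versions version names, default all eight.
#' @param n_cycles cycles per simulation (default 8).
#' @return object of class `suite_result`: data.frame, one row per
#'   version.
#' @export
run_all_versions <- function(shared = calibrated_params(),
                             versions = model_version_names(),
                             n_cycles = 8L) {
  rows <- lapply(versions, function(v) {
    sim <- tryCatch(simulate_circuit(cv_config(v, shared), n_cycles = n_cycles),
                    error = function(e)
                      stop("version '", v, "': ", conditionMessage(e),
                           call. = FALSE))
    metrics_row(sim, shared)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("suite_result", class(out))
  out
}

# the parameter group(s) each version varies, as cv_config overrides
varied_overrides <- function(name, factor) {
  mv <- build_model_version(name)
  if (length(mv$overrides) == 0)
    stop("version '", name, "' varies no parameter; nothing to perturb",
         call. = FALSE)
  lapply(mv$overrides, function(v) v * factor)
}

#' Sensitivity of a version's metrics to a +/-5% parameter alteration
#'
#' Re-runs a model version with its defining parameter value(s) altered by
#' -5% and +5% (for the idealized female, all six groups are perturbed
#' jointly). The returned envelope is the per-metric min/max across the
#' three runs, with the nominal value always inside.
#'
#' @param version a version name other than `idealized_male`.
#' @param shared shared parameter set.
#' @param delta relative alteration, default 0.05.
#' @return list with data.frames `low`, `nominal`, `high` (single metric
#'   rows) and `envelope` (metric, low, nominal, high).
#' @export
sensitivity_pm5 <- function(version, shared = calibrated_params(),
                            delta = 0.05) {
  runs <- lapply(c(low = 1 - delta, nominal = 1, high = 1 + delta),
                 function(f) {
    ov <- varied_overrides(version, f)
    cfg <- cv_config(ov, shared)
    # start on the parent version's settled orbit
    if (!is.null(shared$init_states) && version %in% names(shared$init_states))
      cfg$y0_init <- unlist(shared$init_states[[version]])
    sim <- suppressWarnings(simulate_circuit(cfg))
    row <- metrics_row(sim, shared)
    row$version <- version
    row
  })
  num <- vapply(runs$nominal, is.numeric, logical(1))
  m <- vapply(runs, function(r) unlist(r[num]), numeric(sum(num)))
  envelope <- data.frame(metric = rownames(m),
                         low = apply(m, 1, min),
                         nominal = m[, "nominal"],
                         high = apply(m, 1, max))
  c(runs, list(envelope = envelope))
}

#' Male/female comparison tables
#'
#' Builds the model-vs-clinical comparison table (model predictions for
#' the idealized male and female, percent difference with the convention
#' `(male - female) / male * 100`, and the embedded clinical literature
#' values for reference) and optionally writes it, the full suite table,
#' and raw unrounded values, as CSV files.
#'
#' @param suite a `suite_result` from [run_all_versions()].
#' @param dir optional output directory for CSV files.
#' @return data.frame comparison table (raw values; printing rounds).
#' @export
report_tables <- function(suite, dir = NULL) {
  stopifnot(inherits(suite, "suite_result"))
  male <- suite[suite$version == "idealized_male", , drop = FALSE]
  female <- suite[suite$version == "idealized_female", , drop = FALSE]
  if (nrow(male) != 1 || nrow(female) != 1)
    stop("suite must contain idealized_male and idealized_female rows",
         call. = FALSE)
  pars <- .CLINICAL$parameter
  cmp <- data.frame(
    parameter = pars,
    male_model = as.numeric(male[1, pars]),
    female_model = as.numeric(female[1, pars]),
    percent_difference = percent_difference(as.numeric(male[1, pars]),
                                            as.numeric(female[1, pars])),
    male_clinical = .CLINICAL$male_clinical,
    female_clinical = .CLINICAL$female_clinical)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(cmp, file.path(dir, "male_female_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(suite), file.path(dir, "suite_metrics.csv"),
                     row.names = FALSE)
  }
  cmp
}
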