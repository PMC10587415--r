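# Arterial geometry of the idealized male, and the female geometry used by
# the single-change versions (diameters/lengths 10% smaller, as tabulated).
.SEGMENT_NAMES <- c("ascending_aorta", "aortic_arch", "thoracic_aorta",
                    "abdominal_aorta", "iliac_artery", "carotid_artery")

.MALE_D   <- c(1.44, 1.14, 0.96, 0.85, 0.52, 0.39)
.FEMALE_D <- c(1.30, 1.03, 0.86, 0.77, 0.47, 0.35)
.MALE_L   <- c(4.0, 5.9, 15.6, 15.9, 5.8, 20.8)
.FEMALE_L <- c(3.6, 5.31, 14.04, 14.31, 5.22, 18.72)

.MALE_CARDIAC <- list(HR = 75, ELS = 1.375, ELD = 0.04, ERS = 0.23)
.FEMALE_CARDIAC <- list(HR = 78.75, ELS = 1.581, ELD = 0.05, ERS = 0.27)

#' Names of the eight model versions
#'
#' The idealized male baseline, the six versions that change one parameter
#' group at a time (heart rate; left systolic, left diastolic and right
#' systolic elastance; arterial diameters; arterial lengths), and the
#' idealized female version in which all six changes act simultaneously.
#'
#' @return character vector of length 8.
#' @export
model_version_names <- function() {
  c("idealized_male", "HR", "ELS", "ELD", "ERS",
    "arterial_diameter", "arterial_length", "idealized_female")
}

#' Parameter overrides defining a model version
#'
#' Returns the set of parameter overrides, relative to the idealized male
#' preset, that defines one of the eight model versions. The female version
#' is exactly the union of the six single changes.
#'
#' @param name one of [model_version_names()].
#' @return object of class `model_version`: list with `name` and `overrides`
#'   (named list; possible entries `HR`, `ELS`, `ELD`, `ERS`, `d`, `l`).
#' @examples
#' build_model_version("ELS")
#' @export
build_model_version <- function(name) {
  name <- match.arg(name, model_version_names())
  ov <- switch(name,
    idealized_male    = list(),
    HR                = list(HR = .FEMALE_CARDIAC$HR),
    ELS               = list(ELS = .FEMALE_CARDIAC$ELS),
    ELD               = list(ELD = .FEMALE_CARDIAC$ELD),
    ERS               = list(ERS = .FEMALE_CARDIAC$ERS),
    arterial_diameter = list(d = .FEMALE_D),
    arterial_length   = list(l = .FEMALE_L),
    idealized_female  = list(HR = .FEMALE_CARDIAC$HR, ELS = .FEMALE_CARDIAC$ELS,
                             ELD = .FEMALE_CARDIAC$ELD, ERS = .FEMALE_CARDIAC$ERS,
                             d = .FEMALE_D, l = .FEMALE_L)
  )
  structure(list(name = name, overrides = ov), class = "model_version")
}

#' @export
print.model_version <- function(x, ...) {
  cat("<model_version>", x$name, "\n")
  if (length(x$overrides) == 0) cat("  baseline (no overrides)\n")
  for (nm in names(x$overrides))
    cat(" ", nm, "=", paste(signif(x$overrides[[nm]], 6), collapse = ", "), "\n")
  invisible(x)
}

#' Full model configuration for a version
#'
#' Assembles the complete parameter set for one model version: the cardiac
#' and arterial inputs that define the version, the fixed physical
#' constants, and the shared parameters (ventricular pressure generators,
#' microcirculation, venous and pulmonary properties) that are determined
#' once by calibration against the male anchors and reused unchanged by
#' every version.
#'
#' @param version a version name (see [model_version_names()]), a
#'   `model_version` object, or a named list of raw overrides.
#' @param shared shared parameter set, by default the frozen calibrated set
#'   shipped with the package ([calibrated_params()]).
#' @return list of class `cv_config`.
#' @export
cv_config <- function(version = "idealized_male", shared = calibrated_params()) {
  if (is.character(version)) version <- build_model_version(version)
  if (inherits(version, "model_version")) {
    vname <- version$name
    ov <- version$overrides
  } else if (is.list(version)) {
    vname <- "custom"
    ov <- version
  } else stop("`version` must be a name, model_version, or override list",
              call. = FALSE)

  card <- utils::modifyList(.MALE_CARDIAC, ov[intersect(names(ov),
                                                        c("HR", "ELS", "ELD", "ERS"))])
  d <- if (!is.null(ov$d)) ov$d else .MALE_D
  l <- if (!is.null(ov$l)) ov$l else .MALE_L
  if (length(d) != 6L || length(l) != 6L)
    stop("arterial override must give all six segments", call. = FALSE)

  Tc <- cycle_length_from_hr(card$HR)
  cfg <- list(
    version = vname,
    HR = card$HR, Tc = Tc, T_act = default_t_act(Tc),
    rise_frac = if (is.null(shared$rise_frac)) 0.4 else shared$rise_frac,
    ventricles = list(
      left  = list(E_D = card$ELD, E_S = card$ELS,
                   U_max = shared$U_L, V0 = shared$V0_LV),
      right = list(E_D = shared$ERD, E_S = card$ERS,
                   U_max = shared$U_R, V0 = shared$V0_RV)
    ),
    vessels = data.frame(name = .SEGMENT_NAMES, d = d, l = l),
    # effective-tree homogenization: each named segment lumps the compliance
    # of the arterial tree it feeds (C multiplied up) and the parallel flow
    # paths of that tree (L multiplied down)
    C_art_scale = shared$C_art_scale,
    L_art_scale = shared$L_art_scale,
    edge_damping = shared$edge_damping,
    damping_ref = if (is.null(shared$damping_ref) || shared$damping_ref == 1)
      "male" else "self",
    carotid_parallel = shared$carotid_parallel,
    iliac_parallel = shared$iliac_parallel,
    blood = list(eta = 0.04, rho = 1.05),
    micro = list(R_sa = shared$R_sa * shared$R_sys_scale,
                 R_ua = shared$R_ua * shared$R_sys_scale,
                 R_uv = shared$R_uv * shared$R_sys_scale,
                 R_la = shared$R_la * shared$R_sys_scale,
                 R_va = shared$R_va * shared$R_sys_scale,
                 R_lv = shared$R_lv * shared$R_sys_scale,
                 C_um = shared$C_um * shared$C_per_scale,
                 C_lm = shared$C_lm * shared$C_per_scale,
                 # distal arterial-bed compliance hanging off the carotid
                 # and iliac nodes (sex-invariant peripheral buffering)
                 C_arch_d = shared$C_arch_d * shared$C_per_scale,
                 C_car_d = shared$C_car_d * shared$C_per_scale,
                 C_ab_d = shared$C_ab_d * shared$C_per_scale,
                 C_il_d = shared$C_il_d * shared$C_per_scale),
    venous = list(C_sv = shared$C_sv),
    pulmonary = list(R_pa = shared$R_pa * shared$R_pul_scale,
                     R_pm = shared$R_pm * shared$R_pul_scale,
                     C_pa = shared$C_pa, C_pm = shared$C_pm,
                     C_pv = shared$C_pv),
    valves = list(R_av = 0.005, R_mv = 0.01, R_tv = 0.003, R_pav = 0.0025,
                  G_leak_tv = shared$G_leak_tv, eps = 0.05),
    init = list(P_art0 = shared$P_art0, P_um0 = shared$P_um0,
                P_sv0 = shared$P_sv0, P_pa0 = shared$P_pa0,
                P_pm0 = shared$P_pm0, P_pv0 = shared$P_pv0),
    numerics = list(n_cycles = 8L, dt = 1e-3, tol = 1e-6)
  )
  # settled state stored with the calibrated set, so named versions start
  # on (or very near) their periodic orbit
  if (!is.null(shared$init_states) && vname %in% names(shared$init_states))
    cfg$y0_init <- unlist(shared$init_states[[vname]])
  class(cfg) <- "cv_config"
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks completeness and the structural invariants a configuration must
#' satisfy before the circuit can be assembled: all six named arterial
#' segments present with positive geometry, positive elastances and
#' compliances, non-negative resistances, and a valid timing block.
#'
#' @param config a `cv_config` list.
#' @return the configuration, invisibly; errors on violation.
#' @export
validate_config <- function(config) {
  need <- c("HR", "Tc", "T_act", "ventricles", "vessels", "blood", "micro",
            "venous", "pulmonary", "valves", "init", "numerics")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("configuration missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vs <- config$vessels
  miss_seg <- setdiff(.SEGMENT_NAMES, vs$name)
  if (length(miss_seg))
    stop("configuration missing arterial segment(s): ",
         paste(miss_seg, collapse = ", "), call. = FALSE)
  if (any(vs$d <= 0) || any(vs$l <= 0))
    stop("arterial geometry must be strictly positive", call. = FALSE)
  for (side in c("left", "right")) {
    v <- config$ventricles[[side]]
    if (v$E_D <= 0 || v$E_S <= 0)
      stop(side, " ventricle elastances must be positive", call. = FALSE)
  }
  if (config$Tc <= 0 || config$T_act <= 0 || config$T_act >= config$Tc)
    stop("timing must satisfy 0 < T_act < Tc", call. = FALSE)
  rr <- unlist(config$micro[c("R_sa", "R_ua", "R_uv", "R_la", "R_va",
                              "R_lv")])
  cc <- c(unlist(config$micro[c("C_um", "C_lm")]), config$venous$C_sv,
          unlist(config$pulmonary[c("C_pa", "C_pm", "C_pv")]))
  if (any(rr < 0)) stop("resistances must be non-negative", call. = FALSE)
  if (any(cc <= 0)) stop("compliances must be positive", call. = FALSE)
  invisible(config)
}
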