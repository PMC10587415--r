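# Compartment bookkeeping. Volumes are states 1..14, inertial flows 15..19.
.COMP_NAMES <- c("lv", "asc_aorta", "aortic_arch", "carotid", "thoracic_aorta",
                 "abdominal_aorta", "iliac", "upper_micro", "lower_micro",
                 "sys_veins", "rv", "pulm_artery", "pulm_micro", "pulm_veins")
.FLOW_NAMES <- c("q_arch", "q_carotid", "q_thoracic", "q_abdominal", "q_iliac")

#' Regularized valve flow
#'
#' Ideal-diode valve with a smooth sigmoidal gate: forward flow is Ohmic,
#' `Q = dP / R` for `dP >> 0`; reverse flow is blocked exponentially fast.
#' The gate `sigma(dP / eps)` keeps the right-hand side of the circuit ODEs
#' smooth so that implicit solvers do not stall on valve events.
#'
#' @param dP pressure difference across the valve (mmHg); vectorized.
#' @param R_valve forward valve resistance (mmHg s/mL), positive.
#' @param eps smoothing scale (mmHg); default 0.05.
#' @return flow (mL/s).
#' @examples
#' valve_flow(10, 0.01)    # ~1000 mL/s, forward
#' valve_flow(-10, 0.01)   # ~0, blocked
#' @export
valve_flow <- function(dP, R_valve, eps = 0.05) {
  if (!is.numeric(R_valve) || R_valve <= 0)
    stop("`R_valve` must be positive", call. = FALSE)
  dP / R_valve * stats::plogis(dP / eps)
}

#' Assemble the closed-loop circuit
#'
#' Builds the state-space right-hand side of the closed-loop model from a
#' configuration. The loop runs: left ventricle -> aortic valve -> ascending
#' aorta -> aortic arch -> {carotid -> upper-body microcirculation} and
#' {thoracic -> abdominal aorta -> iliac -> lower-body microcirculation} ->
#' systemic veins -> tricuspid -> right ventricle -> pulmonary valve ->
#' pulmonary artery -> pulmonary microcirculation -> pulmonary veins ->
#' mitral -> left ventricle. Each arterial segment contributes its lumped
#' compliance at a node and its resistance/inertance on its inflow edge
#' (the ascending-aorta resistance is carried by the aortic-valve edge).
#' States are the 14 compartment volumes plus the 5 arterial inertial
#' flows; summing dV/dt over compartments gives exactly zero, so total
#' blood volume is conserved by construction.
#'
#' @param config a validated `cv_config`.
#' @return list of class `cv_system` with elements `rhs` (deSolve-style
#'   function returning derivatives plus auxiliary pressures/flows), `y0`
#'   (default initial state), `state_names`, `comp_names`, `config`, and
#'   `n_state` (= 19).
#' @export
assemble_system <- function(config) {
  validate_config(config)
  segs <- vessel_segments(config)
  rownames(segs) <- segs$name
  sg <- function(nm) segs[nm, ]

  lv <- config$ventricles$left
  rv <- config$ventricles$right
  rise_frac <- if (is.null(config$rise_frac)) 0.4 else config$rise_frac
  mic <- config$micro
  pul <- config$pulmonary
  vlv <- config$valves
  Tc <- config$Tc
  T_act <- config$T_act

  # node compliances / unstressed volumes (segments: geometric lumen volume)
  seg_order <- c("ascending_aorta", "aortic_arch", "carotid_artery",
                 "thoracic_aorta", "abdominal_aorta", "iliac_artery")
  Cn <- c(NA, segs[seg_order, "C"] * config$C_art_scale,
          mic$C_um, mic$C_lm, config$venous$C_sv,
          NA, pul$C_pa, pul$C_pm, pul$C_pv)
  # distal arterial beds buffer the pulse where the tree actually branches:
  # at the arch (subclavian/upper-limb supply), the carotid and iliac
  # outlets, and the abdominal aorta, whose visceral branches (celiac,
  # mesenteric, renal) carry roughly half the cardiac output in rest
  Cn[match(c("aortic_arch", "carotid", "abdominal_aorta", "iliac"),
           .COMP_NAMES)] <-
    Cn[match(c("aortic_arch", "carotid", "abdominal_aorta", "iliac"),
             .COMP_NAMES)] +
    c(mic$C_arch_d, mic$C_car_d, mic$C_ab_d, mic$C_il_d)
  V0n <- c(NA, segs[seg_order, "V_geom"], 0, 0, 0, NA, 0, 0, 0)

  # inertial edges (downstream segment's R and L); the carotid and iliac
  # segments lump several parallel supply arteries (both carotids plus
  # vertebrals/subclavians; both iliacs), dividing their R and L
  np <- c(1, config$carotid_parallel, 1, 1, config$iliac_parallel)
  eR <- c(sg("aortic_arch")$R, sg("carotid_artery")$R, sg("thoracic_aorta")$R,
          sg("abdominal_aorta")$R, sg("iliac_artery")$R) / np
  eL <- c(sg("aortic_arch")$L, sg("carotid_artery")$L, sg("thoracic_aorta")$L,
          sg("abdominal_aorta")$L, sg("iliac_artery")$L) *
    config$L_art_scale / np
  # wall viscoelasticity / viscous wave damping, lumped onto each inertial
  # edge as a multiple of its characteristic impedance sqrt(L/C); without it
  # the discrete LC chain rings at unphysical amplitude. The damping is a
  # property of the homogenized effective tree and is evaluated once at the
  # reference (idealized male) geometry, so version comparisons carry only
  # the R, L, C changes the vessel formulas dictate.
  ref <- if (identical(config$damping_ref, "self")) {
    list(L = stats::setNames(segs$L, segs$name),
         C = stats::setNames(segs$C, segs$name))
  } else reference_damping_geometry(config)
  eC_dn <- ref$C[c("aortic_arch", "carotid_artery", "thoracic_aorta",
                   "abdominal_aorta", "iliac_artery")] * config$C_art_scale +
    c(0, mic$C_car_d, 0, 0, mic$C_il_d)
  eL_ref <- ref$L[c("aortic_arch", "carotid_artery", "thoracic_aorta",
                    "abdominal_aorta", "iliac_artery")] *
    config$L_art_scale / np
  eR <- unname(eR + config$edge_damping * sqrt(eL_ref / eC_dn))
  R_av_tot <- unname(vlv$R_av + sg("ascending_aorta")$R +
    config$edge_damping *
      sqrt(ref$L[["ascending_aorta"]] * config$L_art_scale /
             (ref$C[["ascending_aorta"]] * config$C_art_scale)))

  i <- as.list(stats::setNames(seq_along(.COMP_NAMES), .COMP_NAMES))
  nV <- length(.COMP_NAMES)

  rhs <- function(t, y, parms) {
    V <- y[seq_len(nV)]
    q <- y[nV + seq_along(.FLOW_NAMES)]

    a <- activation_waveform(t, Tc, T_act, rise_frac)
    P <- numeric(nV)
    P[i$lv] <- lv$U_max * a + (lv$E_D + lv$E_S * a) * (V[i$lv] - lv$V0)
    P[i$rv] <- rv$U_max * a + (rv$E_D + rv$E_S * a) * (V[i$rv] - rv$V0)
    pas <- -c(i$lv, i$rv)
    P[pas] <- (V[pas] - V0n[pas]) / Cn[pas]

    q_mv  <- valve_flow(P[i$pulm_veins] - P[i$lv], vlv$R_mv, vlv$eps)
    q_av  <- valve_flow(P[i$lv] - P[i$asc_aorta], R_av_tot, vlv$eps)
    # tricuspid: forward diode plus a small regurgitant conductance when
    # closed (physiological mild tricuspid regurgitation; lets the RV
    # volume excursion exceed the net stroke volume)
    dp_tv <- P[i$sys_veins] - P[i$rv]
    q_tv  <- valve_flow(dp_tv, vlv$R_tv, vlv$eps) +
      vlv$G_leak_tv * dp_tv * (1 - stats::plogis(dp_tv / vlv$eps))
    q_pav <- valve_flow(P[i$rv] - P[i$pulm_artery], vlv$R_pav, vlv$eps)

    # upper-body bed fed by the carotid (head) and the subclavian arteries
    # leaving the arch (arms)
    q_sa     <- (P[i$aortic_arch] - P[i$upper_micro]) / mic$R_sa
    q_um_in  <- (P[i$carotid] - P[i$upper_micro]) / mic$R_ua
    q_um_out <- (P[i$upper_micro] - P[i$sys_veins]) / mic$R_uv
    # lower-body bed fed by the legs (iliac) and the visceral branches
    # leaving the abdominal aorta
    q_va     <- (P[i$abdominal_aorta] - P[i$lower_micro]) / mic$R_va
    q_lm_in  <- (P[i$iliac] - P[i$lower_micro]) / mic$R_la
    q_lm_out <- (P[i$lower_micro] - P[i$sys_veins]) / mic$R_lv
    q_pa_pm  <- (P[i$pulm_artery] - P[i$pulm_micro]) / pul$R_pa
    q_pm_pv  <- (P[i$pulm_micro] - P[i$pulm_veins]) / pul$R_pm

    dV <- numeric(nV)
    dV[i$lv]              <- q_mv - q_av
    dV[i$asc_aorta]       <- q_av - q[1]
    dV[i$aortic_arch]     <- q[1] - q[2] - q[3] - q_sa
    dV[i$carotid]         <- q[2] - q_um_in
    dV[i$thoracic_aorta]  <- q[3] - q[4]
    dV[i$abdominal_aorta] <- q[4] - q[5] - q_va
    dV[i$iliac]           <- q[5] - q_lm_in
    dV[i$upper_micro]     <- q_um_in + q_sa - q_um_out
    dV[i$lower_micro]     <- q_lm_in + q_va - q_lm_out
    dV[i$sys_veins]       <- q_um_out + q_lm_out - q_tv
    dV[i$rv]              <- q_tv - q_pav
    dV[i$pulm_artery]     <- q_pav - q_pa_pm
    dV[i$pulm_micro]      <- q_pa_pm - q_pm_pv
    dV[i$pulm_veins]      <- q_pm_pv - q_mv

    P_up <- c(P[i$asc_aorta], P[i$aortic_arch], P[i$aortic_arch],
              P[i$thoracic_aorta], P[i$abdominal_aorta])
    P_dn <- c(P[i$aortic_arch], P[i$carotid], P[i$thoracic_aorta],
              P[i$abdominal_aorta], P[i$iliac])
    dq <- (P_up - P_dn - eR * q) / eL

    list(c(dV, dq),
         P = stats::setNames(P, paste0("P_", .COMP_NAMES)),
         Qv = c(q_mv = q_mv, q_av = q_av, q_tv = q_tv, q_pav = q_pav))
  }

  # initial state: ventricles full at their diastolic operating point,
  # passive compartments at the configured initial pressures
  ini <- config$init
  P0 <- c(NA, rep(ini$P_art0, 6), ini$P_um0, ini$P_um0, ini$P_sv0,
          NA, ini$P_pa0, ini$P_pm0, ini$P_pv0)
  y0 <- numeric(nV + length(.FLOW_NAMES))
  y0[seq_len(nV)] <- ifelse(is.na(P0), 0, V0n + Cn * P0)
  y0[i$lv] <- lv$V0 + ini$P_pv0 / lv$E_D
  y0[i$rv] <- rv$V0 + ini$P_sv0 / rv$E_D
  names(y0) <- c(paste0("V_", .COMP_NAMES), .FLOW_NAMES)
  if (!is.null(config$y0_init) && length(config$y0_init) == length(y0))
    y0 <- stats::setNames(as.numeric(config$y0_init), names(y0))

  structure(list(rhs = rhs, y0 = y0,
                 state_names = names(y0), comp_names = .COMP_NAMES,
                 n_state = length(y0), config = config),
            class = "cv_system")
}
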