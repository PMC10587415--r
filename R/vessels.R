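#' @keywords internal
"_PACKAGE"

# Unit bridge between the CGS pressure unit (dyn/cm^2) and mmHg.
MMHG_DYN_CM2 <- 1333.22

#' Convert pressures between mmHg and dyn/cm^2
#'
#' Single declared conversion used everywhere in the package:
#' 1 mmHg = 1333.22 dyn/cm^2.
#'
#' @param x numeric vector.
#' @return converted vector.
#' @export
mmHg_to_dyn_cm2 <- function(x) x * MMHG_DYN_CM2

#' @rdname mmHg_to_dyn_cm2
#' @export
dyn_cm2_to_mmHg <- function(x) x / MMHG_DYN_CM2

#' Lumped R, L, C of a cylindrical vessel segment
#'
#' Poiseuille resistance, blood inertance, and wall compliance of a straight
#' elastic tube, from its geometry and wall properties:
#' \deqn{R = 128 l \eta / (\pi d^4), \quad L = 4 \rho_b l / (\pi d^2), \quad
#'       C = 3 l \pi d^2 (d+2h)^2 / (16 E h (d+h))}
#' with diameter `d` (cm), length `l` (cm), wall thickness `h` (cm), wall
#' Young modulus `E` (dyn/cm^2), blood viscosity `eta` (g cm^-1 s^-1) and
#' blood density `rho` (g/cm^3). Results are returned both in CGS units
#' (dyn s/cm^5, g/cm^4, cm^5/dyn) and in the mmHg-mL-s system used by the
#' circuit model.
#'
#' @param d inner diameter (cm).
#' @param l length (cm).
#' @param h wall thickness (cm); default one tenth of the diameter.
#' @param E wall Young modulus (dyn/cm^2).
#' @param eta blood viscosity (g cm^-1 s^-1).
#' @param rho blood density (g/cm^3).
#' @return list with elements `R`, `L`, `C` (mmHg-mL-s units), `R_cgs`,
#'   `L_cgs`, `C_cgs`, and `V_geom` (the geometric lumen volume, mL).
#' @examples
#' vessel_rlc(d = 1.44, l = 4.0, E = 4e6)  # ascending aorta, male preset
#' @export
vessel_rlc <- function(d, l, h = 0.1 * d, E = 4e6, eta = 0.04, rho = 1.05) {
  vals <- c(d = d, l = l, h = h, E = E, eta = eta, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid vessel geometry: all of d, l, h, E, eta, rho must be positive",
         call. = FALSE)
  R_cgs <- 128 * l * eta / (pi * d^4)
  L_cgs <- 4 * rho * l / (pi * d^2)
  C_cgs <- 3 * l * pi * d^2 * (d + 2 * h)^2 / (16 * E * h * (d + h))
  list(
    R = R_cgs / MMHG_DYN_CM2,
    L = L_cgs / MMHG_DYN_CM2,
    C = C_cgs * MMHG_DYN_CM2,
    R_cgs = R_cgs, L_cgs = L_cgs, C_cgs = C_cgs,
    V_geom = pi * d^2 * l / 4
  )
}

# Reference-geometry L and C used for the wave-damping term (male preset
# diameters/lengths), per unit homogenization scales.
reference_damping_geometry <- function(config) {
  d <- c(1.44, 1.14, 0.96, 0.85, 0.52, 0.39)
  l <- c(4.0, 5.9, 15.6, 15.9, 5.8, 20.8)
  nm <- c("ascending_aorta", "aortic_arch", "thoracic_aorta",
          "abdominal_aorta", "iliac_artery", "carotid_artery")
  L <- C <- numeric(6)
  for (i in 1:6) {
    rlc <- vessel_rlc(d[i], l[i], E = segment_young_modulus(nm[i]),
                      eta = config$blood$eta, rho = config$blood$rho)
    L[i] <- rlc$L; C[i] <- rlc$C
  }
  list(L = stats::setNames(L, nm), C = stats::setNames(C, nm))
}

# Young moduli by segment: elastic aorta vs stiffer muscular branches.
segment_young_modulus <- function(name) {
  ifelse(name %in% c("carotid_artery", "iliac_artery"), 8e6, 4e6)
}

#' Named arterial segments of a preset
#'
#' Geometry (diameter, length) of the six modelled systemic arterial
#' segments for a given parameter preset, together with derived R, L, C.
#'
#' @param config a model configuration from [cv_config()].
#' @return data.frame with one row per segment: `name`, `d`, `l`, `h`, `E`,
#'   `R`, `L`, `C` (mmHg-mL-s units) and `V_geom` (mL).
#' @export
vessel_segments <- function(config) {
  segs <- config$vessels
  out <- lapply(seq_len(nrow(segs)), function(i) {
    rlc <- vessel_rlc(segs$d[i], segs$l[i],
                      E = segment_young_modulus(segs$name[i]),
                      eta = config$blood$eta, rho = config$blood$rho)
    data.frame(name = segs$name[i], d = segs$d[i], l = segs$l[i],
               h = 0.1 * segs$d[i], E = segment_young_modulus(segs$name[i]),
               R = rlc$R, L = rlc$L, C = rlc$C, V_geom = rlc$V_geom)
  })
  do.call(rbind, out)
}
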