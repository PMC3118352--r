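# Parameterization of the six-compartment HPG-axis model for adult female
# fathead minnows: fixed physiological/biochemical constants, calibrated
# parameters (posterior-mean defaults), and compartment geometry.

.chems <- c("E2", "T", "EE2", "TB", "LH", "VTG")
.comps <- c("brn", "gon", "liv", "oth", "ven")
.perfused <- c("brn", "gon", "liv", "oth")

# Molecular weights (g/mol) used for mass <-> molar unit conversion.
.molecular_weights <- c(E2 = 272.39, T = 288.43, EE2 = 296.41, TB = 270.37)

#' Per-fish physiology record
#'
#' Bundles the organism-level inputs of the model: body weight and the
#' somatic indices that set compartment volumes. Defaults are the median
#' values for sexually mature female fathead minnows used throughout the
#' model (body weight 0.0016 kg, GSI 11%, HSI 3.0%, BSI 1.18%).
#'
#' @param body_weight body weight in kg.
#' @param gsi gonadosomatic index, percent of body weight.
#' @param hsi hepatosomatic index, percent of body weight.
#' @param bsi brain somatic index, percent of body weight.
#' @return An object of class `fhm_physiology` (named list).
#' @export
fhm_physiology <- function(body_weight = 0.0016, gsi = 11, hsi = 3.0,
                           bsi = 1.18) {
  vals <- c(body_weight = body_weight, gsi = gsi, hsi = hsi, bsi = bsi)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("physiology values must be finite and strictly positive")
  }
  if (gsi + hsi + bsi >= 100) {
    stop("somatic indices must sum to less than 100%")
  }
  structure(as.list(vals), class = "fhm_physiology")
}

#' Median physiology of an adult female fathead minnow
#' @return `fhm_physiology` at the median values.
#' @export
default_physiology <- function() fhm_physiology()

# Fixed model constants. Values with a `NULL` here are derived from other
# entries in hpg_params() so that the construction identities
# (e.g. Kd_EE2ER = Kd_E2ER / RBA_EE2_E2) always hold.
.fixed_params <- list(
  # allometric flows (L/hr) as coef * BW^exp
  FW_gil_coef = 10.6, F_car_coef = 2.06, allometric_exp = 0.75,
  # body-weight percentages not supplied by physiology
  P_gil = 1.67, P_ven = 2.59,
  F_plasma_ven = 0.45,
  tissue_density = 1,           # kg/L, converts weight percent to volume
  # receptor / binding-protein totals (nmol/L)
  C_ER_brn = 14.3, C_ER_gon = 29, C_LR_gon = 2.0,
  C_AR_gon = 1.05, C_SBP_ven = 400,
  # ligand-receptor association rates (L/nmol/hr) and dissociation
  # constants (nmol/L); one value per ligand-receptor pair, shared across
  # compartments
  k1_E2ER = 0.743,
  k1_TAR = 0.08, Kd_TAR = 3,
  k1_E2SBP = 5.6687, Kd_E2SBP = 3.13,
  k1_TSBP = 5.6687, Kd_TSBP = 4.89,
  k1_EE2SBP = 5.6687, Kd_EE2SBP = 0.58,
  k1_LHLR = 0.2, Kd_LHLR = 2.9,
  # T production (side-chain cleavage chain)
  sc_Vmax_Scc_gon = 1.1e5,      # nmol/hr/kg^0.75
  K05_Scc_gon = 190,            # nmol/L
  K_T = 0.016,                  # nmol/L, bound-ER inhibition of T production
  Rho_STAR_gon = 1,
  # aromatase (E2 production)
  Km_aro_gon = 9.6, Km_aro_brn = 9.6,   # nmol/L
  D_mp_gon = 3100,              # mg microsomal protein / L tissue
  Rho_mp = 0.174,               # gonad:brain microsomal protein ratio
  sc_aro_brn_factor = 4.6,      # sc_Vmax_aro_brn = 4.6 * sc_Vmax_aro_gon
  # VTG
  k_vtg_gon = 0.05,             # 1/hr uptake of VTG into oocytes
  K05_Vtg_liv = 1.0,            # nmol/L
  # receptor turnover
  ke_ER_liv = 0.01, ke_AR_brn = 0.01,   # 1/hr
  # first-order eliminations in "other" (1/hr)
  ke_LH_oth = 0.1, ke_E2_oth = 0.1, ke_T_oth = 0.1,
  ke_EE2_oth = 0.1, ke_TB_oth = 0.1, ke_VTG_oth = 0.001,
  # blood:water partition coefficients
  lam_E2_bld = 300, lam_EE2_bld = 300,
  # tissue:blood partition coefficients (all 1 except steroid liver 3)
  lam_E2_brn = 1, lam_E2_gon = 1, lam_E2_liv = 3, lam_E2_oth = 1,
  lam_T_brn = 1, lam_T_gon = 1, lam_T_liv = 1, lam_T_oth = 1,
  lam_EE2_brn = 1, lam_EE2_gon = 1, lam_EE2_liv = 3, lam_EE2_oth = 1,
  lam_TB_brn = 1, lam_TB_gon = 1, lam_TB_liv = 1, lam_TB_oth = 1,
  lam_LH_brn = 1, lam_LH_gon = 1, lam_LH_liv = 1, lam_LH_oth = 1,
  lam_VTG_brn = 1, lam_VTG_gon = 1, lam_VTG_liv = 1, lam_VTG_oth = 1,
  # molecular weights (g/mol)
  MW_E2 = 272.39, MW_T = 288.43, MW_EE2 = 296.41, MW_TB = 270.37,
  MW_VTG = 1.8e5
)

# Calibrated parameters; defaults are the posterior means of the reference
# calibration. These 17 names are the model parameters the calibration
# module samples (the other 9 calibrated quantities are the error variances
# of the measurement model).
.calibrated_defaults <- list(
  lam_TB_bld = 7.47,
  Kd_E2ER = 1.12,
  RBA_EE2_E2 = 3.24,
  RBA_TB_T = 5.25,
  rho_d_LH_brn = 0.11,
  rho_u_LH_brn = 238,
  n_T = 1.03,
  rho_Chol_gon = 2.37,
  sc_Vmax_aro_gon = 1.56e-3,
  rho_E2_LHLR_gon = 79.84,
  sc_Vmax_Vtg_liv = 175,
  n_VTG = 2.88,
  Pbg_ER_liv = 0.12,
  k_ER_liv = 0.027,
  Pbg_AR_brn = 0.012,
  K_AR_brn = 3.95,
  Mag_LH = 8.86e-6
)

#' Names of the calibratable model parameters
#' @return Character vector of the 17 calibratable model-parameter names.
#' @export
calibratable_parameters <- function() names(.calibrated_defaults)

#' Full model parameter set
#'
#' Returns the complete named parameter list of the HPG-axis model: fixed
#' constants plus the calibrated parameters at their posterior-mean
#' defaults. Derived entries are recomputed so that the construction
#' identities always hold: `Kd_EE2ER = Kd_E2ER / RBA_EE2_E2`,
#' `Kd_TBAR = Kd_TAR / RBA_TB_T`, `C_AR_liv = C_AR_gon`,
#' `sc_Vmax_aro_brn = 4.6 * sc_Vmax_aro_gon`, `D_mp_brn = D_mp_gon / Rho_mp`,
#' and the shared association rates `k1_EE2ER = k1_E2ER`, `k1_TBAR = k1_TAR`.
#'
#' @param ... named scalar overrides of any non-derived parameter.
#' @return Named list of class `hpg_params`.
#' @examples
#' p <- hpg_params(RBA_TB_T = 5.25)
#' p$Kd_TBAR  # 3 / 5.25
#' @export
hpg_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  p <- c(.fixed_params, .calibrated_defaults)
  derived <- c("Kd_EE2ER", "Kd_TBAR", "k1_EE2ER", "k1_TBAR",
               "C_AR_liv", "sc_Vmax_aro_brn", "D_mp_brn")
  if (length(over)) {
    unknown <- setdiff(names(over), c(names(p), derived))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    if (any(names(over) %in% derived)) {
      stop("parameters ", paste(intersect(names(over), derived), collapse = ", "),
           " are derived by construction; override their components instead")
    }
    p[names(over)] <- over
  }
  bad <- vapply(p, function(x) !is.numeric(x) || !is.finite(x) || x <= 0,
                logical(1))
  if (any(bad)) stop("non-positive or non-finite parameter(s): ",
                     paste(names(p)[bad], collapse = ", "))
  p$Kd_EE2ER <- p$Kd_E2ER / p$RBA_EE2_E2
  p$Kd_TBAR <- p$Kd_TAR / p$RBA_TB_T
  p$k1_EE2ER <- p$k1_E2ER
  p$k1_TBAR <- p$k1_TAR
  p$C_AR_liv <- p$C_AR_gon
  p$sc_Vmax_aro_brn <- p$sc_aro_brn_factor * p$sc_Vmax_aro_gon
  p$D_mp_brn <- p$D_mp_gon / p$Rho_mp
  structure(p, class = "hpg_params")
}

#' Derive compartment geometry from physiology
#'
#' Computes compartment volumes from body weight and somatic indices
#' (tissue density 1 kg/L), the allometric gill water flow
#' `FW_gil = 10.6 * BW^0.75` and cardiac output `F_car = 2.06 * BW^0.75`
#' (L/hr), and per-compartment blood flows. The "other" compartment takes
#' the remaining body-weight percentage. Blood flow fractions of the
#' perfused compartments (brain, gonad, liver, other) are proportional to
#' their body-weight percentages, so that the flows sum exactly to cardiac
#' output.
#'
#' @param phys an [fhm_physiology()] record.
#' @param params an [hpg_params()] parameter set.
#' @return Named list of class `hpg_geometry` with volumes `V_*` (L), blood
#'   flows `F_*` (L/hr), `F_car`, `FW_gil`, and `F_plasma_ven`.
#' @export
derive_geometry <- function(phys, params = hpg_params()) {
  if (!inherits(phys, "fhm_physiology")) phys <- do.call(fhm_physiology, phys)
  bw <- phys$body_weight
  if (!is.finite(bw) || bw <= 0) stop("body weight must be positive")
  pc <- c(brn = phys$bsi, gon = phys$gsi, liv = phys$hsi,
          gil = params$P_gil, ven = params$P_ven)
  p_oth <- 100 - sum(pc)
  if (p_oth <= 0) stop("compartment percentages exceed 100% of body weight")
  pc <- c(pc, oth = p_oth)
  vol <- bw * (pc / 100) / params$tissue_density   # L
  f_car <- params$F_car_coef * bw^params$allometric_exp
  fw_gil <- params$FW_gil_coef * bw^params$allometric_exp
  frac <- pc[.perfused] / sum(pc[.perfused])
  flows <- frac * f_car
  structure(list(
    V_brn = unname(vol["brn"]), V_gon = unname(vol["gon"]),
    V_liv = unname(vol["liv"]), V_gil = unname(vol["gil"]),
    V_ven = unname(vol["ven"]), V_oth = unname(vol["oth"]),
    F_brn = unname(flows["brn"]), F_gon = unname(flows["gon"]),
    F_liv = unname(flows["liv"]), F_oth = unname(flows["oth"]),
    F_car = f_car, FW_gil = fw_gil,
    F_plasma_ven = params$F_plasma_ven,
    P_oth = unname(p_oth)
  ), class = "hpg_geometry")
}
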