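# Elementary rate laws of the HPG-axis model. These are the building blocks
# of the ODE right-hand side; each is exported so the kinetics can be probed
# and tested in isolation.

#' Net ligand-receptor binding flux
#'
#' Second-order association / first-order dissociation kinetics:
#' `d(C_bound)/dt = k1 * C_free * C_Rfree - (k1 * Kd) * C_bound`,
#' so the dissociation rate constant is `koff = k1 * Kd` (1/hr).
#'
#' @param C_free free ligand concentration (nmol/L).
#' @param C_Rfree free receptor concentration (nmol/L).
#' @param C_bound complex concentration (nmol/L).
#' @param k1 association rate constant (L/nmol/hr).
#' @param Kd equilibrium dissociation constant (nmol/L).
#' @return d(C_bound)/dt in nmol/L/hr.
#' @export
binding_net_flux <- function(C_free, C_Rfree, C_bound, k1, Kd) {
  if (any(c(C_free, C_Rfree, C_bound) < 0)) {
    stop("binding_net_flux: concentrations must be >= 0")
  }
  k1 * C_free * C_Rfree - k1 * Kd * C_bound
}

#' Gill exchange of a water-borne chemical
#'
#' Equilibrium-partitioning gill model. The effective exchange flow is
#' `F_eff = min(FW_gil, F_car * lambda_bld)`, which caps uptake at
#' thermodynamic equilibrium; the net uptake flux is
#' `F_eff * (C_water - C_ven / lambda_bld)` (nmol/hr) and the arterial
#' concentration is `C_ven + uptake/F_car`. The gill itself accumulates
#' nothing. Only chemicals with a blood:water partition coefficient
#' (E2, EE2, TB) have a gill route.
#'
#' @param C_water water concentration (nmol/L).
#' @param C_ven venous blood concentration (nmol/L).
#' @param chem one of `"E2"`, `"EE2"`, `"TB"`.
#' @param geom [derive_geometry()] output.
#' @param params [hpg_params()] parameter set.
#' @return List with `C_art` (nmol/L) and `uptake_flux` (nmol/hr).
#' @export
gill_exchange <- function(C_water, C_ven, chem, geom, params) {
  if (!chem %in% c("E2", "EE2", "TB")) {
    stop("no gill exchange route for chemical: ", chem)
  }
  if (C_water < 0 || C_ven < 0) stop("concentrations must be >= 0")
  lam <- params[[paste0("lam_", chem, "_bld")]]
  f_eff <- min(geom$FW_gil, geom$F_car * lam)
  uptake <- f_eff * (C_water - C_ven / lam)
  list(C_art = C_ven + uptake / geom$F_car, uptake_flux = uptake)
}

#' Diurnal background LH production rate
#'
#' `Pb_LH(t) = Mag_LH * (1 + sin(2*pi*t/24))`: a 24-hour cycle with mean
#' `Mag_LH` (nmol/hr), never negative, phase zero at lights-on.
#'
#' @param t time (hr).
#' @param params parameter set.
#' @return nmol/hr.
#' @export
lh_background_rate <- function(t, params) {
  params$Mag_LH * (1 + sin(2 * pi * t / 24))
}

#' LH production rate in the brain
#'
#' Diurnal background production up-regulated by bound ER and down-regulated
#' by bound AR:
#' `P_LH = Pb_LH(t) * (1 + C_ERbd/rho_u) / (1 + C_ARbd/rho_d)`.
#'
#' @param t time (hr).
#' @param C_ERbd_brn total bound ER in brain (E2-ER + EE2-ER complexes,
#'   nmol/L).
#' @param C_ARbd_brn total bound AR in brain (T-AR + TB-AR complexes,
#'   nmol/L).
#' @param params parameter set.
#' @return nmol/hr.
#' @export
lh_production_rate <- function(t, C_ERbd_brn, C_ARbd_brn, params) {
  if (C_ERbd_brn < 0 || C_ARbd_brn < 0) stop("concentrations must be >= 0")
  lh_background_rate(t, params) *
    (1 + C_ERbd_brn / params$rho_u_LH_brn) /
    (1 + C_ARbd_brn / params$rho_d_LH_brn)
}

#' Brain AR production rate
#'
#' Background AR synthesis down-regulated hyperbolically by free androgens:
#' `Pbg_AR * K_AR / (K_AR + C_T + C_TB)` (nmol/L/hr). The full free-AR
#' balance in the right-hand side adds the (negative) binding fluxes for T
#' and TB and first-order degradation `-ke_AR * C_ARfree`.
#'
#' @param C_T_brn free T in brain (nmol/L).
#' @param C_TB_brn free TB in brain (nmol/L).
#' @param params parameter set.
#' @return nmol/L/hr.
#' @export
brain_ar_production_rate <- function(C_T_brn, C_TB_brn, params) {
  if (C_T_brn < 0 || C_TB_brn < 0) stop("concentrations must be >= 0")
  params$Pbg_AR_brn * params$K_AR_brn /
    (params$K_AR_brn + C_T_brn + C_TB_brn)
}

#' Testosterone production rate in the gonad
#'
#' Bound LH receptor drives StAR (`C_STAR = Rho_STAR * C_LHLR`), StAR sets
#' cholesterol delivery (`C_chol = rho_Chol * C_STAR`), and the side-chain
#' cleavage chain converts cholesterol with Hill kinetics, inhibited by
#' bound ER in the gonad:
#' `P_T = sc_Vmax_Scc * BW^0.75 * C_chol^n / (K05^n + C_chol^n)
#'        / (1 + C_ERbd_gon / K_T)`.
#'
#' @param C_LHLR_gon bound LH receptor in gonad (nmol/L).
#' @param C_ERbd_gon total bound ER in gonad (nmol/L).
#' @param phys physiology record.
#' @param params parameter set.
#' @return nmol/hr.
#' @export
t_production_rate <- function(C_LHLR_gon, C_ERbd_gon, phys, params) {
  if (C_LHLR_gon < 0 || C_ERbd_gon < 0) stop("concentrations must be >= 0")
  c_star <- params$Rho_STAR_gon * C_LHLR_gon
  c_chol <- params$rho_Chol_gon * c_star
  if (c_chol <= 0) return(0)
  hill <- c_chol^params$n_T /
    (params$K05_Scc_gon^params$n_T + c_chol^params$n_T)
  params$sc_Vmax_Scc_gon * phys$body_weight^params$allometric_exp * hill /
    (1 + C_ERbd_gon / params$K_T)
}

#' Estradiol (aromatase) production rate
#'
#' Michaelis-Menten conversion of free T to E2. In the gonad the rate is
#' induced by bound LH receptor, `(1 + rho_E2_LHLR * C_LHLR)`; in the brain
#' there is no LH induction. `Vmax = sc_Vmax_aro * D_mp * V` with
#' `sc_Vmax_aro_brn = 4.6 * sc_Vmax_aro_gon` and
#' `D_mp_brn = D_mp_gon / Rho_mp`.
#'
#' @param C_T free T in the compartment (nmol/L).
#' @param C_LHLR_gon bound LH receptor (nmol/L, ignored for the brain).
#' @param compartment `"gon"` or `"brn"`.
#' @param geom geometry (for the compartment volume).
#' @param params parameter set.
#' @return nmol/hr.
#' @export
e2_production_rate <- function(C_T, C_LHLR_gon, compartment, geom, params) {
  if (C_T < 0 || C_LHLR_gon < 0) stop("concentrations must be >= 0")
  compartment <- match.arg(compartment, c("gon", "brn"))
  if (compartment == "gon") {
    vmax <- params$sc_Vmax_aro_gon * params$D_mp_gon * geom$V_gon
    induction <- 1 + params$rho_E2_LHLR_gon * C_LHLR_gon
    km <- params$Km_aro_gon
  } else {
    vmax <- params$sc_Vmax_aro_brn * params$D_mp_brn * geom$V_brn
    induction <- 1
    km <- params$Km_aro_brn
  }
  induction * vmax * C_T / (km + C_T)
}

#' Vitellogenin production rate in the liver
#'
#' Hill response to bound liver ER:
#' `P_VTG = sc_Vmax_Vtg * BW^0.75 * C_ERbd^n / (K05^n + C_ERbd^n)`.
#'
#' @param C_ERbd_liv total bound ER in liver (nmol/L).
#' @param phys physiology record.
#' @param params parameter set.
#' @return nmol/hr.
#' @export
vtg_production_rate <- function(C_ERbd_liv, phys, params) {
  if (C_ERbd_liv < 0) stop("concentrations must be >= 0")
  if (C_ERbd_liv == 0) return(0)
  hill <- C_ERbd_liv^params$n_VTG /
    (params$K05_Vtg_liv^params$n_VTG + C_ERbd_liv^params$n_VTG)
  params$sc_Vmax_Vtg_liv * phys$body_weight^params$allometric_exp * hill
}

#' Liver ER production rate (auto-regulation)
#'
#' Background synthesis plus bound-ER induction:
#' `production = Pbg_ER + k_ER * C_ERbd` (nmol/L/hr). The free-ER balance
#' adds the binding fluxes for E2 and EE2 and degradation
#' `-ke_ER * C_ERfree`.
#'
#' @param C_ERbd_liv total bound ER in liver (nmol/L).
#' @param params parameter set.
#' @return nmol/L/hr.
#' @export
liver_er_production_rate <- function(C_ERbd_liv, params) {
  if (C_ERbd_liv < 0) stop("concentrations must be >= 0")
  params$Pbg_ER_liv + params$k_ER_liv * C_ERbd_liv
}

#' VTG uptake into oocytes
#'
#' First-order sink from the gonad VTG pool:
#' `R = k_vtg * C_VTG_gon * V_gon` (nmol/hr).
#'
#' @param C_VTG_gon VTG concentration in gonad (nmol/L).
#' @param geom geometry.
#' @param params parameter set.
#' @return nmol/hr.
#' @export
vtg_oocyte_uptake_rate <- function(C_VTG_gon, geom, params) {
  if (C_VTG_gon < 0) stop("concentrations must be >= 0")
  params$k_vtg_gon * C_VTG_gon * geom$V_gon
}

#' First-order elimination in the "other" compartment
#'
#' `R = ke_chem * C * V_oth` (nmol/hr). TB shares the EE2 elimination rate
#' constant.
#'
#' @param C_oth concentration in the "other" compartment (nmol/L).
#' @param chem one of `"E2"`, `"T"`, `"EE2"`, `"TB"`, `"LH"`, `"VTG"`.
#' @param geom geometry.
#' @param params parameter set.
#' @return nmol/hr.
#' @export
elimination_rate <- function(C_oth, chem, geom, params) {
  chem <- match.arg(chem, .chems)
  if (C_oth < 0) stop("concentrations must be >= 0")
  params[[paste0("ke_", chem, "_oth")]] * C_oth * geom$V_oth
}

#' Numerical half-saturation of a binding pair
#'
#' Integrates the binding kinetics `dC_b/dt = k1*C_free*(C_tot - C_b) -
#' k1*Kd*C_b` with the free ligand clamped, reads off the equilibrium
#' occupancy `C_b/C_tot`, and root-finds the free-ligand concentration at
#' which occupancy is 50%. For Langmuir kinetics this equals the
#' dissociation constant, so the function is an independent numerical
#' check that a parameterized pair equilibrates at its printed Kd.
#'
#' @param k1 association rate constant (L/nmol/hr).
#' @param Kd dissociation constant (nmol/L).
#' @param C_total total receptor concentration (nmol/L).
#' @param interval search interval for the half-saturating free-ligand
#'   concentration (defaults to a wide bracket around `Kd`).
#' @param occupancy_at if supplied, skip the root search and return the
#'   integrated equilibrium occupancy at this clamped concentration.
#' @return Half-saturating concentration (nmol/L), or the occupancy when
#'   `occupancy_at` is given.
#' @export
binding_half_saturation <- function(k1, Kd, C_total,
                                    interval = c(Kd / 100, Kd * 100),
                                    occupancy_at = NULL) {
  occ <- function(C_free) {
    # clamped-ligand relaxation rate is k1*(C_free + Kd); integrate far
    # past equilibrium
    t_end <- 30 / (k1 * (C_free + Kd))
    out <- deSolve::ode(
      y = c(Cb = 0), times = c(0, t_end),
      func = function(t, y, p) {
        list(k1 * C_free * (C_total - y[1]) - k1 * Kd * y[1])
      }, parms = NULL, rtol = 1e-10, atol = 1e-12)
    unname(out[2, "Cb"]) / C_total
  }
  if (!is.null(occupancy_at)) return(occ(occupancy_at))
  uniroot(function(x) occ(x) - 0.5, interval = interval, tol = 1e-10)$root
}
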