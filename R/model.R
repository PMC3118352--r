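# State layout, the coupled ODE right-hand side (portable R reference
# implementation), baseline initialization, forward simulation via the
# compiled solver, and observable extraction.

.state_names <- c(
  as.vector(t(outer(.chems, .comps, function(i, j) paste0("C_", i, "_", j)))),
  paste0("C_E2ER_", c("brn", "gon", "liv")),
  paste0("C_EE2ER_", c("brn", "gon", "liv")),
  paste0("C_TAR_", c("brn", "gon", "liv")),
  paste0("C_TBAR_", c("brn", "gon", "liv")),
  "C_LHLR_gon",
  "C_E2SBP_ven", "C_TSBP_ven", "C_EE2SBP_ven",
  "C_ERfree_liv", "C_ARfree_brn"
)

#' State-variable names of the HPG-axis model
#'
#' Free chemical concentrations `C_<chem>_<compartment>` for the six
#' chemicals (E2, T, EE2, TB, LH, VTG) in brain, gonad, liver, "other" and
#' venous blood; receptor-ligand complexes; venous SBP complexes; and the
#' two dynamic free-receptor pools (liver ER, brain AR). All in nmol/L.
#'
#' @return Character vector of length 48.
#' @export
state_names <- function() .state_names

#' Solver and baseline-initialization options
#'
#' @param rtol,atol relative / absolute integration tolerances (atol in
#'   nmol/L).
#' @param method deSolve integration method (stiff solver by default).
#' @param baseline_tol maximum relative change of any state component
#'   between consecutive 24-hr windows for the baseline to count as
#'   converged.
#' @param baseline_horizon maximum integration time (hr) allowed for
#'   baseline convergence.
#' @param maxsteps maximum internal solver steps per call.
#' @return List of class `hpg_solver_options`.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-12, method = "lsoda",
                           baseline_tol = 1e-6, baseline_horizon = 4000,
                           maxsteps = 50000) {
  structure(list(rtol = rtol, atol = atol, method = method,
                 baseline_tol = baseline_tol,
                 baseline_horizon = baseline_horizon,
                 maxsteps = maxsteps),
            class = "hpg_solver_options")
}

# Coarser options used inside MCMC calibration, where thousands of forward
# solves are needed and likelihood differences, not absolute accuracy,
# drive the sampler.
.coarse_solver <- function() {
  solver_options(rtol = 1e-6, atol = 1e-9, baseline_tol = 1e-4,
                 baseline_horizon = 4000)
}

# ---------------------------------------------------------------------------
# R reference right-hand side

#' ODE right-hand side of the HPG-axis model (reference implementation)
#'
#' Assembles the full coupled mass-balance derivative for all 48 state
#' variables from the elementary rate laws. A compiled equivalent is used
#' by [simulate_hpg()]; this R version is the readable reference against
#' which the compiled code is verified.
#'
#' @param t time (hr).
#' @param state named numeric state vector (see [state_names()]).
#' @param phys physiology record.
#' @param params parameter set.
#' @param scenario exposure scenario.
#' @param kinetics_only if `TRUE`, all productions, eliminations, gill
#'   exchange and oocyte uptake are disabled, leaving only transport and
#'   binding kinetics (used for mass-conservation checks).
#' @param geom optional precomputed geometry.
#' @return Named derivative vector, nmol/L/hr.
#' @export
hpg_rhs <- function(t, state, phys, params, scenario = zero_exposure(),
                    kinetics_only = FALSE, geom = NULL) {
  if (is.null(geom)) geom <- derive_geometry(phys, params)
  s <- pmax(state, 0)  # components within -atol of 0 are treated as 0
  g <- function(nm) s[[nm]]
  V <- c(brn = geom$V_brn, gon = geom$V_gon, liv = geom$V_liv,
         oth = geom$V_oth, ven = geom$V_ven)
  Fj <- c(brn = geom$F_brn, gon = geom$F_gon, liv = geom$F_liv,
          oth = geom$F_oth)

  # free receptor pools (fixed totals)
  ERfree <- c(
    brn = max(params$C_ER_brn - g("C_E2ER_brn") - g("C_EE2ER_brn"), 0),
    gon = max(params$C_ER_gon - g("C_E2ER_gon") - g("C_EE2ER_gon"), 0),
    liv = g("C_ERfree_liv"))
  ARfree <- c(
    brn = g("C_ARfree_brn"),
    gon = max(params$C_AR_gon - g("C_TAR_gon") - g("C_TBAR_gon"), 0),
    liv = max(params$C_AR_liv - g("C_TAR_liv") - g("C_TBAR_liv"), 0))
  LRfree <- max(params$C_LR_gon - g("C_LHLR_gon"), 0)
  SBPfree <- max(params$C_SBP_ven - g("C_E2SBP_ven") - g("C_TSBP_ven") -
                   g("C_EE2SBP_ven"), 0)

  # binding fluxes (nmol/L/hr)
  b <- list()
  for (j in c("brn", "gon", "liv")) {
    b[[paste0("E2ER_", j)]] <- binding_net_flux(
      g(paste0("C_E2_", j)), ERfree[[j]], g(paste0("C_E2ER_", j)),
      params$k1_E2ER, params$Kd_E2ER)
    b[[paste0("EE2ER_", j)]] <- binding_net_flux(
      g(paste0("C_EE2_", j)), ERfree[[j]], g(paste0("C_EE2ER_", j)),
      params$k1_EE2ER, params$Kd_EE2ER)
    b[[paste0("TAR_", j)]] <- binding_net_flux(
      g(paste0("C_T_", j)), ARfree[[j]], g(paste0("C_TAR_", j)),
      params$k1_TAR, params$Kd_TAR)
    b[[paste0("TBAR_", j)]] <- binding_net_flux(
      g(paste0("C_TB_", j)), ARfree[[j]], g(paste0("C_TBAR_", j)),
      params$k1_TBAR, params$Kd_TBAR)
  }
  b$LHLR <- binding_net_flux(g("C_LH_gon"), LRfree, g("C_LHLR_gon"),
                             params$k1_LHLR, params$Kd_LHLR)
  b$E2SBP <- binding_net_flux(g("C_E2_ven"), SBPfree, g("C_E2SBP_ven"),
                              params$k1_E2SBP, params$Kd_E2SBP)
  b$TSBP <- binding_net_flux(g("C_T_ven"), SBPfree, g("C_TSBP_ven"),
                             params$k1_TSBP, params$Kd_TSBP)
  b$EE2SBP <- binding_net_flux(g("C_EE2_ven"), SBPfree, g("C_EE2SBP_ven"),
                               params$k1_EE2SBP, params$Kd_EE2SBP)

  # arterial concentrations: gill exchange for chemicals with a blood:water
  # partition coefficient, pass-through otherwise
  C_art <- vapply(.chems, function(i) g(paste0("C_", i, "_ven")), numeric(1))
  if (!kinetics_only) {
    for (i in c("E2", "EE2", "TB")) {
      cw <- water_concentration(scenario, i, t)
      C_art[[i]] <- gill_exchange(cw, g(paste0("C_", i, "_ven")), i,
                                  geom, params)$C_art
    }
  }

  # productions (nmol/hr) and sinks
  C_ERbd_brn <- g("C_E2ER_brn") + g("C_EE2ER_brn")
  C_ARbd_brn <- g("C_TAR_brn") + g("C_TBAR_brn")
  C_ERbd_gon <- g("C_E2ER_gon") + g("C_EE2ER_gon")
  C_ERbd_liv <- g("C_E2ER_liv") + g("C_EE2ER_liv")
  if (!kinetics_only) {
    P_LH <- lh_production_rate(t, C_ERbd_brn, C_ARbd_brn, params)
    P_T <- t_production_rate(g("C_LHLR_gon"), C_ERbd_gon, phys, params)
    P_E2_gon <- e2_production_rate(g("C_T_gon"), g("C_LHLR_gon"), "gon",
                                   geom, params)
    P_E2_brn <- e2_production_rate(g("C_T_brn"), 0, "brn", geom, params)
    P_VTG <- vtg_production_rate(C_ERbd_liv, phys, params)
    R_VTG_gon <- vtg_oocyte_uptake_rate(g("C_VTG_gon"), geom, params)
  } else {
    P_LH <- P_T <- P_E2_gon <- P_E2_brn <- P_VTG <- R_VTG_gon <- 0
  }
  prod <- matrix(0, 6, 4, dimnames = list(.chems, .perfused))  # nmol/hr
  prod["LH", "brn"] <- P_LH
  prod["T", "gon"] <- P_T - P_E2_gon   # aromatase consumes T
  prod["T", "brn"] <- -P_E2_brn
  prod["E2", "gon"] <- P_E2_gon
  prod["E2", "brn"] <- P_E2_brn
  prod["VTG", "liv"] <- P_VTG
  prod["VTG", "gon"] <- -R_VTG_gon
  if (!kinetics_only) {
    for (i in .chems) {
      prod[i, "oth"] <- prod[i, "oth"] -
        elimination_rate(g(paste0("C_", i, "_oth")), i, geom, params)
    }
  }

  # binding losses of free chemical, per compartment (nmol/L/hr)
  bind_loss <- matrix(0, 6, 5, dimnames = list(.chems, .comps))
  for (j in c("brn", "gon", "liv")) {
    bind_loss["E2", j] <- b[[paste0("E2ER_", j)]]
    bind_loss["EE2", j] <- b[[paste0("EE2ER_", j)]]
    bind_loss["T", j] <- b[[paste0("TAR_", j)]]
    bind_loss["TB", j] <- b[[paste0("TBAR_", j)]]
  }
  bind_loss["LH", "gon"] <- bind_loss["LH", "gon"] + b$LHLR
  bind_loss["E2", "ven"] <- b$E2SBP
  bind_loss["T", "ven"] <- b$TSBP
  bind_loss["EE2", "ven"] <- b$EE2SBP

  d <- setNames(numeric(length(.state_names)), .state_names)
  for (i in .chems) {
    ret <- 0  # venous return flow, nmol/hr
    for (j in .perfused) {
      lam <- params[[paste0("lam_", i, "_", j)]]
      cij <- g(paste0("C_", i, "_", j))
      transport <- Fj[[j]] * (C_art[[i]] - cij / lam)
      d[paste0("C_", i, "_", j)] <-
        (transport + prod[i, j]) / V[[j]] - bind_loss[i, j]
      ret <- ret + Fj[[j]] * cij / lam
    }
    d[paste0("C_", i, "_ven")] <-
      (ret - geom$F_car * g(paste0("C_", i, "_ven"))) / V[["ven"]] -
      bind_loss[i, "ven"]
  }
  for (j in c("brn", "gon", "liv")) {
    d[paste0("C_E2ER_", j)] <- b[[paste0("E2ER_", j)]]
    d[paste0("C_EE2ER_", j)] <- b[[paste0("EE2ER_", j)]]
    d[paste0("C_TAR_", j)] <- b[[paste0("TAR_", j)]]
    d[paste0("C_TBAR_", j)] <- b[[paste0("TBAR_", j)]]
  }
  if (!kinetics_only) {
    # receptor-mediated turnover of the dynamic pools: complexes of the
    # auto-regulated liver ER and brain AR are internalized and degraded
    # (receptor and ligand) at the pool's elimination rate; without this
    # the bound-ER induction of ER synthesis has no stable fixed point
    d["C_E2ER_liv"] <- d["C_E2ER_liv"] - params$ke_ER_liv * g("C_E2ER_liv")
    d["C_EE2ER_liv"] <- d["C_EE2ER_liv"] - params$ke_ER_liv * g("C_EE2ER_liv")
    d["C_TAR_brn"] <- d["C_TAR_brn"] - params$ke_AR_brn * g("C_TAR_brn")
    d["C_TBAR_brn"] <- d["C_TBAR_brn"] - params$ke_AR_brn * g("C_TBAR_brn")
  }
  d["C_LHLR_gon"] <- b$LHLR
  d["C_E2SBP_ven"] <- b$E2SBP
  d["C_TSBP_ven"] <- b$TSBP
  d["C_EE2SBP_ven"] <- b$EE2SBP
  if (!kinetics_only) {
    d["C_ERfree_liv"] <- liver_er_production_rate(C_ERbd_liv, params) -
      b$E2ER_liv - b$EE2ER_liv - params$ke_ER_liv * g("C_ERfree_liv")
    d["C_ARfree_brn"] <- brain_ar_production_rate(g("C_T_brn"), g("C_TB_brn"),
                                                  params) -
      b$TAR_brn - b$TBAR_brn - params$ke_AR_brn * g("C_ARfree_brn")
  } else {
    d["C_ERfree_liv"] <- -b$E2ER_liv - b$EE2ER_liv
    d["C_ARfree_brn"] <- -b$TAR_brn - b$TBAR_brn
  }
  d
}

# ---------------------------------------------------------------------------
# Packing for the compiled right-hand side (src/hpg_model.c). The order here
# is mirrored by the #define indices in the C source.

.max_seg <- 10L

.pack_segments <- function(scenario, chem) {
  seg <- scenario$segments
  seg <- seg[seg$chemical == chem, , drop = FALSE]
  if (nrow(seg) > .max_seg) {
    stop("compiled solver supports at most ", .max_seg,
         " exposure segments per chemical")
  }
  out <- numeric(1 + 4 * .max_seg)
  out[1] <- nrow(seg)
  if (nrow(seg)) {
    for (k in seq_len(nrow(seg))) {
      out[1 + (k - 1) * 4 + 1:4] <- c(seg$t_start[k], seg$t_end[k],
                                      seg$conc_nmol[k], seg$decay_rate[k])
    }
  }
  out
}

.pack_parms <- function(phys, params, geom, scenario, kinetics_only = FALSE) {
  p <- params
  # 4 x 6 matrix (rows = perfused compartments, cols = chemicals);
  # column-major flattening gives the chemical-major order the C side expects
  lam <- as.vector(vapply(.chems, function(i) {
    vapply(.perfused, function(j) p[[paste0("lam_", i, "_", j)]], numeric(1))
  }, numeric(4)))
  c(geom$V_brn, geom$V_gon, geom$V_liv, geom$V_oth, geom$V_ven,
    geom$F_brn, geom$F_gon, geom$F_liv, geom$F_oth,
    geom$F_car, geom$FW_gil,
    phys$body_weight^p$allometric_exp,
    as.numeric(kinetics_only),
    lam,
    p$lam_E2_bld, p$lam_EE2_bld, p$lam_TB_bld,
    p$ke_E2_oth, p$ke_T_oth, p$ke_EE2_oth, p$ke_TB_oth, p$ke_LH_oth,
    p$ke_VTG_oth,
    p$k1_E2ER, p$Kd_E2ER, p$k1_EE2ER, p$Kd_EE2ER,
    p$k1_TAR, p$Kd_TAR, p$k1_TBAR, p$Kd_TBAR,
    p$k1_LHLR, p$Kd_LHLR,
    p$k1_E2SBP, p$Kd_E2SBP, p$k1_TSBP, p$Kd_TSBP, p$k1_EE2SBP, p$Kd_EE2SBP,
    p$C_ER_brn, p$C_ER_gon, p$C_LR_gon, p$C_AR_gon, p$C_AR_liv, p$C_SBP_ven,
    p$Mag_LH, p$rho_u_LH_brn, p$rho_d_LH_brn,
    p$Pbg_AR_brn, p$K_AR_brn, p$ke_AR_brn,
    p$sc_Vmax_Scc_gon, p$K05_Scc_gon, p$n_T, p$K_T, p$Rho_STAR_gon,
    p$rho_Chol_gon,
    p$rho_E2_LHLR_gon,
    p$sc_Vmax_aro_gon * p$D_mp_gon * geom$V_gon, p$Km_aro_gon,
    p$sc_Vmax_aro_brn * p$D_mp_brn * geom$V_brn, p$Km_aro_brn,
    p$sc_Vmax_Vtg_liv, p$K05_Vtg_liv, p$n_VTG, p$k_vtg_gon,
    p$Pbg_ER_liv, p$k_ER_liv, p$ke_ER_liv,
    .pack_segments(scenario, "EE2"),
    .pack_segments(scenario, "TB"))
}

.integrate <- function(state0, times, phys, params, scenario, solver,
                       kinetics_only = FALSE, engine = c("c", "r")) {
  engine <- match.arg(engine)
  geom <- derive_geometry(phys, params)
  t0 <- times[1]
  t1 <- times[length(times)]
  breaks <- if (kinetics_only) numeric() else .scenario_breaks(scenario, t0, t1)
  grid <- sort(unique(c(times, breaks)))
  if (engine == "c") {
    parms <- .pack_parms(phys, params, geom, scenario, kinetics_only)
    out <- deSolve::ode(y = setNames(as.numeric(state0), .state_names),
                        times = grid, func = "hpg_derivs", parms = parms,
                        dllname = "hpgaxis", initfunc = "hpg_init",
                        nout = 0, method = solver$method,
                        rtol = solver$rtol, atol = solver$atol,
                        maxsteps = solver$maxsteps)
  } else {
    rhs <- function(t, y, parms) {
      list(unname(hpg_rhs(t, setNames(y, .state_names), phys, params,
                          scenario, kinetics_only, geom = geom)))
    }
    out <- deSolve::ode(y = setNames(as.numeric(state0), .state_names),
                        times = grid, func = rhs, parms = NULL,
                        method = solver$method, rtol = solver$rtol,
                        atol = solver$atol, maxsteps = solver$maxsteps)
  }
  if (any(!is.finite(out[, -1]))) stop("integration produced non-finite values")
  out[match(times, out[, "time"]), , drop = FALSE]
}

# ---------------------------------------------------------------------------

#' Initialize the unexposed baseline state
#'
#' Integrates the unexposed system from a small positive seed state until
#' the trajectory is 24-hr periodic: the maximum relative change of every
#' state component between consecutive 24-hr windows must fall below
#' `solver$baseline_tol`. The returned state sits at diurnal phase
#' `t mod 24 = 0`.
#'
#' @param phys physiology record.
#' @param params parameter set.
#' @param solver [solver_options()].
#' @param seed_scale multiplier on the default seed state (the baseline is
#'   insensitive to it; exposed for uniqueness probes).
#' @return Named state vector at the periodic baseline.
#' @export
initialize_baseline <- function(phys, params = hpg_params(),
                                solver = solver_options(), seed_scale = 1) {
  state <- setNames(numeric(length(.state_names)), .state_names)
  for (i in c("E2", "T", "LH", "VTG")) {
    state[paste0("C_", i, "_", .comps)] <- 1e-3 * seed_scale
  }
  state["C_ERfree_liv"] <- params$Pbg_ER_liv / params$ke_ER_liv * seed_scale
  state["C_ARfree_brn"] <- params$Pbg_AR_brn / params$ke_AR_brn * seed_scale
  .settle(state, phys, params, solver)
}

# Integrate the unexposed system in blocks of 24-hr windows until the
# maximum relative change of every state component between consecutive
# window boundaries falls below solver$baseline_tol; returns the state at
# the first converged boundary (diurnal phase 0).
.settle <- function(state, phys, params, solver, block = 10L) {
  t <- 0
  floor_abs <- max(solver$atol, 1e-12)
  repeat {
    times <- t + 24 * (0:block)
    out <- .integrate(state, times, phys, params, zero_exposure(), solver)
    for (i in seq_len(block)) {
      s0 <- out[i, .state_names]
      s1 <- out[i + 1, .state_names]
      rel <- abs(s1 - s0) / pmax(abs(s0), floor_abs)
      rel[s0 == 0 & s1 == 0] <- 0  # identically-zero unexposed pools
      if (max(rel) < solver$baseline_tol) {
        return(setNames(pmax(s1, 0), .state_names))
      }
    }
    state <- setNames(pmax(out[block + 1, .state_names], 0), .state_names)
    t <- t + 24 * block
    if (t >= solver$baseline_horizon) {
      stop("baseline initialization did not converge within ",
           solver$baseline_horizon, " hr (max relative change ",
           signif(max(rel), 3), ")")
    }
  }
}

#' Extract plasma and tissue observables from model states
#'
#' Plasma steroid concentrations are the total (free + SBP-bound) venous
#' concentration divided by the plasma fraction of venous blood, converted
#' to mass units (ng/ml for E2 and T, mg/ml for VTG); LH is reported in
#' nmol/L of plasma. Liver ER and brain AR totals (free + bound) are in
#' nmol/L of tissue.
#'
#' @param state named state vector, or a matrix/data.frame with state
#'   columns (e.g. a [simulate_hpg()] trajectory).
#' @param params parameter set.
#' @return Named vector (or data.frame, matching the input shape) with
#'   `plasma_E2_ng_ml`, `plasma_T_ng_ml`, `plasma_VTG_mg_ml`,
#'   `plasma_LH_nmol_L`, `liver_ER_nmol_L`, `brain_AR_nmol_L`.
#' @export
extract_observables <- function(state, params = hpg_params()) {
  fp <- params$F_plasma_ven
  if (is.matrix(state) || is.data.frame(state)) {
    g <- function(nm) state[, nm]
  } else {
    g <- function(nm) state[[nm]]
  }
  out <- list(
    plasma_E2_ng_ml = (g("C_E2_ven") + g("C_E2SBP_ven")) / fp *
      params$MW_E2 / 1000,
    plasma_T_ng_ml = (g("C_T_ven") + g("C_TSBP_ven")) / fp *
      params$MW_T / 1000,
    plasma_VTG_mg_ml = g("C_VTG_ven") / fp * params$MW_VTG / 1e9,
    plasma_LH_nmol_L = g("C_LH_ven") / fp,
    liver_ER_nmol_L = g("C_ERfree_liv") + g("C_E2ER_liv") + g("C_EE2ER_liv"),
    brain_AR_nmol_L = g("C_ARfree_brn") + g("C_TAR_brn") + g("C_TBAR_brn")
  )
  if (is.matrix(state) || is.data.frame(state)) {
    as.data.frame(out)
  } else {
    unlist(out)
  }
}

#' Simulate the HPG-axis model
#'
#' Integrates the model under an exposure scenario and returns the state
#' trajectory with plasma/tissue observables appended. The integration is
#' restarted at every exposure-segment boundary so the stiff solver never
#' steps across a forcing discontinuity.
#'
#' @param phys physiology record.
#' @param params parameter set.
#' @param scenario exposure scenario (default: unexposed).
#' @param times output times (hr), increasing; time 0 is the start of the
#'   scenario clock.
#' @param state0 initial state; if `NULL`, [initialize_baseline()] is run.
#' @param solver [solver_options()].
#' @param kinetics_only disable all sources/sinks (transport + binding
#'   only); for conservation diagnostics.
#' @param engine `"c"` (compiled, default) or `"r"` (reference
#'   implementation; slow, for verification).
#' @return `data.frame` with `time`, the 48 state columns and the 6
#'   observable columns.
#' @export
simulate_hpg <- function(phys, params = hpg_params(),
                         scenario = zero_exposure(),
                         times = seq(0, 504, by = 24), state0 = NULL,
                         solver = solver_options(), kinetics_only = FALSE,
                         engine = c("c", "r")) {
  engine <- match.arg(engine)
  if (!inherits(phys, "fhm_physiology")) phys <- do.call(fhm_physiology, phys)
  if (is.null(state0)) {
    state0 <- initialize_baseline(phys, params, solver)
  }
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  out <- .integrate(state0, times, phys, params, scenario, solver,
                    kinetics_only, engine)
  df <- as.data.frame(out)
  cbind(df, extract_observables(df, params))
}

#' Total moles of a chemical over all compartments and complexes
#'
#' Bookkeeping helper for conservation checks: sums `C * V` over the free
#' pools in all compartments plus every complex holding the chemical.
#'
#' @param state named state vector or trajectory data.frame/matrix.
#' @param chem chemical identity.
#' @param geom geometry.
#' @return Total amount in nmol.
#' @export
total_moles <- function(state, chem, geom) {
  chem <- match.arg(chem, .chems)
  if (is.matrix(state) || is.data.frame(state)) {
    g <- function(nm) state[, nm]
  } else {
    g <- function(nm) state[[nm]]
  }
  V <- c(brn = geom$V_brn, gon = geom$V_gon, liv = geom$V_liv,
         oth = geom$V_oth, ven = geom$V_ven)
  tot <- 0
  for (j in .comps) tot <- tot + g(paste0("C_", chem, "_", j)) * V[[j]]
  cplx <- switch(chem,
    E2 = list(c("C_E2ER_brn", "brn"), c("C_E2ER_gon", "gon"),
              c("C_E2ER_liv", "liv"), c("C_E2SBP_ven", "ven")),
    EE2 = list(c("C_EE2ER_brn", "brn"), c("C_EE2ER_gon", "gon"),
               c("C_EE2ER_liv", "liv"), c("C_EE2SBP_ven", "ven")),
    T = list(c("C_TAR_brn", "brn"), c("C_TAR_gon", "gon"),
             c("C_TAR_liv", "liv"), c("C_TSBP_ven", "ven")),
    TB = list(c("C_TBAR_brn", "brn"), c("C_TBAR_gon", "gon"),
              c("C_TBAR_liv", "liv")),
    LH = list(c("C_LHLR_gon", "gon")),
    VTG = list())
  for (cc in cplx) tot <- tot + g(cc[1]) * V[[cc[2]]]
  tot
}
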