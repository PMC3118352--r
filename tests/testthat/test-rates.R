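params <- fix_params()
phys <- fix_phys()
geom <- derive_geometry(phys, params)

test_that("binding kinetics: trivial zeros, koff, and the Langmuir isotherm", {
  expect_equal(binding_net_flux(0, 5, 0, 0.08, 3), 0)
  # koff = k1 * Kd for brain T-AR: 0.08 * 3 = 0.24 /hr
  C_bound <- 1
  expect_equal(binding_net_flux(0, 0, C_bound, 0.08, 3), -0.24 * C_bound)
  expect_error(binding_net_flux(-1, 0, 0, 0.08, 3), ">= 0")
  # equilibrium occupancy at C_free = Kd is 50% of total (Langmuir oracle)
  occ <- binding_half_saturation(0.08, 3, 1.05, occupancy_at = 3)
  expect_equal(occ, 0.5, tolerance = 1e-6)
  # and across a range, occupancy follows C/(Kd + C)
  for (cf in c(0.3, 3, 30)) {
    expect_equal(binding_half_saturation(0.08, 3, 1.05, occupancy_at = cf),
                 cf / (3 + cf), tolerance = 1e-6)
  }
})

test_that("gill exchange: partitioning, trivial zeros, analytic equilibrium", {
  expect_equal(params$lam_EE2_bld, 300)
  gx <- gill_exchange(0, 0, "EE2", geom, params)
  expect_equal(gx$C_art, 0)
  expect_equal(gx$uptake_flux, 0)
  expect_error(gill_exchange(1, 0, "LH", geom, params), "gill")
  # constant water concentration, no elimination: venous blood converges to
  # lambda * C_water (analytic fixed point of dC_ven/dt = uptake / V)
  cw <- 0.01
  out <- deSolve::ode(c(C = 0), seq(0, 2000, 100), function(t, y, p) {
    list(gill_exchange(cw, y[1], "TB", geom, params)$uptake_flux / 1e-3)
  }, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(out[nrow(out), "C"], params$lam_TB_bld * cw,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("LH production: background cycle, feedback limits", {
  # no feedback: pure diurnal background
  expect_equal(lh_production_rate(6, 0, 0, params),
               params$Mag_LH * (1 + sin(2 * pi * 6 / 24)))
  expect_equal(lh_production_rate(0, 0, 0, params), params$Mag_LH)
  # never negative over the cycle, mean equals Mag_LH
  tt <- seq(0, 24, by = 0.1)
  pb <- vapply(tt, lh_background_rate, numeric(1), params = params)
  expect_true(all(pb >= 0))
  expect_equal(mean(pb[-length(pb)]), params$Mag_LH, tolerance = 1e-3)
  # bound AR suppresses monotonically toward zero
  r <- vapply(c(0, 0.1, 1, 10, 1e4), function(ar) {
    lh_production_rate(0, 0, ar, params)
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_lt(r[length(r)], params$Mag_LH * 1e-3)
  # bound ER induces
  expect_gt(lh_production_rate(0, 10, 0, params),
            lh_production_rate(0, 0, 0, params))
})

test_that("brain AR production: background level and half-inhibition", {
  expect_equal(brain_ar_production_rate(0, 0, params), params$Pbg_AR_brn)
  # C_T + C_TB = K_AR gives half the background rate
  expect_equal(brain_ar_production_rate(params$K_AR_brn / 2,
                                        params$K_AR_brn / 2, params),
               params$Pbg_AR_brn / 2)
  expect_equal(params$ke_AR_brn, 0.01)
})

test_that("T production: substrate chain zero, Hill saturation, ER inhibition", {
  expect_equal(t_production_rate(0, 0, phys, params), 0)
  # cholesterol far above K05 with no ER inhibition saturates at
  # sc_Vmax * BW^0.75
  big_lhlr <- 1e9
  expect_equal(t_production_rate(big_lhlr, 0, phys, params),
               params$sc_Vmax_Scc_gon * phys$body_weight^0.75,
               tolerance = 1e-4)
  expect_equal(params$K05_Scc_gon, 190)
  # bound ER inhibits hyperbolically: halved at C_ERbd = K_T
  expect_equal(t_production_rate(1, params$K_T, phys, params),
               t_production_rate(1, 0, phys, params) / 2)
})

test_that("E2 production: Michaelis-Menten limits and LH induction", {
  expect_equal(e2_production_rate(0, 1, "gon", geom, params), 0)
  expect_equal(params$Km_aro_gon, 9.6)
  vmax_gon <- params$sc_Vmax_aro_gon * params$D_mp_gon * geom$V_gon
  expect_equal(e2_production_rate(1e7, 0, "gon", geom, params), vmax_gon,
               tolerance = 1e-5)
  # LH induction multiplies by (1 + rho * C_LHLR)
  expect_equal(e2_production_rate(5, 1, "gon", geom, params),
               (1 + params$rho_E2_LHLR_gon) *
                 e2_production_rate(5, 0, "gon", geom, params))
  # brain: no induction, scaled Vmax
  vmax_brn <- params$sc_Vmax_aro_brn * params$D_mp_brn * geom$V_brn
  expect_equal(e2_production_rate(1e7, 99, "brn", geom, params), vmax_brn,
               tolerance = 1e-5)
  expect_error(e2_production_rate(1, 0, "ven", geom, params))
})

test_that("VTG production: Hill half-saturation at K05", {
  expect_equal(vtg_production_rate(0, phys, params), 0)
  expect_equal(params$K05_Vtg_liv, 1.0)
  expect_equal(vtg_production_rate(params$K05_Vtg_liv, phys, params),
               params$sc_Vmax_Vtg_liv * phys$body_weight^0.75 / 2)
})

test_that("liver ER production and its no-ligand fixed point", {
  expect_equal(liver_er_production_rate(0, params), params$Pbg_ER_liv)
  expect_equal(liver_er_production_rate(2, params),
               params$Pbg_ER_liv + 2 * params$k_ER_liv)
  expect_equal(params$ke_ER_liv, 0.01)
  # with no ligand the free-ER ODE relaxes to Pbg/ke
  out <- deSolve::ode(c(er = 0), c(0, 2000), function(t, y, p) {
    list(liver_er_production_rate(0, params) - params$ke_ER_liv * y[1])
  }, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(out[2, "er"], params$Pbg_ER_liv / params$ke_ER_liv,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("first-order sinks: oocyte VTG uptake and eliminations", {
  expect_equal(vtg_oocyte_uptake_rate(0, geom, params), 0)
  expect_equal(params$k_vtg_gon, 0.05)
  r1 <- vtg_oocyte_uptake_rate(10, geom, params)
  expect_equal(vtg_oocyte_uptake_rate(20, geom, params), 2 * r1)
  expect_equal(r1, 0.05 * 10 * geom$V_gon)
  expect_equal(elimination_rate(0, "E2", geom, params), 0)
  # TB shares the EE2 elimination constant; VTG eliminates slowly
  expect_equal(params$ke_TB_oth, params$ke_EE2_oth)
  expect_equal(params$ke_TB_oth, 0.1)
  expect_equal(params$ke_VTG_oth, 0.001)
  expect_equal(elimination_rate(5, "TB", geom, params), 0.1 * 5 * geom$V_oth)
  expect_error(elimination_rate(1, "DDT", geom, params))
})
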