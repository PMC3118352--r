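params <- fix_params()
phys <- fix_phys()
geom <- derive_geometry(phys, params)

test_that("compiled and reference right-hand sides agree", {
  scen <- exposure_scenario(c("TB", "EE2"), 0, 48, c(15, 10), unit = "ng/L")
  for (seed in 1:5) {
    st <- random_state(seed)
    for (ko in c(FALSE, TRUE)) {
      dR <- hpg_rhs(10.5, st, phys, params, scen, kinetics_only = ko)
      pk <- hpgaxis:::.pack_parms(phys, params, geom, scen, ko)
      dC <- deSolve::DLLfunc(func = "hpg_derivs", times = 10.5,
                             y = unname(st), parms = pk,
                             dllname = "hpgaxis", initfunc = "hpg_init")$dy
      expect_equal(unname(dR), unname(dC), tolerance = 1e-12)
    }
  }
  # short trajectory from both engines matches
  bl <- fix_baseline()
  tt <- seq(0, 48, by = 12)
  simC <- simulate_hpg(phys, params, scen, tt, state0 = bl)
  simR <- simulate_hpg(phys, params, scen, tt, state0 = bl, engine = "r")
  expect_equal(as.matrix(simR[, state_names()]),
               as.matrix(simC[, state_names()]), tolerance = 1e-6)
})

test_that("per-chemical mass is conserved when sources and sinks are disabled", {
  st <- random_state(3, scale = 5)
  sim <- simulate_hpg(phys, params, zero_exposure(), seq(0, 200, by = 20),
                      state0 = st, kinetics_only = TRUE)
  for (chem in c("E2", "T", "EE2", "TB", "LH", "VTG")) {
    tot <- total_moles(sim, chem, geom)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("fixed-total receptor pools never exceed their totals", {
  scen <- exposure_scenario(c("TB", "EE2"), 0, 200, c(50, 50), unit = "ng/L")
  sim <- simulate_hpg(phys, params, scen, seq(0, 300, by = 10),
                      state0 = fix_baseline())
  # brain ER bookkeeping: free = 14.3 - bound stays non-negative
  expect_true(all(sim$C_E2ER_brn + sim$C_EE2ER_brn <= params$C_ER_brn + 1e-9))
  expect_true(all(sim$C_E2ER_gon + sim$C_EE2ER_gon <= params$C_ER_gon + 1e-9))
  expect_true(all(sim$C_TAR_gon + sim$C_TBAR_gon <= params$C_AR_gon + 1e-9))
  expect_true(all(sim$C_TAR_liv + sim$C_TBAR_liv <= params$C_AR_liv + 1e-9))
  expect_true(all(sim$C_LHLR_gon <= params$C_LR_gon + 1e-9))
  expect_true(all(sim$C_E2SBP_ven + sim$C_TSBP_ven + sim$C_EE2SBP_ven <=
                    params$C_SBP_ven + 1e-9))
  # non-negativity of every state along the trajectory
  expect_true(all(as.matrix(sim[, state_names()]) >= -1e-8))
})

test_that("baseline is a 24-hr periodic state with positive endpoints", {
  bl <- fix_baseline()
  out <- simulate_hpg(phys, params, zero_exposure(), c(0, 24), state0 = bl)
  s24 <- unlist(out[2, state_names()])
  rel <- abs(s24 - bl) / pmax(abs(bl), 1e-9)
  expect_lt(max(rel[bl > 0]), 1e-5)
  obs <- extract_observables(bl, params)
  expect_gt(obs[["plasma_VTG_mg_ml"]], 0)
  expect_gt(obs[["plasma_E2_ng_ml"]], 0)
  # unexposed pools stay identically zero
  expect_equal(unname(bl["C_TB_ven"]), 0)
  expect_equal(unname(bl["C_EE2_ven"]), 0)
})

test_that("baseline is independent of the seed-state magnitude", {
  bl <- fix_baseline()
  for (sc in c(10, 0.1)) {
    bl2 <- initialize_baseline(phys, params, seed_scale = sc)
    rel <- abs(bl2 - bl) / pmax(abs(bl), 1e-9)
    expect_lt(max(rel[bl > 0]), 1e-3)
  }
})

test_that("trajectories from baseline are diurnally periodic", {
  sim <- simulate_hpg(phys, params, zero_exposure(), seq(0, 96, by = 2),
                      state0 = fix_baseline())
  for (col in c("plasma_E2_ng_ml", "plasma_T_ng_ml", "plasma_LH_nmol_L")) {
    a <- sim[[col]][sim$time < 24]
    b <- sim[[col]][sim$time >= 72 & sim$time < 96]
    expect_equal(a, b, tolerance = 1e-4)
  }
  # LH actually cycles (diurnal forcing is alive)
  lh <- sim$plasma_LH_nmol_L
  expect_gt(diff(range(lh)) / mean(lh), 0.01)
})

test_that("observable extraction converts units as documented", {
  st <- setNames(numeric(48), state_names())
  expect_true(all(extract_observables(st, params) == 0))
  st["C_E2_ven"] <- 1
  obs <- extract_observables(st, params)
  # 1 nmol/L total venous E2 at plasma fraction 0.45 and MW 272.39
  expect_equal(obs[["plasma_E2_ng_ml"]], (1 / 0.45) * 272.39 / 1000,
               tolerance = 1e-12)
  expect_equal(obs[["plasma_E2_ng_ml"]], 0.605, tolerance = 1e-3)
  # linear in the underlying venous concentration
  st2 <- st; st2["C_E2_ven"] <- 2
  expect_equal(extract_observables(st2, params)[["plasma_E2_ng_ml"]],
               2 * obs[["plasma_E2_ng_ml"]])
  # SBP-bound steroid counts toward plasma
  st3 <- st; st3["C_E2SBP_ven"] <- 1; st3["C_E2_ven"] <- 0
  expect_equal(extract_observables(st3, params)[["plasma_E2_ng_ml"]],
               obs[["plasma_E2_ng_ml"]])
})

test_that("simulate_hpg validates times and reports requested rows", {
  expect_error(simulate_hpg(phys, params, times = c(10, 5),
                            state0 = fix_baseline()), "increasing")
  tt <- c(0, 7, 13, 48)
  sim <- simulate_hpg(phys, params, times = tt, state0 = fix_baseline())
  expect_equal(sim$time, tt)
  expect_true(all(c(state_names(), "plasma_E2_ng_ml") %in% names(sim)))
})
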