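test_that("physiology generator: medians, dispersion, missingness", {
  # gsd = 1 collapses every fish onto the medians
  p0 <- generate_physiology(5, gsd = 1)
  expect_true(all(p0$bw_kg == 0.0016))
  expect_true(all(p0$gsi_pct == 11))
  expect_true(all(p0$hsi_pct == 3.0))
  # lognormal dispersion: sample geometric mean near the medians
  set.seed(21)
  p <- generate_physiology(4000, gsd = 1.3)
  se <- log(1.3) / sqrt(4000)
  expect_equal(exp(mean(log(p$bw_kg))), 0.0016,
               tolerance = 4 * se)
  expect_equal(exp(mean(log(p$gsi_pct))), 11, tolerance = 11 * 4 * se)
  # requested missingness fraction is honored
  set.seed(22)
  pm <- generate_physiology(4000, missing = c(bw = 0.2, gsi = 0, hsi = 0))
  # Bernoulli(0.2) at n = 4000: 4 standard errors
  expect_lt(abs(mean(is.na(pm$bw_kg)) - 0.2), 4 * sqrt(0.2 * 0.8 / 4000))
  expect_true(all(!is.na(pm$gsi_pct)))
})

test_that("zero-variance studies reproduce deterministic predictions", {
  set.seed(23)
  tiny <- setNames(rep(1e-18, 6), names(error_cells(c("unexposed", "TB"))))
  ds <- generate_study(true_error_model = tiny,
                       design = design_tb_recovery(doses_ug_L = 0.5, n = 3),
                       gsd = 1)
  rec <- ds$records
  # all fish in a group are identical fish at zero noise
  for (g in split(rec, rec$scenario_id)) {
    expect_lt(diff(range(g$e2_ng_ml)) / g$e2_ng_ml[1], 1e-6)
    expect_lt(diff(range(g$vtg_mg_ml)) / g$vtg_mg_ml[1], 1e-6)
  }
})

test_that("disjoint endpoint design splits E2 and VTG across fish", {
  set.seed(24)
  ds <- generate_study(design = design_tb_48h_static(doses_ug_L = 0.5, n = 8),
                       gsd = 1)
  rec <- ds$records
  for (g in split(rec, rec$scenario_id)) {
    expect_equal(nrow(g), 8)
    expect_equal(sum(!is.na(g$e2_ng_ml)), 4)
    expect_equal(sum(!is.na(g$vtg_mg_ml)), 4)
    expect_true(all(is.na(g$e2_ng_ml) != is.na(g$vtg_mg_ml)))
    expect_true(all(is.na(g$t_ng_ml)))
  }
})

test_that("log-residual variance of a large synthetic group matches truth", {
  set.seed(25)
  vars <- setNames(rep(0.5, 6), names(error_cells(c("unexposed", "TB"))))
  vars["Var_VTG_TB"] <- 0.8
  ds <- generate_study(true_error_model = vars,
                       design = design_tb_recovery(doses_ug_L = 0.5,
                                                   n = 2000),
                       gsd = 1)
  pr <- calib_problem(ds, calibrate = "lam_TB_bld")
  ll <- log_likelihood(c(lam_TB_bld = 7.47), vars, pr)
  cells <- attr(ll, "residuals")
  # round-trip: estimated variance within 5% of the generating value
  expect_equal(var(cells$Var_VTG_TB), 0.8, tolerance = 0.05)
  expect_equal(var(cells$Var_E2_unexposed), 0.5, tolerance = 0.05)
  expect_equal(mean(cells$Var_VTG_TB), 0, tolerance = 0.05)
})

test_that("dataset CSV round-trips through the documented schema", {
  set.seed(26)
  ds <- generate_study(design = design_tb_recovery(doses_ug_L = 0.5, n = 2),
                       gsd = 1.3, missing = c(bw = 0.5, gsi = 0, hsi = 0))
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  rec2 <- read_dataset(f)
  expect_equal(names(rec2), names(ds$records)[names(ds$records) != "sim_key"])
  expect_equal(rec2$vtg_mg_ml, ds$records$vtg_mg_ml, tolerance = 1e-12)
  expect_equal(is.na(rec2$bw_kg), is.na(ds$records$bw_kg))
  unlink(f)
})

test_that("study designs encode the laboratory group structures", {
  d <- design_tb_21d()
  expect_length(d$groups, 6)  # control + 5 doses
  expect_equal(vapply(d$groups, `[[`, numeric(1), "n"),
               c(12, 12, 12, 12, 12, 12))
  expect_equal(d$groups[[2]]$times, 504)
  d2 <- design_tb_depuration()
  expect_equal(d2$groups[[2]]$times, c(24, 48, 96, 192, 216, 240, 288, 384))
  # exposure ends at 192 hr, depuration follows
  seg <- d2$groups[[2]]$scenario$segments
  expect_equal(seg$t_end, 192)
  d3 <- design_ee2_21d()
  expect_equal(vapply(d3$groups, `[[`, numeric(1), "n"), c(28, 28, 28))
  expect_equal(unname(vapply(d3$groups, function(g) g$endpoints,
                             character(1))), rep("VTG", 3))
})
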