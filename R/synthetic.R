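# Synthetic study generator: per-fish physiology, study designs mirroring
# the laboratory exposure experiments, lognormal endpoint noise, and
# end-to-end parameter-recovery experiments.

#' Generate per-fish physiology records
#'
#' Body weight, GSI and HSI are drawn lognormally around the adult female
#' medians (0.0016 kg, 11%, 3.0%) with a common geometric standard
#' deviation; each field can carry an independent missingness probability
#' (missing values appear as `NA`, to be median-filled downstream).
#'
#' @param n number of fish.
#' @param gsd geometric standard deviation of the lognormal dispersion
#'   (1 = every fish at the medians).
#' @param missing named numeric vector of missingness probabilities for
#'   `bw`, `gsi`, `hsi`.
#' @param medians named vector of medians `bw` (kg), `gsi`, `hsi` (%).
#' @return `data.frame` with `bw_kg`, `gsi_pct`, `hsi_pct`.
#' @export
generate_physiology <- function(n, gsd = 1.3,
                                missing = c(bw = 0, gsi = 0, hsi = 0),
                                medians = c(bw = 0.0016, gsi = 11, hsi = 3.0)) {
  stopifnot(n >= 1, gsd >= 1)
  sl <- base::log(gsd)
  draw <- function(med) {
    if (sl == 0) rep(med, n) else rlnorm(n, base::log(med), sl)
  }
  out <- data.frame(bw_kg = draw(medians[["bw"]]),
                    gsi_pct = draw(medians[["gsi"]]),
                    hsi_pct = draw(medians[["hsi"]]))
  for (f in c("bw", "gsi", "hsi")) {
    p <- if (f %in% names(missing)) missing[[f]] else 0
    if (p > 0) {
      col <- c(bw = "bw_kg", gsi = "gsi_pct", hsi = "hsi_pct")[[f]]
      out[[col]][as.logical(rbinom(n, 1, p))] <- NA
    }
  }
  out
}

#' Assemble a study design
#'
#' A design is a list of groups, each naming its exposure class, scenario,
#' number of fish, sampling times, and which endpoints are measured.
#'
#' @param groups list of group specifications; each a list with fields
#'   `name`, `group` (exposure class: `"unexposed"`, `"TB"` or `"EE2"`),
#'   `scenario` (an [exposure_scenario()]), `n`, `times` (sampling times,
#'   hr), and `endpoints` (character subset of `c("E2","T","VTG")`, or
#'   `"disjoint_E2_VTG"` for the split-measurement pattern where half the
#'   fish have E2 and the other half VTG measured).
#' @return Object of class `hpg_design`.
#' @export
study_design <- function(groups) {
  for (g in groups) {
    stopifnot(!is.null(g$name), g$group %in% .groups,
              inherits(g$scenario, "exposure_scenario"), g$n >= 1,
              length(g$times) >= 1)
  }
  structure(list(groups = groups), class = "hpg_design")
}

#' 21-day flow-through TB design
#'
#' Five nominal TB concentrations (0.005-50 ug/L) plus an unexposed
#' control; all three endpoints measured in every fish on day 21.
#'
#' @param doses_ug_L nominal TB water concentrations.
#' @param n fish per treatment group.
#' @param n_control fish in the unexposed group.
#' @return `hpg_design`.
#' @export
design_tb_21d <- function(doses_ug_L = c(0.005, 0.05, 0.5, 5, 50), n = 12,
                          n_control = 12) {
  groups <- list(list(name = "control", group = "unexposed",
                      scenario = zero_exposure(), n = n_control, times = 504,
                      endpoints = c("E2", "T", "VTG")))
  for (d in doses_ug_L) {
    groups[[length(groups) + 1]] <- list(
      name = paste0("TB_", d), group = "TB",
      scenario = exposure_scenario("TB", 0, 504, d, unit = "ug/L"),
      n = n, times = 504, endpoints = c("E2", "T", "VTG"))
  }
  study_design(groups)
}

#' 48-hour static TB design with disjoint endpoint measurement
#'
#' Eight fish per group; plasma E2 measured in four fish and plasma VTG in
#' the other four (the split-laboratory pattern).
#'
#' @param doses_ug_L nominal TB concentrations (plus an unexposed control).
#' @param n fish per group (split evenly between the two endpoints).
#' @return `hpg_design`.
#' @export
design_tb_48h_static <- function(doses_ug_L = c(0.05, 0.5, 5), n = 8) {
  groups <- list(list(name = "control", group = "unexposed",
                      scenario = zero_exposure(), n = n, times = 48,
                      endpoints = "disjoint_E2_VTG"))
  for (d in doses_ug_L) {
    groups[[length(groups) + 1]] <- list(
      name = paste0("TB_", d), group = "TB",
      scenario = exposure_scenario("TB", 0, 48, d, unit = "ug/L"),
      n = n, times = 48, endpoints = "disjoint_E2_VTG")
  }
  study_design(groups)
}

#' 8-day TB exposure + 8-day depuration design
#'
#' Sampling on exposure days 1, 2, 4, 8 and depuration days 9, 10, 12, 16;
#' E2 and VTG measured in each fish.
#'
#' @param doses_ug_L nominal TB concentrations.
#' @param n fish per group and sampling time.
#' @return `hpg_design`.
#' @export
design_tb_depuration <- function(doses_ug_L = c(0.05, 0.5), n = 8) {
  times <- c(24, 48, 96, 192, 216, 240, 288, 384)
  groups <- list(list(name = "control", group = "unexposed",
                      scenario = zero_exposure(), n = n, times = times,
                      endpoints = c("E2", "VTG")))
  for (d in doses_ug_L) {
    groups[[length(groups) + 1]] <- list(
      name = paste0("TB_", d), group = "TB",
      scenario = exposure_scenario("TB", 0, 192, d, unit = "ug/L"),
      n = n, times = times, endpoints = c("E2", "VTG"))
  }
  study_design(groups)
}

#' 21-day flow-through EE2 design
#'
#' Nominal EE2 concentrations of 0.5, 1.5 and 4.5 ng/L; plasma VTG
#' measured on day 21.
#'
#' @param doses_ng_L nominal EE2 concentrations.
#' @param n fish per group.
#' @return `hpg_design`.
#' @export
design_ee2_21d <- function(doses_ng_L = c(0.5, 1.5, 4.5), n = 28) {
  groups <- list()
  for (d in doses_ng_L) {
    groups[[length(groups) + 1]] <- list(
      name = paste0("EE2_", d), group = "EE2",
      scenario = exposure_scenario("EE2", 0, 504, d, unit = "ng/L"),
      n = n, times = 504, endpoints = "VTG")
  }
  study_design(groups)
}

#' Reduced paper-like TB design for desk-scale calibration runs
#'
#' Control plus three TB doses spanning the U-shaped response, a handful
#' of fish per group, all three endpoints on day 21. Small enough that a
#' four-chain calibration completes in minutes.
#'
#' @param doses_ug_L TB doses.
#' @param n fish per group.
#' @return `hpg_design`.
#' @export
design_tb_recovery <- function(doses_ug_L = c(0.05, 0.5, 5), n = 6) {
  design_tb_21d(doses_ug_L, n = n, n_control = n)
}

#' Generate a synthetic study dataset
#'
#' Simulates each fish of a design deterministically under `true_params`
#' and then draws its measured endpoints from the lognormal error model
#' with the (group x endpoint) variances of `true_error_model`.
#'
#' @param true_params generating parameter set ([hpg_params()] or named
#'   overrides).
#' @param true_error_model named vector of log-space variances per
#'   `Var_<endpoint>_<group>` cell (cells not supplied default to 0.5).
#' @param design an [study_design()].
#' @param gsd physiology dispersion passed to [generate_physiology()]
#'   (1 = all fish at the medians).
#' @param missing physiology missingness probabilities.
#' @param solver solver options for the forward simulations.
#' @return Object of class `hpg_dataset`: list with `records` (the dataset
#'   data frame, NA for unmeasured endpoints and missing physiology) and
#'   `scenarios` (named scenario list).
#' @export
generate_study <- function(true_params = hpg_params(),
                           true_error_model = NULL,
                           design = design_tb_recovery(), gsd = 1.3,
                           missing = c(bw = 0, gsi = 0, hsi = 0),
                           solver = .coarse_solver()) {
  if (!inherits(true_params, "hpg_params")) {
    true_params <- hpg_params(true_params)
  }
  stopifnot(inherits(design, "hpg_design"))
  groups_present <- unique(vapply(design$groups, `[[`, character(1), "group"))
  defaults <- setNames(rep(0.5, 3 * length(groups_present)),
                       names(error_cells(groups_present)))
  if (is.null(true_error_model)) {
    true_error_model <- defaults
  } else {
    defaults[names(true_error_model)] <- true_error_model
    true_error_model <- defaults
  }
  records <- list()
  scenarios <- list()
  fish_counter <- 0L
  baseline_cache <- new.env(parent = emptyenv())
  sim_cache <- new.env(parent = emptyenv())
  for (g in design$groups) {
    scen_id <- g$name
    scenarios[[scen_id]] <- g$scenario
    phys_df <- generate_physiology(g$n, gsd = gsd, missing = missing)
    filled <- .median_fill(phys_df)
    for (i in seq_len(g$n)) {
      fish_counter <- fish_counter + 1L
      phys <- fhm_physiology(filled$bw_kg[i], filled$gsi_pct[i],
                             filled$hsi_pct[i])
      pkey <- paste(signif(unlist(phys), 12), collapse = ",")
      bl <- baseline_cache[[pkey]]
      if (is.null(bl)) {
        bl <- initialize_baseline(phys, true_params, solver)
        baseline_cache[[pkey]] <- bl
      }
      times <- sort(unique(g$times))
      sim_times <- if (times[1] > 0) c(0, times) else times
      skey <- paste(scen_id, pkey, paste(times, collapse = ";"))
      sim <- sim_cache[[skey]]
      if (is.null(sim)) {
        sim <- simulate_hpg(phys, true_params, g$scenario, sim_times,
                            state0 = bl, solver = solver)
        sim_cache[[skey]] <- sim
      }
      if (identical(g$endpoints, "disjoint_E2_VTG")) {
        eps <- if (i <= ceiling(g$n / 2)) "E2" else "VTG"
      } else {
        eps <- g$endpoints
      }
      for (tt in times) {
        yhat <- sim[match(tt, sim$time), unname(.obs_cols)]
        row <- data.frame(fish_id = sprintf("fish_%04d", fish_counter),
                          group = g$group, scenario_id = scen_id,
                          time_hr = tt,
                          bw_kg = phys_df$bw_kg[i],
                          gsi_pct = phys_df$gsi_pct[i],
                          hsi_pct = phys_df$hsi_pct[i],
                          e2_ng_ml = NA_real_, t_ng_ml = NA_real_,
                          vtg_mg_ml = NA_real_)
        for (e in eps) {
          v <- true_error_model[[paste0("Var_", e, "_", g$group)]]
          mu <- base::log(max(yhat[[.obs_cols[[e]]]], 1e-12))
          row[[.endpoints[[e]]]] <- exp(rnorm(1, mu, sqrt(v)))
        }
        records[[length(records) + 1]] <- row
      }
    }
  }
  structure(list(records = do.call(rbind, records), scenarios = scenarios,
                 true_error_model = true_error_model),
            class = "hpg_dataset")
}

#' Write / read a dataset in the calibration CSV schema
#'
#' Columns: `fish_id`, `group`, `scenario_id`, `time_hr`, `bw_kg`,
#' `gsi_pct`, `hsi_pct`, `e2_ng_ml`, `t_ng_ml`, `vtg_mg_ml`; empty fields
#' are missing values.
#'
#' @param dataset an `hpg_dataset` or records data frame.
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns the records data frame.
#' @export
write_dataset <- function(dataset, path) {
  rec <- if (inherits(dataset, "hpg_dataset")) dataset$records else dataset
  write.csv(rec, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic study from known true parameters, calibrates the
#' model on it, and reports, per calibrated quantity, the truth, posterior
#' median and 95% interval, whether the interval covers the truth, and the
#' convergence diagnostics.
#'
#' @param design study design.
#' @param true_values named vector of true values for the calibrated model
#'   parameters (defaults: the reference posterior means).
#' @param true_error_model generating error variances (see
#'   [generate_study()]).
#' @param calibrate parameters to calibrate (default: `names(true_values)`).
#' @param n_chains,n_iter MCMC protocol.
#' @param seed integer seed controlling data generation and the chains.
#' @param gsd physiology dispersion of the generated fish.
#' @param solver solver options.
#' @param progress passed to [run_chains()].
#' @return List of class `hpg_recovery` with `summary` (data frame), `max_rhat`,
#'   `coverage` (fraction of quantities whose 95% CI covers truth),
#'   `chains`, and `pool`.
#' @export
recovery_experiment <- function(design = design_tb_recovery(),
                                true_values = NULL,
                                true_error_model = NULL,
                                calibrate = NULL,
                                n_chains = 4, n_iter = 400, seed = 1,
                                gsd = 1.3, solver = .coarse_solver(),
                                progress = 0) {
  if (is.null(true_values)) {
    true_values <- unlist(.calibrated_defaults[c("lam_TB_bld", "RBA_TB_T",
                                                 "sc_Vmax_Vtg_liv",
                                                 "rho_d_LH_brn")])
  }
  if (is.null(calibrate)) calibrate <- names(true_values)
  set.seed(seed)
  true_params <- hpg_params(as.list(true_values))
  ds <- generate_study(true_params, true_error_model, design, gsd = gsd,
                       solver = solver)
  problem <- calib_problem(ds, calibrate = calibrate, solver = solver)
  chains <- run_chains(problem, n_chains = n_chains, n_iter = n_iter,
                       seed = seed, progress = progress)
  keep <- chains$n_iter - chains$burn
  thin <- max(1L, floor(keep / 100L))
  pool <- pool_posterior(chains, keep_last = keep, thin = thin)
  summ <- summarize_posterior(pool)
  truth_all <- c(true_values[calibrate], ds$true_error_model)
  summ$truth <- truth_all[summ$parameter]
  summ$covered <- summ$q2.5 <= summ$truth & summ$truth <= summ$q97.5
  summ$rhat <- .rhat_all(chains)[summ$parameter]
  structure(list(summary = summ, max_rhat = max(summ$rhat),
                 coverage = mean(summ$covered), chains = chains,
                 pool = pool, dataset = ds),
            class = "hpg_recovery")
}
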