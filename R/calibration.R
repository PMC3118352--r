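# Bayesian calibration by component-wise Metropolis-within-Gibbs:
# priors, lognormal measurement-error likelihood, conjugate inverse-gamma
# variance updates, multi-chain runner, pooling, Gelman-Rubin diagnostics.

# ---------------------------------------------------------------------------
# Priors

.new_prior <- function(kind, p1, p2) {
  structure(list(kind = kind, p1 = p1, p2 = p2), class = "hpg_prior")
}

#' Prior distribution constructors
#'
#' `prior_lognormal(gm, gsd)` is parameterized by geometric mean and
#' geometric standard deviation; `prior_loguniform(lo, hi)` is uniform in
#' log space; `prior_uniform(lo, hi)` is uniform in linear space;
#' `prior_invgamma(shape, scale)` is the conjugate inverse-gamma prior for
#' a normal variance.
#'
#' @param gm,gsd geometric mean and geometric standard deviation (> 1).
#' @param lo,hi support bounds (positive, finite).
#' @param shape,scale inverse-gamma parameters.
#' @return An `hpg_prior` object.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_lognormal <- function(gm, gsd) {
  stopifnot(gm > 0, gsd > 1)
  .new_prior("lognormal", gm, gsd)
}

#' @rdname priors
#' @export
prior_loguniform <- function(lo, hi) {
  stopifnot(lo > 0, hi > lo, is.finite(hi))
  .new_prior("loguniform", lo, hi)
}

#' @rdname priors
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(hi > lo, is.finite(hi), lo > 0)
  .new_prior("uniform", lo, hi)
}

#' @rdname priors
#' @export
prior_invgamma <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  .new_prior("invgamma", shape, scale)
}

#' Prior log density
#' @param prior an `hpg_prior`.
#' @param x evaluation point(s), positive.
#' @param log return log density (default `TRUE`).
#' @return (Log) density; `-Inf` outside the support.
#' @export
prior_density <- function(prior, x, log = TRUE) {
  ld <- switch(prior$kind,
    lognormal = dlnorm(x, meanlog = base::log(prior$p1),
                       sdlog = base::log(prior$p2), log = TRUE),
    loguniform = ifelse(x >= prior$p1 & x <= prior$p2,
                        -base::log(x) - base::log(base::log(prior$p2 / prior$p1)),
                        -Inf),
    uniform = ifelse(x >= prior$p1 & x <= prior$p2,
                     -base::log(prior$p2 - prior$p1), -Inf),
    invgamma = ifelse(x > 0,
                      prior$p1 * base::log(prior$p2) - lgamma(prior$p1) -
                        (prior$p1 + 1) * base::log(x) - prior$p2 / x,
                      -Inf),
    stop("unknown prior kind")
  )
  ld[!is.finite(x) | x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' Sample from a prior
#' @param prior an `hpg_prior`.
#' @param n number of draws.
#' @return Numeric vector of draws (uses the current RNG stream).
#' @export
prior_sample <- function(prior, n) {
  switch(prior$kind,
    lognormal = rlnorm(n, meanlog = base::log(prior$p1),
                       sdlog = base::log(prior$p2)),
    loguniform = exp(runif(n, base::log(prior$p1), base::log(prior$p2))),
    uniform = runif(n, prior$p1, prior$p2),
    invgamma = 1 / rgamma(n, shape = prior$p1, rate = prior$p2),
    stop("unknown prior kind")
  )
}

#' Reference priors of the 17 calibratable model parameters
#' @return Named list of `hpg_prior` objects.
#' @export
default_priors <- function() {
  list(
    lam_TB_bld = prior_loguniform(1, 1e3),
    Kd_E2ER = prior_lognormal(8.6, 3),
    RBA_EE2_E2 = prior_lognormal(1.66, 3),
    RBA_TB_T = prior_lognormal(6.03, 3),
    rho_d_LH_brn = prior_loguniform(0.01, 1e3),
    rho_u_LH_brn = prior_loguniform(0.01, 1e3),
    n_T = prior_lognormal(1.8, 3),
    rho_Chol_gon = prior_loguniform(1, 5e3),
    sc_Vmax_aro_gon = prior_loguniform(2.3e-5, 0.23),
    rho_E2_LHLR_gon = prior_loguniform(0.1, 100),
    sc_Vmax_Vtg_liv = prior_loguniform(1, 1e4),
    n_VTG = prior_uniform(1, 10),
    Pbg_ER_liv = prior_loguniform(5e-5, 0.5),
    k_ER_liv = prior_lognormal(0.08, 3),
    Pbg_AR_brn = prior_loguniform(5e-5, 0.5),
    K_AR_brn = prior_loguniform(5e-4, 5),
    Mag_LH = prior_loguniform(2.7e-7, 2.7e-3)
  )
}

.endpoints <- c(E2 = "e2_ng_ml", T = "t_ng_ml", VTG = "vtg_mg_ml")
.obs_cols <- c(E2 = "plasma_E2_ng_ml", T = "plasma_T_ng_ml",
               VTG = "plasma_VTG_mg_ml")
.groups <- c("unexposed", "TB", "EE2")

#' Inverse-gamma error-variance priors per endpoint
#'
#' One conjugate inverse-gamma prior per plasma endpoint, shared across
#' exposure groups: E2 `(2, 1.19)`, T `(2, 0.53)`, VTG `(2, 5.31)` in
#' natural-log space.
#' @return Named list (`E2`, `T`, `VTG`) of `hpg_prior` objects.
#' @export
default_error_priors <- function() {
  list(E2 = prior_invgamma(2, 1.19), T = prior_invgamma(2, 0.53),
       VTG = prior_invgamma(2, 5.31))
}

#' Error-variance cells for a set of exposure groups
#'
#' The measurement-error model has one lognormal variance per
#' (exposure group x endpoint) cell; the full design (unexposed, TB, EE2)
#' has 9 cells.
#'
#' @param groups exposure groups present.
#' @return Named list of `hpg_prior` objects, one per cell, named
#'   `Var_<endpoint>_<group>`.
#' @export
error_cells <- function(groups = .groups) {
  groups <- match.arg(groups, .groups, several.ok = TRUE)
  ep <- default_error_priors()
  cells <- list()
  for (g in groups) {
    for (e in names(ep)) cells[[paste0("Var_", e, "_", g)]] <- ep[[e]]
  }
  cells
}

#' Joint log prior density
#' @param theta named vector of parameter (and/or variance) values.
#' @param priors named list of `hpg_prior` objects covering `names(theta)`.
#' @return Scalar log density; `-Inf` outside any support.
#' @export
log_prior <- function(theta, priors) {
  stopifnot(all(names(theta) %in% names(priors)))
  sum(vapply(names(theta),
             function(nm) prior_density(priors[[nm]], theta[[nm]]),
             numeric(1)))
}

# ---------------------------------------------------------------------------
# Calibration problem: dataset + scenarios + priors + forward model

.median_fill <- function(records) {
  for (col in c("bw_kg", "gsi_pct", "hsi_pct")) {
    med <- median(records[[col]], na.rm = TRUE)
    if (!is.finite(med)) {
      med <- switch(col, bw_kg = 0.0016, gsi_pct = 11, hsi_pct = 3.0)
    }
    records[[col]][is.na(records[[col]])] <- med
  }
  records
}

#' Define a calibration problem
#'
#' Binds an observed dataset (per-fish physiology and plasma endpoints),
#' the exposure scenarios its groups reference, the subset of model
#' parameters to calibrate with their priors, and the forward-model
#' configuration. Missing body weight / GSI / HSI values are filled with
#' the dataset-wide medians; by default each (group, scenario) is simulated
#' once at the group-median physiology and shared across its fish.
#'
#' @param dataset either an `hpg_dataset` (from [generate_study()]) or a
#'   records data frame with columns `fish_id`, `group`, `scenario_id`,
#'   `time_hr`, `bw_kg`, `gsi_pct`, `hsi_pct`, `e2_ng_ml`, `t_ng_ml`,
#'   `vtg_mg_ml` (NA = not measured).
#' @param scenarios named list of [exposure_scenario()] objects keyed by
#'   `scenario_id` (taken from `dataset` if it is an `hpg_dataset`).
#' @param calibrate names of model parameters to calibrate.
#' @param priors named priors for `calibrate` (defaults from
#'   [default_priors()]).
#' @param params base parameter set supplying everything not calibrated.
#' @param solver solver options for the embedded forward simulations
#'   (coarser than the display default).
#' @param physiology one of `"median"` (group-median physiology, default)
#'   or `"per_fish"`.
#' @return Object of class `hpg_calib_problem`.
#' @export
calib_problem <- function(dataset, scenarios = NULL,
                          calibrate = c("lam_TB_bld", "RBA_TB_T",
                                        "sc_Vmax_Vtg_liv", "rho_d_LH_brn"),
                          priors = default_priors()[calibrate],
                          params = hpg_params(),
                          solver = .coarse_solver(),
                          physiology = c("median", "per_fish")) {
  physiology <- match.arg(physiology)
  if (inherits(dataset, "hpg_dataset")) {
    if (is.null(scenarios)) scenarios <- dataset$scenarios
    records <- dataset$records
  } else {
    records <- dataset
  }
  stopifnot(is.data.frame(records), !is.null(scenarios))
  need <- c("fish_id", "group", "scenario_id", "time_hr", "bw_kg",
            "gsi_pct", "hsi_pct", "e2_ng_ml", "t_ng_ml", "vtg_mg_ml")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("dataset missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(records$group %in% .groups)) {
    stop("groups must be in {", paste(.groups, collapse = ", "), "}")
  }
  ep <- as.matrix(records[, .endpoints])
  if (any(rowSums(!is.na(ep)) == 0L)) {
    stop("every record needs at least one measured endpoint")
  }
  if (any(ep <= 0, na.rm = TRUE)) stop("endpoint measurements must be positive")
  if (!all(records$scenario_id %in% names(scenarios))) {
    stop("records reference unknown scenario_id(s)")
  }
  stopifnot(all(calibrate %in% calibratable_parameters()),
            all(calibrate %in% names(priors)))
  records <- .median_fill(records)

  # simulation units: one forward run per unique (scenario, physiology, times)
  if (physiology == "median") {
    key <- paste(records$group, records$scenario_id)
  } else {
    key <- paste(records$fish_id, records$scenario_id)
  }
  records$sim_key <- key
  units <- lapply(split(records, key), function(r) {
    list(scenario_id = r$scenario_id[1],
         phys = fhm_physiology(median(r$bw_kg), median(r$gsi_pct),
                               median(r$hsi_pct)),
         times = sort(unique(r$time_hr)))
  })
  groups <- sort(unique(records$group))
  structure(list(records = records, scenarios = scenarios,
                 calibrate = calibrate, priors = priors,
                 error_priors = error_cells(groups), groups = groups,
                 params = params, solver = solver, units = units,
                 physiology = physiology),
            class = "hpg_calib_problem")
}

# Baseline-affecting parameters: the unexposed periodic state depends on
# every calibratable except the TB-specific uptake/affinity ones.
.baseline_free <- c("lam_TB_bld", "RBA_TB_T")

# Forward-predict every record's endpoints for one theta. `cache` is an
# environment reused across proposals: baselines are keyed by the values of
# the baseline-affecting parameters and warm-started from the previous
# baseline when those change.
.predict_records <- function(problem, theta, cache = new.env(parent = emptyenv())) {
  params <- hpg_params(modifyList(unclass(problem$params)[
    setdiff(names(problem$params),
            c("Kd_EE2ER", "Kd_TBAR", "k1_EE2ER", "k1_TBAR", "C_AR_liv",
              "sc_Vmax_aro_brn", "D_mp_brn"))],
    as.list(theta)))
  solver <- problem$solver
  bkey_vals <- theta[setdiff(names(theta), .baseline_free)]
  preds <- vector("list", length(problem$units))
  names(preds) <- names(problem$units)
  for (uk in names(problem$units)) {
    u <- problem$units[[uk]]
    pkey <- paste0(uk, "|", paste(signif(c(u$phys$body_weight, u$phys$gsi,
                                           u$phys$hsi), 12), collapse = ","))
    bkey <- paste(signif(bkey_vals, 12), collapse = ",")
    slot <- cache[[pkey]]
    if (!is.null(slot) && identical(slot$bkey, bkey)) {
      baseline <- slot$baseline
    } else {
      seed_state <- if (!is.null(slot)) slot$baseline else NULL
      baseline <- .baseline(u$phys, params, solver, seed_state)
      cache[[pkey]] <- list(bkey = bkey, baseline = baseline)
    }
    scen <- problem$scenarios[[u$scenario_id]]
    times <- u$times
    if (nrow(scen$segments) == 0L) {
      # unexposed: the baseline is 24-hr periodic, so observables at any
      # time are those at its diurnal phase
      phases <- times %% 24
      up <- sort(unique(phases))
      if (identical(up, 0)) {
        ob1 <- extract_observables(baseline, params)[unname(.obs_cols)]
        obs <- as.data.frame(matrix(rep(ob1, each = length(times)),
                                    nrow = length(times)))
        names(obs) <- unname(.obs_cols)
      } else {
        sim <- .integrate(baseline, unique(c(0, up)), u$phys, params, scen,
                          solver)
        od <- extract_observables(as.data.frame(sim), params)
        obs <- od[match(phases, sim[, "time"]), unname(.obs_cols)]
      }
    } else {
      sim_times <- if (times[1] > 0) c(0, times) else times
      sim <- simulate_hpg(u$phys, params, scen, sim_times, state0 = baseline,
                          solver = solver)
      obs <- sim[match(times, sim$time), unname(.obs_cols)]
    }
    rownames(obs) <- as.character(times)
    preds[[uk]] <- obs
  }
  preds
}

# internal: baseline with optional warm start from a nearby theta's baseline
.baseline <- function(phys, params, solver, seed_state = NULL) {
  if (is.null(seed_state)) {
    return(initialize_baseline(phys, params, solver))
  }
  .settle(pmax(seed_state, 0), phys, params, solver, block = 4L)
}

# log-space residuals per (group x endpoint) cell given unit predictions
.residual_cells <- function(problem, preds) {
  rec <- problem$records
  cells <- list()
  for (i in seq_len(nrow(rec))) {
    pr <- preds[[rec$sim_key[i]]]
    yhat <- pr[as.character(rec$time_hr[i]), ]
    for (e in names(.endpoints)) {
      y <- rec[[.endpoints[[e]]]][i]
      if (is.na(y)) next
      cell <- paste0("Var_", e, "_", rec$group[i])
      r <- base::log(y) - base::log(max(yhat[[.obs_cols[[e]]]], 1e-12))
      cells[[cell]] <- c(cells[[cell]], r)
    }
  }
  cells
}

.cell_stats <- function(cells) {
  list(n = vapply(cells, length, integer(1)),
       SS = vapply(cells, function(r) sum(r^2), numeric(1)))
}

.loglik_from_stats <- function(stats, variances) {
  nm <- names(stats$n)
  v <- variances[nm]
  sum(-0.5 * stats$n * base::log(2 * pi * v) - stats$SS / (2 * v))
}

#' Log likelihood of a parameter vector under the lognormal error model
#'
#' Runs the forward model for every simulation unit of the problem and
#' accumulates, over all present endpoint measurements, the normal log
#' density of the log-scale residual with the (group x endpoint) error
#' variance. Missing endpoints are skipped.
#'
#' @param theta named vector of calibrated model-parameter values.
#' @param error_model named vector of error variances (one per
#'   `Var_<endpoint>_<group>` cell of the problem).
#' @param problem an [calib_problem()] object.
#' @param cache optional environment carrying warm-start baselines across
#'   repeated calls.
#' @return Scalar log likelihood, with attributes `stats` (per-cell
#'   residual counts and sums of squares) and `residuals`.
#' @export
log_likelihood <- function(theta, error_model, problem,
                           cache = new.env(parent = emptyenv())) {
  stopifnot(inherits(problem, "hpg_calib_problem"))
  preds <- .predict_records(problem, theta, cache)
  cells <- .residual_cells(problem, preds)
  stats <- .cell_stats(cells)
  ll <- .loglik_from_stats(stats, error_model)
  attr(ll, "stats") <- stats
  attr(ll, "residuals") <- cells
  ll
}

#' Conjugate Gibbs update of the error variances
#'
#' Each (group x endpoint) variance cell is drawn from its inverse-gamma
#' full conditional `InvGamma(shape + n/2, scale + SS/2)` given the
#' log-scale residuals; cells with no residuals are drawn from the prior.
#'
#' @param residuals_by_cell named list of log-scale residual vectors.
#' @param priors named list of `prior_invgamma` cells (see [error_cells()]).
#' @return Named vector of variance draws covering `names(priors)`.
#' @export
gibbs_update_variances <- function(residuals_by_cell, priors) {
  out <- numeric(length(priors))
  names(out) <- names(priors)
  for (nm in names(priors)) {
    pr <- priors[[nm]]
    stopifnot(pr$kind == "invgamma")
    r <- residuals_by_cell[[nm]]
    shape <- pr$p1 + length(r) / 2
    scale <- pr$p2 + sum(r^2) / 2
    out[nm] <- 1 / rgamma(1, shape = shape, rate = scale)
  }
  out
}

#' One component-wise Metropolis sweep
#'
#' Random-walk proposals are made for each component in turn: in log space
#' for positively supported components (`log_scale = TRUE`, with the
#' appropriate Jacobian term), in linear space otherwise. A proposal is
#' accepted with probability `min(1, exp(delta log-posterior))`.
#'
#' @param theta named numeric vector, current state.
#' @param lp current log-posterior value of `theta`.
#' @param log_post function of a theta vector returning the log posterior.
#' @param scales per-component proposal standard deviations.
#' @param log_scale logical per component; propose on the log scale.
#' @return List with updated `theta`, `lp`, and logical `accepted` per
#'   component.
#' @export
metropolis_step <- function(theta, lp, log_post, scales,
                            log_scale = rep(TRUE, length(theta))) {
  accepted <- logical(length(theta))
  names(accepted) <- names(theta)
  for (k in seq_along(theta)) {
    prop <- theta
    if (log_scale[k]) {
      prop[k] <- theta[k] * exp(scales[k] * rnorm(1))
      jac <- base::log(prop[k]) - base::log(theta[k])
    } else {
      prop[k] <- theta[k] + scales[k] * rnorm(1)
      jac <- 0
    }
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) &&
        base::log(runif(1)) < (lp_prop + jac) - lp) {
      theta <- prop
      lp <- lp_prop
      accepted[k] <- TRUE
    }
  }
  list(theta = theta, lp = lp, accepted = accepted)
}

#' Run multiple Markov chains on a calibration problem
#'
#' Component-wise Metropolis-within-Gibbs: each sweep updates every
#' calibrated model parameter by a random-walk Metropolis proposal
#' (log-space except for uniform-prior parameters) and then draws the
#' error variances from their conjugate inverse-gamma full conditionals.
#' Proposal scales adapt toward an acceptance rate of 0.23-0.44 during the
#' burn-in (first half) only, so the kept draws are Markovian. Chains are
#' deterministic given `seed`.
#'
#' @param problem an [calib_problem()] object.
#' @param n_chains number of independent chains (>= 2 for diagnostics).
#' @param n_iter sweeps per chain.
#' @param seed integer seed; chain `i` uses `seed + i - 1`.
#' @param init_scales initial proposal standard deviations (log units).
#' @param start optional named starting theta (defaults to prior medians,
#'   jittered per chain).
#' @param progress print a line every `progress` iterations (0 = quiet).
#' @return Object of class `hpg_chains`: list of per-chain draw matrices
#'   (`n_iter` rows; columns = calibrated parameters then variance cells),
#'   plus acceptance rates and metadata.
#' @export
run_chains <- function(problem, n_chains = 4, n_iter = 400, seed = 1,
                       init_scales = 0.3, start = NULL, progress = 0) {
  stopifnot(inherits(problem, "hpg_calib_problem"), n_chains >= 1)
  pars <- problem$calibrate
  vcells <- names(problem$error_priors)
  log_scale <- vapply(pars, function(nm) {
    problem$priors[[nm]]$kind != "uniform"
  }, logical(1))
  burn <- floor(n_iter / 2)
  chains <- vector("list", n_chains)
  acc_rates <- matrix(NA_real_, n_chains, length(pars),
                      dimnames = list(NULL, pars))
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    cache <- new.env(parent = emptyenv())
    # start at prior medians (jittered) unless supplied
    theta <- if (is.null(start)) {
      vapply(pars, function(nm) {
        pr <- problem$priors[[nm]]
        med <- switch(pr$kind,
          lognormal = pr$p1,
          loguniform = sqrt(pr$p1 * pr$p2),
          uniform = (pr$p1 + pr$p2) / 2)
        if (pr$kind == "uniform") {
          min(max(med * (1 + 0.1 * rnorm(1)), pr$p1), pr$p2)
        } else {
          med * exp(0.25 * rnorm(1))
        }
      }, numeric(1))
    } else {
      stopifnot(all(pars %in% names(start)))
      start[pars]
    }
    lprior <- log_prior(theta, problem$priors)
    ll <- log_likelihood(theta, setNames(rep(1, length(vcells)), vcells),
                         problem, cache)
    stats <- attr(ll, "stats")
    resid <- attr(ll, "residuals")
    variances <- gibbs_update_variances(resid, problem$error_priors)
    ll_val <- .loglik_from_stats(stats, variances)
    lp <- lprior + ll_val
    scales <- rep_len(init_scales, length(pars))
    names(scales) <- pars
    draws <- matrix(NA_real_, n_iter, length(pars) + length(vcells),
                    dimnames = list(NULL, c(pars, vcells)))
    acc_win <- integer(length(pars))
    win <- 25L
    acc_tot <- integer(length(pars))
    cur_stats <- stats
    cur_resid <- resid
    for (it in seq_len(n_iter)) {
      for (k in seq_along(pars)) {
        prop <- theta
        if (log_scale[k]) {
          prop[k] <- theta[k] * exp(scales[k] * rnorm(1))
          jac <- base::log(prop[k]) - base::log(theta[k])
        } else {
          prop[k] <- theta[k] + scales[k] * rnorm(1)
          jac <- 0
        }
        lpr <- log_prior(prop, problem$priors)
        if (is.finite(lpr)) {
          llv <- log_likelihood(prop, variances, problem, cache)
          lp_prop <- lpr + as.numeric(llv)
          if (base::log(runif(1)) < (lp_prop + jac) - lp) {
            theta <- prop
            lp <- lp_prop
            cur_stats <- attr(llv, "stats")
            cur_resid <- attr(llv, "residuals")
            acc_win[k] <- acc_win[k] + 1L
            if (it > burn) acc_tot[k] <- acc_tot[k] + 1L
          }
        }
      }
      variances <- gibbs_update_variances(cur_resid, problem$error_priors)
      lp <- log_prior(theta, problem$priors) +
        .loglik_from_stats(cur_stats, variances)
      if (it <= burn && it %% win == 0L) {
        rate <- acc_win / win
        scales[rate < 0.23] <- scales[rate < 0.23] * exp(-0.35)
        scales[rate > 0.44] <- scales[rate > 0.44] * exp(0.35)
        acc_win[] <- 0L
      }
      draws[it, ] <- c(theta, variances)
      if (progress > 0 && it %% progress == 0L) {
        message("chain ", ch, " iteration ", it, "/", n_iter)
      }
    }
    chains[[ch]] <- draws
    acc_rates[ch, ] <- acc_tot / (n_iter - burn)
  }
  structure(list(chains = chains, parameters = pars, variance_cells = vcells,
                 n_iter = n_iter, burn = burn, seed = seed,
                 acceptance = acc_rates),
            class = "hpg_chains")
}

#' Pool thinned posterior draws across chains
#'
#' Takes the last `keep_last` iterations of each chain, extracts every
#' `thin`-th draw, and concatenates chain-major. The reference protocol
#' (4 chains, keep 10,000 of 20,000, thin 10) yields 4,000 pooled sets.
#'
#' @param chains an `hpg_chains` object or list of draw matrices.
#' @param keep_last number of final iterations to keep per chain.
#' @param thin thinning stride.
#' @return Matrix of pooled draws (class `hpg_pool`), rows in chain-major
#'   order, with a `chain` attribute.
#' @export
pool_posterior <- function(chains, keep_last = 10000, thin = 10) {
  mats <- if (inherits(chains, "hpg_chains")) chains$chains else chains
  stopifnot(length(mats) >= 1)
  n <- nrow(mats[[1]])
  stopifnot(keep_last <= n, thin >= 1, keep_last %% thin == 0 ||
              thin <= keep_last)
  idx <- (n - keep_last) + seq(thin, keep_last, by = thin)
  pooled <- do.call(rbind, lapply(mats, function(m) m[idx, , drop = FALSE]))
  attr(pooled, "chain") <- rep(seq_along(mats), each = length(idx))
  class(pooled) <- c("hpg_pool", class(pooled))
  pooled
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `Rhat = sqrt((n-1)/n + B/(n*W))` from the between-chain variance of the
#' chain means (`B = n * var(means)`) and the mean within-chain variance
#' `W`, computed over the kept portion of each chain.
#'
#' @param chains an `hpg_chains` object, a list of draw matrices, or a
#'   numeric matrix with one column per chain.
#' @param param parameter name (for chain objects/matrices with named
#'   columns); ignored when `chains` is already an iterations x chains
#'   matrix of one quantity.
#' @param keep_last number of final iterations per chain to use (default:
#'   the post-burn-in half).
#' @return Scalar Rhat (>= values near 1 indicate convergence; the
#'   acceptance band of the reference protocol is [1.0, 1.2]).
#' @export
rhat <- function(chains, param = NULL, keep_last = NULL) {
  if (inherits(chains, "hpg_chains")) {
    mats <- chains$chains
    if (is.null(keep_last)) keep_last <- chains$n_iter - chains$burn
    x <- vapply(mats, function(m) {
      m[(nrow(m) - keep_last + 1):nrow(m), param]
    }, numeric(keep_last))
  } else if (is.list(chains) && !is.matrix(chains)) {
    x <- vapply(chains, function(m) {
      v <- if (is.matrix(m)) m[, param] else m
      if (!is.null(keep_last)) v <- v[(length(v) - keep_last + 1):length(v)]
      v
    }, numeric(if (is.null(keep_last)) {
      if (is.matrix(chains[[1]])) nrow(chains[[1]]) else length(chains[[1]])
    } else keep_last))
  } else {
    x <- as.matrix(chains)
  }
  n <- nrow(x)
  m <- ncol(x)
  stopifnot(m >= 2, n >= 10)
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  if (W == 0) return(1)
  sqrt((n - 1) / n + B / (n * W))
}

#' Maximum Rhat over all calibrated quantities
#' @param chains an `hpg_chains` object.
#' @param keep_last kept iterations per chain (default: post-burn-in half).
#' @return Named vector of Rhat values with attribute-free max via `max()`.
#' @keywords internal
.rhat_all <- function(chains, keep_last = NULL) {
  quant <- c(chains$parameters, chains$variance_cells)
  vapply(quant, function(q) rhat(chains, q, keep_last), numeric(1))
}

#' Summarize a posterior pool
#'
#' Per calibrated quantity: mean, median, and central 95% interval
#' (2.5th/97.5th percentiles, linear-interpolation rule, `quantile`
#' type 7).
#'
#' @param pool matrix of pooled draws (from [pool_posterior()]).
#' @return `data.frame` with columns `parameter`, `mean`, `median`,
#'   `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(pool) {
  stopifnot(nrow(pool) >= 1)
  qs <- t(apply(pool, 2, quantile, probs = c(0.025, 0.5, 0.975),
                type = 7, names = FALSE))
  data.frame(parameter = colnames(pool),
             mean = unname(colMeans(pool)),
             median = qs[, 2], q2.5 = qs[, 1], q97.5 = qs[, 3],
             row.names = NULL)
}
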