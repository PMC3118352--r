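# Posterior-predictive simulation: the pooled posterior draws are treated
# as a population of fish; sampled draws are simulated under a study's
# scenario and observed endpoints are drawn from the lognormal error model.

#' Sample "fish" (parameter sets) from a posterior pool
#'
#' Uniform sampling with replacement; each sampled row carries the error
#' variances of its own posterior iteration, preserving the
#' parameter-variance correlation.
#'
#' @param pool pooled draw matrix from [pool_posterior()].
#' @param n number of fish to sample.
#' @return Matrix of `n` sampled rows (all pool columns), with attribute
#'   `draw_index` giving the pool rows sampled.
#' @export
sample_fish <- function(pool, n) {
  stopifnot(n >= 1, nrow(pool) >= 1)
  idx <- sample.int(nrow(pool), n, replace = TRUE)
  out <- pool[idx, , drop = FALSE]
  attr(out, "draw_index") <- idx
  out
}

#' Posterior-predictive endpoint simulation for one fish
#'
#' Runs the forward model under one sampled parameter set and draws
#' observed endpoints from the lognormal error model
#' `exp(Normal(ln yhat, Var))` with the (group x endpoint) variance carried
#' by the parameter set; both the deterministic prediction and the sampled
#' observation are returned.
#'
#' @param param_set named vector: calibrated model parameters (any subset
#'   of [calibratable_parameters()]) plus optionally `Var_<endpoint>_<group>`
#'   cells. Non-calibrated parameters come from `params`.
#' @param physiology an [fhm_physiology()]; missing fields of a partial
#'   list are filled with the medians.
#' @param scenario exposure scenario.
#' @param times sampling times (hr).
#' @param group exposure class used to select the variance cells.
#' @param params base parameter set.
#' @param variances optional named variance vector overriding the cells in
#'   `param_set` (e.g. fixed at posterior medians).
#' @param solver solver options.
#' @param n_draws number of observation draws per time point (one forward
#'   simulation regardless).
#' @return `data.frame` with columns `time_hr`, `endpoint`, `draw`,
#'   `deterministic_pred`, `sampled_obs`.
#' @export
predict_endpoints <- function(param_set, physiology = default_physiology(),
                              scenario = zero_exposure(), times = 504,
                              group = "unexposed", params = hpg_params(),
                              variances = NULL, solver = solver_options(),
                              n_draws = 1) {
  group <- match.arg(group, .groups)
  ps <- as.list(param_set)
  model_pars <- ps[names(ps) %in% calibratable_parameters()]
  p <- if (length(model_pars)) hpg_params(modifyList(unclass(params)[
    setdiff(names(params), c("Kd_EE2ER", "Kd_TBAR", "k1_EE2ER", "k1_TBAR",
                             "C_AR_liv", "sc_Vmax_aro_brn", "D_mp_brn"))],
    model_pars)) else params
  if (is.null(variances)) {
    vn <- grep("^Var_", names(ps), value = TRUE)
    variances <- unlist(ps[vn])
  }
  times <- sort(unique(times))
  sim_times <- if (length(times) == 0 || times[1] > 0) c(0, times) else times
  sim <- simulate_hpg(physiology, p, scenario, sim_times, solver = solver)
  out <- list()
  for (e in names(.endpoints)) {
    yhat <- sim[match(times, sim$time), .obs_cols[[e]]]
    cell <- paste0("Var_", e, "_", group)
    v <- if (cell %in% names(variances)) variances[[cell]] else 0
    yh <- rep(yhat, n_draws)
    draw <- if (v > 0) {
      exp(rnorm(length(yh), base::log(pmax(yh, 1e-12)), sqrt(v)))
    } else {
      yh
    }
    out[[e]] <- data.frame(time_hr = rep(times, n_draws), endpoint = e,
                           draw = rep(seq_len(n_draws), each = length(times)),
                           deterministic_pred = yh, sampled_obs = draw)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Coverage report: posterior predictions against observations
#'
#' Per (group, endpoint, time): the prediction percentiles used in the
#' box-plot convention (5, 10, 25, 50, 75, 90, 95), the observed median,
#' whether the observed median falls inside the central 95% prediction
#' interval, and the ratio of predicted to observed medians.
#'
#' @param predictions data frame with columns `group`, `endpoint`,
#'   `time_hr`, `sampled_obs` (one row per simulated fish and time).
#' @param observations data frame with columns `group`, `endpoint`,
#'   `time_hr`, `value` (one row per measured fish and time).
#' @return `data.frame` keyed by group/endpoint/time with percentile
#'   columns `p5` ... `p95`, `obs_median`, `median_in_ci95`,
#'   `median_ratio`.
#' @export
coverage_report <- function(predictions, observations) {
  need_p <- c("group", "endpoint", "time_hr", "sampled_obs")
  need_o <- c("group", "endpoint", "time_hr", "value")
  stopifnot(all(need_p %in% names(predictions)),
            all(need_o %in% names(observations)))
  keys <- unique(observations[, c("group", "endpoint", "time_hr")])
  probs <- c(5, 10, 25, 50, 75, 90, 95) / 100
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    pv <- predictions$sampled_obs[
      predictions$group == k$group & predictions$endpoint == k$endpoint &
        predictions$time_hr == k$time_hr]
    ov <- observations$value[
      observations$group == k$group & observations$endpoint == k$endpoint &
        observations$time_hr == k$time_hr]
    if (length(pv) == 0 || length(ov) == 0) return(NULL)
    qs <- quantile(pv, probs = probs, type = 7, names = FALSE)
    ci <- quantile(pv, probs = c(0.025, 0.975), type = 7, names = FALSE)
    om <- median(ov)
    data.frame(k, p5 = qs[1], p10 = qs[2], p25 = qs[3], p50 = qs[4],
               p75 = qs[5], p90 = qs[6], p95 = qs[7], obs_median = om,
               median_in_ci95 = ci[1] <= om & om <= ci[2],
               median_ratio = qs[4] / om)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
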