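test_that("prior densities match closed forms and supports", {
  # outside a loguniform support
  expect_identical(prior_density(prior_loguniform(1, 1000), 0.5), -Inf)
  expect_identical(prior_density(prior_uniform(1, 10), 12), -Inf)
  # lognormal(8.6, 3): density of log(x) maximal at log(8.6)
  pr <- prior_lognormal(8.6, 3)
  xs <- exp(seq(log(0.1), log(500), length.out = 501))
  dens_in_log <- prior_density(pr, xs) + log(xs)  # density of log(x)
  expect_equal(xs[which.max(dens_in_log)], 8.6, tolerance = 0.02)
  # inverse-gamma closed form
  ig <- prior_invgamma(2, 1.19)
  v <- c(0.2, 0.5, 1.3)
  expect_equal(prior_density(ig, v, log = FALSE),
               1.19^2 / gamma(2) * v^(-3) * exp(-1.19 / v), tolerance = 1e-12)
  # loguniform normalizes to 1
  lu <- prior_loguniform(0.01, 1e3)
  expect_equal(integrate(function(x) prior_density(lu, x, log = FALSE),
                         0.01, 1e3)$value, 1, tolerance = 1e-6)
  # joint log prior is the sum of the marginals
  pri <- list(a = pr, b = lu)
  th <- c(a = 3, b = 5)
  expect_equal(log_prior(th, pri),
               prior_density(pr, 3) + prior_density(lu, 5))
})

test_that("the nine error-variance cells follow the endpoint priors", {
  cells <- error_cells()
  expect_length(cells, 9)  # 3 groups x 3 endpoints
  expect_setequal(names(cells),
                  as.vector(outer(c("Var_E2_", "Var_T_", "Var_VTG_"),
                                  c("unexposed", "TB", "EE2"), paste0)))
  expect_equal(cells$Var_E2_TB$p2, 1.19)
  expect_equal(cells$Var_T_unexposed$p2, 0.53)
  expect_equal(cells$Var_VTG_EE2$p2, 5.31)
  expect_equal(cells$Var_E2_TB$p1, 2)
})

test_that("Gibbs variance update: prior draw at n = 0, consistency at large n", {
  priors <- list(Var_E2_TB = prior_invgamma(2, 1.19))
  set.seed(1)
  # n = 0: draws distributed as the prior
  d0 <- replicate(4000, gibbs_update_variances(list(), priors))
  expect_equal(median(d0), 1.19 / qgamma(0.5, 2), tolerance = 0.05)
  # large n at true variance v: posterior concentrates near v
  v_true <- 0.7
  set.seed(2)
  r <- rnorm(20000, 0, sqrt(v_true))
  d1 <- replicate(200, gibbs_update_variances(list(Var_E2_TB = r), priors))
  expect_equal(mean(d1), v_true, tolerance = 0.03)
  expect_lt(sd(d1), 0.02)
})

test_that("metropolis sweep: free moves always accepted, supports respected", {
  set.seed(1)
  # flat target: every proposal has delta log-posterior = 0
  flat <- function(th) 0
  th <- c(a = 1, b = 2)
  for (i in 1:20) {
    st <- metropolis_step(th, 0, flat, scales = c(0.5, 0.5),
                          log_scale = c(FALSE, FALSE))
    expect_true(all(st$accepted))
    th <- st$theta
  }
  # proposals outside a loguniform support are always rejected
  pri <- list(a = prior_loguniform(1, 10))
  lp_fun <- function(th) log_prior(th, pri)
  th <- c(a = 9.99)
  rejected_out <- TRUE
  set.seed(2)
  for (i in 1:200) {
    st <- metropolis_step(th, lp_fun(th), lp_fun, scales = 2)
    if (st$theta > 10 || st$theta < 1) rejected_out <- FALSE
    th <- st$theta
  }
  expect_true(rejected_out)
})

test_that("metropolis sampler reproduces a known target distribution", {
  # target Gamma(3, rate 2), sampled with log-scale random-walk proposals;
  # compare moments against the analytic mean 1.5 and var 0.75
  lp <- function(th) dgamma(th[["x"]], 3, 2, log = TRUE)
  set.seed(42)
  th <- c(x = 1)
  cur <- lp(th)
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    st <- metropolis_step(th, cur, lp, scales = 0.9)
    th <- st$theta
    cur <- st$lp
    draws[i] <- th
  }
  keep <- draws[-(1:2000)]
  ess_guess <- length(keep) / 10
  expect_equal(mean(keep), 1.5, tolerance = 3 * sqrt(0.75 / ess_guess))
  expect_equal(var(keep), 0.75, tolerance = 0.1)
  # empirical acceptance rate matches the brute-force acceptance integral
  # E_pi E_q [min(1, pi(y) y / (pi(x) x))] for the log-scale walk
  set.seed(7)
  x <- rgamma(20000, 3, 2)
  y <- x * exp(0.9 * rnorm(20000))
  alpha <- pmin(1, exp(dgamma(y, 3, 2, log = TRUE) + log(y) -
                         dgamma(x, 3, 2, log = TRUE) - log(x)))
  acc_theory <- mean(alpha)
  acc_emp <- mean(diff(draws) != 0)
  expect_equal(acc_emp, acc_theory, tolerance = 0.02)
})

test_that("pooling bookkeeping: chain-major, thinned, reproducible", {
  chains <- lapply(1:4, function(ch) {
    matrix(ch * 1e5 + 1:20000, ncol = 1, dimnames = list(NULL, "p"))
  })
  pool <- pool_posterior(chains, keep_last = 10000, thin = 10)
  expect_equal(nrow(pool), 4000)
  # chain-major order: first block from chain 1, starting at iteration 10010
  expect_equal(unname(pool[1, "p"]), 1e5 + 10010)
  expect_equal(unname(pool[1001, "p"]), 2e5 + 10010)
  expect_equal(attr(pool, "chain"), rep(1:4, each = 1000))
  # thin = keep_last: one draw per chain
  p1 <- pool_posterior(chains, keep_last = 10000, thin = 10000)
  expect_equal(nrow(p1), 4)
})

test_that("Gelman-Rubin Rhat: common target near 1, separated chains large", {
  set.seed(5)
  same <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(same), 1.02)
  expect_gte(rhat(same), sqrt((nrow(same) - 1) / nrow(same)))
  apart <- same + rep(c(0, 5, 10, 15), each = 1000)
  expect_gt(rhat(apart), 1.2)
  # formula oracle computed directly from between/within variances
  n <- nrow(apart)
  W <- mean(apply(apart, 2, var))
  B <- n * var(colMeans(apart))
  expect_equal(rhat(apart), sqrt((n - 1) / n + B / (n * W)),
               tolerance = 1e-12)
  expect_error(rhat(same[, 1, drop = FALSE]))
})

test_that("posterior summaries match a sorting-based percentile oracle", {
  const <- matrix(2.5, nrow = 50, ncol = 1, dimnames = list(NULL, "p"))
  s <- summarize_posterior(const)
  expect_equal(unlist(s[, c("mean", "median", "q2.5", "q97.5")]),
               c(mean = 2.5, median = 2.5, q2.5 = 2.5, q97.5 = 2.5))
  set.seed(9)
  pool <- matrix(rlnorm(600), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  s <- summarize_posterior(pool)
  # type-7 percentile oracle: sorted linear interpolation
  oracle_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (i in 1:2) {
    expect_equal(s$q2.5[i], oracle_q(pool[, i], 0.025), tolerance = 1e-12)
    expect_equal(s$q97.5[i], oracle_q(pool[, i], 0.975), tolerance = 1e-12)
    expect_equal(s$median[i], oracle_q(pool[, i], 0.5), tolerance = 1e-12)
  }
})

test_that("log likelihood: perfect fit contribution and variance monotonicity", {
  # a dataset whose observations equal the deterministic predictions
  set.seed(11)
  design <- design_tb_recovery(doses_ug_L = 0.5, n = 2)
  tiny <- setNames(rep(1e-12, 6), names(error_cells(c("unexposed", "TB"))))
  ds <- generate_study(true_error_model = tiny, design = design, gsd = 1)
  pr <- calib_problem(ds, calibrate = c("lam_TB_bld", "RBA_TB_T"))
  theta <- c(lam_TB_bld = 7.47, RBA_TB_T = 5.25)
  vars <- setNames(rep(0.5, 6), names(error_cells(c("unexposed", "TB"))))
  ll <- log_likelihood(theta, vars, pr)
  st <- attr(ll, "stats")
  # residuals are (numerically) zero, so each of the n contributions is
  # -0.5 * log(2*pi*Var)
  n_obs <- sum(st$n)
  expect_equal(n_obs, 12)  # 2 groups x 2 fish x 3 endpoints
  expect_equal(as.numeric(ll), -0.5 * n_obs * log(2 * pi * 0.5),
               tolerance = 1e-4)
  # doubling the variance of a perfectly fit group lowers the likelihood
  vars2 <- vars
  vars2["Var_E2_TB"] <- 1.0
  expect_lt(as.numeric(hpgaxis:::.loglik_from_stats(st, vars2)),
            as.numeric(ll))
})

test_that("calib_problem validates its dataset contract", {
  set.seed(12)
  ds <- generate_study(design = design_tb_recovery(doses_ug_L = 0.5, n = 2),
                       gsd = 1)
  rec <- ds$records
  expect_s3_class(calib_problem(rec, ds$scenarios), "hpg_calib_problem")
  bad <- rec; bad$group <- "mystery"
  expect_error(calib_problem(bad, ds$scenarios), "group")
  bad <- rec; bad$e2_ng_ml[1] <- -2
  expect_error(calib_problem(bad, ds$scenarios), "positive")
  bad <- rec; bad[1, c("e2_ng_ml", "t_ng_ml", "vtg_mg_ml")] <- NA
  expect_error(calib_problem(bad, ds$scenarios), "endpoint")
  bad <- rec; bad$scenario_id <- "nope"
  expect_error(calib_problem(bad, ds$scenarios), "scenario")
})

test_that("chains are deterministic given seeds", {
  set.seed(13)
  ds <- generate_study(design = design_tb_recovery(doses_ug_L = 0.5, n = 2),
                       gsd = 1)
  pr <- calib_problem(ds, calibrate = c("lam_TB_bld", "sc_Vmax_Vtg_liv"))
  c1 <- run_chains(pr, n_chains = 2, n_iter = 6, seed = 99)
  c2 <- run_chains(pr, n_chains = 2, n_iter = 6, seed = 99)
  expect_identical(c1$chains, c2$chains)
  c3 <- run_chains(pr, n_chains = 2, n_iter = 6, seed = 100)
  expect_false(identical(c1$chains, c3$chains))
})
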