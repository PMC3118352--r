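# Shared, lazily computed fixtures (memoised so expensive objects are
# built once per test run).

.fix <- new.env(parent = emptyenv())

fix_phys <- function() default_physiology()
fix_params <- function() hpg_params()

fix_baseline <- function() {
  if (is.null(.fix$baseline)) {
    .fix$baseline <- initialize_baseline(fix_phys(), fix_params())
  }
  .fix$baseline
}

# one scaled-down synthetic calibration shared by the convergence and
# parameter-recovery checks
fix_recovery <- function() {
  if (is.null(.fix$recovery)) {
    .fix$recovery <- recovery_experiment(
      design = design_tb_recovery(doses_ug_L = c(0.05, 0.5, 5), n = 3),
      n_chains = 4, n_iter = 160, seed = 7, gsd = 1.3)
  }
  .fix$recovery
}

random_state <- function(seed, scale = 2) {
  set.seed(seed)
  setNames(runif(48, 0, scale), state_names())
}
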