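---
title: "Modelling the HPG axis of female fathead minnows under endocrine disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the HPG axis of female fathead minnows under endocrine disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpgaxis)
```

## The biological problem

The hypothalamic–pituitary–gonadal (HPG) axis controls reproduction in fish
through a cascade of hormones: the brain produces luteinizing hormone (LH),
LH bound to its gonadal receptor drives steroidogenesis (testosterone, T,
and — via aromatase — 17β-estradiol, E2), and estrogen-bound receptors in
the liver drive production of vitellogenin (VTG), the egg-yolk precursor.
Endocrine-disrupting chemicals perturb this axis: 17α-ethynylestradiol
(EE2), a synthetic estrogen from contraceptive pills, binds the estrogen
receptor (ER); 17β-trenbolone (TB), a stable metabolite of a livestock
growth promoter, binds the androgen receptor (AR). Both reach surface
waters at ng/L levels and alter plasma E2, T and VTG in the fathead minnow
(*Pimephales promelas*, FHM), the standard small-fish model of
ecotoxicology. TB exposure in particular produces non-monotonic, "U-shaped"
dose–responses in female FHM plasma steroids.

`hpgaxis` implements a physiologically based toxicokinetic/toxicodynamic
model of this axis for the adult female FHM, together with the Bayesian
machinery to calibrate it and to propagate posterior uncertainty into
population-level predictions.

## Model structure

### Compartments and transport

The fish is divided into six compartments: gill, brain, gonad, liver,
venous blood, and "other" (the aggregated remainder). Arterial blood is not
an independent compartment: its concentrations equal venous ones except
where gill exchange intervenes. Each perfused compartment $j$ obeys a
flow-limited mass balance for each mobile species $i$:

$$V_j \frac{dC_{i,j}}{dt} = F_j \left(C_{i,\mathrm{art}} -
  \frac{C_{i,j}}{\lambda_{i,j}}\right) + P_{i,j} - S_{i,j} -
  V_j\, b_{i,j},$$

where $F_j$ is the compartment blood flow, $\lambda_{i,j}$ the
tissue:blood partition coefficient, $P$ and $S$ production and sink terms
(nmol/hr), and $b_{i,j}$ the net receptor-binding flux (nmol/L/hr). Venous
blood collects the returns $\sum_j F_j C_{i,j}/\lambda_{i,j}$ and feeds the
arterial side at cardiac output $F_\mathrm{car}$.

Volumes follow body-weight percentages at tissue density 1 kg/L: the
gonadosomatic, hepatosomatic and brain somatic indices (GSI, HSI, BSI) are
per-fish inputs; gill and venous percentages are constants; "other" is the
remainder. Gill water flow and cardiac output scale allometrically
($10.6\,BW^{0.75}$ and $2.06\,BW^{0.75}$ L/hr). The per-compartment blood
flow *fractions* are not independently known for all compartments, so the
package assigns flows proportional to the perfused compartments'
body-weight percentages; this guarantees the internal-consistency
requirement $\sum_j F_j = F_\mathrm{car}$ exactly, which in turn makes
transport exactly mass-conserving.

### Gill exchange

Water-borne chemicals (EE2, TB, and in principle E2) enter across the gill
under equilibrium partitioning with blood:water coefficient
$\lambda_{i,\mathrm{bld}}$. The net uptake flux is
$F_\mathrm{eff}\,(C_{i,\mathrm{H_2O}} - C_{i,\mathrm{ven}}/\lambda)$ with
$F_\mathrm{eff} = \min(FW_\mathrm{gil},\, F_\mathrm{car}\lambda)$; the
$\min$ caps exchange at the thermodynamic limit when ventilation exceeds
what perfusion can carry. The gill itself accumulates nothing.

### Receptor binding

Every ligand–receptor pair follows mass-action kinetics
$db/dt = k_1 C_\mathrm{free} C_{R,\mathrm{free}} - k_1 K_d\, b$, so the
dissociation rate constant is $k_\mathrm{off} = k_1 K_d$. ER pools in
brain and gonad, AR pools in gonad and liver, the gonadal LH receptor, and
the venous steroid-binding protein (SBP, total 400 nmol/L) have fixed
totals: the free receptor is computed as total minus bound, which makes
the pool-conservation identity exact by construction. Competitive binding
of the xenobiotics uses relative binding affinities:
$K_{d,\mathrm{EE2\cdot ER}} = K_{d,\mathrm{E2\cdot ER}}/RBA_\mathrm{EE2:E2}$
and $K_{d,\mathrm{TB\cdot AR}} = K_{d,\mathrm{T\cdot AR}}/RBA_\mathrm{TB:T}$.

Two receptor pools are dynamic. Liver ER is auto-regulated: synthesized at
$Pbg_\mathrm{ER} + k_\mathrm{ER}\,C_\mathrm{ERbd}$ and degraded at
$k_{e,\mathrm{ER}}$. Brain AR is synthesized at a rate inhibited
hyperbolically by free androgens,
$Pbg_\mathrm{AR}\,K_\mathrm{AR}/(K_\mathrm{AR} + C_T + C_{TB})$, and
degraded at $k_{e,\mathrm{AR}}$.

**Receptor-mediated turnover.** For the two dynamic pools the package also
degrades the ligand–receptor *complexes* at the pool's elimination rate
(internalization destroying receptor and ligand). This term is required
for the model to possess a baseline at all: because bound liver ER induces
its own synthesis faster ($k_\mathrm{ER} = 0.027$/hr at the calibrated
mean) than free-ER degradation removes it ($k_{e,\mathrm{ER}} = 0.01$/hr),
a formulation that degrades only free ER grows the ER pool without bound
whenever liver free E2 exceeds
$K_d\,k_e/(k_\mathrm{ER}-k_e) \approx 0.66$ nmol/L, which the
self-consistent unexposed state does. With complex turnover the system has
a stable 24-hour periodic baseline. The term is part of the
sources-and-sinks group and is switched off in the kinetics-only
(conservation-checking) mode.

### Endocrine feedback

* **LH (brain).** Background production is a diurnal cycle
  $Mag_\mathrm{LH}(1 + \sin 2\pi t/24)$ — period 24 h, mean
  $Mag_\mathrm{LH}$, never negative, phase 0 at lights-on — up-regulated by
  bound ER, $(1 + C_\mathrm{ERbd}/\rho_u)$, and down-regulated by bound AR,
  $1/(1 + C_\mathrm{ARbd}/\rho_d)$. All regulation terms are hyperbolic in
  a concentration because each regulation parameter carries nmol/L units.
* **T (gonad).** Bound LH receptor sets StAR
  ($C_\mathrm{StAR} = \rho_\mathrm{StAR} C_\mathrm{LHLR}$), StAR sets
  cholesterol delivery ($C_\mathrm{chol} = \rho_\mathrm{chol}
  C_\mathrm{StAR}$), and the side-chain-cleavage chain converts cholesterol
  with Hill kinetics ($n_T$, $K_{0.5} = 190$ nmol/L), inhibited by gonadal
  bound ER through $1/(1 + C_\mathrm{ERbd}/K_T)$ with $K_T = 0.016$
  (treated as nmol/L; the source table prints it unitless).
* **E2 (gonad and brain aromatase).** Michaelis–Menten conversion of free
  T ($K_m = 9.6$ nmol/L), with $(1 + \rho_{E2}\,C_\mathrm{LHLR})$ induction
  in the gonad only. $V_\mathrm{max}$ scales with microsomal protein
  density and compartment volume. Aromatization consumes T mole-for-mole —
  the reaction converts the substrate, so E2 production appears as an equal
  T sink in the same compartment.
* **VTG (liver).** Hill response to bound liver ER
  ($n_\mathrm{VTG}$, $K_{0.5} = 1$ nmol/L) scaled by $BW^{0.75}$; VTG is
  absorbed into oocytes from the gonad pool at 0.05/hr and eliminated
  slowly (0.001/hr) in "other".
* **Eliminations.** First-order in the "other" compartment for all six
  species; TB shares the EE2 rate constant (0.1/hr).

### Observables

Plasma steroid concentrations are the total (free + SBP-bound) venous
concentration divided by the plasma fraction of venous blood (0.45) and
converted to mass units with molecular weights 272.39 (E2), 288.43 (T),
296.41 (EE2) and 270.37 (TB) g/mol. VTG uses a configurable molecular
weight, default $1.8\times10^5$ g/mol — a literature-typical teleost VTG
monomer scale; the source material never states one, and the choice only
rescales the reported mg/ml. Division by the plasma fraction (rather than
reporting whole-blood concentration) was chosen because the assays are run
on plasma.

## Numerical treatment

The 48-state stiff system is integrated with `deSolve::lsoda`, default
tolerances `rtol = 1e-8`, `atol = 1e-12` nmol/L. The right-hand side exists
twice: a readable R reference (`hpg_rhs()`), assembled from the exported
rate laws, and a compiled C mirror used by `simulate_hpg()`; the test suite
asserts exact agreement between the two on random states. Integrations are
restarted at exposure-segment boundaries so the solver never steps across a
forcing discontinuity, and state components within `-atol` of zero are
clamped to zero inside rate evaluations.

The unexposed baseline is found by integrating from a small positive seed
state until the maximum relative change of every component between
consecutive 24-hour windows falls below `1e-6` (the attractor is a diurnal
limit cycle, not a fixed point, because of the LH forcing); the returned
state sits at diurnal phase 0. The baseline is insensitive to the seed
magnitude, which the tests probe at ×10 and ×0.1.

During MCMC calibration a coarser profile is used (`rtol = 1e-6`,
`atol = 1e-9`, baseline tolerance `1e-4`), and baselines are warm-started
from the previous accepted parameter point. Unexposed-group predictions
exploit the baseline's exact 24-hour periodicity instead of re-integrating
the full study duration.

## Calibration machinery

The measurement model is lognormal: each plasma measurement has geometric
mean equal to the model prediction, with one log-space variance per
(exposure group × endpoint) cell — 9 cells in the full three-group design.
Variances carry conjugate inverse-gamma priors (E2: IG(2, 1.19), T:
IG(2, 0.53), VTG: IG(2, 5.31)) and are drawn from their full conditionals
by Gibbs steps. The 17 calibratable model parameters carry the reference
priors (lognormal, log-uniform, or uniform; e.g. the brain E2–ER
dissociation constant is lognormal with geometric mean 8.6 nmol/L and
geometric SD 3) and are updated by component-wise random-walk Metropolis —
log-space proposals with the matching Jacobian, linear-space for
uniform-prior parameters. Proposal scales adapt toward an acceptance rate
of 0.23–0.44 during the burn-in (first half) only, so kept draws are
Markovian. The sampler kernel is a package design choice: the reference
protocol names its software but not its kernel, so equivalence is claimed
at the level of the posterior, not the trace.

Convergence is monitored with the Gelman–Rubin potential scale reduction
factor, $\hat R = \sqrt{(n-1)/n + B/(nW)}$, acceptance band [1.0, 1.2].
The reference protocol runs 4 chains × 20,000 iterations, keeps the last
10,000, and thins by 10, pooling 4 × 1,000 = 4,000 parameter sets.

During calibration each fish's missing body weight, GSI or HSI is filled
with the dataset medians, and by default each (group, scenario) is
simulated once at the group-median physiology — mirroring the median
fill-in practice of the reference study; an exact per-fish mode is
available (`physiology = "per_fish"`).

### Posterior-predictive simulation

The pooled draws are treated as a population: `sample_fish()` samples
parameter sets uniformly *with replacement* (the protocol does not state
with or without; with-replacement treats the pool as the population
distribution and keeps draws exchangeable for any study size). Each
sampled fish is simulated deterministically, then observed endpoints are
drawn from the lognormal error model using the variances of the same
posterior iteration, preserving parameter–variance correlation (a
fixed-at-median mode is available through the `variances` argument).
`coverage_report()` summarizes predictions against observations with the
box-plot percentile convention (5/10/25/50/75/90/95) and flags whether
each observed median falls inside the central 95% prediction interval.

## The synthetic-data generator

No machine-readable fish data accompany the source material, so the
package generates its own studies with the statistical structure the
calibration assumes: per-fish physiology lognormal around the adult female
medians (0.0016 kg, GSI 11%, HSI 3.0%) with geometric SD 1.3 — a
conventional modest biological dispersion, chosen once; the dispersion is
not printed anywhere — optional missingness masks, group-wise exposure
designs mirroring the laboratory studies (21-day flow-through TB at five
doses with n = 12; 48-hour static TB with E2 and VTG measured in disjoint
halves of n = 8; 8-day exposure + 8-day depuration; 21-day EE2 at
0.5/1.5/4.5 ng/L with n = 28), and lognormal endpoint noise with
group-specific variances. `recovery_experiment()` closes the loop:
generate → calibrate → check that the 95% posterior intervals cover the
generating truth and that $\hat R \le 1.2$.

What the generator does *not* emulate: assay-specific biases (polyclonal
vs monoclonal ELISA scale differences), seasonal physiology, and any
between-fish correlation beyond physiology — so passing recovery tests
demonstrates the calibration machinery is self-consistent, not that the
model is correct for real fish.

### Problem sizes of the shipped experiments

The scaled-down calibration used by the acceptance script calibrates a
4-parameter subset (`lam_TB_bld`, `RBA_TB_T`, `sc_Vmax_Vtg_liv`,
`rho_d_LH_brn`) plus the 6 error-variance cells of a two-group design,
on a 21-day TB study with control + 3 doses (0.05/0.5/5 µg/L) at n = 4
fish per group, 4 chains × 280 iterations with the coarse solver profile.
The test suite runs a slightly smaller variant (n = 3, 160 iterations).
These sizes are the package's desk-scale defaults; the full protocol
(17 parameters, 9 cells, 20,000 iterations) is available through the same
functions.

## Known limitations

* The exact algebraic bodies of the source model's equations are not
  recoverable from the available material (they are typeset as images);
  the forms here are reconstructed from the printed symbol lists and
  units, with every regulation term hyperbolic in its concentration. This
  is the single most important structural gap.
* At the calibrated-mean parameters the reconstructed system settles at a
  baseline whose bound liver ER (~220 nmol/L) sits far above the VTG Hill
  half-saturation constant (1 nmol/L), so the VTG branch operates near
  saturation: the qualitative dose–response properties (monotone EE2→VTG;
  U-shaped TB→VTG) hold but with very small VTG amplitudes, while E2 and T
  respond with full amplitude. Baseline plasma levels are correspondingly
  higher than typical assay values. Re-calibration against real data would
  move the operating point.
* No seasonality, no GnRH state, no oocyte growth or fecundity: these are
  outside the model's scope.
* Calibration-scale runs use the coarse solver profile; observables move
  by well under 0.1% when tolerances are halved (tested), but the coarse
  baseline tolerance (1e-4) is part of the likelihood definition during
  MCMC.

## A short tour

```{r tour, eval = FALSE}
phys <- default_physiology()
params <- hpg_params()

# unexposed periodic baseline and its observables
baseline <- initialize_baseline(phys, params)
extract_observables(baseline, params)

# 48-hour mixture exposure: 15 ng TB/L + 10 ng EE2/L
mix <- exposure_scenario(c("TB", "EE2"), 0, 48, c(15, 10), unit = "ng/L")
sim <- simulate_hpg(phys, params, mix, times = seq(0, 96, by = 2),
                    state0 = baseline)

# synthetic study, calibration, recovery
rec <- recovery_experiment(design = design_tb_recovery(n = 4),
                           n_chains = 4, n_iter = 280, seed = 1)
rec$summary
```
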