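---
title: "Methods: the glomerular fibrosis network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the glomerular fibrosis network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`glomfib` simulates an eight-species kinetic network for diabetes-induced
glomerular fibrosis in the mouse. Sustained high blood glucose drives the
cascade

glucose → AGE → MCP → macrophages → TGF-β → activated mesangial cells →
{MMP ⇄ TIMP} → collagen,

with each arrow a saturating (Hill or Michaelis–Menten) activation and each
species subject to first-order removal. The state vector, in fixed order, is
`AGE, MCP, MAC, TGF, AMC, MMP, TIMP, COL` (all concentrations in g/mL;
`gf_species()` returns this order). Blood glucose is an input, not a state: a
continuous piecewise-linear ramp from the healthy level `G1 = 1e-3` g/mL to
the diabetic level `G2 = 5e-3` g/mL between weeks 6 and 16, mimicking disease
onset in a db/db-like mouse.

Structural assumptions worth knowing before using the package:

* The network is feed-forward except for the MMP/TIMP pair, which inhibit
  one another bilinearly. Nothing downstream feeds back on AGE or glucose.
* Mesangial cells are a constant density `MC` (g/mL of tissue); activation
  moves a signalling state, it does not consume the pool.
* Collagen lysis is modelled as a flux proportional to MMP alone
  (`gamma_COL * MMP`, no collagen factor), following the source model's
  collagen balance. At very low collagen this term could in principle drive
  the state negative; over all simulated scenarios collagen stays positive,
  and the test suite asserts positivity across every scenario.
* Internally all rates are per day and time is in days; every user-facing
  interface (horizons, treatment times, trajectory columns) is in weeks.

## Parameters and two derived constants

`gf_params()` returns the default parameter set: production rates
(`lambda_*`, (g/mL)/day or /day depending on the balance), removal rates
(`mu_*`, /day), saturation constants (`K_*`, g/mL), Hill exponents (`n_*`,
dimensionless, ≥ 1), the bilinear MMP/TIMP couplings (`gamma_*`), the glucose
programme (`G1`, `G2`, `t1 = 6`, `t2 = 16` weeks), and culture-side constants
(`MCP_vitro`, `mu_AMC_vitro`). Two constants are derived, not tabulated:

* `S_MCP = mu_MCP * MCP_vitro = 2.77e-10` (g/mL)/day — baseline MCP
  production balancing unstimulated culture turnover.
* `MC` — the mesangial density is recovered by inverting the MCP
  steady-state balance at the healthy state (`derive_mc_density()`): given
  the healthy MCP (`1.783e-10` g/mL) and AGE (`1.5e-7` g/mL) concentrations,
  `MC = (mu_MCP * MCP_ss - S_MCP) / (lambda_MCP * AGE_ss / (K_AGE + AGE_ss))
  ≈ 0.661` g/mL. The reported healthy activated-cell concentration is then
  reproduced within 1%, which is the consistency check that validates the
  inversion.

One documented inconsistency: the tabulated TIMP production rate is
incompatible with the stated constraint that TIMP production is one fifth of
MMP production. The default follows the constraint
(`lambda_TIMP = lambda_MMP / 5`); `gf_params(lambda_TIMP_rule = "printed")`
selects the tabulated value instead. Under the default, the healthy TIMP
steady state lands ~41% from its reported value while MMP and collagen agree
within ~5%; no choice of the two rules reconciles all three, and the package
does not hide that.

## Steady states and initial values

`steady_state()` integrates to a long horizon and polishes the fixed point
with a damped Newton iteration (finite-difference Jacobian, positivity line
search). By default AGE is *anchored* at its measured healthy value
`1.5e-7` g/mL rather than at the model's own glucose-G1 fixed point
(`1.33e-7` g/mL); the anchored value is what the downstream balances were
calibrated against. Consequence: in the base-case simulation AGE first drifts
down toward its unanchored fixed point until the glucose ramp (week 6)
reverses it. `age_anchor = NULL` gives the self-consistent fixed point.

Trajectories carry an `at_steady_state` diagnostic flag per species, true
when `|dX/dt| < max(atol, 1e-3 |X|)` per day at the final time. Note the
strictness of that 0.1%/day yardstick: at 24 weeks of the base case only MCP
and TIMP qualify — AGE is still changing at ~0.9%/day and the others at
0.3–0.6%/day. The flags describe local flatness, not global convergence.

## Scenarios and reversal

`run_scenario()` simulates three idealised interventions applied at
`t_treat` (default week 24): `glucose_control` (glucose overridden to `G1`),
`age_production_inhibition` (AGE production divided by `1 + K_I`), and
`age_degradation_enhanced` (AGE removal multiplied by `1 + K_I`). The state
is continuous at `t_treat`; only the rate laws change, and the solver is
restarted there so the discontinuity in the right-hand side never crosses a
solver step.

`reversal_time()` defines reversal as collagen *entering and staying* within
a relative band (default 5%) of the healthy steady-state collagen, with the
entry time refined by linear interpolation. Threshold sensitivity: moving the
band over 2–10% shifts the glucose-control reversal clock by less than 15%
(≈80 weeks at 5%). The definition matters for the inhibition scenario, whose
collagen approaches the band tangentially — under the 5% band its elapsed
reversal is ~48 weeks, whereas a ~2.5–3% band would push it past 54 weeks.

Equivalence of glucose control and production inhibition: the two
post-treatment AGE courses share the first-order fall from the diabetic
burden but settle at different floors (G1-driven formation versus ~zero
formation). Inhibition reproduces glucose control *exactly* when
`1 + K_I` equals the ratio of the Hill activations at `G2` and `G1` (~77);
for stronger inhibition the maximum distance, normalised by the
treatment-time AGE burden, converges to a ~2.6% floor-difference limit.

## Calibration

`fit_subsystem()` estimates parameters a stage at a time in network order
(`age`, `mcp`, `mac`, `tgf`, `amc`, `mmp_timp_col`), holding upstream
parameters fixed — mirroring how the constants were originally obtained from
stage-specific experiments. Because the network is feed-forward, the upstream
trajectories are simulated once per fit and interpolated; each stage then
only needs its own species' balance, which is *linear* given the upstream
forcing. Predictions use an exponential integrator that is exact for
piecewise-linear forcing (quarter-day resolution), so no stiff-solver call
sits inside the optimiser. Fitting is bounded Levenberg–Marquardt
(`minpack.lm`) on log10-transformed parameters, box bounds `1e±3` times the
defaults (Hill exponents in [1, 20]), from a fixed deterministic five-point
multi-start. Time-series stages fit fold changes against the dataset's
recorded baseline; dose-response stages fit concentrations. The collagen
stage first (optionally) solves `lambda_MMP` against a healthy-MMP target
with `lambda_TIMP = lambda_MMP / 5`, and applies the single-study
`exclusion_rule()` before fitting.

## Synthetic data

`generate_timeseries()` and `generate_dose_response()` produce calibration
inputs with the structure of the original pooled literature data: fold-change
time series over 0–24 weeks (sparse two-point designs for AGE and the
activated-cell marker, denser for macrophages, TGF-β and collagen) and
in vitro dose-response curves. Noise is multiplicative log-normal calibrated
to mean 1 (`sigma^2 = log(1 + cv^2)`), so noiseless expectations are unbiased
at any CV; seeds make datasets reproducible without touching the global RNG
stream. The 10-week collagen point is tagged as single-study to give the
exclusion rule a realistic target. Limits: real inter-study heterogeneity is
not just multiplicative i.i.d. noise (systematic lab offsets, correlated
time points), and the actual replicate counts of the source figures are not
reproduced — the generator is for recovery testing, not for re-deriving the
published fits.

## Numerics and problem sizes

The ODE system is stiff (rates span `8.7e-3`–`3.33`/day and concentrations
span `1e-13`–`1` g/mL); `deSolve::lsoda` with `rtol = 1e-8`,
`atol = 1e-15` integrates it. Ramp breakpoints and treatment times are
inserted into the output grid and the solver is restarted at treatment.
Typical costs on one CPU: a 24-week base case ~0.4 s, a 120-week scenario
~1.5 s, a steady state <1 s, one noiseless stage fit ~1 s, the
100-replicate noisy-recovery study ~3 minutes, a full one-at-a-time
sensitivity scan (~30 parameters, two simulations each) ~1 minute.

## Worked example

```{r}
library(glomfib)

p <- gf_params()
ss <- steady_state(p)            # healthy state, AGE anchored at 1.5e-7
tr <- run_scenario(p, gf_scenario("glucose_control"), horizon_weeks = 120)
reversal_time(tr, ss[["COL"]])   # ~80.4 weeks on the simulation clock

sens <- local_sensitivity(p, parameters = c("lambda_COLA", "mu_AGE", "K_TGF"))
print(sens)
```

## Limitations

* Point estimates only: no uncertainty quantification, no global sensitivity
  analysis, no formal identifiability beyond the recovery tests.
* The interventions are idealised step changes in rate laws, not
  pharmacokinetics.
* The documented TIMP inconsistency (above) means absolute TIMP
  concentrations should not be trusted to better than ~40%; MMP and collagen
  dynamics are only mildly affected.
* The model is calibrated to mouse data pooled across studies; nothing here
  is a clinical prediction.
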