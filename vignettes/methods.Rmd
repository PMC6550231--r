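---
title: "Methods: the hybrid Markov-von Mises ingestion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid Markov-von Mises ingestion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosechain)
```

## Overview

`dosechain` models medication ingestion event streams from digital medicine
systems (drug + ingestible sensor). Each patient's record is reduced to a
binary sequence of successes (observed ingestions, S) and failures
(unobserved, F) over scheduled dosing opportunities, and four model
components are estimated per patient by maximum likelihood; a hierarchical
Bayesian layer then fits population distributions to the individual
estimates by MCMC. This vignette documents the modelling conventions, the
numerical choices, and the design decisions taken where the design was
genuinely open, in enough detail to audit or re-implement the package.

## From timestamps to dose-event sequences

A patient's log is a dosing interval `tau` (24 h for once-daily dosing), a
schedule anchor, and ingestion timestamps. Derivation conventions:

* **Nearest-opportunity assignment.** Each observed timestamp maps to the
  scheduled opportunity minimizing `|actual - expected|`. A tie at exactly
  `tau/2` breaks toward the *earlier* opportunity (the definition of
  "closest expected time" does not resolve ties; a fixed rule keeps
  derivation deterministic).
* **Observed ingestion duration.** The sequence spans the first to last
  observed ingestion inclusive, so `n_total = (last slot - first slot) + 1`
  and the sequence starts and ends with S by construction. Whether the
  endpoints are counted inclusively is not fixed by the verbal definition
  ("elapsed dosing intervals between first and last observed ingestion");
  we adopt inclusive slot counting so that `oip = #S / n_total` is the
  fraction of opportunities with an ingestion and a one-day record is
  impossible (patients need two or more ingestions; others are excluded
  with a logged reason).
* **Excess dosing.** An excess dosing event is any ingestion beyond the
  first within a calendar day. The first ingestion of a day fills its
  opportunity slot and contributes the timing deviation; later same-day
  ingestions only increment that day's excess count and never enter the
  Markov sequence (the chain is over scheduled opportunities; duplicate
  events are modelled separately as Poisson).
* **Excess denominators.** The per-day Poisson rate `lambda` is the mean
  excess count over days with at least one observed ingestion (S days). An
  excess event on an F day is a contradiction in terms — its first
  ingestion would make the day S — so empty days carry no information about
  duplicate dosing and are not counted. The generator mirrors this exactly,
  which is what makes the simulate-derive round trip exact.

## Individual estimation

**Markov component.** Closed-form MLEs from first-order transition counts:
`p_ss = n_ss/(n_ss+n_sf)`, `p_fs = n_fs/(n_fs+n_ff)`. A zero denominator
yields `NA` plus an `undefined_*` flag, never an exception, because
undefinedness is informative (an all-success patient has no failures to
correct). The helix-coil parameters are the row odds of the transition
matrix: `s = p_ss/(1-p_ss)`, `sigma = (p_fs/(1-p_fs))/s`. The transform is
undefined at probabilities 0 or 1, so inputs are clipped to
`[1e-6, 1 - 1e-6]` *for the transform only*, with a flag; the raw `p_fs` is
retained so that the prompt-corrector definition (`p_fs == 1` exactly, with
at least one failure) survives clipping untouched.

**Timing component.** Deviations map to angles `theta = 2*pi*delta/tau`.
The von Mises MLE uses the circular mean for `psi` and solves
`A1(omega) = Rbar` (Bessel-function ratio vs mean resultant length) by
bracketed root finding to `1e-10`. Degenerate cases: identical angles
(`Rbar = 1`) cap `omega` at 500 with a flag — a finite stand-in for a point
mass; `Rbar = 0` leaves `psi` undefined and sets `omega = 0`. No
small-sample bias correction is applied to `omega`: plain ML is what the
source toolchain for this model family computes, and a silent correction
would change results invisibly.

**Duration component.** `N_Total ~ Weibull(upsilon, kappa)` is fitted
across patients by profile likelihood (for fixed shape the scale MLE is
closed-form; the 1-D profile score is solved by `uniroot`). The density is
used in its *standard normalized* form. The unnormalized form
`x^(upsilon-1) exp(-(x/kappa)^upsilon)` sometimes quoted for this model is
not a probability density — its integral depends on the parameters — and is
not self-consistent for ML across both parameters; normalization is the
only coherent reading and matches every standard Weibull implementation.
Zero-variance input (all durations equal) sends the shape to infinity; it
is capped at 500 and flagged. The fit is deliberately performed outside the
MCMC: the Weibull shape mixes poorly in this hierarchy.

## The synthetic cohort: a stated world

Real DMS study data are proprietary, so the generator *is* the test bed.
Per-patient parameters are drawn from the population prior families, then
sequences are simulated forward: chain started at S, truncated at the last
simulated S (re-drawn if no second success), von Mises deviations attached
to each S, Poisson excess counts per S day, and exact timestamps
reconstructed as `anchor + slot*tau + delta`, excess ingestions strictly
after the slot-filling one within the same calendar day.

Default hyperparameters (a scenario is one stated world, chosen once):

| parameter | default | rationale |
|---|---|---|
| `a_s`, `b_s` | 1.7, 1.0 | median `p_ss ~ 0.85`; with median `p_fs ~ 0.5` the stationary success rate `pi_S = p_fs/(1+p_fs-p_ss) ~ 0.77`, matching a median observed ingestion percent near 76% |
| `a_sigma`, `b_sigma` | 1.2, 0.25 | right-skewed `sigma` with median `sigma*s` near 1, i.e. median `p_fs ~ 0.5` |
| `a_psi`, `b_psi` | 0, 2 | timing deviations centred on schedule, spread of a few hours |
| `a_omega`, `b_omega` | 1.5, 2 | median concentration ~4.5 (angular sd roughly 0.5 rad ~ 1.8 h) |
| `a_lambda` | 40 | mean excess rate 0.025/day: most patients show zero excess events over a few weeks, the rest a few percent |
| `upsilon`, `kappa` | 2, 55 | durations mostly 3-9 weeks, median ~46 days, consistent with 8-week use |
| anchor | noon | keeps realistic deviations inside their scheduled calendar day, so the excess-day and nearest-slot conventions never conflict |

Durations are rounded half-up and floored at 2 (they are counts of dosing
intervals). A single master seed is split into per-patient streams
(`patient_seed(seed, i)`), so any patient's data are reproducible
independently of cohort size.

`pc_fraction` deserves a note: it is implemented as a *target prevalence*.
A coin with probability `pc_fraction` forces `p_fs = 1` for that patient;
on tails, chance prompt-corrector sequences are rejected and re-simulated.
Without the rejection step the realized PC fraction would be
`pc_fraction + (1 - pc_fraction) * Pr(chance PC)` and could not concentrate
at the requested value, which is the property the generator is specified to
have. Leaving `pc_fraction` unset (the default) gives fully emergent PC
prevalence; at the default hyperparameters it lands near the ~22% reported
for this model family, which is a calibration check, not a fit.

What a green test on synthetic data does establish: correctness of the
derivation rules, the estimators against independent oracles, sampler
calibration, and end-to-end determinism. What it does not establish:
anything about real patients — the generator has no patch-wear gaps, no
sensor false negatives/positives, no covariate-dependent behaviour, no
non-daily regimens, and its parametric families are exactly the model's
assumptions (so model misfit cannot be detected by construction).

## The population layer

**Two-stage inference.** The individual MLEs are treated as observations
whose sampling distributions are the prior families (`z = log s` Normal
with mean/precision, `sigma` Gamma with shape/scale, `psi` von Mises,
`omega` LogNormal with mean/precision on the log scale, `lambda`
Exponential). This is deliberately *not* a joint raw-data hierarchical
model: the two-stage design is the defining feature of the framework being
implemented. Its known cost is attenuation: MLE noise inflates the apparent
population spread, so precision-type hyperparameters (`b_s`, `b_psi`,
`b_omega`) are biased low relative to the generative truth when fitted to
estimated rather than true parameters. The tests therefore separate the
concerns — sampler calibration is checked against cohorts of *exact* prior
draws, and the estimation layer is checked by individual-parameter recovery
(median absolute error of `p_ss`).

**Input policy.** Undefined or degenerate components are dropped per
component, never per patient: `p_fs`-undefined patients leave the `sigma`
model only; boundary `p_ss` (0 or 1) leaves the `z` and `sigma` models
(a clipped odds of `1e6` is an artifact of the clip constant, not data —
including such values demonstrably destroys the Normal and Gamma fits);
capped `omega` values leave the LogNormal model. Raw `p_fs` is always kept
for PC classification. Prompt correctors consequently do not enter the
`sigma` population model; the model family is known not to capture the
excess density at `p_fs = 1` (a mixture prior would, and is out of scope).

**Hyperpriors** (unspecified in the source framework; weakly informative,
domain-respecting, overridable in `mcmc_config()`): Normal(0, precision
0.001) for the unconstrained locations `a_s`, `a_omega`; Exponential(rate
0.01) for every positive hyperparameter; von Mises(0, 0.01) for the
circular location `a_psi`.

**Sampler.** Adaptive random-walk Metropolis-within-Gibbs: one univariate
update per hyperparameter per sweep, log-scale proposals (with Jacobian)
for positive parameters, wrapped proposals for `a_psi`. Every component
likelihood reduces to sufficient statistics, so an update is O(1) in cohort
size. Proposal scales adapt toward 0.44 acceptance in 50-iteration batches
during burn-in only and are frozen afterwards, preserving detailed balance
for every kept draw. Because the Gamma shape and scale are strongly
anti-correlated in the posterior, each sweep adds one mean-preserving joint
"ridge" move — opposite shifts in `(log a_sigma, log b_sigma)`, symmetric in
log space with unit Jacobian — which roughly doubles the effective sample
size for that pair. Chains are overdispersed at start (moment estimates
jittered chain-specifically) so the Gelman-Rubin diagnostic is meaningful.

**Scales.** Desk-scale defaults (3 chains x 20,000 kept, burn-in 5,000,
thinning 2) converge far below the PSRF < 1.05 bound in well under a minute
for 80-patient cohorts; `full_scale = TRUE` restores the conservative
3 x 200,000 / 50,000 settings of the original analysis. Convergence is
summarized by the Gelman-Rubin PSRF (implemented from the between/within
variance definition and verified against a hand-computed two-chain example)
and by Geyer initial-positive-sequence effective sample sizes.

**Posterior predictives.** Modeled density curves average the prior-family
density over posterior draws. The `p_ss` and `p_fs` curves push joint
`(s, sigma)` posterior-predictive draws through the transition-matrix
parameterization; the observed-ingestion-fraction curve pushes them through
the chain's stationary success probability `pi_S = p_fs/(1 + p_fs - p_ss)`,
followed by kernel density estimation on [0, 1]. How the original
framework computed its modeled OIP curve is not documented; the stationary
distribution is one defensible construction and is flagged as such.

## Subgroup analysis

Classification uses the raw `p_fs` only (invariant to clipping): PC iff
`p_fs == 1` with at least one observed failure; all-success patients are
*excluded* from classification rather than assigned — "prompt corrector"
presupposes a failure to correct. The battery reports unadjusted p-values:
Mann-Whitney for model parameters and numeric covariates (exact
enumeration, midranks for ties, for pooled n up to 20; normal approximation
with tie correction above), chi-square without continuity correction for
the diagnosis distribution (degrees of freedom as emitted by the table
actually tested), Fisher exact for sex and race, and the Kaplan-Meier
log-rank test for duration (no censoring arises: every patient has a last
observed ingestion). The PC threshold is exposed as the exact-1 rule only;
alternative thresholds are a config knob deliberately left unanalyzed.

## Numerical choices, collected

* probability clipping bound `1e-6` (helix-coil transform only);
* `omega` cap 500 and Weibull shape cap 500 for degenerate point masses,
  always flagged;
* von Mises concentration solved to `|A1(omega) - Rbar| < 1e-10`; log-space
  Bessel evaluation (`besselI(..., expon.scaled = TRUE)`) keeps likelihoods
  finite for concentrations beyond ~700;
* nearest-slot ties break toward the earlier opportunity;
* Weibull durations floored at 2 intervals, rounded half-up;
* all randomness flows from explicit seeds; chain `c` of a run seeded `s`
  uses `s + 1000c`, patient `i` uses a fixed integer recurrence, all below
  `2^31`.

## Limitations

Patch-wear compliance, sensor error, PRN/non-daily regimens and
covariate-dependent parameters are out of scope. The population model has
no mixture component for the prompt-corrector point mass at `p_fs = 1`, so
its `p_fs` predictive density understates that spike by design. Two-stage
inference attenuates precision hyperparameters as described above. The
`chi-square` diagnosis comparison needs expected counts that small cohorts
may not provide (R then warns); Fisher tests are reported only for tables
with at least two observed levels.
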