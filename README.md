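# dosechain

Hybrid Markov–von Mises modelling of medication ingestion patterns captured by
digital medicine systems.

## The problem

A digital medicine system (DMS) pairs an oral drug with an ingestible sensor,
a wearable patch and a phone app, so every scheduled dose either produces an
*observed ingestion* event with a timestamp or it does not. In populations
where adherence is both critical and hard to measure — notably serious mental
illness (schizophrenia, bipolar 1 disorder, major depressive disorder) on
once-daily antipsychotics — these event streams make it possible to move past
"percent of doses taken" and characterize the *temporal structure* of dosing
behaviour: streaks of success and failure, how promptly a missed dose is
corrected, how tightly timing clusters around the scheduled hour, duplicate
("excess") dosing, and how long patients keep using the system.

`dosechain` is for biostatisticians and digital-health researchers who have
per-patient ingestion timestamps (or want realistic synthetic ones) and need a
tested implementation of this model family.

## The model

For each patient *i*, four components are estimated by maximum likelihood from
the derived success/failure sequence over scheduled dosing opportunities:

1. **Two-state Markov chain.** Successes (S) and failures (F) follow a
   first-order chain with transition matrix

   ```
   A_i = [ p_SS   1 - p_SS ]   =  [ s/(1+s)            1/(1+s)      ]
         [ p_FS   1 - p_FS ]      [ sigma*s/(1+sigma*s) 1/(1+sigma*s) ]
   ```

   with closed-form MLEs `p_SS = N_SS/(N_SS+N_SF)`, `p_FS = N_FS/(N_FS+N_FF)`
   from the transition counts. The (s, sigma) parameterization comes from the
   helix-coil transition model of polymer physics: `s` is the success odds
   after a success, `sigma` modulates the odds after a failure. A patient with
   `p_FS = 1` exactly (every failure immediately corrected, at least one
   failure observed) is a **prompt corrector (PC)**.

2. **von Mises timing deviations.** Each observed ingestion deviates from its
   nearest scheduled time by `delta` hours; `theta = 2*pi*delta/tau` is
   modelled as von Mises(psi, omega) on the circle.

3. **Poisson excess dosing.** Ingestions beyond the first within a day occur
   at per-day rate `lambda`.

4. **Weibull duration.** The number of scheduled opportunities spanned by the
   first-to-last observed ingestion, `N_Total`, follows Weibull(upsilon,
   kappa), fitted across patients (outside the MCMC, where the shape mixes
   poorly).

A hierarchical Bayesian layer then treats the individual estimates as
observations from the population prior families — `z = log s ~ Normal(a_s,
precision b_s)`, `sigma ~ Gamma(a_sigma, scale b_sigma)`, `psi ~
vonMises(a_psi, b_psi)`, `omega ~ LogNormal(a_omega, precision b_omega)`,
`lambda ~ Exponential(a_lambda)` — and samples the nine hyperparameters by
adaptive Metropolis-within-Gibbs MCMC (3 chains, Gelman-Rubin PSRF < 1.05 as
the convergence bound), yielding posterior-predictive density curves for
visual checks and a PC-vs-NPC comparison battery (Mann-Whitney, chi-square,
Fisher exact, Kaplan-Meier log-rank).

Because real DMS study data are proprietary, the package ships a
synthetic-cohort generator with exactly the generative structure the model
assumes, used for all tests and recovery studies.

## Worked example

```r
library(dosechain)

scenario <- cohort_scenario(n_patients = 40)   # population defaults
cohort   <- simulate_cohort(scenario, seed = 8)
fit      <- dosechain(cohort$logs)             # per-patient MLEs
fit
#> Hybrid Markov-von Mises ingestion model
#>   40 patients fitted (0 excluded)
#>   median OIP = 74.3%, PC fraction = 22.5%
#>   duration: Weibull(upsilon = 2.23, kappa = 49.8)

summary(fit)
#> Adherence characteristics (median / IQR / range / mean / se):
#>                     median    iqr    min     max   mean    se
#> oip_percent         74.265 31.030 25.926 100.000 72.420 3.324
#> excess_rate_percent  0.000  5.336  0.000  50.000  4.129 1.360
#> duration_days       43.500 29.750  7.000  93.000 44.175 3.361
#> p_ss                 0.842  0.178  0.000   1.000  0.808 0.029
#> p_fs                 0.500  0.500  0.138   1.000  0.536 0.052
#> ...
```

The median observed ingestion percent (74.3%) is the fraction of scheduled
opportunities with an observed ingestion within each patient's observed
ingestion duration; the PC fraction (22.5%) is the share of classifiable
patients whose every failure was immediately followed by a success.

```r
pop <- fit_population(fit, mcmc_config(n_iter = 5000, burn_in = 2000, seed = 8))
pop
#> Population MCMC fit: 3 chains x 5000 kept (burn-in 2000, thin 2)
#>   max Gelman-Rubin PSRF = 1.0002 (converged, < 1.05)
#>   parameter     mean   median    q025    q975   psrf  ess
#> 1       a_s  1.71105  1.71286  1.4095  2.0160 1.0001 6484
#> 2       b_s  1.22735  1.20682  0.7286  1.8697 0.9999 5922
#> ...

compare_groups(fit)
#> Prompt-corrector subgroup report: 9 PC vs 28 NPC (3 unclassifiable)
#>   PC fraction: 24.3%
#>   mw_p_ss                  Mann-Whitney p = 0.002195
#>   mw_oip                   Mann-Whitney p = 2.945e-05
#>   ...
```

Here the posterior means bracket the generating hyperparameters (the cohort
was simulated at `a_s = 1.7`, `b_s = 1`), and the prompt correctors show the
expected profile: higher `p_SS` and OIP than non-prompt correctors.

`run_pipeline(scenario = scenario, out = "run1", seed = 8)` executes the whole
chain (simulate/read, derive, individual fits, population MCMC, subgroup
battery, report) and writes every stage artifact as plain CSV plus a
`report.md`; identical seed and configuration reproduce every artifact
byte-for-byte.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the closed-form
failure-to-success MLE of a hand-constructed prompt-corrector dose-event
sequence, and the maximum Gelman-Rubin PSRF across the nine population
hyperparameters for three independently seeded chains fitted to individual
estimates from the standard 80-patient, 60-opportunity synthetic cohort. The
results are written as JSON to `--out`.
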