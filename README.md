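# neosleep

Survival analysis and simulation of neonatal sleep–wake bout durations.

Preterm and term infants spend most of their time asleep, and the
*durations* of their sleep and wake bouts — not just the fraction of time
per state — carry the signature of how immature brainstem circuitry
regulates state switching. This package implements that bout-level
analysis for epoch-scored cot-side recordings, for researchers in neonatal
neurophysiology and developmental sleep science:

* **Censored bout extraction** — converts 30-second-epoch hypnograms
  (states `W` wakefulness, `AS` active sleep, `TS` transitional sleep,
  `QS` quiet sleep) into survival records, handling the one-minute minimum
  state rule, left-censoring of the first run, right-censoring at the end
  of the recording, and transitional-sleep interruptions.
* **Parametric duration laws under censoring** — maximum-likelihood fits
  of exponential, Weibull, lognormal and power-law bout-duration
  distributions with accelerated-failure-time (AFT) covariates, ranked by
  AIC and classified by tail weight (light / exponential-like / heavy).
  For covariate row *x*, durations scale as *T = e^{β'x} T₀*, so
  *e^{β}* is the duration ratio per covariate unit — e.g. per week of
  postmenstrual age (PMA) or per µg/10 dL of salivary cortisol.
* **Kaplan–Meier curves** with Greenwood bands for graphical
  goodness-of-fit against the fitted survival functions.
* **Perturbation-window analysis** — do awakenings cluster in the 5
  minutes after a noxious heel lance? Likelihood-ratio (G) tests with
  Cramér's V on awakening vs. sleep-to-sleep transitions, and latency
  skewness summaries.
* **A semi-Markov hypnogram generator** — an alternating-renewal model
  whose defaults encode the fitted neonatal sleep architecture (heavy-
  tailed wake and active-sleep durations, light-tailed quiet sleep, the
  observed transition structure, PMA/cortisol/destination effects and
  age-gated lance-evoked awakenings), used for power studies and for
  validating every estimator by parameter recovery.

## Worked example

```r
library(neosleep)

cfg <- simConfig()                       # the default sleep architecture
coh <- simulateCohort(cfg, 120, seed = 42)
bs  <- extractCohortBouts(coh$hypnograms)
bs
#> BoutSet: 86 modelled bouts (26 offsets observed), 120 left-censored run(s)
#>   by state: W 16, AS 42, QS 28

transitionTable(bs)
#>    W AS QS unknown censored
#> W  0  5  0       0       11
#> AS 4  0  1       0       37
#> QS 0 16  0       0       12
```

Most active-sleep offsets are censored — typical AS bouts outlast the
recording, which is exactly why the fitting is built on the censored
likelihood. Fitting and ranking the four candidate laws for active sleep
with a PMA covariate:

```r
rep <- runFit(coh, covariateNames = "pma_weeks", seed = 42)
rep$AS$ranking
#>        family k    loglik      aic     delta
#> 1   lognormal 3 -30.20554 66.41108 0.0000000
#> 2 exponential 2 -31.44545 66.89089 0.4798113
#> 3     weibull 3 -30.51577 67.03154 0.6204570
#> 4    powerlaw 2 -35.57131 75.14263 8.7315451

rep$AS$tail_class
#> [1] "heavy"

unlist(rep$AS$acceleration_factors$pma_weeks)
#>      factor       lower       upper        coef          se
#>  0.94490301  0.82045935  1.08822174 -0.05667299  0.07205128
```

The lognormal (heavy tail) wins for active sleep, and the fitted PMA
factor of 0.945 means simulated AS bouts shorten by about 5–6% per week
of postmenstrual age (the generating value; at 120 subjects the 95% CI
still spans 1). The perturbation report for the older age group shows
lance-triggered awakenings concentrating inside the 5-minute window:

```r
pert <- runPerturbation(coh, pmaSplit = 34, seed = 42)
pert$perturbation$older_lance$counts
#>                within outside
#> awakening           2       1
#> sleep_to_sleep      1      12
unlist(pert$perturbation$older_lance$g_test)
#>          G         df    p.value  cramers_v          n
#> 4.57247338 1.00000000 0.03248962 0.53458356 16.00000000
```

`runSimulate()` writes a cohort as plain-text epoch/covariate/event tables
(the same formats `readCohort()` ingests), and `inst/scripts/neosleep` is
a thin command-line wrapper with `simulate`, `fit` and `perturb`
subcommands.

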