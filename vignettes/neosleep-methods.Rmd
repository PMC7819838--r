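---
title: "Modelling neonatal sleep-wake bout durations with neosleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neonatal sleep-wake bout durations with neosleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosleep)
```

## The problem

Neonatal sleep-wake behaviour is scored from EEG and behavioural monitoring
as a sequence of 30-second epochs, each labelled wakefulness (`W`), active
sleep (`AS`, the REM precursor), transitional sleep (`TS`) or quiet sleep
(`QS`). The scientifically interesting quantity is not the fraction of time
in each state but the *duration of each bout* — a maximal uninterrupted run
of one state — because the shape of the bout-duration distribution carries
information about how the underlying circuitry regulates state switching.
An exponential distribution means exits from the state occur at a constant
hazard (random switching); a Weibull with shape $k > 1$ means the exit
hazard grows with time in state (bout lengths are capped: a light tail);
a lognormal right tail is heavier than any exponential, implying that
long-lasting bouts become ever more likely to endure, the signature of a
self-reinforcing state.

Bout-duration data from bedside recordings are heavily right-censored: a
recording of roughly an hour frequently ends in the middle of a bout,
particularly for active sleep, whose typical bouts are longer than the
recording itself. Ignoring those censored bouts would discard exactly the
extra-long durations that distinguish a heavy tail, so every stage of this
package is built around the censored likelihood.

## From epochs to censored bout records

`extractBouts()` converts an epoch sequence into survival records under a
small set of conventions:

* **Minimum state rule.** A state change is only scored when the new state
  persists for at least one minute (two epochs). `enforceMinStateRule()`
  relabels any shorter interior run to the state of the *preceding* run —
  when the two flanking runs share a state this simply absorbs the
  interruption; when they differ, the ongoing bout is conservatively
  continued and the transition is scored at the start of the next
  full-length run. Sub-minimum runs at the recording edges join their only
  neighbour, since they cannot constitute a scored state. The operation is
  idempotent.
* **Left-censoring.** The first run of a recording has no observed onset;
  its full duration is unknown on the left. It is excluded from duration
  modelling and kept in a separate list for occupancy summaries.
* **Right-censoring.** A run reaching the end of the recording has
  `event_observed = 0` and contributes survival mass $S(t)$ rather than
  density mass to the likelihood.
* **Transitional sleep.** `TS` never forms a modelled bout. A TS run of at
  least one minute terminates the preceding bout, and the recorded
  destination (`next_state`) is the first non-TS state after it. If the
  recording ends in TS the offset is observed but the destination is
  unknown (`next_state = NA`); `transitionTable()` reports these in an
  `unknown` column. A trailing TS run shorter than one minute does not
  terminate anything and the preceding bout is treated as censored.

Times are measured in minutes from recording start; epochs are 0-based and
bout intervals are half-open $[\mathrm{onset}, \mathrm{offset})$, so every
epoch of the recording is accounted for exactly once (the package tests
assert this partition identity on simulated recordings).

## The censored AFT likelihood

Four candidate duration laws are fitted by `fitFamily()`: exponential
(rate $\lambda$), Weibull (shape $k$, scale $\lambda$), lognormal
($\mu$, $\sigma$ on the log-minute scale), and a continuous power law
(Pareto) with exponent $\alpha$ and fixed lower bound $x_{\min} = 1$ minute
— the minimum scoreable bout. Covariates enter as accelerated failure time
(AFT) effects: a bout with covariate row $x_i$ has duration
$T_i = a_i T_{0i}$ with $a_i = e^{\beta^\top x_i}$ and $T_{0i}$ following
the baseline law, so the log-likelihood is

$$\ell(\theta, \beta) \;=\; \sum_{i:\,\delta_i = 1}
  \left[ \log f_\theta\!\left(t_i / a_i\right) - \log a_i \right]
  \;+\; \sum_{i:\,\delta_i = 0} \log S_\theta\!\left(t_i / a_i\right),$$

where $\delta_i$ indicates an observed offset. $e^{\beta_j}$ is the
duration ratio per unit of covariate $j$ — e.g. a per-week postmenstrual
age (PMA) factor of 1.146 means wake bouts lengthen by 15% per week.

Numerical choices, all deliberate and tested:

* Positive parameters are optimised on the log scale (the power-law
  exponent as $\log(\alpha - 1)$), so the optimiser never leaves the
  support; out-of-support parameters passed directly to
  `negLoglikCensored()` are an error, never a silent clip.
* Initial values are moment-based: the censored closed form
  (events $\div$ exposure) for the exponential, log-duration moments of
  the observed events for the lognormal, rank regression of
  $\log(-\log \hat S_{KM})$ on $\log t$ for the Weibull, and the Hill
  estimator for the power law. BFGS runs with up to three deterministic
  perturbed restarts, so fits are reproducible and touch no random stream.
* Standard errors come from the inverse numerical Hessian (central
  differences, relative step $10^{-5}$) at the optimum, delta-transformed
  back to the natural scale. Confidence intervals are Wald, symmetric on
  the log scale.
* Covariates are centered before fitting — PMA at 35 weeks, cortisol at
  0.2 µg/dL — so baseline parameters describe an interpretable reference
  infant. Cortisol effects are expressed per µg/10 dL (`cortisol_10dl`,
  ten times the µg/dL value), the scale on which the wake factor is
  conventionally reported.

Model choice follows AIC ($2k - 2\ell$; `selectModel()` reports deltas to
the best model, with ties broken by fewer parameters and then a fixed
family order). AICc is available as an argument-free alternative the user
can compute from the reported $k$ and $n$, but AIC is the default and the
criterion used throughout. `classifyTail()` maps the winner to a tail
class: lognormal or power law → heavy, exponential → exponential-like,
Weibull shape $> 1$ → light. A Weibull winner with shape $< 1$ falls
outside that taxonomy (heavy by skew); it is reported as heavy with a
warning. `likelihoodRatioTest()` is provided as a companion for nested
comparisons (same family with nested covariates, or exponential inside
Weibull, where the usual boundary caveat on the $\chi^2_1$ reference
applies).

Bouts from the same infant are treated as independent: no frailty or
cluster adjustment is applied, which mirrors the analysis convention this
package reproduces and keeps the likelihood exact. Users with strongly
unbalanced cohorts should interpret the standard errors accordingly.

## Perturbation-window analysis

Heel lances — clinically necessary noxious procedures — are natural probes
of sleep resilience. `windowCounts()` cross-classifies observed state
transitions (awakening, i.e. destination `W`, versus sleep-to-sleep) by
whether they fall in the half-open window $[0, 5)$ minutes after any lance
of the same subject; overlapping windows count a transition once.
`associationTest()` applies the likelihood-ratio (G) test,
$G = 2\sum O \log(O/E)$ with $0\log 0 = 0$, and reports Cramér's
$V = \sqrt{G / n}$ for a 2×2 table. Latencies from the most recent prior
event are summarised by the adjusted Fisher-Pearson skewness
$G_1 = g_1\sqrt{n(n-1)}/(n-2)$ — a right-skewed latency distribution with
mass just after the stimulus is the signature of evoked awakenings.
Repeated lances in one infant are treated as independent events.

## The semi-Markov generator

Because bedside recordings of this kind are not generally redistributable,
the package ships a generative model rich enough to exercise and validate
every analysis step: an alternating-renewal (semi-Markov) process whose
defaults encode the fitted neonatal sleep architecture the analysis
machinery is designed around.

* **Duration laws** (minutes, at the 35-week reference): `W` lognormal
  $(\mu = 3.187, \sigma = 0.996)$, `AS` lognormal
  $(\mu = 4.137, \sigma = 0.891)$ for bouts destined for wakefulness, `QS`
  Weibull (shape 2.181, scale 34.243).
* **Embedded transition chain**: $P(W \to AS) = 1$;
  $P(AS \to QS) = 49/75$, $P(AS \to W) = 26/75$;
  $P(QS \to AS) = 117/118$, $P(QS \to W) = 1/118$.
* **Covariate effects**, multiplicative on duration (AFT-consistent),
  centered at 35 weeks PMA and 0.2 µg/dL cortisol: per-week PMA factors
  1.146 (`W`), 0.945 (`AS`), 1.027 (`QS`); wake factor 1.335 per µg/10 dL
  cortisol.
* **Destination-dependent active sleep**: the offset destination is drawn
  *first*, and a bout destined for quiet sleep is 1.602 times longer than
  one destined for wakefulness. Drawing the destination before the
  duration realises the observed duration/destination association as one
  concrete generative mechanism; it is of course not the only mechanism
  consistent with the fitted model.
* **Recording window**: length uniform on 44-70 minutes (the observed
  interquartile range of such recordings), with all durations quantised to
  30-second epochs (nearest epoch, two-epoch floor).
* **Transitional sleep filler**: inserted at state changes with
  probability 0.3 and a short lognormal duration (median 1.5 min, log-sd
  0.5) — values chosen once as a realistic nuisance level whose only role
  is to exercise the extraction rules; TS is never fitted.
* **Sensory events**: a heel lance is scheduled for 102/175 of subjects
  and a non-noxious control stimulus for 135/175, at uniform random times
  (the observed fractions of infants receiving each). A lance landing
  inside an active-sleep bout truncates it into an awakening with
  probability 0.35, only for subjects at $\geq 34$ weeks PMA, after an
  exponential latency (rate 0.6/min) truncated below 5 minutes. The gate
  and window reproduce the age-dependence of nociception-evoked
  awakenings; the trigger probability and latency law are the package's
  own choices of a plausible effect size, as no direct per-lance
  probability is available to copy.

The initial state is drawn from the analytic occupancy and its duration
from the equilibrium residual-life distribution (closed-form length-biased
draws for the lognormal, Weibull and exponential), which makes the process
time-stationary: `expectedOccupancy()` — embedded-chain stationarity
weighted by mean durations — is then an unbiased prediction of empirical
epoch fractions, and the tests verify the two agree within 2% absolute on
a simulated cohort. The first, left-censored run is discarded by the
extractor exactly as in real data, so no special-casing is needed.

Successive bout durations are conditionally independent given covariates;
the generator deliberately omits within-subject correlation beyond the
covariate structure, circadian rhythmicity (absent at this age), and any
biophysical model of the underlying circuitry. Passing recovery tests on
this generator therefore demonstrates the correctness of the estimators
under the stated model, not robustness to serial correlation or
misspecification in real recordings.

## What the validation computes

The test suite and `scripts/acceptance.R` regenerate data from the default
configuration and re-fit it from scratch:

* duration-law recovery from 5,000 bouts per state under recording-window
  censoring, each parameter within three reported standard errors of its
  generating value;
* acceleration-factor recovery (PMA per state, cortisol on wake, the
  active-sleep destination ratio) — per-subject designs of 500 subjects
  (800 bouts for the destination effect), plus a coverage study of 40
  replicate 500-subject semi-Markov cohorts in which the Wald 95%
  intervals must cover the generating effects in at least 90% of
  replicates;
* AIC family selection on 600-bout samples per state, required to pick
  the generating family in at least 95% of 20 replicates;
* exact oracles: the censored exponential MLE closed form, hand-computed
  product-limit curves, direct G/Cramér's V formula evaluation, and AFT
  time-rescaling equivariance;
* a constructed perturbation fixture whose 5-minute windows contain
  exactly 10 of 35 awakenings.

Problem sizes (replicate counts in particular) were chosen to make the
default suite complete in a few minutes on one CPU while keeping each
check statistically sharp; all seeds are fixed in the tests and derived
from `--seed` in the acceptance script.

## Worked example

```{r example, eval = FALSE}
library(neosleep)

## simulate a cohort, write it to disk, read it back
cfg <- simConfig()
dir <- tempfile()
coh <- runSimulate(cfg, nSubjects = 120, outDir = dir, seed = 42)

## censored bout records
bs <- extractCohortBouts(coh$hypnograms)
bs
transitionTable(bs)

## fit, rank, classify per state
report <- runFit(coh, covariateNames = "pma_weeks", outDir = dir, seed = 42)
report$AS$ranking
report$AS$tail_class
report$AS$acceleration_factors$pma_weeks

## perturbation analysis around heel lances
pert <- runPerturbation(coh, pmaSplit = 34, seed = 42)
pert$perturbation$older_lance$counts
```

## Known limitations

* Independence across bouts of one infant (no frailty), interval censoring
  and time-varying covariates are out of scope.
* The power law competes with a fixed $x_{\min}$ of 1 minute; no
  Clauset-style $x_{\min}$ estimation is performed, and the family refuses
  data containing sub-minute durations rather than silently truncating.
* The Weibull-versus-exponential likelihood-ratio reference ignores the
  boundary issue at shape = 1; AIC is the primary selection tool.
* Simulated recordings are single sessions without caregiving structure;
  the `held_start`/`held_end` event kinds are parsed and carried but not
  generated or modelled.
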