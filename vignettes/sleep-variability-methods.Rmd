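---
title: "Modeling night-to-night sleep variability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling night-to-night sleep variability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctvar)
```

## The scientific problem

Chronic insomnia is characterized not only by worse *average* sleep but by
more *variable* sleep from one night to the next. Quantifying that
variability requires long longitudinal runs of objective nightly recordings
— here, 8 weeks of nightly hypnograms scored by a contactless bedside
monitor in 30-second epochs over five states: wake, light, deep, REM, and
absence (the sleeper is out of bed). `noctvar` implements the full analysis
chain: epoch sequences to nightly sleep parameters, nightly parameters to a
jointly estimated model of group means *and* group-specific within-subject
SDs, and planned contrasts between an insomnia group and good-sleeper
controls.

## From epochs to nightly parameters

All derivations operate inside an **analysis window**: from the first epoch
after the last absence bout preceding sleep onset, to the epoch before the
first absence following the final sleep epoch (or the end of the
recording). Within it:

* **SL_adj** (adjusted sleep latency): time from the window start to the
  first sleep epoch when a pre-sleep absence exists; otherwise time from
  the start of the recording (recordings are user-initiated, so the
  recording start is the natural latency origin when the sleeper never
  left the bed). Sleep onset is the first epoch scored light, deep, or
  REM; no persistent-sleep consolidation rule is applied, because the
  latency definition references the first sleep epoch directly.
* **TST**: summed duration of light + deep + REM epochs in the window.
* **WASO**: wake strictly between the first and last sleep epochs, with
  absence epochs excluded.
* **Final awakening**: from the last sleep epoch to the window end.
* **TIB**: presence-based (non-absence) time *within the window*. Scoping
  TIB to the window — rather than the whole recording — makes sleep
  efficiency `100·TST/TIB` and the partition identity
  `SL_adj + TST + WASO + FA = TIB` (exact on absence-free windows)
  internally consistent, and keeps pre-window lounging out of efficiency.
* All analysis values are unrounded epoch totals (0.5-minute granularity).
  Whole-minute rounding (half-up, since the tie rule is otherwise
  unspecified) lives only in `display_round()` and never enters the
  statistics path.

Degenerate nights with no sleep epoch are flagged `valid = FALSE`, counted,
and excluded from modeling — never dropped silently. When multiple absence
bouts precede sleep, only the last one defines the window start (the
literal reading of the window rule).

## The location-scale model

For one outcome (nightly sleep efficiency, latency, WASO, TIB, or TST),

$$y_{ij} = x_{ij}^\top\beta + b_i + e_{ij},\qquad
  b_i \sim N(0,\sigma_b^2),\qquad
  e_{ij} \sim N\!\big(0, \sigma_w^2(g_i)\big),$$

with fixed effects for group, age, and sex; a subject random intercept
absorbing stable interindividual differences; and one within-subject SD per
group — the model's index of night-to-night variability. Integrating
$b_i$ gives a compound-symmetric marginal covariance
$\sigma_w^2(g_i) I + \sigma_b^2 J$ per subject, so the log-likelihood has a
closed form which `melsm()` evaluates in $O(n_i)$ per subject via the
rank-one (Sherman–Morrison) structure. The model is fit to nightly values;
the day-by-day tabulation into weekly means and SDs
(`weekly_summaries()`) is descriptive output, not the estimation target.

Numerical choices:

* Variance parameters are optimized on the log scale (unconstrained); the
  random-intercept SD has a floor at $e^{-10}$ and is reported as 0 at the
  boundary. SD-parameter SEs map back by the delta method.
* The start is deterministic — OLS for $\beta$, pooled within-subject
  residual SDs per group for $\sigma_w$, a moment estimate for
  $\sigma_b$ — so refits are bit-reproducible under row permutation.
* A quasi-Newton pass (`nlminb`, analytic gradient) is polished by damped
  Newton steps until the gradient max-norm is below `1e-6`; fits that do
  not reach it are flagged `converged = FALSE` and contrasts refuse to run.
* The covariance of all parameters is the inverse observed information
  (central-difference Jacobian of the analytic gradient); a singular
  Hessian is reported explicitly and pseudo-inverted with eigenvalue
  clipping.
* The closed form is validated in the test suite against an adaptive
  Gauss–Hermite quadrature oracle (64 nodes, tolerance 1e-8) and
  cross-checked against `nlme::lme` with `varIdent` under ML, an
  independent route to the same model.

**Planned contrasts.** `mean_contrast()` tests the group fixed effect;
`sd_contrast()` tests $\hat\sigma_w(\text{insomnia}) -
\hat\sigma_w(\text{control})$ with a delta-method SE from the log-scale
covariance. Both report $F = (\hat\theta/\mathrm{SE})^2$ on $(1,\,\nu)$ and
a 95% CI using $t_\nu$. The denominator df rule is not fully determined by
the design it emulates; the default $\nu = N_{\text{subjects}} - 5$
reproduces the reference value $\nu = 107$ at $N = 112$ for this
five-parameter design, and `ddf = "n_minus_rank"`
($N - \mathrm{rank}(X) = N - 4$ here) is available as the documented
alternative. CIs deliberately reuse the same $\nu$ as the F tests.
Outcomes are modeled independently with no multiplicity adjustment,
matching a planned-contrast framing. Because age enters linearly and
centering it changes only the intercept (a property the suite checks),
`melsm()` does not auto-center covariates.

## The synthetic cohort generator

No participant-level data are released with the study this package
emulates, so the generator is the test bed: it realizes exactly the
statistical structure the model assumes, at the published study geometry —
83 insomnia and 29 control subjects, 56 nights, ages 38.3 (SD 12.0) vs
29.7 (SD 8.8) truncated to 18–65, ~70%/72% female, and weekly adherence
probabilities that interpolate the published usage pattern (insomnia >80%
in weeks 1–2 peaking at 83.8% in week 3 and falling to 63.2% by week 8,
overall 75.9%; control from 80.8% to 69.5%, overall 71.8%). Missingness is
completely at random: the emulated analysis used no imputation and reported
no dependence of usage on sleep, and the model's likelihood uses exactly
the observed nights.

Night-level generation works on the natural scale with truncated-normal
noise (not lognormal), because the fitted model assumes normal residuals
and the package's validation criterion is parameter recovery. Each night
draws SL, WASO, final awakening, and TIB as group mean + subject intercept
+ night noise, then sets TST = TIB − SL − WASO − FA; epoch realization
(`realize_epochs()`) then emits a hypnogram whose derived summary
reproduces the targets *exactly* (a round-trip identity the suite checks on
a thousand random target tuples), including optional pre-sleep and
mid-sleep absence bouts and 1–4 interior WASO bouts.

Three calibration details matter and were fixed at design time:

* **Anchors.** Grand TIB (7.65 h) and TST (6.59 h) pin the grand
  efficiency anchor at `100·6.59/7.65 ≈ 86.1%`. Grand anchors split into
  group means with subject-count weights, so the configured
  insomnia-minus-control differences (−5.34% efficiency, +10.15 min
  latency, +18.45 min WASO; SD differences +1.77%, +8.80 min, +8.60 min)
  are preserved exactly. The study prints no control-group anchors for the
  latency/WASO SDs or means; the defaults (control within-subject SD: 2%
  efficiency, 4 min latency, 5 min WASO; grand means 28.4/29.2 min) were
  chosen so that every truncated-normal component keeps roughly ≤1% mass
  below zero — larger anchors are incompatible with the control group's
  expected nightly wake budget (≈46 min) implied by the efficiency
  anchors. Recovery targets depend only on the configured differences, not
  on these anchors.
* **Efficiency is derived, not sampled.** Sleep efficiency is the ratio
  `100·TST/TIB` of generated quantities. Its group means are hit by
  letting the final-awakening means absorb each group's wake budget, with
  a second-order correction for E[1/TIB] curvature; its within-subject SDs
  are hit by solving, per group, the night-level correlation between SL
  and WASO that makes the delta-method SD of the ratio equal its target.
  With the default anchors this gives a strongly positive SL–WASO
  correlation in controls and a mildly negative one in the insomnia group
  — a calibration artifact of reconciling marginal SD anchors with the
  ratio's SD under a stable TIB, not an empirical claim.
* **Truncation.** Clamping at zero is kept below ~1% of nights per
  component under the default configuration (the generator warns
  otherwise), so recovery bias is negligible relative to the model SEs.

**What the generator does not emulate** — and therefore what passing tests
cannot show about real data: realistic ultradian stage architecture (stage
labels are drawn i.i.d. within the sleep block), clock-time/circadian
structure, informative missingness, right-skewed latency distributions, or
device staging error (the emulated study itself disclaims staging-accuracy
claims). Recovery results certify the estimator under the model's own
assumptions, not robustness to their violation.

## Problem sizes used for validation

Validation runs are sized for precision, not ceremony: the recovery checks
use the full study geometry (112 subjects × 56 nights at epoch level)
averaged over 25 seeds; likelihood-oracle checks use many small instances
(5 subjects × 4 nights) where 64-node quadrature is exact to well below the
1e-8 comparison tolerance; the type-I-error study for the SD contrast uses
1,000 null cohorts of 20 subjects × 10 nights and requires the empirical
rejection rate at $\alpha = .05$ to lie in [0.03, 0.07].

## Known limitations

* The scale model is group-level only: no subject-level random scale
  effects and no location-scale correlation, so heterogeneity of
  variability *within* a group loads onto the group σ̂.
* Normal likelihood on bounded outcomes (efficiency ≤ 100, durations ≥ 0)
  is an approximation that degrades near the bounds; with the default
  anchors the bounds are several SDs away.
* The unadjusted-latency origin (recording start) and the window-scoped
  TIB are documented conventions; a vendor pipeline may scope either
  differently, shifting absolute values but not the contrast logic.
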