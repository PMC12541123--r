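---
title: "Health utility adjusted survival: model, estimation and trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Health utility adjusted survival: model, estimation and trial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hussurv)
```

## The composite endpoint

Randomised trials that compare a new treatment against a standard often face
a split verdict: overall survival (OS) is non-inferior while quality of life
differs. Testing OS and longitudinal health utility separately costs power
through multiplicity adjustment; hierarchical or co-primary schemes can
discard a clinically meaningful utility benefit. Health utility adjusted
survival (HUS) folds the two outcomes into a single quantity per arm:

$$Q_g \;=\; \int_0^{T} \bigl[S_g(t)\bigr]^{\lambda_1}\,
  \bigl[\bar U_g(t)\bigr]^{\lambda_2}\, dt,$$

where $S_g$ is the arm's survival function, $\bar U_g(t)$ is the mean health
utility of the subjects of arm $g$ still at risk at time $t$, and $T$ is the
study horizon in months. With $\lambda_1 = 1, \lambda_2 = 0$ the quantity is
the restricted mean survival time (RMST); with $\lambda_1 = 0, \lambda_2 = 1$
it is the time-integral of mean utility; the default $\lambda_1 = \lambda_2
= 1$ weighs both equally, and $\lambda_2 \in \{0.5, 2\}$ down- or up-weights
utility. The two-sample statistic is $T = Q_1 - Q_2$, and the one-sided null
hypothesis is $H_0\!: T \le 0$ ("arm 1 is not better").

Estimation substitutes the Kaplan-Meier curve $\hat S_g$ for $S_g$ and a
risk-set average of per-subject utility trajectories for $\bar U_g$. Both
estimated curves are simple on the segments cut by the union of departure
times and trajectory knots — $\hat S$ piecewise constant, $\bar U$ piecewise
linear — so the integral is evaluated in closed form segment by segment, not
by numerical quadrature.

## Conventions the estimate depends on

Several boundary conventions are not forced by the definition; the package
fixes them as follows and keeps them identical in the R curve API and the
compiled resampling engine (the two are cross-checked against each other in
the test suite):

* **Risk set.** "Alive at $t$" is operationalised as observed time $\ge t$:
  a censored subject leaves the utility average at censoring, exactly as it
  leaves the Kaplan-Meier risk set. A subject still counts at its own
  departure time (boundary inclusive).
* **Beyond the last departure.** When the risk set empties while
  $\hat S > 0$ (last subject censored), $\bar U$ is carried forward at its
  last value so the integrand stays defined over the horizon.
* **Extinct survival.** Wherever $\hat S(t) = 0$ the integrand is defined as
  0, regardless of $\lambda_1$ and of $\bar U$.
* **Ties.** Tied deaths are processed before tied censorings (the standard
  product-limit convention, inherited from `survival::survfit`).
* **Weights.** Non-integer $\lambda_2$ requires a non-negative utility
  curve; violations raise an error naming the offending segment rather than
  producing complex powers.

## Utility imputation

Utility scores arrive as sparse visit-level observations; the risk-set
average needs a value for every at-risk subject at every time. Three
single-imputation methods produce complete piecewise-linear trajectories
(`impute_utilities()`):

1. **`subject_linear`** — interpolate each subject's own recorded scores;
   constant before the first and after the last; a single score gives a
   constant trajectory.
2. **`group_mean_linear`** (default) — fill each missing value at a *key
   time point* (a time where at least one subject in the arm has a score)
   with the arm mean of the recorded scores there, optionally plus
   $N(0, \mathrm{sd}_t)$ noise with $\mathrm{sd}_t$ the standard deviation
   of the recorded scores at that time; then interpolate.
3. **`trajectory_mean`** — fill missing key-time values with the mean of the
   subject's own recorded scores. This method is defined in the literature
   only loosely; the subject-own-mean reading implemented here is an
   interpretation and is labelled as such.

A consequential detail: methods 2 and 3 impute at **all** key times,
including visits after a subject's departure. Those later knots are never
evaluated directly — the risk-set average only reads a trajectory on
$[0, \text{observed time}]$ — but they act as interpolation scaffolding: a
subject who dies between two visits keeps the arm's utility *trend* up to
death instead of freezing at the last recorded score. With a rising base
utility, freezing systematically drags $\bar U$ (and hence $Q$) down; in the
built-in scenarios the freeze costs about $0.67$ utility-adjusted months per
arm, while with scaffolding the only residual approximation is the flat
back-extrapolation before the first visit (about $-0.05$, largely cancelling
between arms). This is also why the subject-only method deteriorates as
missingness grows: it has no scaffolding.

Subjects with no recorded score at all receive the arm-mean curve under
every method, and their ids are flagged. A key time with no recorded score
in the arm (possible inside bootstrap resamples) borrows the nearest key
time's mean; the resampling engine does this silently, the user-facing
function warns. Noise draws are not truncated by default (`noise_range`
clamps them if a bounded instrument demands it).

## Decision procedures

`hus_test()` implements three one-sided procedures at level $\alpha$
(default 0.05):

* **Bootstrap** (default): $B = 500$ stratified resamples — subjects drawn
  with replacement within each arm, carrying their utility records — and a
  one-sided percentile interval; reject when the empirical
  $\alpha$-quantile of $T^{(b)}$ is positive. The resampled distribution
  sits under the alternative, hence the comparison of the interval with 0.
* **Permutation**: arm labels reassigned $B$ times give the null
  distribution; reject when the observed $T$ exceeds the
  $(1-\alpha)$-quantile of the permuted statistics.
* **Jackknife**: delete-one replicates pooled over both arms give a grouped
  jackknife standard error; reject when $T - z_{1-\alpha}\,SE > 0$.

Imputation is re-run inside every resample, treating the resample as the
dataset, so imputation uncertainty propagates into the resampling
distribution (switchable in principle by pre-imputing and testing the
completed data, but not exposed: re-imputation is the honest default).
Empirical quantiles use type-7 interpolation, fixed for reproducibility.
Two-sided variants of all three rules are available via `two_sided = TRUE`.
$B = 500$ is enough to control the type-I error in the built-in scenarios;
the test suite checks calibration at 200 simulated trials, which bounds the
Monte-Carlo standard error of a rejection rate near 0.05 at about 0.015.

## The analytic engine: X*, variance balance, power

For design calculations the package assumes, per arm, piecewise-exponential
survival with hazards $h_1$ on $[0, C]$ and $h_2$ on $(C, T]$ (the common
single-exponential case is $h_1 = h_2$) and a three-knot piecewise-linear
base utility $A_1 \to A_2 \to A_3$ at times $0, C, T$, where $C$ is a
clinical landmark such as the end of surgery. Writing $X = \min(\xi, T) =
X_1 + X_2$ with $X_1 = \min(X, C)$, $X_2 = \max(X - C, 0)$, the scalar
transform

$$X^* = A_1 X_1 + \frac{T A_2 - C A_3}{T - C} X_2
  + \frac{A_2 - A_1}{2C} X_1^2
  + \frac{A_3 - A_2}{2(T - C)} X_2^2
  + \frac{A_3 - A_2}{T - C} X_1 X_2$$

satisfies $E(X^*) = M = \int_0^T S(t)\,U_0(t)\,dt$, the ideal (noise- and
censoring-free) value of $Q$. Because $X^*$ is a deterministic transform of
the scalar survival time, its mean and variance are one-dimensional
integrals; `xstar_moments()` evaluates them by adaptive quadrature split at
the kink $C$, plus the point mass at $T$, to an absolute tolerance of
$10^{-10}$ (the identity $M = E(X^*)$ is verified against an independent
quadrature of $S \cdot U_0$ in the tests).

The standard error of the estimated $Q$ is modelled as

$$SE(Q_g) = \phi_g\,\frac{SD(X^*_g)}{\sqrt{n_g}},$$

where the *variance balance factor* $\phi_g \ge 1$ absorbs what the ideal
$X^*$ sampling noise misses: censoring, missing utility scores, imputation
and Kaplan-Meier estimation. $\phi_g$ and the true difference
$T_{true} = E(Q_1 - Q_2)$ are estimated once per scenario by simulating full
trials (`estimate_phi()`, default 200 subjects per arm and 4000
replications, about ten seconds; the factor is robust to the calibration arm
size, which the tests check by comparing $n = 200$ against $n = 500$). Then

$$\mathrm{var}(T) = \phi_1^2\,\frac{\mathrm{var}(X^*_1)}{n_1}
                  + \phi_2^2\,\frac{\mathrm{var}(X^*_2)}{n_2},
\qquad
\omega = \Phi\!\left(\frac{T_{true}}{\sqrt{\mathrm{var}(T)}} -
  z_{1-\alpha}\right),$$

give the analytic decision rule ($T - z_{1-\alpha}\sqrt{\mathrm{var}(T)} >
0$, strict), the power at any arm sizes (`hus_power()`), and, under equal
arms, the per-arm sample size for target power $\omega$
(`hus_sample_size()`):

$$n = \left\lceil \frac{(\Phi^{-1}(\omega) + z_{1-\alpha})^2\,
  [\phi_1^2\,\mathrm{var}(X^*_1) + \phi_2^2\,\mathrm{var}(X^*_2)]}
  {T_{true}^2} \right\rceil.$$

The ceiling (rather than rounding) guarantees the target: the tests verify
the round trip — power at the returned $n$ is at least $\omega$, and drops
below it at $n - 1$. Because $\phi$ enters squared, its Monte-Carlo noise
(relative standard error $\approx 1/\sqrt{2R}$ at $R$ replications, about
1% at $R = 4000$) moves $n$ by roughly 2%; sample sizes from this engine
carry that jitter.

## The trial simulator

`generate_trial()` draws, per arm $g$:

* survival $T_{gi} \sim \mathrm{Exp}(h_g)$, dropout
  $\xi_{gi} \sim \mathrm{Unif}(0, \zeta_g)$, observed time
  $X_{gi} = \min(T_{gi}, \xi_{gi}, T)$ and death indicator
  $\mathbf 1(T_{gi} < \xi_{gi},\, T_{gi} < T)$;
* utility scores at the scheduled visits (default months $1, C, T$) for
  subjects still under follow-up, distributed
  $N(U_{g0}(t), 0.1)$ around the arm's base utility; the first scheduled
  visit is always recorded, later ones are missing independently with
  probability `p_missing`.

Four independent random streams (survival, dropout, utility noise,
missingness) are derived from the seed, so switching one mechanism off does
not perturb the draws of the others — the tests rely on this to compare
matched datasets.

**Censoring calibration.** $\zeta$ is chosen so that "the censoring rate"
equals `p_censoring` — but that phrase admits three readings, and they
differ materially. `calibrate_censoring()` implements all three:

* `latent` (default): $P(\xi < T_{gi})$, the probability that dropout would
  precede death with no horizon in the way. This expresses the censoring
  intensity as a property of the dropout mechanism relative to the survival
  process alone, independent of the administrative horizon; it is also the
  mildest reading (largest $\zeta$) for a given rate.
* `dropout`: $P(\xi < T_{gi},\, \xi < T)$, the probability of an observed
  dropout before the horizon; closed form $\zeta = (1 - e^{-hT})/(hp)$ when
  $\zeta \ge T$.
* `total`: the probability of ending the study without an observed death,
  counting administrative censoring at $T$; infeasible below the
  administrative floor $e^{-hT}$ (the error reports the attainable range).

The choice matters for design operating characteristics: heavier effective
dropout thins the late risk sets, inflates Kaplan-Meier noise and leaves
late visits recorded for very few subjects, so $\phi$ — and with it the
required sample size — grows. Under the default scenarios the `dropout`
reading yields roughly 4% larger $\phi$ than `latent` at a nominal 30%
rate, and the gap widens sharply at 60%. Users replicating a published
design should check which reading the source used; the scenario constructor
exposes `censoring_type` for exactly that reason.

**Built-in scenarios.** Three presets share $T = 36$, $C = 3$, a common
hazard $h = 0.02$/month and visits at months 1, 3, 36: a null scenario
(both arms' base utility $0.8/0.4/0.7$, 30% censoring and missingness), a
utility-difference scenario ($0.8/0.5/0.8$ vs $0.8/0.35/0.7$, same rates)
and a high-missingness variant ($0.8/0.5/0.8$ vs $0.8/0.4/0.7$ with both
rates at 60%). The hazard is the one free parameter; it is pinned by the
analytic effect size of the utility-difference scenario (about 3.1
utility-adjusted months, see `inst/scripts/hazard-calibration.R`) and kept
at the round value 0.02. A fourth preset sketches a 24-month head-and-neck
non-inferiority setting with per-arm hazards recovered from two-year OS
proportions (84.9% vs 81.5%, hazard ratio 0.80) and visits at months
0, 1, 3, 6, 12, 24; its base utility knots are study-specific and must be
supplied by the user before simulating.

**What the generator does not emulate.** Utility noise is Gaussian,
homoscedastic and independent across visits and of survival — real
instruments are bounded, skewed near the ceiling, serially correlated
within subject, and sicker patients both die sooner and score lower
(informative missingness). Survival is exponential; dropout is uniform.
Passing tests therefore certify the estimator and design machinery under
the stated model, not robustness to these violations.

## Overall-survival comparators

For context in the simulation tables the package includes the two OS-based
procedures a trial team would otherwise use: a one-sided log-rank
superiority test (signed so positive means arm 1 better;
`survival::survdiff`) and hazard-ratio non-inferiority — declare
non-inferiority when the upper bound of the Wald CI from a two-group
proportional-hazards fit (Breslow ties, `survival::coxph`) is below
$1 + \text{margin}$. OS sample sizes in `run_samplesize_table()` use the
standard exponential one-sided log-rank events formula with the analytic
event probability under the scenario's censoring; they are approximate by
construction and not comparable digit-for-digit with specialised commercial
software.

## Numerical and design choices, in brief

* Exact segment integration everywhere ($S$ piecewise constant, $\bar U$
  piecewise linear, closed-form $\int (a + bt)^{\lambda_2} dt$); the tests
  pin it against a breakpoint-aligned trapezoid oracle at $10^{-6}$ and
  against RMST at $10^{-10}$ for $\lambda_2 = 0$.
* The resampling loops run through a small compiled engine (~700k $Q$
  evaluations are needed for a full rejection table); the engine is
  verified against the independent R composition (`fit_km` +
  `mean_utility_curve` + `q_statistic`) to $10^{-10}$ on simulated trials.
* Type-7 empirical quantiles; strict inequalities at decision boundaries;
  one-sided $\alpha = 0.05$ defaults throughout.
* Reported simulation profiles: rejection-rate checks use 200 simulated
  trials with $B = 500$; calibration runs use 4000 replications at 200 per
  arm. These sizes keep the full suite in the minutes range while holding
  Monte-Carlo error below the assertion tolerances stated in the tests.

## Known limitations

* Two arms only; no covariate adjustment or stratification.
* The analytic engine requires the three-knot utility shape and
  piecewise-exponential survival; scenarios outside that family (such as
  the 24-month preset) support simulation-based power only.
* Single imputation: between-imputation variance in the sense of multiple
  imputation is not propagated (though re-imputation inside resamples
  captures part of it).
* $\phi$-based sample sizes inherit Monte-Carlo jitter from the calibration
  run, and $\phi$ itself depends on the censoring-rate reading as described
  above — two teams quoting the same nominal censoring percentage can
  legitimately arrive at sample sizes tens of subjects apart under heavy
  censoring and missingness.
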