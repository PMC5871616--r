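---
title: "Maternal-care tactics, protective hunting regulation, and bear demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal-care tactics, protective hunting regulation, and bear demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caretactics)
```

## The scientific problem

Brown-bear females in heavily hunted Scandinavian populations wean their
litters after either 1.5 or 2.5 years of maternal care. Longer care costs
reproductive opportunities — a female cannot mate before family break-up,
so her inter-birth interval stretches from 2 to 3 years — but hunting
regulation pays part of that cost back: family groups are legally
protected, so a 2.5-year mother is exposed to hunters in only one year of
three (versus every second year for a 1.5-year mother), and her yearlings
ride through a hunting season under her protection as well.

`caretactics` quantifies this trade-off the way a demographer would: it
classifies females into tactics, estimates tactic- and age-class-specific
survival and recruitment with mixed models, folds those rates into
tactic-specific Leslie matrices, and compares the resulting fitness
proxies — the asymptotic growth rate $\lambda$, the net reproductive rate
$R_0$, the generation time $T$, and the stable age structure — including
their response to hunting pressure.

## Data model

Two tables carry everything. A *bear-year* is one monitored female in one
hunting-season year (age, tactic, hunting-season status, survival, cause
of death, legal availability, yearling daughters recruited). A *litter* is
one reproductive event with its realized care duration (1.5, 2.5, or lost
before weaning). Years index hunting seasons (the season runs from late
August), so survival intervals are year $t$ to year $t+1$ anchored at the
season. Validation is total: survivors must have no cause of death,
family-group members cannot be legally available, care durations must
match weaning-year arithmetic, litter sizes lie in 1–4 and recruit counts
in 0–3.

## Tactic classification and its statistics

A female's tactic is the average care duration over her weaned litters:
mean $\ge 2$ years is the 2.5-year tactic. Single-litter females are
classified by that litter; litters lost before weaning are excluded.

Three GLMM-based analyses characterize the trait:

* **Trend** — a binomial mixed model of "litter received 2.5 years" on
  calendar year with a female random intercept; the annual odds ratio is
  the exponentiated year coefficient. Complete separation (all litters one
  tactic, or a single year) is reported as a flagged non-estimable result.
* **Repeatability** — for females with at least two care periods, a
  logit-link intercept-only mixed model gives the between-female variance
  $\sigma^2_\alpha$. Latent-scale repeatability is
  $r = \sigma^2_\alpha / (\sigma^2_\alpha + \sigma^2_\varepsilon + \pi^2/3)$,
  with the multiplicative overdispersion fixed at 1 for binary data
  ($\sigma^2_\varepsilon = 0$). The original-scale repeatability is
  computed exactly rather than by a delta-method approximation: with
  $p(b) = \mathrm{logit}^{-1}(\mu + b)$ and $b \sim N(0, \sigma^2_\alpha)$,
  the observation-scale intraclass correlation of the binary responses is
  $(E[p^2] - E[p]^2) / (E[p](1 - E[p]))$, evaluated by adaptive
  quadrature. Confidence intervals are a percentile bootstrap that
  resamples *females* (keeping each female's litters together), because
  the female is the exchangeable unit. Variance estimates at zero are
  reported as zero with a boundary flag, and $r$ is capped to $[0, 1]$.
* **Correlates** — parity (primiparous vs multiparous, female random
  intercept; unknown parity removed) and a pooled-variance Student's
  t-test of mean age between consistent and flexible females. Because the
  published consistency percentage is ambiguous about its denominator, the
  summary reports the percentage among multi-litter females and among all
  classified females.

## Demographic rates

Survival uses `survival ~ tactic + age_class + (1|year)` (binomial, logit;
reference: yearling, 1.5-year tactic) over the five age classes 1, 2, 3,
4–8, 9+. The tactic × age-class interaction is retained only if a
likelihood-ratio test keeps it at $\alpha = 0.05$. Recruitment (yearling
daughters per female-year, ages 5+) uses a negative-binomial (NB2, log
link) mixed model with female and year random intercepts; age class is
not a predictor, so the 5–9 and 10+ classes share the fitted value. When
a random-effect variance sits on the boundary and leaves the Hessian
singular, random terms are dropped one at a time (flagged) until the
fixed-effect covariance is finite — the inferential contract is the
fixed-effect estimate and its uncertainty, not the variance components.

The rate table is a parametric bootstrap: coefficient vectors are drawn
from the asymptotic normal distribution of the fixed effects (random
effects at zero, i.e. population-level prediction), back-transformed to
the 10 survival cells and 2 recruitment values, and summarized by means
and 2.5/97.5 percentiles. With the covariance set to zero the intervals
collapse to the point predictions exactly — a property the tests exploit.
Note that bootstrap *means* of back-transformed rates exceed the plug-in
point estimates slightly (Jensen's inequality on the inverse link); the
table therefore carries both `mean` and `point` columns, and the same
distinction explains why published bootstrap-mean summaries (e.g. $R_0$
or generation time) sit a few percent above plug-in computations.

The protective effect of family-group status is estimated on adult
(≥ 4 y) bear-years: a logistic mixed model of survival on status with a
linear age control and a year random intercept (linear age was chosen
where the age control's functional form was not specified), plus raw
finite mortality rates by status and cause. Rate intervals default to the
normal (Wald) binomial interval, which reproduces the reported intervals
for this system at two decimals; the Wilson score interval — preferable at
very small counts — is one argument away. The odds ratio of hunting death
(solitary vs family) is computed from the exact rates; computing it from
rates rounded to two decimals, as one may do from a printed table, gives
a noticeably larger value (3.9 vs 3.4 here) — a rounding artifact worth
knowing about.

## Matrix demography

Each tactic gets a 9 × 9 female-based Leslie matrix: classes 1, 2, 3, five
explicit prime-age classes sharing $S_{4\text{–}8}$ and
$F_{4\text{–}8}$, and a 9+ class with self-loop $S_{9+}$. Fecundity is
$F_t = S_{(t \to t+1)} \times R_{t+1}$: survive the year, then recruit
yearling daughters. Expanding 4–8 into five columns avoids arbitrary
stage-transition fractions while keeping single shared estimates.

* $\lambda$ is the dominant eigenvalue (QR eigendecomposition; asserted
  real; a fertility-free matrix is reducible and is flagged). The
  implementation is verified against the renewal (Euler–Lotka) equation,
  whose residual at the returned $\lambda$ must vanish to $10^{-10}$.
* $R_0$ is the dominant eigenvalue of $F(I-U)^{-1}$; for this structure
  it equals the closed-form lifetime sum
  $F_{4\text{–}8}(l_4 + \dots + l_8) + F_{9+} l_9/(1 - S_{9+})$, and both
  routes must agree to $10^{-10}$. $S_{9+} \ge 1$ is rejected (infinite
  lifetime).
* $T = \ln R_0 / \ln \lambda$; $\lambda = 1$ is an explicit indeterminate
  error (a cohort generation time would be needed there).
* The stable age vector is the normalized dominant right eigenvector; the
  adult fraction sums classes of age 4 and older, which reproduces the
  published adult percentages. Elasticities (from the left and right
  eigenvectors) are included because they explain the headline asymmetry:
  in this long-lived matrix the survival transitions carry most of the
  elasticity budget, which is why a ~5% survival advantage can offset a
  ~35% recruitment deficit.

Uncertainty propagates by pushing every bootstrap rate draw through the
matrix construction, giving paired draws of $\lambda$, $R_0$, $T$ and the
adult fraction for both tactics, percentile intervals, and the exceedance
probability $P(T_{2.5} > T_{1.5})$ with ties counted half.

## Hunting response

The annual pressure index is shot marked bears over available marked
bears; family-group members are excluded from both sides (an accidental
kill of a protected female does not enter), and a year with no available
bears has a missing index rather than zero. Survival is regressed on
pressure separately per tactic × age-class cell (logistic regression with
the annual index as a shared year-level covariate), and estimation
uncertainty is carried by 1000 draws from the asymptotic distribution of
each cell's MLE — a parametric bootstrap standing in for posterior
sampling, which satisfies the same prediction contract. For each pressure
on a 12-point grid over the observed range $[0, 0.33]$ and each draw, the
five predicted survivals enter the tactic's Leslie matrix with recruitment
held fixed (hunting acts on survival components only), yielding a
distribution of $\lambda$ per tactic per pressure. Under the protection
rule the median $\lambda$ of the 1.5-year tactic falls steadily with
pressure while the 2.5-year tactic is buffered, so the fitness gap
(2.5-year minus 1.5-year) widens — the mechanism by which the regulation
can shift tactic frequencies.

## The synthetic population

Because the monitoring data are not public, an individual-based simulator
generates records with the statistical structure the analysis assumes.
Its annual cycle (census at the hunting season): yearling daughters enter
the monitored population → January births for eligible females (age ≥ 4,
not caring) → hunting season with the protection rule → residual
other-cause mortality → litter fates and ageing. A female's dominant
tactic is drawn at first reproduction from a year-dependent logistic
trend (`p25_intercept`, `p25_trend`) and repeated at each subsequent
reproduction with probability `tactic_consistency`; the realized litter
tactic sets the care and protection schedule (protected in the birth year,
plus the following year for 2.5-year litters) and the next eligible birth
year.

Key calibration choices, made once:

* **Rates are the study magnitudes.** Default survival means and
  recruitment (0.384 / 0.251 yearling daughters per female-year) are the
  published tactic- and age-class-specific values; the trend slope is
  `log(1.17)` per year; the default horizon is 23 years from 1993 with 60
  founding females, the era in which both tactics coexisted.
* **Residual mortality is the balancing hazard.** Other-cause survival is
  set so that *total* annual survival equals the configured value at the
  calibration pressure (default: the mean configured pressure). Hunting
  is thereby a genuine manipulable cause: at other pressures total
  survival moves, which is exactly what the hunting-response module
  estimates. A configuration whose hunting hazard alone exceeds the
  mortality allowance of a class is rejected with the class named.
* **A lifecycle dynamic program does the bookkeeping.** Naive
  calibration (nominal 1/2 and 1/3 exposure, cycle-length arithmetic for
  cub survival) misses several structural effects: females enter the
  cycle at a birth year, mortality concentrates in exposed years, tactic
  switches mix cycle lengths, and a growing population over-weights young
  females. An exact DP over the adult cycle states (birth year, second
  care year, available year), iterated to a fixed point with the
  stable-age discount, yields the exposure fractions and the pair of
  cub-to-yearling survivals that make realized per-year rates equal the
  configured ones. Empirical rates in simulated data recover the
  configured values within binomial 3-SE at the scales the tests use.
* **Consistency calibrated to observed repeatability.** No within-female
  consistency probability is published beyond a repeatability of about
  0.33, so `tactic_consistency = 0.82` was calibrated once at the default
  scale to land the GLMM original-scale repeatability near that value.
* **Defaults are internally consistent, not a replica of every published
  number.** The published class-level survival means cannot coexist with
  the published hunting-mortality levels in a single homogeneous-hazard
  model (the real population is heterogeneous in ways the generator does
  not model), so the default pressure (0.025) and accidental-kill hazard
  (0.002) are set low enough for the survival targets to be attainable;
  hunting-response experiments instead use configurations with lower
  baseline survival and pressures spanning the observed 0–0.33 range.
  The shared annual perturbation on the survival log-odds
  (`year_effect_sd = 0.1`) justifies the year random terms in the fitted
  models without drowning class-level rates in year noise.
* **Only female yearlings enter the records.** Offspring sex is 1:1
  internally, but the first monitored age class is the yearling, so no
  sex assumption is made about cubs-of-the-year. Recruit counts are
  truncated at 3, the observable range. Pre-weaning litter loss occurs
  only through the mother's death by default; a mother is treated as
  protected through her litter's intended care period.

What simulated data do *not* contain: density dependence, spatial
structure, an explicit infanticide mechanism, male bears, or detection
failure (recapture of marked females is near-certain in the study
system). Tests passing on simulated data therefore validate the
estimators and the pipeline plumbing, not those field complications.

## Numerical and testing conventions

Eigen-analysis uses dense QR decomposition (9 × 9 matrices; tolerance
$10^{-12}$ in the oracle identities). Bootstrap draws and simulator runs
are deterministic given their seed arguments; the pipeline writes JSON
with fixed formatting so identical configurations produce byte-identical
outputs. Model-based generators (logistic survival, NB recruitment,
logit-normal care histories) complement the individual-based simulator
for recovery and coverage experiments because their truths are exact;
the problem sizes used in the test suite (e.g. 200 trend replicates of 60
females × 3 litters; 200 coverage replicates of 2000 bear-years; 1000
random matrices for the oracle identities) were chosen to keep Monte
Carlo error well below the tested tolerances.

Known limitations: the recruitment model's NB dispersion is weakly
identified at small counts (the Poisson limit is flagged, not fatal);
pressure-response cells with constant pressure or separation are excluded
with a warning rather than imputed; and the bootstrap is parametric-normal
on the link scale, which can differ from a Bayesian posterior in small
samples even though both satisfy the same interval contract.
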