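---
title: "Methods: a dynamic Markov projection of diagnosed-diabetes burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dynamic Markov projection of diagnosed-diabetes burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabproj)
```

## The model

`diabproj` projects the number and percent prevalence of diagnosed
diabetes among adults with a discrete-time illness--death model.  Three
states exist -- *No Diabetes*, *Diabetes*, and *Death* -- with Death kept
as a per-year outflow ledger rather than a stock.  The population is
divided into six race × sex sub-cohorts (white/black/other × female/male),
each of which runs its own Markov chain over single years of age 18--84
plus an open-ended "85+" bucket.  One year of simulated time applies, in
fixed order per cell:

1. **Death allocation.**  Total deaths $D$ for the cell-year come from an
   external cohort-component population projection.  They are split
   between the two alive states by the relative mortality risk $RR$ of
   diabetes: solving $m_{nd} = D / (n_{nd} + RR\,n_d)$ and
   $m_d = RR\,m_{nd}$ gives state-specific death counts
   $(m_{nd} n_{nd},\; m_d n_d)$.  If either implied rate exceeds 1 it is
   capped, the residual deaths move to the other state, and a warning is
   raised (never silent).
2. **Incidence.**  A fraction $i(a, r, s)$ of the surviving No Diabetes
   population is diagnosed and moves to Diabetes.  There is no remission
   flow anywhere in the engine: bariatric-surgery remission is rare and
   relapse-prone, so a Diabetes → No Diabetes transition is deliberately
   absent.
3. **Migration.**  Census net migration enters the cell.  In-migrants are
   split by the destination cell's current prevalence (default) or
   arrive diabetes-free; out-migration (negative net migration) always
   removes people pro-rata from both states.
4. **Aging.**  Everyone advances one year of age; the "85+" bucket
   absorbs both the age-84 survivors and its own.
5. **Entrants.**  The cohort turning 18 during the year enters, split by
   the age-18 prevalence margin (default) or diabetes-free.

Because every demographic flow (deaths, migration, entrants) is taken
from the census table, the engine's alive population $n_{nd} + n_d$
reproduces the census population in every cell-year to machine precision;
prevalence is the only modelled quantity.  This conservation is asserted
by the test suite at $10^{-6}$ persons over a 47-year horizon.

The update order (deaths → incidence → migration → aging → entrants) is a
declared convention of this package: deaths-first matches the
cohort-component convention that deaths occur among the start-of-year
population.  The order is visible in the step function and exercised by a
hand-computed test ledger, so a user who needs a different convention can
see exactly what would change.

## Estimated transition inputs

Three regressions supply the engine's rate tables.

* **Initial prevalence** — survey-weighted logistic regression of
  diagnosed diabetes on race, sex, age ($z$, $z^2$, $z^3$), survey year,
  and the pairwise interactions sex:age, sex:year, age:year.  The
  starting-year prevalence is the *single-year predictive margin*: the
  weighted average of predicted probabilities over a standardizing
  population with the year covariate pinned.  "All second-order
  interactions between sex, age and survey year" is read as the three
  pairwise products with linear age only — interactions with $z^2$ or
  $z^3$ are excluded.
* **Incidence** — the same structure with the continuous year replaced by
  a five-level period factor (1985-1989 … 2006-2014); annual diagnosis
  events are too sparse for single-year estimation.  The base-case
  projection holds the 2006-2014 period's rates constant into the future.
* **Relative mortality** — Poisson log-linear regression of per-period
  death indicators with a log person-years offset (discretized survival
  time, annual periods) on race, sex, $z$, $z^2$, diabetes status, and
  interactions.  $RR(a,r,s)$ is the ratio of the predicted rate with and
  without diabetes at the cell's covariates.

Age is centred and scaled as $z = (\text{age} - 50)/10$ before polynomial
expansion and calendar year as $(\text{year}-2000)/10$; without this the
cubic terms are numerically fragile and coefficients unreadable.  In
survey and census contexts the "85+" bucket is evaluated at a fixed
effective age of 87 (roughly the bucket's population centre); follow-up
ages are literal person ages that keep advancing past 85.

**A design deviation worth recording.**  A first implementation gave the
mortality model only a linear age × diabetes interaction, making the
fitted log relative risk linear in age.  No such line can pass near the
three benchmark values the model must reproduce (about 3 at age 20, 2 at
65, 1.2 at 85): the recovered curve was systematically wrong at young
ages (about $-35\%$ at age 20) no matter the sample size.  The reported
curvature implies the source model carried age-squared × diabetes
structure, so this package includes the `diabetes:z2` term.  With it, the
default synthetic truth lies exactly in the estimation family and the
anchors are recovered without systematic bias.

Fitting is by iteratively reweighted least squares (max 100 iterations,
relative deviance tolerance $10^{-10}$), with model-based covariance
$(X'WX)^{-1}$.  Synthetic records are independent, so no design-based
(Taylor-linearised) variance is attempted; users with real survey data
and replicate weights should compute design-based variances externally.
Logistic coefficients larger than 20 in absolute value are treated as
separation and raise an error rather than returning a junk fit.  Aliased
columns (e.g. a period level absent from the data) get coefficient zero
and zero variance, with a warning at prediction time.

Poisson-predicted rates are converted to annual probabilities as
$1 - e^{-\text{rate}}$ where a probability is required; logistic outputs
are used directly as annual probabilities.

## The synthetic world

The generators emulate three data sources: cross-sectional
health-interview surveys (prevalence and incidence modes), person-period
mortality follow-up, and a census-style cohort-component projection.
Every generator is a pure function of `(truth, arguments, seed)`.

The default ground truth states, once, the conditions the projection
literature reports:

* overall diagnosed prevalence calibrated to **9.1%** in 2014, with a
  linear-on-logit calendar trend (slope 0.035/yr) reproducing the rise
  from about 3.5% (mid-1980s) to 9.1% (2014);
* overall annual incidence among the non-diabetic calibrated to
  **0.8%/yr** in the 2006-2014 period, with period effects that rise and
  then plateau;
* relative mortality risk through **(20, 3.0), (65, 2.0), (85, 1.2)**,
  log-quadratic in $z$ and held flat below its vertex (~age 21) so the
  curve is monotone non-increasing; the flat value is 3.0015, within half
  a percent of the age-20 anchor;
* non-diabetic mortality Gompertz in age
  ($\log m = -9.7 + 0.088\,a$ plus small race/sex offsets), giving
  realistic adult death rates (0.03% at 20, 1.4% at 65, 13% at 87) while
  keeping $RR \times m \le 1$ up to age 100;
* age profiles of prevalence and incidence are cubic-on-logit fits to a
  realistic diagnosed-diabetes age pattern (~1% prevalence at age 20 —
  the type 1 floor — peaking around 20% at ages 70--80; incidence
  ~0.1%/yr at 20 peaking ~1.4%/yr in the 60s).  Both profiles lie exactly
  inside the regression families above, so parameter-recovery tests
  measure estimation, not approximation, error;
* population composition: race shares 66/12/22 (white/black/other),
  51/49 female/male, an age pyramid flat to 50 and exponentially
  declining after (rate 0.035/yr), with the "85+" bucket holding the
  tail mass (~2.5% of adults);
* survey weights log-uniform on [0.5, 2], self-normalised to mean 1, with
  records independent — no strata or clustering, because the restricted
  design variables of the real surveys cannot be emulated faithfully.
  Users substituting real microdata must pre-normalise their weights.

The census generator draws integer deaths by largest-remainder
apportionment within each cohort-year, so the accounting identity
$P_{y+1,a+1} = P_{y,a} - D_{y,a} + M_{y,a}$ holds *exactly* in integers
(the "85+" bucket absorbs two streams; age 18 of year $y+1$ is the
entrant cohort of year $y$, defined net of within-entry-year attrition).
Net migration is drawn per cell at 0.2% ± 0.2% of population and clamped
so no cell goes negative; entrants are about 1.6% of the cohort's
population per year with 5% lognormal noise.

What a green test does *not* establish: the synthetic world has no
complex survey design, no undiagnosed-diabetes state, no youth under 18,
no obesity or biomarker covariates, and its demographic noise is
stylised.  Green tests certify the *machinery* — estimation consistency,
conservation, allocation algebra, interval coverage — not any real-world
projection magnitude.

## Uncertainty and scenarios

Interval estimates follow the parametric-sampling recipe: draw
coefficient vectors from the multivariate normal on the link scale
centred at each fit's estimates with its covariance (5000 draws in
production; tests use 200), rebuild all three rate tables per draw
jointly, re-run the deterministic projection, and take empirical
percentile intervals (type-7 linear interpolation) per year, with the
point estimate from the base-case run.  Normal-on-link draws keep every
rebuilt probability inside $(0,1)$ by construction.  Covariance
eigenvalues in $[-10^{-8}, 0)$ are clipped to zero with a message; more
negative values error.  Whether the original 5000 samples redrew all
three models jointly or one at a time is not documented; joint redraw is
implemented (it is the conservative choice, capturing covariance of all
three parameter sets in every replicate).

A separate Monte Carlo mode draws individual-level flows (binomial
incidence, census death totals split between states by a binomial draw at
the allocation weight, hypergeometric removal for out-migration) for
users who want demographic stochasticity; its replicate mean converges to
the deterministic expectation run and is asserted to within 3 ensemble
standard errors at 500 replicates.

Sensitivity scenarios scale every incidence probability by a factor
$\lambda$ (±20% in the standard worst/best cases) *on the probability
scale* — the literal reading of "varied the incidence by ±20%" — leaving
initial prevalence and relative risk untouched.  Trajectories are
provably monotone in $\lambda$, and the suite asserts the ordering cell
by cell.

## Reporting conventions

Counts are reported in millions to 2 decimals, percents and derived
statistics to 1 decimal, and headline scenario differences to whole
millions (full precision retained alongside).  Percent denominators are
always the model's own alive population — the only denominator consistent
with conservation.  Age groups are frozen to 18-44 / 45-64 / 65-74 / ≥75
plus a total row (configurable to race-sex cohorts).  The worked-example
tests reproduce, from published projection-table inputs, the 65+ shares
(41.1%, 53.0%, 58.0%), 65+ totals (9.18, 35.2 million), the
undiagnosed-adjusted totals at a 27.8% undiagnosed proportion (55.0, 84.0
million), the 6.4-fold increase for women of other race, the 0.3
points/yr pre-2030 rise, and the 5- and 10-million scenario reductions —
all to printed precision.

## Numerical choices and degenerate inputs

* Deterministic mode carries fractional persons; rounding happens only at
  reporting.  Stochastic mode is integer throughout.
* Death-allocation caps (rate > 1) reassign the residual and warn; the
  caps cannot trigger under the default truth but guard user inputs.
* An empty cell (zero alive) takes zero deaths and passes through.
* The scale of a synthetic census must give every cell at least one
  person, otherwise a degenerate-input error names the problem.
* `allocate_deaths` rejects infeasible inputs (deaths exceeding the alive
  population, non-positive relative risk) instead of clamping.
* Separation, missing factor levels, a single survey year, or a diabetes
  stratum with zero deaths raise typed errors with advice, not silent
  misfits.

## Known limitations

* Single-run recovery of the relative-risk *age-20* anchor is noisy at
  desk scale: diabetic deaths under age 30 are so rare that the anchor is
  an extrapolation, with a sampling sd near 15% of its value at 200,000
  persons, while the 65 and 85 anchors are tight (sd ≈ 3%).  The
  acceptance suite therefore judges anchor recovery on a 30-replicate
  mean at 100,000 persons (which it computes itself), not on a
  single-draw coin flip.
* Real-data ingestion is schema-only: CSV files in the documented layouts
  are read, but no survey-design variance, weight calibration, or
  raking is performed.
* The undiagnosed adjustment is a post-hoc proportional multiplier, not a
  model state.
* The CLI takes a JSON configuration file (no YAML parser is available in
  the supported dependency set).
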