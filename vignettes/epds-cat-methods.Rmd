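---
title: "Adaptive short forms of the EPDS: models, simulation and fairness audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive short forms of the EPDS: models, simulation and fairness audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epdscat)
```

## The problem

The Edinburgh Postnatal Depression Scale (EPDS) is a 10-item screen for
perinatal mood and anxiety disorders. Each item is scored 0--3, the
total runs 0--30, and in the clinical workflow this package models a
total of 8 or more flags moderate risk, while a total of 13 or more or
*any* endorsement of the suicidal-ideation item (item 10) flags high
risk; moderate- and high-risk screens trigger referral. Computerized
adaptive testing (CAT) can shorten the questionnaire by selecting
informative items one at a time and stopping once the trait estimate has
stabilised, but a shortened screen is only acceptable if it neither
loses diagnostic accuracy nor misses cases at different rates across
demographic groups. `epdscat` implements the whole evaluation loop:
graded-response IRT models, real-data CAT simulation, expected-score
risk classification with a suicidal-ideation override, screening
accuracy metrics, and a false-negative-rate (FNR) parity audit.

## The graded response model

Item $i$ loads on exactly one latent factor $f(i)$ (simple structure,
or between-item multidimensionality). With slope $a_i > 0$ and strictly
decreasing intercepts $d_{i,1} > d_{i,2} > d_{i,3}$, the cumulative
probability of answering in category $k$ or higher is

$$P^*_{i,k}(\theta) = \frac{1}{1 + e^{-(a_i \theta_{f(i)} + d_{i,k})}},$$

and category probabilities are adjacent differences
$P_{i,k} = P^*_{i,k} - P^*_{i,k+1}$ with $P^*_{i,0} = 1$,
$P^*_{i,4} = 0$. We use the logistic metric with no 1.7 scaling
constant, matching the convention of the mainstream IRT estimation
software family; for unidimensional reporting the difficulty
parameterisation is $b_{i,k} = -d_{i,k} / a_i$ (see `coef.grm`). Three
factor structures are supported: a single depression--anxiety factor;
anxiety (items 3--5) versus anhedonia--depression (items 1, 2, 6--10);
and anhedonia (items 1--2), anxiety (items 3--5), depression
(items 6--10). Traits are multivariate normal with zero mean, unit
variances and a free correlation matrix $\Sigma$.

## Estimation

`grm()` maximises the marginal likelihood by EM over a fixed
rectangular quadrature grid on $[-6, 6]$: 61 points for one factor, 31
per dimension for two, 15 for three. These are desk-scale defaults --
dense enough that the one-factor EAP reproduces a 10,001-point
reference integration to about $10^{-3}$ (asserted in the tests) while
keeping the three-factor grid at $15^3$ nodes tractable.

* **E step.** Respondents are collapsed to unique response patterns;
  each pattern's posterior over the grid is computed from per-item
  probability tables evaluated once per cycle on the one-dimensional
  per-axis grid (simple structure makes every item's likelihood a
  function of a single axis).
* **M step.** Each item's expected complete-data log-likelihood is
  maximised by BFGS on the transformed parameters
  $(\log a,\; d_1,\; \log(d_1 - d_2),\; \log(d_2 - d_3))$, which keeps
  the slope positive and the intercepts strictly ordered by
  construction. A candidate update is accepted only if it improves the
  item's objective, so every cycle is a generalised EM step and the
  marginal log-likelihood is non-decreasing (asserted to $10^{-8}$ for
  one-factor fits).
* **$\Sigma$ update.** The average posterior second moment of $\theta$,
  rescaled to unit diagonal each cycle -- the standard confirmatory
  identification with fixed factor variances. The rescaling makes the
  update approximate rather than an exact M step, so for multi-factor
  fits the monotonicity and nesting properties are asserted with a
  small numerical tolerance rather than exactly.
* **Start values and convergence.** Slopes start at 1, intercepts at
  the logits of the observed cumulative category frequencies, $\Sigma$
  at the identity; estimation is fully deterministic. EM stops when the
  largest absolute parameter change falls below $10^{-4}$ or after 500
  cycles (the `converged` flag records which).

Model comparison uses `AIC = -2\ell + 2p` and `BIC = -2\ell + p\log N`
with $p = 10 + 30 + D(D-1)/2$ free parameters. Limited-information fit
statistics (M2, RMSEA, TLI, CFI) are out of scope.

A category that never occurs in the data leaves its intercept
unidentified; `grm(collapse = TRUE)` merges such a category into its
lower neighbour (recoding that item) instead of failing, and
`recode_responses()` maps raw tables onto the contracted coding before
scoring or CAT replay. The pipeline uses this path because the
suicidal-ideation item's top categories are genuinely rare.

## Scoring and the shrinkage correction

`eap_score()` returns the posterior mean and SD of $\theta$ under the
$N(0, \Sigma)$ prior. EAP estimates shrink toward 0, so across a cohort
their variance understates the trait variance; the empirical
reliability per dimension is
$\rho_d = \operatorname{Var}(\hat\theta_d) /
(\operatorname{Var}(\hat\theta_d) + \overline{SE_d^2})$ and the
correction divides by $\sqrt{\rho_d}$, restoring unit variance to first
order (verified against the conjugate normal--normal model, where
$\rho$ has a closed form). The source describing the correction we
follow presents it as a formula-based rescaling of all CAT-estimated
trait levels; we isolate it in `empirical_reliability()` so an
alternative formula can be swapped in at a single point. Whether the
correction is applied before or after mapping to the score scale is
genuinely open; the default (`correct_before_total = TRUE`) corrects
$\hat\theta$ first and then evaluates the expected total
$T(\theta) = \sum_i \sum_k k\, P_{i,k}(\theta)$, which always uses the
full 10-item bank regardless of which items the CAT administered.

## The adaptive test

`run_cat()` replays a patient's recorded full-test responses through
the engine, so no responses are ever generated or altered -- only the
order and number of items change (real-data simulation). Selection
rules follow the design being evaluated: for one-factor models the
first item maximises Fisher information at $\theta = 0$ and subsequent
items maximise posterior-weighted information
$\int \operatorname{tr} I_i(\theta)\, p(\theta \mid \text{responses})
\, d\theta$; multi-factor models use the (unweighted by default) trace
rule $\operatorname{tr} I_i(\hat\theta)$ throughout, including the
first item, since the maximum-information start is only defined for
the unidimensional design. Ties break toward the lowest item index.

The test stops once the change in estimated trait scores between
successive EAP estimates falls below $\delta = 0.05$ (max-absolute
change across dimensions; the norm is configurable because the design
statement does not fix one), with at least `min_items = 2` administered
-- a change needs two estimates, and the observed minimum test length
is 2. The suicidal-ideation item competes for selection like any other
item by default, matching the simulated design, which is exactly why
classification consults the recorded item-10 response separately; a
`force_si` flag administers it unconditionally for deployments that
require universal suicide screening.

Administering all ten items reproduces the full-test EAP exactly (the
engine and the batch scorer share one likelihood kernel), and lowering
$\delta$ can only lengthen tests -- both are asserted as properties.

## Classification, accuracy and the fairness audit

The full-length reference classification is positive when the observed
total is $\ge 8$ or item 10 is endorsed (recorded response $> 0$); the
CAT-implied classification is positive when the *expected* total is
$\ge 8$ or item 10's recorded response is endorsed. Because no clinical
diagnosis is available, the full-length classification is the reference
standard for NPV, PPV and FNR. Proportions get Wilson intervals;
Cronbach's alpha gets the Feldt F interval; the predicted-observed
correlation gets the Fisher-z interval.

`fnr_parity()` tabulates false negatives and true positives per
demographic group among reference positives, tests homogeneity with a
Pearson chi-square on the groups × {FN, TP} table (no continuity
correction, no minimum-count enforcement -- small expected counts
trigger a warning suggesting an exact test), and reports each group's
FNR as a ratio to a named reference group ("White" by default). Groups
with zero reference positives are dropped with a warning and the
degrees of freedom shrink accordingly; the "Unknown" category is a
group like any other.

## What the synthetic generator emulates -- and what it does not

`generate_item_bank()` and `generate_cohort()` emulate the statistical
structure of a postpartum screening population: 10 four-category items
with the EPDS factor assignments; traits correlated at 0.6 across
factors (EPDS subscales are strongly related facets of one syndrome);
demographic proportions 54/12/12/10/7/4/1 percent for White / AAPI /
Other / Hispanic White / Black / Multiracial / Unknown; age
$N(34.26, 4.89)$ truncated to 18--54 (schema fidelity only); and a
positive-screen rate near 11.7%. Slopes are drawn uniformly from
[1.3, 2.6], first thresholds from [0.65, 1.45] with gaps from
[0.8, 1.5]; the suicidal-ideation item draws its first threshold from
[2.5, 3.1] so that endorsement is appropriately rare (~2--3%). These
ranges were calibrated once, by simulation at $N = 10{,}000$, to place
the default positive rate in the 0.09--0.14 band around the 11.7%
target, and are frozen. Group-level trait shifts default to zero -- the
fairness null -- and can be set per group to stress-test the audit's
power.

The generator does **not** emulate differential item functioning across
groups, item-level response margins of any real EPDS sample, missing
responses, or non-normal trait distributions. Passing tests therefore
demonstrate that the machinery is correct and calibrated under the
stated generating process, not that a particular clinical population
behaves this way.

Two deliberate test-design choices follow from the generator. First,
parameter-recovery runs draw the suicidal-ideation item's threshold
from the ordinary range, because with the default rare-endorsement
threshold the item's top category is often unobserved even at
$N = 5000$ and its intercept would be unidentifiable -- recovery is
only meaningful when all 40 parameters are estimable. Second, the
type-I-error calibration of the FNR chi-square uses 500 replicate
cohorts of $N = 4000$ with four equal groups and classifies by the
full-bank EAP expected-total rule (the all-items limit of the CAT):
equal groups keep every expected FN cell large enough for the
chi-square approximation the calibration is about, and the calibration
concerns the test's level under group exchangeability, which does not
depend on which deterministic classifier produced the predictions.

## Numerical choices and degenerate inputs

Category probabilities are floored at $10^{-10}$ inside information and
likelihood computations, so extreme respondents produce warnings about
boundary posteriors rather than infinities. Expected totals are clipped
to the attainable score range. A cohort of identical records has
undefined empirical reliability; `simulate_cat()` then skips the
correction with a message instead of failing. Metrics with empty
denominators are reported as `NA` ("undefined"), never silently
propagated. Item banks serialise to CSV and JSON with 17 significant
digits, which round-trips every double bit-exactly.

## Problem sizes

The shipped tests fit at $N$ between 400 and 5000 (one factor) and
1200--2500 (two/three factors), simulate CAT cohorts of 2000, and run
the 500-replicate fairness calibration at $N = 4000$; the acceptance
script evaluates the full pipeline on a 4000-patient synthetic cohort.
These sizes give stable estimates of every reported quantity on a
single CPU in minutes.

## Limitations

The package evaluates CAT designs by simulation on recorded or
synthetic full-test data; it does not administer live tests, control
item exposure, or balance content. Only FNR parity is audited --
equalized odds, calibration within groups and causal analyses are out
of scope, as are nominal/partial-credit models, within-item
multidimensionality and non-logistic links. AIC/BIC are the only fit
indices. Standard errors of item parameters are not computed.
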