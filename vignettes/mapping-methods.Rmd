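---
title: "Mapping QoL-AD responses to EQ-5D utilities: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QoL-AD responses to EQ-5D utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qoladmap)
```

## The estimation problem

Dementia studies routinely collect the QoL-AD, a 13-item disease-specific
quality-of-life questionnaire (four response levels per item, composite
13–52), but often not the EQ-5D, the generic five-dimension instrument whose
value-set utilities feed cost-utility analyses. A *mapping algorithm* is a
fitted statistical relationship that predicts EQ-5D utilities (or EQ-5D item
responses) from QoL-AD item data, age and sex, so that utilities can be
attached retrospectively to datasets where only the QoL-AD was collected.
Both the person with dementia (self-rated) and their carer (proxy-rated) may
complete the instruments, giving four possible rater pairings; the
scientifically preferred pairings map self to self and proxy to proxy.

Two features of EQ-5D utility data drive the modelling choices. First, a
*ceiling effect*: a sizeable mass of observations sits exactly at 1 (full
health), which ordinary least squares ignores. Second, utilities are an
awkward, bounded, left-skewed quantity; predicting the five item responses
and valuing the implied health state (*response mapping*) often behaves
better than regressing the utility directly.

## Instrument scoring

Items are scored poor = 1 … excellent = 4. Item 7 (the respondent's
marriage) is frequently not applicable, so the default composite drops it
and standardises back onto the 13-item range by the affine map

$$\text{score} = 13 + (\text{sum}_{12} - 12)\times\tfrac{39}{36},$$

the unique affine transformation sending the 12-item extremes (12, 48) to
(13, 52). This choice reproduces all the printed worked examples we are
aware of for 12-item sums of 23, 32 and 42 (24.9, 34.7, 45.5 to one
decimal); since the convention is only ever stated via its preserved range,
we flag the formula as inferred, and keep full precision internally,
rounding only for display.

## Value sets and the crosswalk

An EQ-5D-3L tariff is an additive decrement scheme:

$$u(s) = 1 - c\,\mathbf 1\{\exists d: s_d > 1\}
  - \sum_d \delta_{d,s_d} - N_3\,\mathbf 1\{\exists d: s_d = 3\},$$

with the published UK (Dolan) coefficients shipped as a fixture
(`inst/extdata/uk_tariff_3l.csv`; worst state 33333 values −0.594). Because
a validated UK 5L value set is a moving target, 5L data are valued through a
*crosswalk* — a table mapping each of the $5^5 = 3125$ 5L states to a
3L-valued utility. The package cannot ship the published crosswalk table,
so `synthetic_crosswalk()` constructs a labelled synthetic one: each 5L
level splits its mass over adjacent 3L levels
(1→{1}, 2→½{1}+½{2}, 3→{2}, 4→½{2}+½{3}, 5→{3}) and the exact expectation
of the tariff is taken over the five independent dimensions. It shares the
qualitative properties that matter for testing (full health → 1, monotone
in every dimension, minimum −0.594 at 55555), but numeric results under it
are not comparable with published crosswalk utilities; users with access to
a published table can load it with `load_crosswalk()` and every function
accepts it.

## Direct mapping estimators

With design matrix $X$ (items as indicator contrasts with level 1 as
reference, or the composite score; optionally age in years, uncentred, and
a male indicator with female reference):

* **OLS** (continuous or categorical): least squares, predictions clamped
  at 1.
* **Tobit**: $y^* \sim N(x'\beta, \sigma^2)$ right-censored at 1, fitted by
  maximum likelihood (analytic-gradient BFGS on $(\beta, \log\sigma)$,
  relative-tolerance $10^{-8}$, cap 200 iterations; the last iterate is
  kept with a warning on the cap). The default prediction is the censored
  expectation
  $E[\min(y^*,1)] = \mu\Phi(a) - \sigma\phi(a) + 1 - \Phi(a)$, $a =
  (1-\mu)/\sigma$, which is strictly below 1 for finite $\sigma$ — the
  behaviour reported for ceiling-aware models, whose maximum predictions sit
  just below 1. The clamped linear predictor is available behind
  `type = "clamped_linear"`. Only upper censoring is modelled; the utility
  floor is left free, since the ceiling is the motivating phenomenon.
* **CLAD** (Powell's censored least absolute deviations): iterate
  { fit median regression on the current subsample; keep observations with
  $x'\hat\beta < 1$ } until the kept set is stable, capped at 400
  iterations. The LAD subproblems are solved as exact linear programs
  (Barrodale–Roberts, via quantreg) for reproducible tie handling. The
  trimming fixed point can cycle on discrete data; the cap then applies and
  the last iterate is kept, flagged.
* **Two-part**: logistic regression for $\Pr(\text{utility} = 1)$ plus OLS
  on the sub-ceiling observations, combined as
  $\text{Utility} = \Pr + (1 - \Pr)\times Y$ and clamped at 1. Perfect
  separation in the logistic part is tolerated (cap-retained coefficients
  with a warning), mirroring practice with sparse cells.

## Response mapping

Each of the five EQ-5D dimensions is modelled separately from the shared
design (five models per algorithm): multinomial logit (reference level 1),
proportional-odds ordinal logit (four ordered cutpoints), or OLS on the
level as a 1–5 score. OLS-family predictions are rounded to the nearest
level with halves toward the *worse* level — an arbitrary but fixed and
serialized convention — and yield a degenerate one-level distribution.
Levels never observed in the estimation data get structural-zero
probability with a logged note. A small optional ridge (weight-decay)
penalty on the mlogit is offered for perfect-prediction cells when a model
will be applied to populations unlike its estimation data; the default is
no penalty.

The five predicted level distributions are combined assuming independence
across dimensions (each dimension is modelled separately, so the joint is
taken as the product) and converted to a utility by **exact enumeration**:

$$\hat u = \sum_{s \in \{1..5\}^5} \Big(\prod_d p_d(s_d)\Big)\,
  \text{crosswalk}(s),$$

no sampling involved. Since the conversion from predicted responses to
utilities can also be read as "take the most likely state", a
`modal_state_utility()` variant (per-dimension argmax, ties toward the
lower level) is provided; the expectation is the default because it is the
estimand cost-effectiveness analysis needs and is deterministic and smooth
in the coefficients.

## Evaluation and inference

Predictions are compared with observed utilities by RMSE, MAE, the
percentage within 0.1 utility points (the boundary counts as accurate —
the convention had to be fixed somewhere and inclusive is the natural
reading of "within"), the predicted range, and a calibration table over
quartiles of the observed utilities (type-7 quantile boundaries, ties to
the lower quartile; per quartile the mean observed and the median, IQR and
10th–90th centiles of predictions). Metrics are computed on the final,
post-clamping predictions, pooled over observations; clustering is
acknowledged in fitting, not in the pooled error summaries.

Repeated visits nest within subjects, so coefficient covariance uses the
cluster sandwich: score contributions summed within clusters, with the
small-sample factor $G/(G-1)$. With every observation its own cluster this
reproduces the HC-robust covariance exactly. Clustering never moves point
estimates; the CLAD deliberately gets no cluster adjustment.

## The simulator: what it emulates, and what it does not

`simulate_qolad_eq5d()` generates the structure the mapping assumes:

* a latent health trait per subject (SD 0.55) with visit noise (SD 0.6),
  giving within-subject clustering of roughly the strength seen in
  three-visit cohort data;
* 13 QoL-AD items by thresholding the trait plus item noise (SD 1.0),
  cutpoints staggered across items; defaults give a self-rated composite
  mean near 35–36 with SD ≈ 7;
* EQ-5D-5L items drawn from known multinomial-logit models given the
  realised standardised 12-item sum, age and sex — so the mlogit response
  mapper is *correctly specified* and parameter-recovery tests are
  well-posed;
* a common intercept shift calibrated by root-finding so the probability of
  full health matches `ceiling_target` (default 0.15);
* proxy ratings as a shifted latent trait (−0.8 SD), reproducing the
  familiar pattern of carers rating quality of life below the person's own
  rating;
* ~13% missing item 7 and 2% general item missingness; age ~ N(78, 8),
  55% female.

Under the defaults the Spearman correlation between composite score and
utility is ≈ 0.5, inside the 0.3–0.7 band typical of dementia cohorts. The
slope scale (0.4 per level step on the standardised composite), the latent
SDs and the thresholds were calibrated once against those targets and then
frozen.

What the simulator does **not** emulate: country or language effects,
cognition covariates (MMSE/CDR), informative dropout, response styles, or
dependence between EQ-5D dimensions beyond what the shared predictors
induce. Passing tests on simulated data therefore demonstrate algorithmic
correctness (estimators recover the truth of their own model class;
pipelines compose correctly), not that any particular family will win on a
given real cohort.

## Numerical choices and degenerate inputs

* Design columns for item levels never observed at fit time are dropped
  with a warning; at prediction time an unseen level is an error, never a
  silent fall-back to the reference.
* Tobit needs at least one uncensored observation; an all-ceiling sample is
  an error. The two-part model needs both classes. A single observed level
  in an EQ-5D item is a degenerate outcome error naming the dimension.
* Probability vectors must sum to 1 within $10^{-10}$; expected-utility
  enumeration is chunked so memory stays flat for large prediction sets.
* Models serialize to JSON with 17 significant digits, so a save/load
  round trip reproduces predictions bit for bit; prediction is computed
  from the stored coefficient blocks, independent of the estimation
  backend.
* All simulation draws come from one seeded stream in documented order;
  identical seeds give byte-identical CSV output.

## Problem sizes used in the test suite

The suite favours a few deep, parameterised checks. Oracle equivalences use
$10^6$-draw Monte Carlo (3 standard errors) or dense grids; parameter
recovery uses n = 5000 with a fixed seed; the nine-family self-consistency
comparison runs on 1200 simulated observations, where the correctly
specified mlogit response mapper attains the lowest RMSE. These sizes give
stable verdicts at interactive runtimes.

## Known limitations

* The shipped crosswalk is synthetic (see above); absolute utility levels
  under it are internally consistent but not citable.
* Cluster-robust covariance is implemented for estimators exposing
  per-observation scores (OLS families, logistic part, Tobit); the
  mlogit/ologit item models report conventional convergence diagnostics
  only, and the CLAD — following field practice — gets no cluster
  adjustment.
* No uncertainty intervals around predicted utilities are produced; the
  mapping targets population means, and individual predictions in the
  lowest quality-of-life range are the least reliable, a pattern shared by
  mapping algorithms generally.
* Ordinal logit assumes proportional odds; the multinomial logit drops the
  ordering information instead. Both are reported so users can judge the
  trade-off on their own data.
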