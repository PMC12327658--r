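---
title: "Best-worst scaling with the maximum-difference model"
author: "bwsmaxdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-worst scaling with the maximum-difference model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwsmaxdiff)
```

## The measurement problem

Object-case best-worst scaling asks each respondent to mark the most and the
least important option in a sequence of small choice sets drawn from a fixed
universe of $v$ items. Under random utility theory every item $i$ has a
latent value $\gamma_i$; a respondent's picks are noisy revelations of these
values, and the analyst's task is to recover the $\gamma_i$ — and derived
summaries such as choice shares and pairwise differences — from the observed
selections. The package's running example is a study of 15 candidate factors
influencing self-medication with antimicrobial drugs, surveyed with 15 choice
sets of 7 options among 300 respondents.

## Questionnaire designs

A usable BWS questionnaire shows every item equally often and every pair of
items together equally often, so that no item's utility is estimated from a
systematically easier comparison set. That is exactly a balanced incomplete
block design (BIBD) with parameters $(v, b, k, r, \lambda)$. The package
constructs such designs by **cyclic development of a difference set**: a
$k$-subset $D \subset Z_v$ whose ordered differences cover every nonzero
residue exactly $\lambda$ times; block $j$ is $\{(d + j) \bmod v : d \in D\}$
for $j = 0, \dots, v - 1$, giving $b = v$ blocks with $r = k$ and
$\lambda = k(k-1)/(v-1)$.

Design choices made here, where several constructions would do:

* `find_difference_set()` searches candidates **containing 0 in lexicographic
  order** and returns the first hit, so the design is deterministic without
  any seed. For the 15-item, 7-option layout the search space is only
  $\binom{14}{6} = 3003$ candidates and the result is
  $\{0, 1, 2, 4, 5, 8, 10\}$; the developed design shows every item 7 times
  and every pair 3 times, verified exactly by `check_balance()`.
* Within-block item order is the cyclic-shift order. Position balancing is
  not attempted; the command-line tool can shuffle presentation order with a
  seeded `--randomize` flag, off by default.
* All questionnaires are assumed shared: every respondent answers the same
  $b$ blocks. External designs can be supplied as CSV and verified with
  `check_balance()` instead of constructed.
* Files reference items **by label, never by index**, which removes any
  0- versus 1-based ambiguity between tools.

## The maximum-difference model

For a choice set $T$ with $|T| = k \ge 3$:

* best: $Q_T(b) = e^{\gamma_b} / \sum_{r \in T} e^{\gamma_r}$
* worst: $R_T(b) = e^{-\gamma_b} / \sum_{r \in T} e^{-\gamma_r}$ — the worst
  scale is the negative of the best scale, which on any two-item set makes
  "pick $a$ best" and "pick $b$ worst" the same event:
  $Q_{\{a,b\}}(a) = R_{\{a,b\}}(b)$
* completed task: the ordered pair $(a, b)$, $a \ne b$, has probability
  $QR_T(a, b) = e^{\gamma_a - \gamma_b} / \sum_{u \ne v \in T}
  e^{\gamma_u - \gamma_v}$ over the $k(k-1)$ ordered pairs.

The likelihood maximised by `maxdiff()` is the product of the **pair-model**
probabilities over answered tasks — the joint best-worst model, not a
sequential best-then-worst factorisation. The sequential process exists in
the simulator as an alternative response rule precisely because survey data
do not reveal which cognitive process generated them; the two coincide when
all utilities are equal.

### Identification

All three probability maps are invariant to adding a constant to every
utility, so one linear constraint is needed. The package uses **effects
(sum-to-zero) coding**: $\sum_i \gamma_i = 0$, with the $v - 1$ free
parameters being the first $v - 1$ utilities and the last reconstructed as
minus their sum. Each estimate is then a contrast against the average item,
and an omitted "baseline" item in a published table can be recovered as minus
the sum of the printed estimates. The worked example depends on this: the 14
published estimates sum to $+0.500$, placing the baseline factor at
$-0.500$, and only under this convention do the published marginal
probabilities and pairwise differences cohere.

### Estimation and uncertainty

The log-likelihood is concave in $\gamma$, so optimisation is undramatic:
start at zero, run BFGS with the analytic gradient, then Newton-polish until
the gradient infinity-norm is below `tol` ($10^{-8}$ by default). Failure to
reach the tolerance sets `converged = FALSE` and warns rather than erroring.
Internally the likelihood uses sufficient statistics — per-item best and
worst counts plus per-block task counts — and the product identity
$\sum_{u \ne v} e^{\gamma_u - \gamma_v} =
(\sum_u e^{\gamma_u})(\sum_v e^{-\gamma_v}) - k$, so one evaluation costs
$O(bk)$ regardless of the number of respondents. Utilities are centred
before exponentiation for numerical stability.

The covariance of the free parameters is the inverse observed information
(finite differences of the analytic gradient at the optimum), mapped to all
$v$ items through the sum-to-zero contrast matrix; per-item standard errors
and 95% Wald intervals ($z = 1.959964$) follow. An estimate is flagged
significant when its 95% interval strictly excludes zero — an interval
touching zero is not significant.

Degenerate inputs: an item chosen best (or worst) *every* time its set is
shown has no finite MLE; `maxdiff()` warns naming the item (separation) and
reports non-convergence instead of raising. Items never chosen at all draw a
softer warning. Skipped tasks are simply absent from the product — no
imputation — while duplicate (respondent, block) records are an error, never
silently deduplicated.

### Fit statistics

The likelihood-ratio chi-square compares the fit to the null of all-equal
utilities (uniform pair probabilities), on $v - 1$ degrees of freedom — 14
for a 15-item study. For the information criteria an effective sample size
must be chosen, and reasonable software disagrees; this package uses
$n =$ **number of answered tasks** for BIC and reports plain AIC alongside
the small-sample AICc. These statistics are reported for model comparison,
not matched against any external value.

## Post-estimation summaries

* **Marginal probability (MP)**: $MP_i = e^{\gamma_i} / \sum_j e^{\gamma_j}$
  over all $v$ items — the model-implied share were the full universe offered
  at once. This functional form was chosen because, applied to the published
  worked-example estimates (baseline included at minus the printed sum), it
  reproduces all ten published MP values to four decimals; rescaled-utility
  and count-share alternatives do not. MP preserves the utility ranking and
  is recentring-invariant.
* **Pairwise contrasts (DUE)**: $\gamma_i - \gamma_j$ with delta-method
  standard error $\sqrt{V_{ii} + V_{jj} - 2V_{ij}}$, two-sided Wald $p$ and
  95% interval; unadjusted for multiplicity, matching common reporting
  practice for these tables. The table is antisymmetric and satisfies the
  triangle identity exactly. When comparing against values printed at three
  decimals, a tolerance of $\pm 0.01$ absorbs the input rounding.
* **Greatest utility difference (GUD)**: $\max_i \gamma_i - \min_i \gamma_i$,
  computed over *all* items including any reconstructed baseline — the
  published definition is loose on this point, so the choice is recorded here
  rather than silently applied.
* **Count scores**: per item, best picks minus worst picks — the classic
  model-free importance metric — standardised by the item's number of
  appearances across answered tasks (equal to $r \times$ respondents for a
  complete BIBD study, and still well-defined under missing tasks).

## The simulator

`simulate_bws()` draws one record per (respondent, block). The default
`maxdiff_pair` rule samples the ordered pair directly from the pair model, so
simulation and estimation share a model family and parameter recovery is a
clean test of the estimator; the `sequential_best_worst` rule (best from the
best model, then worst from the worst model over the remainder) probes
sensitivity to the unknown response process. Draws proceed respondents-outer,
blocks-inner, one categorical draw per task (two for the sequential rule), on
R's default Mersenne-Twister stream; the rule, seed and stream are recorded
in the returned object's `simulation` field, and a fixed seed reproduces the
dataset byte-for-byte.

`study_fixture()` packages the study-scale conditions as defaults: the 15
published factor labels, the published estimates (baseline $-0.500$) as true
utilities, the 15×7 balanced design, and 300 respondents — 4 500 tasks.

What the simulator deliberately does **not** emulate: respondent
heterogeneity (every simulated respondent shares one utility vector, where
real populations mix preferences), position and order effects, attention
lapses or straight-lining, and the beginning-versus-end consistency checks
used in fieldwork. Passing recovery tests therefore demonstrates that the
estimator inverts its own data-generating process at realistic sample sizes
— internal validity — not that real survey data satisfy the model.

## Validation performed by the test suite

The suite pins deterministic worked-example numbers (choice shares of a
3-item utility block, the published MP and DUE values recomputed from
printed estimates, GUD $= 1.195$), checks exact structure (design balance
$r = 7$, $\lambda = 3$; $df = 14$; unit-sum probability tables; the two-item
reversal identity; the antisymmetry and triangle identities), verifies the
aggregated likelihood against an independent brute-force pair-enumeration
oracle to $10^{-10}$, and calibrates the estimator by Monte Carlo under the
fixture conditions: 200 replicates of 300 respondents × 15 tasks, requiring
per-item mean bias below 0.05, pooled 95% interval coverage between 92% and
98%, and an LR rejection rate consistent with the nominal 5% at the
all-equal null. Coverage is pooled across the 15 items because a per-item
coverage estimate from 200 replicates carries binomial noise of about
±3 percentage points, wider than the band being checked; the pooled rate is
the calibration summary the replicate budget can actually resolve. These
sizes keep the whole suite under a minute on a laptop while leaving the
Monte-Carlo tolerances meaningful.

## Known limitations

Single shared utility vector (no mixed logit, latent-class or hierarchical
Bayes extensions); object-case BWS only (no profile- or multi-profile
cases); no anchored/dual-response variants; no optimal-design search beyond
balance (no D-efficiency optimisation); Wald inference only (no profile
likelihood or bootstrap); contrasts are reported unadjusted for multiple
testing by design.
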