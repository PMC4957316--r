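---
title: "Concordance-index boosting with stability selection: models, parameters, design"
author: "cindexboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance-index boosting with stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cindexboost)
```

## The model and its estimators

For right-censored data $(\tilde T_i, \Delta_i, x_i)$ the package fits a
linear risk score $\eta = x^\top\beta$ whose quality is judged purely by
discrimination: the concordance index
$C = P(\eta_j > \eta_i \mid T_j < T_i)$.  No proportional-hazards or other
regression assumption enters; only the agreement between the ranking of
the scores and the ranking of the survival times matters.

Censoring makes naive pair counting biased, so estimation uses inverse
probability of censoring weighting.  With $\hat G$ the Kaplan–Meier
estimate of the censoring survival function (censored observations are
the "events" of the censoring process), the Uno estimator is

$$\hat C = \frac{\sum_{j,i} \Delta_j \hat G(\tilde T_j-)^{-2}\,
  I(\tilde T_j < \tilde T_i)\, I(\eta_j > \eta_i)}
  {\sum_{j,i} \Delta_j \hat G(\tilde T_j-)^{-2}\, I(\tilde T_j < \tilde T_i)}.$$

Conventions that matter and how we fixed them:

* **Left limits.** Weights evaluate $\hat G$ at $\tilde T_j-$, the
  standard IPCW convention, so a subject's own censoring jump cannot
  deflate its weight.  `eval_censoring_km(..., left = )` exposes both
  conventions so the sensitivity is testable.
* **Ties.** Tied times form no comparable pair; tied scores contribute
  zero to the numerator (no half credit).  The smoothed estimator below
  assigns them $K(0) = 1/2$ by continuity.
* **Zero weights.** Events beyond the last censoring support point, where
  $\hat G = 0$, get weight zero with a warning instead of producing
  infinities.
* A **truncated** variant restricts to event pairs with
  $\tilde T_j \le \tau$ (no IPCW weights enter it, matching its standard
  definition); it is provided for evaluation, not boosted.

## The smoothed loss and its gradient

The indicator $I(\eta_j > \eta_i)$ is replaced by the sigmoid
$K(u) = (1 + e^{-u/\sigma})^{-1}$, giving a smooth criterion
$\hat C_{\text{smooth}}$ whose analytic gradient has components

$$\frac{\partial \hat C_{\text{smooth}}}{\partial \eta_k} =
\frac{1}{D}\Big[\textstyle\sum_i w_k I(\tilde T_k < \tilde T_i)
K'(\eta_k - \eta_i) - \sum_j w_j I(\tilde T_j < \tilde T_k)
K'(\eta_j - \eta_k)\Big],$$

with $K'(u) = K(u)(1 - K(u))/\sigma$ and $D$ the total pair weight.
Every pair contributes equal and opposite amounts to its two members, so
the gradient sums to zero exactly — a property the test suite checks to
$10^{-10}$, alongside agreement with central finite differences to
$10^{-6}$ relative error.

**Bandwidth $\sigma$** (default 0.1): smaller values track the raw
C-index more closely but make the gradient spikier; $\sigma \to 0$
recovers the Uno estimator pointwise (checked at $\sigma = 10^{-4}$).
All internals accept any $\sigma > 0$.

## Component-wise boosting

Each iteration fits a slope-only least-squares base-learner of the
current ascent direction on every mean-centered covariate and updates
only the best-fitting one by $\nu$ times its slope (ties broken towards
the lowest column index, so reruns are deterministic).  Never-selected
covariates keep coefficients that are exactly zero.  No intercept
base-learner exists because every concordance criterion is
shift-invariant.  IPCW weights are computed once per training sample:
$\hat G$ does not depend on $\eta$.

**Step length $\nu = 0.1$** is the conventional boosting default; it
interacts only with `mstop`.

**Gradient scaling.** The exported `cindex_gradient()` is the exact
gradient above, including the $1/D$ normalization.  The boosting engine
uses the same direction scaled by $1/n$ instead of $1/D$.  The direction
is identical; the difference is what one unit of `mstop` means.  $D$
grows quadratically with $n$, so under $1/D$ scaling the per-iteration
steps at a fixed $\nu$ shrink with the pair count and four-digit `mstop`
values barely move a moderate-sized fit.  Per-subject scaling keeps step
sizes comparable across sample sizes and gives `mstop` its conventional
semantics: at $\nu = 0.1$, `mstop = 1000` suffices for a low-dimensional
refit to converge, and `mstop = 10000` on p = 50 visibly overfits —
the regime the benchmark tables describe.  Training-score monotonicity
(non-decreasing within $10^{-8}$ at $\nu \le 0.1$) holds across the test
fixtures under this scaling; the fully unnormalized gradient would not
satisfy it.

**Run-until-q fitting** (`cboost(..., q = )`) iterates until `q` distinct
covariates have been selected and stops immediately; a cap of
`50 * q` iterations (overridable) guards against degenerate cases, and
hitting it flags the fit rather than erroring.

## Stability selection and error control

`cboost_stabsel()` draws B random partitions of the sample (child seed
`seed + b` per partition, so parallel or resumed runs reproduce), uses
both halves of each partition (2B subsamples; the complement takes the
extra subject when n is odd), runs the booster until `q` distinct
covariates are selected on each, and averages selection indicators into
frequencies $\hat\pi_j$ — exact multiples of $1/(2B)$.  The stable set is
$\{j : \hat\pi_j \ge \pi_{thr}\}$; the comparison is inclusive so that
frequencies landing exactly on the threshold grid count as stable.  An
empty stable set is a legitimate outcome, reported as such (refitting an
empty set is an explicit error).  Subsamples without a single usable pair
are redrawn from a shifted child seed, with a warning and a counter.

Three PFER bounds are available for $E(V)$, the expected number of
falsely selected covariates, at $\theta = q/p$:

* classical: $q^2 / ((2\pi_{thr} - 1)p)$;
* unimodal: a closed form with a finite-B correction, piecewise in
  $\pi_{thr}$ at $3/4$;
* r-concave (default): $p \cdot \min\{D(\theta^2, B, -1/2,
  \lceil B(2\pi_{thr}-1)\rceil),\ D(\theta, 2B, -1/4,
  \lceil 2B\pi_{thr}\rceil)\}$, where $D$ is the maximal tail probability
  of an r-concave random variable on $\{0, 1/B, \dots, 1\}$ with the
  stated mean.  The first component works through the
  simultaneous-selection frequencies over the B complementary pairs, the
  second through the plain frequencies over all 2B subsamples.

The extremal r-concave distribution has a pmf whose $r$-th power is
linear on a support $\{0,\dots,k\}$, with a deficient atom at $k+1$
absorbing leftover mass so the mean constraint binds exactly.  The bound
maximizes the tail over the support size (outer discrete search) and the
linear shape parameter (golden-section search on the feasible interval,
whose endpoints are the two adjacent pure power laws, located by root
finding to near machine precision).  Two numerical details are
load-bearing: the threshold indices must be computed in exact arithmetic
(naively, `ceiling(50 * (2*0.8 - 1))` is 31 under IEEE doubles, not 30,
which visibly corrupts the $\pi_{thr} = 0.75$–$0.8$ range), and
thresholds at or below twice the mean return the trivial bound 1.  The
implementation is validated against roughly 35 independently published
values of this bound at $B = 50$, all matching to the printed two
decimals, and the three bounds are verified to be totally ordered
(r-concave $\le$ unimodal $\le$ classical) on a parameter grid.

Choosing the knobs: `q` should be comfortably larger than the number of
truly relevant covariates but small relative to `p`; `pi_thr` in
0.6–0.9 mostly trades sparsity against sensitivity, and for a fixed run
the whole `pi_thr` grid can be evaluated at no extra cost.  A sensible
external anchor is to pick the PFER between $\alpha$ and $m\alpha$ for a
significance level $\alpha$ and $m$ implicit tests.

## The synthetic-data generator

`aft_scenario()` / `simulate_aft()` emulate the benchmark design:
equicorrelated standard normal covariates
($\Sigma = (1-\rho)I + \rho J$, drawn exactly via a shared factor),
effects tiling $(1.5, 1, -1, -1.5)$ over the first `p_inf` covariates,
and log-logistic AFT times $\log T = x^\top\beta + \phi W$ with standard
logistic $W$.  Censoring times are independent exponentials; the rate is
calibrated by root finding so the expected censored fraction (computed
exactly given a large seeded pilot of latent times, via
$E[1 - e^{-\lambda T}]$) hits the target within 0.005.  Test samples are
censored by the same mechanism and evaluated with the Uno estimator
under their own censoring Kaplan–Meier.

**The scale $\phi$.** With `ph_violation = TRUE` the scale is
$\exp(x_1)/5$ per subject.  The scalar scale of the
proportional-hazards-compliant scenarios is not derivable from the
design description alone, yet every absolute concordance level depends
on it, so it was calibrated once against the published discrimination
levels and then frozen: for the `p_inf = 4` pattern the variance of the
true predictor is $\beta^\top\Sigma\beta = 3.25$, and pair-probability
Monte Carlo gives an oracle concordance of 0.881/0.856/0.832/0.756 at
$\phi = 0.4/0.5/0.6/1$.  Matching the reported plateau of fitted models
(test C-index near 0.84 with exact support recovery, near 0.79 for
deliberately overfitted dense fits) selects $\phi = 0.55$ (oracle
$\approx 0.845$), the package default.  The sensitivity is roughly
$-0.025$ concordance per $+0.05$ in $\phi$ near the default; selection
behaviour (true/false positive medians) is insensitive across
$\phi \in [0.5, 0.6]$.

What the generator does *not* emulate: real gene-expression data have
heavy-tailed, heteroscedastic covariates with blockwise rather than
uniform correlation, informative censoring is possible, and effects are
rarely exactly sparse.  Passing the benchmark therefore demonstrates
correctness of the machinery under the stated design, not performance on
any particular omics data set.

## Replication harness and problem sizes

`replicate_study()` chains the pieces per replicate — simulate, select,
threshold, refit (`mstop = 1000`), score on n = 1000 test data, plus an
optional dense reference fit (`mstop = 10000` on all p) — and reports
per-cell medians with the r-concave PFER bound attached.  Identical
scenario and seed give bit-identical summaries; empty-stable-set cells
are recorded as missing, mirroring how such cells are reported in
benchmark tables.  The packaged checks run the p = 50, n = 200 scenario
at 10 replicates with 2B = 100 subsamples — enough for stable medians of
small counts and a Monte-Carlo tolerance of about $\pm 0.02$ on median
concordances — whereas the original study used 100 replicates per cell.

## Known limitations

* Base-learners are linear; no splines or trees, so only linear score
  surfaces are reachable.
* The censoring model behind the IPCW weights is the unconditional
  Kaplan–Meier: censoring that depends on covariates or scores breaks
  the unbiasedness argument (conditional weighting is out of scope).
* Confidence intervals for the C-index and p-value-style inference for
  single covariates are not provided; the PFER bound is the supported
  error-control statement.
* The r-concave bound assumes exchangeability and a shape condition on
  selection frequencies that are not diagnosable from a single run;
  empirically the bound is conservative in the null scenarios we
  simulate.
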