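---
title: "Multilocus posterior probabilities of disease and their prognostic utility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus posterior probabilities of disease and their prognostic utility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrisk)
```

## The model

`polyrisk` works with the simplest generative model of polygenic disease
that still captures the essentials of genetic risk prediction. A binary
disease trait $D$ has prior (population prevalence) $K = P(D=1)$. Each of
$n$ susceptibility loci is reduced to a binary carrier state $G_i$: an
individual either carries the predisposing genotype at locus $i$ or does
not. Conditional on disease status the loci are independent, with carrier
frequency $g_{1,i} = P(G_i = 1 \mid D = 1)$ in cases and
$g_{0,i} = P(G_i = 1 \mid D = 0)$ in controls.

Under this conditional-independence assumption the Bayesian network for
$(D, G_1, \dots, G_n)$ collapses to a Naive Bayes model, and the posterior
probability of disease (PPD) for a genotype profile is

$$
\mathrm{PPD}_n \;=\;
\frac{K \prod_i P(G_i \mid D=1)}
     {K \prod_i P(G_i \mid D=1) + (1-K)\prod_i P(G_i \mid D=0)},
$$

or on the log-odds scale,
$\operatorname{logit} \mathrm{PPD}_n = \operatorname{logit} K +
\sum_i \log \mathrm{LR}_i$, where a carried locus contributes
$\log(g_{1,i}/g_{0,i})$ and a non-carried one
$\log\!\big((1-g_{1,i})/(1-g_{0,i})\big)$. `ppd()` accumulates in log
space, so architectures with up to $10^5$ loci are handled without
underflow.

### From relative risk to case frequency

Model tables state each locus by its control frequency $g_0$ and relative
risk $rr$. Two mappings to $g_1$ are provided by `locus_effect()`:

* **`freq_ratio`** (default): $g_1 = rr \cdot g_0$, i.e. the relative risk
  is identified with the carrier likelihood ratio. This is the convention
  under which the benchmark polygenic architectures behave as expected
  (see the actionability analysis below), and it is exact in the
  rare-disease limit.
* **`epidemiological`**: $rr$ is a ratio of penetrances,
  $P(D \mid \text{carrier}) = rr \cdot P(D \mid \text{non-carrier})$, and
  $g_1$ is obtained from the prevalence-consistent system by fixed-point
  iteration (relative tolerance $10^{-12}$, capped at $10^4$ iterations).
  The two mappings agree as $K \to 0$ and differ at first order in $K$
  otherwise.

## The population distribution of the posterior

The clinically interesting object is not one posterior but the
distribution of posteriors across everyone the model is applied to.
`ppd_distribution()` computes it exactly. "The population" is ambiguous
in this setting — it could mean controls, the generative mixture of cases
and controls, or a marginal construction — so the package makes the
choice explicit via `population_mode`:

* **`marginal_independent`** (default): each locus independently at its
  marginal frequency $g_\mathrm{pop} = K g_1 + (1-K) g_0$. Under this
  construction the 1000-locus polygenic benchmark shows its two
  characteristic behaviours — C2 climbing past 80% near
  $rr \approx 1.45$ and C1 never exceeding 0.02 — and it is therefore
  the default.
* **`mixture`**: the exact generative population — a $K$-weighted mixture
  of the case and control genotype laws. Under this mode the law of total
  expectation holds ($E[\mathrm{PPD}] = K$, asserted to $10^{-9}$ in the
  tests), and the posterior is a martingale in the number of loci, so its
  variance is strictly increasing in $n$ — the mode to use when studying
  how information accumulates.
* **`control`**: control frequencies only, for screening-in-the-healthy
  scenarios.

The three modes coincide for a single locus (up to the `control`
construction) and the tests assert this.

### Exact and binned computation

For an **exchangeable** model (all loci identical) the PPD depends only on
the carrier count $k$, which is binomial under every mode; support
$\{\mathrm{PPD}(k)\}_{k=0}^n$ and binomial masses are exact for any $n$, so
the 1000-locus sweeps run in milliseconds. The number of multilocus
genotype combinations behind each support point, $\binom{n}{k}$, is kept on
the object.

For **heterogeneous** models with $n \le 20$ loci the per-locus two-point
log-LR increments are convolved exactly, merging sums that agree to 12
significant digits (this keeps near-exchangeable substructure from
exploding the support). Above 20 loci a fixed-width dynamic-programming
grid over the log-LR range is used, 4096 bins by default (minimum 256);
each locus increment is snapped to the grid, for a worst-case log-odds
discretisation error of $n \cdot \mathrm{step}/2$, and the step is
reported as `grid_step` on the result. The tests verify the exact route
against exhaustive $2^n$ enumeration (total variation $< 10^{-6}$) and the
grid route against the closed-form exchangeable computation and against
Monte Carlo.

## Actionability: the C1 and C2 conditions

A predictor is clinically useful where it pushes posteriors past decision
thresholds. With $\tau_{pos}$ and $\tau_{neg}$ (defaults 0.95 and 0.05),
`threshold_fractions()` reports the fractions of the population with
$\mathrm{PPD} > \tau_{pos}$ (condition C1, actionably high) and
$\mathrm{PPD} < \tau_{neg}$ (C2, actionably low). The inequalities are
strict; mass exactly at a threshold counts as neither. `sweep_relative_risk()`,
`sweep_prior()` and `sweep_locus_count()` trace these fractions across
architectures. `sweep_prior()` maps priors of exactly 0 or 1 to $10^{-6}$
and $1 - 10^{-6}$, the stated limit convention, since the posterior is
degenerate at the endpoints.

Because the support is a discrete set of carrier counts, swept C1/C2
curves are step-like and locally non-monotone — visibly so for the
rare-variant, high-relative-risk architecture (100 loci at $g_0 = 0.001$,
$rr$ from 10 to 400), where single support points carry large mass and
cross thresholds abruptly. The package reproduces this qualitative
behaviour; no smoothness is claimed or tested.

## Prognostic-utility metrics

* **AUC** (`auc()`): $P(S_\text{case} > S_\text{control}) + \tfrac12
  P(\text{tie})$, computed exactly for discrete score distributions and as
  the Mann–Whitney statistic (mid-ranks, ties half-weighted) for samples.
  `roc_curve()` sweeps a strict-exceedance threshold; trapezoidal
  integration of the curve equals the AUC, which the tests assert.
* **PPV/NPV** (`predictive_values()`): Bayes' rule from sensitivity,
  specificity and prevalence, plus their average as a single
  prevalence-aware summary. Zero denominators are reported as `NA` with a
  warning rather than silent `NaN`.
* **NRI** (`nri()`): net upward reclassification of events minus
  non-events between two ordinal category assignments, in $[-2, 2]$.
* **Kullback–Leibler divergence** (`kl_divergence()`, natural log / nats):
  the departure of the posterior distribution from the prior. Two variants
  are shipped because the form of this divergence commonly written down
  sums $\mathrm{PPD}\log(\mathrm{PPD}/K)$ over genotype combinations
  without genotype-probability weighting, while the quantity of clinical
  interest is population-level. The default `weighted` variant is the
  population-expected Bernoulli KL,
  $\sum_g P(g)\,\mathrm{KL}\big(\mathrm{PPD}_g \,\|\, K\big)$, which is
  nonnegative and zero iff the posterior is everywhere the prior (asserted
  over randomized models). The `literal` variant evaluates the unweighted
  disease-term sum exactly as written, using the genotype-combination
  multiplicities carried on the distribution; grid-binned distributions do
  not carry them, so `literal` is `NA` there. Outputs are always labelled
  by variant and no published numeric value is claimed for either.

## Genetic risk scores and calibration

`grs()` implements $\mathrm{GRS} = \sum_i w_i R_i$ over risk-allele counts
$R_i \in \{0,1,2\}$, unweighted when no weights are given.
`quantile_bins()` partitions scores into $q$ near-equal bins
(quintiles by default): sizes differ by at most one with the remainder in
the lower bins, and ties keep stable input order — both choices made for
determinism, since no convention is standard. `bin_risk_ratios()` reports
fold-risk per bin against a reference bin using cumulative incidence
(cases/total), with an odds-ratio option; counts are combined before any
division.

`calibrate_intercept()` moves a case-control logistic intercept to the
target population:
$\beta_0^\mathrm{pop} = \beta_0^\mathrm{cc} - \log(n_1/n_0) +
\operatorname{logit}(\pi)$ for prevalence $\pi$. The carrier-count model
is itself exactly logistic in the count, which the tests exploit: a
calibrated intercept-plus-slope fit on simulated 1:1 case-control data
recovers the generating $\operatorname{logit}(K)$ within three standard
errors.

## The Naive Bayes classifier

`nb_fit()`/`nb_predict()`/`nb_cross_validate()` generalise the PPD
machinery to multi-state genotypes (e.g. 0/1/2 dosages) and two or more
disease classes, the design used for multi-disease panels. Estimation is
additive-smoothed counting,
$(\mathrm{count} + c)/(n_\mathrm{class} + c \cdot n_\mathrm{states})$ with
pseudocount $c = 0.5$ per state by default (a Jeffreys-style prior).
Missing genotypes drop
out of both counting and prediction — the factorisation makes the skipped
factor exact, and imputation is deliberately out of scope. A state never
seen at fitting time is an error under $c = 0$ (its likelihood is
undefined, not zero). In the binary case with matched parameters,
`nb_predict()` equals `ppd()` to $10^{-12}$, asserted in the tests.

Cross-validation uses stratified folds (each class split separately after
a seeded shuffle), accuracy as the fraction of correct top-posterior
calls, and AUC macro-averaged over one-vs-rest comparisons with the class
posterior as score (micro-averaging behind a flag). "Accuracy" is
ambiguous between per-class and overall accuracy in the multi-class
setting; the package implements overall top-call accuracy. Seeded
stratified folds were chosen for determinism and class balance.

## The cohort simulator

`simulate_population()`, `simulate_case_control()` and
`simulate_multiclass()` draw from exactly the generative model above:
label from the prior (or fixed by design), then conditionally independent
loci given the label. That is the point — every stochastic test in the
package is a check of one code path against the same distribution
computed another way (analytic, enumerated, or fitted), so the simulator
emulates the models' statistical structure, not real genotype data.
Features of real data it deliberately does not have: linkage
disequilibrium between loci, genotyping error, covariates, population
structure, and epistasis. Passing tests therefore validate the
probabilistic machinery, not robustness to those violations.

Cohorts are reproducible: a single integer seed drives the R
Mersenne-Twister generator inside a state-restoring wrapper (the caller's
random stream is untouched), and the seed, generator identity and
generating model are written into cohort provenance and into cohort files.

## Problem sizes and numerical choices

The test and acceptance workloads were sized so the whole suite exercises
every code path at statistically meaningful scale: exhaustive-enumeration
oracles up to $2^{12}$ genotype vectors, Monte-Carlo agreement at
$10^5$ subjects against three-binomial-standard-error envelopes, parameter
recovery at $5 \times 10^4$ subjects, cross-validation nulls at
$5 \times 10^3$, and analytic sweeps at the published architecture sizes
(1000 loci). Support values are merged when equal to 12–14 significant
digits; distribution masses must conserve to $10^{-9}$ and are
renormalised only within that tolerance.

## Known limitations

Binary carrier abstraction in the PPD engine (multi-state genotypes live
in the classifier); no LD, epistasis or covariates; the `literal` KL
variant is unavailable for grid-binned distributions; ROC curves for very
large supports enumerate all distinct score values; external-cohort
results (biobank AUCs, published GRS fold-risks) depend on data this
package does not ship and are out of its reproduction scope.
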