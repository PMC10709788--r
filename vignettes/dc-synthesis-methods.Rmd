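---
title: "Divide-and-conquer synthesis of logically consistent clinical tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer synthesis of logically consistent clinical tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsynth)
```

## The problem

Single-table clinical datasets carry deterministic logical relationships
between columns. A patient recorded as a non-smoker must have zero
pack-years; a non-drinker must report zero weekly intake. A generative model
fitted to the whole table treats these as ordinary statistical
associations, and some fraction of its samples will break them — a
non-smoker with 30 pack-years is an *impossible record*. Such records are
not merely noisy: they are detectable contradictions that undermine any
downstream analysis of the synthetic table.

The common remedy, conditional sampling (CS), is rejection sampling: draw
rows, discard the ones that violate predeclared conditions, repeat until
enough valid rows accumulate. It guarantees consistency but pays for it by
throwing records away, and degenerates when the conditions are tight.

This package implements the alternative this family of methods argues for:
**divide and conquer (DC)**. Partition the original data so that within
every subset the constrained columns are constant, fit a generator per
subset, sample each subset, and recombine. Consistency then holds by
construction — nothing is filtered, nothing is discarded.

## The division criteria

Two criteria are applied in sequence.

**Class-specific criterion.** The table is first split on the binary
outcome (e.g. survival vs death). Each class gets its own generators, so
class-conditional feature distributions are preserved and the class mix of
the output can be set exactly at sampling time.

**Cramér V criterion.** All columns are converted to categorical form
(numeric columns through the binning described below) and the Cramér V
statistic

$$V = \sqrt{\frac{\chi^2}{N\,\min(r-1,\;c-1)}}$$

is computed for every unordered column pair, where $\chi^2$ is the Pearson
chi-square of the $r \times c$ contingency table over $N$ observations
(zero-count categories are dropped before $r$ and $c$ are fixed; no
continuity or bias correction is applied — `cramers_v()` implements the
classical statistic). $V = 1$ means complete association: each category of
one column maps to exactly one category of the other. Pairs reaching $V = 1$
(within an absolute tolerance of $10^{-9}$, configurable) are exactly the
deterministic main-attribute/subattribute relationships the output must
preserve, so each such pair contributes a *division feature*: the member of
the pair with fewer observed categories (ties break toward the natively
categorical member, then lexicographically). Splitting on the main
attribute makes the subattribute's constrained value constant within the
triggered subsets.

A dataset with one binary outcome and one perfect pair — the canonical
case — therefore divides into four subsets: class × main-attribute value.

### Why binning needs a point-mass carve-out

Equal-frequency binning alone hides structural zeros: if half the patients
are non-smokers, their pack-years value 0 is smeared into a quantile bin
together with small positive values, and the smoker/pack-years table is no
longer perfectly associated. `discretize_numeric()` therefore gives any
single value holding at least $1/n_\text{bins}$ of the rows its own
dedicated bin before quantile-binning the rest (default `n_bins = 10`).
With the carve-out, the planted non-smoker ⇒ pack-years = 0 rule scores
exactly $V = 1$; without it, it does not. The binning scheme is this
package's choice and is applied uniformly; bins are always fitted on the
real data and re-applied to synthetic data when both are compared.

### Guarding against over-division

Every additional division feature multiplies the number of subsets and
shrinks the training data available to each generator; over-division
starves them. `build_partition()` accepts `min_subset_size` (default 50
rows): if a feature split would leave any subset of a class branch below
it, that split is dropped *for that branch* and logged. The class split is
never dropped — it is the essential first criterion.

## The generator backend

The reference backend is a **Gaussian copula** with empirical marginals,
implemented in `fit_copula()` / `sample_copula()`:

* numeric marginals are the sorted training values; a training cell's
  normal score is $\Phi^{-1}((\mathrm{rank}-0.5)/n)$; sampling inverts the
  empirical CDF by linear interpolation between sorted values, confined to
  the training min/max. The confinement is intentional: a subset whose
  constrained column is constant (pack-years of non-smokers) reproduces
  that constant exactly.
* categorical marginals map category frequencies to contiguous
  sub-intervals of $[0,1]$; a cell's score is the normal quantile of its
  interval midpoint; sampling picks the category whose interval contains
  $\Phi(z)$.
* the dependence is the Pearson correlation matrix of the normal scores,
  repaired to the nearest positive semidefinite correlation matrix
  (`Matrix::nearPD`) when estimation noise pushes an eigenvalue negative.
  Constant columns get zero off-diagonal entries. Sampling uses an
  eigendecomposition square root, so perfectly correlated (semidefinite)
  fits sample correctly.

The copula was chosen as the reference because it is deterministic given a
seed, fits in milliseconds on subsets of a few hundred rows, and captures
exactly the two things the fidelity metrics measure: marginal shapes and
pairwise dependence. Heavier neural tabular generators attach through the
backend contract (`generator_backend()`): any `fit(ds)` / `sample(model,
n)` pair participates in the full pipeline, and a declared hyperparameter
grid (e.g. training epochs 100–500) can be ranked with `backend_sweep()` by
held-out fidelity or utility. The reference backends declare empty grids,
so sweeping them is a no-op by design.

`fit_independent()` keeps the marginals but forces an identity dependence
matrix. It exists purely as an ablation: it destroys every pair trend while
leaving shapes intact, which is what the fidelity ordering tests exploit.

A one-row subset degenerates to row replication with a warning; there is
no dependence to estimate from a single observation.

## Conquer: volumes, balance and recombination

`allocate_volumes()` turns a total volume (default 5000 rows) and an
event : non-event weight pair into per-subset counts. The minority class
receives `round(total * min(w) / sum(w))` rows — a 1:100 ratio at 5000
rows gives `round(5000/101) = 50` minority rows — and the majority the
remainder; within a class, counts follow the subsets' original-data sizes
under largest-remainder rounding, which conserves the total exactly. The
within-class proportional rule is this package's choice (any allocation
summing correctly is admissible); proportionality keeps subset mixtures
representative of the original data. `conquer()` concatenates the
per-subset samples and applies a seeded uniform shuffle so downstream
splits are not order-biased.

Class-balance control belongs to the DC strategy, where the class split
makes exact allocation possible. The CS and unconstrained strategies fit
one model on the whole table and reproduce the original class marginal.

## Evaluation stack

**Logical consistency.** `violation_report()` counts rows whose trigger
column matches a rule while the dependent column deviates from the
required constant (numeric equality within $10^{-9}$).

**Fidelity** (`quality_report()`): per-column *shape* scores — $1 -
\mathrm{KSS}$ for numeric columns (Kolmogorov–Smirnov sup-distance between
empirical CDFs), $1 - \mathrm{TVD}$ for categorical (half-$L_1$ between
frequency vectors); per-pair *trend* scores — $1 - |\rho_R - \rho_S|/2$
on Pearson correlations for numeric–numeric pairs, and a half-$L_1$
contingency similarity over joint cell proportions for all other pairs
(numeric members discretized with bins fitted on the real data). The
divisor 2 in the correlation score is the range of a difference of two
correlations, keeping the score in $[0,1]$; distances are converted to
similarities as $1 - d$ throughout, so *higher is better* and identical
tables score exactly 1. Aggregates are plain means: `shape` over columns,
`pair_trend` over pairs, `overall` over the two. Printed reports use the
conventional × 100 scale.

**Utility** (`tstr_evaluate()`): the train-on-synthetic/test-on-real
protocol. Features are one-hot encoded over the full schema vocabulary (so
categories absent from a training table cannot fail at prediction time),
the classifier contract is an opaque `fit`/`predict_proba` pair, and AUC
(Mann–Whitney pair counting, ties at ½) plus F1 at the 0.5 probability
threshold are aggregated over repeat seeds as mean and population SD
(`n` divisor; configurable). F1 is macro-averaged by default — the
convention under which a majority-collapsed classifier on balanced labels
scores ⅓ rather than 0 and which keeps balanced/imbalanced comparisons
interpretable; positive-class F1 is available via `f1_average =
"positive"`. Built-in adapters cover CART (`rpart`), random forest
(`ranger`), gradient-boosted trees (`xgboost`) and logistic regression,
each with fixed small hyperparameters and single-threaded execution for
reproducibility. `experiment_grid()` crosses strategies × backends ×
balances × classifiers and reports utility, fidelity and violation rate
per cell, with a train-on-real reference row.

## The synthetic test-bed

`generate_fixture()` builds the clinical-like table every test runs on: a
binary `adverse_event` outcome with configurable prevalence; a
class-dependent `smoker` column (default rates 0.3 non-event / 0.7 event);
`pack_years` exactly 0 for non-smokers and log-normal (median 25 years,
log-scale SD 0.5, hence strictly positive) for smokers — the planted rule;
three class-shifted Gaussian clinical analogues (`age`, `fvc`, `dlco`,
default shifts +0.7 / −0.7 / −0.7 SD); and independent numeric and
categorical noise columns. Generation redraws until every class × smoker
cell is populated, so the canonical four-subset partition always exists.

The truth record includes the closed-form Bayes AUC of the planted signal.
Conditional on smoking status, the optimal score is a Gaussian linear
discriminant plus a smoker log-odds offset, so the AUC is a
four-term mixture of normal probabilities; the defaults give ≈ 0.852,
deliberately in the range where tree ensembles trained on a couple of
thousand rows sit near, but not at, the ceiling — making
train-on-synthetic vs train-on-real comparisons informative.

What the fixture does *not* emulate: real registries have missing data
(this package refuses it at load), mixed measurement scales, many weak
associations rather than one perfect one, and label noise. Passing tests
on the fixture demonstrate the mechanics — perfect-pair detection, exact
consistency, balance control, fidelity ordering — not performance on any
particular registry.

## Numerical and design notes

* Preset sizes mirror a lung-cancer-registry study population: 2304 rows
  split 70/30 into development (1616) and validation (688); test and
  example volumes use the standard 5000-row synthetic table. Property
  checks that need asymptotics (marginal recovery, Spearman recovery,
  chance-level AUC) run at n = 5000.
* All randomness flows through explicit integer seeds; seeded package
  functions save and restore the caller's RNG state.
* Cramér V of a table with a single observed row or column is defined as
  0 (no measurable association), preventing degenerate division criteria.
* The correlation-similarity form $1-|\Delta\rho|/2$ follows the standard
  quality-report convention for pair trends; a constant column in a
  numeric pair routes that pair through the contingency path, where the
  comparison is still defined.
* CSV output renders numerics in the shortest decimal form that reads
  back to the identical double, making write/read a true round trip.

## Known limitations

* Multiple simultaneous $V=1$ pairs produce nested cross-splits; the
  subset-size guard prevents starvation but the allocation of volume to
  deeply nested subsets has not been exercised beyond two features.
* Rules are single-trigger equality constraints; implications with
  compound triggers or range consequences are out of scope.
* The copula backend confines numeric output to the training range and
  cannot extrapolate tails; that is the price of exact structural-zero
  reproduction.
* Privacy (membership inference, attribute disclosure) is deliberately
  not evaluated.
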