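---
title: "Covariate-constrained randomisation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-constrained randomisation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The procedure

`ccrand` implements restricted randomisation by enumeration for two-arm
trials with a fixed, fully known roster of randomisation units — the
situation typical of cluster randomised trials, where all clusters are
recruited before allocation. The procedure has four steps:

1. **Generate.** All \(\binom{n_{free}}{n_{A,free}}\) assignments of the
   free units consistent with the allocation ratio and any pre-assigned
   units are constructed (`mode = "enumerate"`), or a large number of
   uniform draws is taken by shuffling a label vector
   (`mode = "sample"`), optionally deduplicated. `mode = "auto"`
   enumerates whenever the count is within `enumeration_cap` (default
   \(10^6\)) and samples otherwise.
2. **Score.** Each scheme's *total imbalance* is
   \(T(s) = \sum_v w_v\, d_v(s)\), where \(d_v\) is the imbalance metric
   declared for variable \(v\) and \(w_v \ge 0\) its weight.
3. **Preselect.** The best schemes by total imbalance are retained — a
   fixed count, a proportion (count = ⌈proportion × n⌉), or every scheme
   below a threshold.
4. **Choose.** The final scheme is drawn uniformly among the preselected
   ones under an explicit, separate seed.

The key statistical assumption is the one inherent to the method: the
preselection restricts the randomisation distribution, so analyses that
rely on the randomisation itself should account for the restricted
scheme set (the preselected set is exportable for exactly this reason).
The package deliberately stops at two arms and does not implement
sequential minimisation.

### Units, ratio and pre-assignments

The arm-A size is \(n_A = \mathrm{round}(r \cdot N)\) with halves rounded
away from zero, so 15 units at ratio \(1/3\) give a 5:10 split. (Base R's
`round()` rounds halves to even, which would be surprising here; the
rounding rule is centralised in one helper.) Units already allocated in
an earlier block are marked `A`/`B` in the roster's `Allocation` column;
they are excluded from shuffling and the free-arm capacities are the
targets minus the fixed counts. Enumeration order is lexicographic in the
positions of the A labels among free units — arbitrary, but fixed, so
scheme ids are reproducible.

### Two random streams

Scheme generation and the final choice use separate seeds
(`generation_config(seed =)` vs `choose_final(seed =)`). Regenerating or
re-scoring schemes therefore never silently changes the final draw, and
the choice step can be performed — and audited — by an independent second
party, which is also why the CLI exposes `generate`, `select` and
`choose` as separate subcommands and why `choose` refuses to run without
an explicit `--seed`.

## Imbalance metrics

For categorical-type variables (binary, categorical, and integers scored
with `Eucl`), the category universe is fixed once from the *full*
dataset, ordered by first appearance. This keeps summaries comparable
across schemes and guarantees \(p_x^A + p_x^B > 0\) for every category,
so the standardised distances (`X2d`, `Canb`) never divide by zero.

| Id | Definition | Range |
|---|---|---|
| `1-PX2` | \(1 - p\)-value of Pearson's \(\chi^2\) on the 2×k count table | [0, 1] |
| `Eucl` | \(\sqrt{\sum_x (p_x^A - p_x^B)^2}\) | [0, √2] |
| `Manh` | \(\sum_x \lvert p_x^A - p_x^B \rvert\) | [0, 2] |
| `Max` | \(\max_x \lvert p_x^A - p_x^B \rvert\) | [0, 1] |
| `X2d` | \(\sqrt{\sum_x (p_x^A - p_x^B)^2 / (p_x^A + p_x^B)}\) | [0, √2] |
| `Canb` | \(\sum_x \lvert p_x^A - p_x^B \rvert / (p_x^A + p_x^B)\) | [0, k] |
| `Hell` | \(\sqrt{1 - \sum_x \sqrt{p_x^A p_x^B}}\) | [0, 1] |
| `SBKL` | symmetrised KL divergence of smoothed proportions | ≥ 0 |
| `1-PKS` | \(1 - p\)-value of the two-sample Kolmogorov–Smirnov test | [0, 1] |
| `1-Pt` | \(1 - p\)-value of Welch's two-sided t test | [0, 1] |
| `1-PU` | \(1 - p\)-value of the two-sided Mann–Whitney U test | [0, 1] |
| `Mrdq` | \(\max\) over quartile pairs of \(\lvert q^A - q^B \rvert / \max(\lvert q^A \rvert, \lvert q^B \rvert)\) | ≥ 0 |
| `AbCDF` | \(\int \lvert F_A - F_B \rvert \, dx\) | ≥ 0 |
| `SKL` | \(\int p^A \ln\frac{p^A}{p^B} + \int p^B \ln\frac{p^B}{p^A}\) over KDEs | ≥ 0 |

All metrics are nonnegative, zero under exact equality of the arm
distributions, and invariant under swapping the arms and (for the
categorical family) under permuting categories. These invariants, the
range bounds, and the small-sample exactness claims below are enforced by
the property-based test suite on hundreds of randomised instances.

### Decisions where the definitions left latitude

* **Chi-squared test (`1-PX2`).** Pearson statistic, df = k−1, asymptotic
  p-value, *no* Yates continuity correction even for 2×2. One consistent
  definition across k was preferred; with fixed margins the binary
  rank-equivalence of `1-PX2` and `Eucl` (verified in the tests) holds
  with or without the correction, so the choice does not affect metric
  comparability. Note this differs from `chisq.test()`'s 2×2 default.
* **`SBKL` smoothing.** The smoothing must make both smoothed
  distributions strictly positive for the divergence to be defined. The
  default is add-one (Laplace) smoothing
  \(\tilde p_x = (n_x + 1)/(n + k)\) per arm, which is strictly positive
  and sums to one. A multiplicative variant \(\tilde p_x = p_x (n_x+1)\)
  is available as `smoothing = "printed"` for auditability, but it keeps
  zeros at \(n_x = 0\) (handled with the \(0 \ln 0 := 0\) convention) and
  is not a probability distribution; it is not recommended.
* **t test (`1-Pt`).** Welch (unequal variances) — the safer default and
  the convention of most statistical environments. Limit cases: both
  samples constant and equal → 0; both constant but unequal → 1; each
  carries a classed warning.
* **Exact small-sample p-values (`1-PU`, `1-PKS`).** Exact distributions
  are used when there are no ties and \(n_A n_B \le 400\); otherwise the
  tie-corrected normal approximation (U) or the asymptotic Kolmogorov
  distribution (KS). The KS statistic is always evaluated on the pooled
  ECDF, which remains valid under ties. The tests verify both exact paths
  against full permutation enumeration for all splits of pooled size ≤ 10
  with distinct values.
* **Quartiles (`Mrdq`).** Linear interpolation of order statistics with
  \(h = (n-1)p + 1\) ("type 7", the default of most environments),
  centralised in `quartiles()` so the convention can be swapped. A
  quartile pair with both values exactly 0 — the only zero-denominator
  case — contributes 0, by continuity (the numerator is also 0).
* **Degenerate variables.** A single-category (constant) variable scores
  0 on every metric with a classed warning rather than an error, so a
  constant covariate cannot abort a run; `standardize_weights()` gives it
  weight 0.

### The `SKL` density estimate

The densities are Gaussian kernel estimates with Silverman's
rule-of-thumb bandwidth per sample (`bw.nrd0`; a constant sample falls
back to a fixed bandwidth of 10⁻³, with a warning), evaluated on a shared
grid of 512 equally spaced points spanning the pooled range widened by
three times the larger bandwidth. Densities are floored at ε = 10⁻¹²
before the logarithm and renormalised to unit trapezoidal integral; the
divergence is integrated by the trapezoidal rule and clamped below at 0,
since quadrature noise can produce tiny negatives.

Two properties of this estimator are worth knowing. First, kernel
smoothing inflates each arm's apparent variance by \(h^2\), attenuating
the divergence slightly. Second, comparing KDEs of two *independent*
finite samples adds a positive noise term that does not vanish at small
true divergence — at \(n = 200\) it is of the same order as the true
symmetrised KL of unit Gaussians half a standard deviation apart. The
estimator-validation test therefore uses noise-free Gaussian *quantile*
samples (`qnorm(ppoints(200))` and its shift by μ), for which the
estimate must match the closed form μ² within ±30%; observed systematic
error is below 10% for μ ∈ {0.5, 1, 2}. Consequences for users: `SKL`
values are comparable *between schemes on the same data* (the use the
package puts them to), but their absolute scale depends on the density
estimator, and near-zero `SKL` does not imply balance in location — one
reason the comparison module exists.

## Standardisation and weights

Weights serve two purposes. Scientifically, they encode the relative
importance of variables. Numerically, setting each weight to the inverse
of the variable's maximum contribution observed over a scored scheme set
(`standardize_weights()`) maps every variable's contribution range onto
[0, 1], making contributions of different metrics commensurable before
summing — this is what the radar export and the study module use. Since
standardisation is a positive rescaling, it never changes how a single
variable orders the schemes.

Ties in count/proportion preselection are broken by generation index
(stable sort by total, then id): deterministic and independent of any
seed. The threshold criterion takes all schemes at or below the value and
errors explicitly when that selection would be empty.

## The synthetic generator

`synth_dataset()` emulates the two study settings used throughout the
tests: 14 units allocated 7:7 (`"tds1-like"`) and 15 units allocated
1:2 (`"tds2-like"`), each with one variable of every type. The
distributions are the package's own documented choices, picked to be
non-degenerate and realistically scaled at n = 14–15: binary
Bernoulli(0.4); categorical with three levels at probabilities
(0.5, 0.3, 0.2); integer Poisson(3); continuous lognormal(0, 0.5) — a
right-skewed positive variable, deliberately not normal so that the rank-
and ECDF-based metrics are exercised off their home turf. Discrete
columns are redrawn (deterministically under the seed, at most 100 times)
if constant.

What the generator does *not* emulate: correlated covariates,
cluster-size variables, measurement error, or missingness (missing values
are rejected at input, since the method itself offers no principled
imputation step). Passing tests on synthetic data therefore demonstrate
the correctness of the machinery and the metric-equivalence properties
that hold on *any* dataset (e.g. the binary rank equivalence), not
distributional claims about real trials.

## Problem sizes and runtime choices

The test and acceptance workloads use the natural sizes of the small-cRCT
setting: full enumerations of \(\binom{14}{7} = 3432\) and
\(\binom{15}{5} = 3003\) schemes, 10,000-draw sampling runs (whose
uniqueness fraction is checked against the exact occupancy expectation
\(m(1-(1-1/m)^n)/m\) across 20 seeds), property suites of 500–1000
randomised metric instances, and permutation enumerations up to pooled
size 10. A full four-variable study over 3432 schemes with all
type-matching metrics runs in seconds to a few tens of seconds on a
single core; the dominant cost is the 512-point KDE pair per scheme for
`SKL`.

## Limitations

* Two arms only; no stratification and no sequential minimisation.
* Weights are per variable; the scoring itself is a linear combination,
  so interactions between variables are not captured by any metric.
* `SKL` absolute values are estimator-dependent (see above).
* XLSX import needs `readxl` at run time; CSV is the primary format, and
  the expected column layout (`ID`, optional `Allocation`, one column per
  declared variable) is this package's documented convention rather than
  a byte-level match to any other tool's template.
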