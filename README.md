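# ccrand — covariate-constrained randomisation for small two-arm trials

In randomised trials with only a handful of randomisation units — most
commonly cluster randomised trials, where a dozen practices or wards are
the units — simple randomisation easily produces arms with very different
baseline characteristics. `ccrand` implements the *covariate-constrained*
(a.k.a. "studywise minimisation" / "best balance") alternative:

1. construct **all** possible allocations of the units to arms A and B at
   the chosen allocation ratio (or a large random subset when enumeration
   is infeasible),
2. score every scheme's **total imbalance** — a weighted sum of
   per-variable imbalance contributions,
3. **preselect** the sufficiently balanced schemes (by count, proportion,
   or an imbalance threshold),
4. let an independent party **choose the final scheme uniformly at
   random** among those, under an explicit seed.

The package is aimed at trial statisticians who need a scriptable,
auditable version of this workflow, and at methodologists comparing
imbalance metrics.

## Imbalance metrics

For a variable with categories \(x\), let \(n_x^A, p_x^A\) be the count
and within-arm proportion of arm-A units in category \(x\) (likewise B).
Fifteen metrics are provided, selected per variable type:

| Type | Identifiers |
|---|---|
| binary | `1-PX2`, `Eucl` |
| categorical | `1-PX2`, `Eucl`, `Manh`, `Max`, `X2d`, `Canb`, `Hell`, `SBKL` |
| integer | `1-PKS`, `Eucl` |
| continuous | `1-Pt`, `1-PU`, `1-PKS`, `Mrdq`, `AbCDF`, `SKL` |

Highlights: `Eucl` is the classical quadratic imbalance
\(\sqrt{\sum_x (p_x^A-p_x^B)^2}\); `1-PX2` is one minus the Pearson
chi-squared p-value of the 2×k table (intrinsically standardised to
[0,1]); `AbCDF` is the exact area \(\int |F_A - F_B|\,dx\) between the two
empirical CDFs; `Mrdq` is the maximum relative difference of the three
quartile pairs; `SKL` is the symmetrised Kullback–Leibler divergence of
kernel density estimates. Every metric is nonnegative, zero under perfect
balance, and symmetric in the arms. See the methods vignette
(`vignettes/covariate-constrained-randomisation.Rmd`) for all definitions
and numerical conventions.

A comparison module reproduces the metric-comparison methodology:
pairwise Spearman rank correlations between metrics over all schemes,
distinct-value counts, optimal-subset overlap, and radar-chart exports of
standardised contributions.

## Worked example

```r
library(ccrand)

tab <- synth_dataset(profile = "tds1-like", seed = 7)   # 14 units, 4 variables
tab
#> <unit_table> 14 units, 4 variables
#>   bin          binary      metric 1-PX2 weight 1
#>   cat          categorical metric 1-PX2 weight 1
#>   int          integer     metric 1-PKS weight 1
#>   con          continuous  metric AbCDF weight 1

ss <- generate_schemes(tab, generation_config(allocation_ratio = 0.5,
                                              mode = "enumerate"))
ss <- score_schemes(ss, tab)
ss <- score_schemes(ss, tab, weights = standardize_weights(ss))
ss
#> <scheme_set> 3432 schemes (enumerate mode), 14 units
#>   coverage: 3432 unique of 3432 possible (100.0%), 3432 generated
#>   scored on 4 variable(s); total imbalance range [0.3354, 3.228]

sel <- preselect(ss, "count", 10)
sel
#> <preselection> 10 of 3432 schemes (count = 10), totals [0.3354, 0.381]

choose_final(sel, seed = 2026)
#> <allocation_scheme> #242, total imbalance 0.381
#> unit01=A, unit02=A, unit03=A, unit04=B, unit05=B, unit06=A, ...
```

All 3,432 ways of splitting 14 units 7:7 were enumerated; after
standardisation each variable's contribution ranges over [0,1], so the
best achievable total imbalance here is 0.335 and the final scheme —
drawn uniformly among the 10 best under seed 2026 — is scheme #242 with
total 0.381. `write_final_scheme()` exports it as a unit/arm CSV.

The same pipeline is available from the shell via the installed
`exec/ccrand` script (`simulate`, `generate`, `select`, `choose`,
`compare` subcommands), which logs to stderr and writes a run manifest
(seeds, settings, config hash) next to every result.

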