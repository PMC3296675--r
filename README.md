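# descmeta

Meta-analysis of **descriptive, single-group data** — rates, incidences and
prevalences — with publication-quality forest plots.

Most meta-analysis tooling is built around comparative effect sizes (odds
ratios, risk ratios, mean differences). Reviews that pool a *single-group
summary* — the prevalence of smoking in a country, the incidence of
myocardial infarction in high-risk patients — need the same machinery
(inverse-variance weighting, heterogeneity statistics, random-effects
adjustment, forest plots) applied to plain proportions. `descmeta`
implements that pipeline end to end as a tested R package with a
command-line interface, for epidemiologists and systematic reviewers who
have a table of `events / total` counts (or pre-computed estimates with
confidence intervals) and want auditable numbers and a customisable plot.

## The model

For study *i* with `events_i` of `total_i` subjects, the effect size is the
rate `es_i = events_i / total_i` with standard error
`SE_i = es_i / sqrt(es_i * total_i) = sqrt(events_i) / total_i`
(the rate formula used by the CMA software; an exact binomial
`sqrt(es(1-es)/n)` variant is available behind a flag). Each study is
weighted by the inverse of its variance, `w_i = 1 / SE_i^2`.

- **Fixed effect:** pooled estimate `ēs = Σ(w·es) / Σw`, standard error
  `sqrt(1/Σw)`, normal confidence interval `ēs ∓ z·SE`.
- **Heterogeneity:** Cochran's `Q = Σ(w·es²) − (Σ w·es)² / Σw`, referred to
  a chi-square distribution with `k − 1` degrees of freedom, and
  `I² = (Q − df)/Q × 100` (floored at 0).
- **Random effects (DerSimonian–Laird):** between-study variance
  `v = (Q − (k−1)) / (Σw − Σw²/Σw)` (floored at 0; usually written τ²),
  adjusted weights `w_v = 1/(SE² + v)`, and the fixed-effect arithmetic
  repeated with `w_v`. The re-computed Q/I² under the adjusted weights is
  reported as a labelled diagnostic, not a test.
- **Sensitivity:** leave-one-out re-pooling across all `k` subsets.

Forest plots are built from explicit scatter geometry: display-scaled
points (percent by default), asymmetric error-bar deltas measured *from*
the estimate, ordinal rows with the summary at the bottom, a vertical
reference line at the pooled value and a CI-spanning summary diamond,
rendered to SVG (losslessly parseable) or PNG, optionally composed beside
the study table.

## Worked example

```r
library(descmeta)

fit <- meta_analysis(example_studies(), leave_one_out = TRUE)
print(fit)
#> Meta-analysis of 10 single-group studies
#>
#> Fixed-effect pooled estimate (k = 10)
#>   es = 0.179535  se = 0.00729678  95% CI [0.165234, 0.193837]
#>   Q = 18.607 (df = 9, p = 0.0288), I2 = 51.6%
#>
#> Random-effects pooled estimate (k = 10)
#>   es = 0.185045  se = 0.0109759  95% CI [0.163533, 0.206558]
#>   between-study variance v = 0.000586011 (raw 0.000586011)
#>   post-adjustment diagnostic: Q = 10.0421 (df = 9, p = 0.347), I2 = 10.4%
#>
#> Leave-one-out sensitivity tables attached ($sensitivity)
```

The ten studies pool to a fixed-effect rate of 18.0% (95% CI 16.5–19.4%).
Q = 18.61 exceeds the 16.919 critical value at 9 df (`q_reference(9)`), and
I² = 51.6% indicates moderate heterogeneity, so the random-effects summary
(18.5%, 95% CI 16.4–20.7%) is the defensible one — note its interval is
about 1.5× wider while the point estimate barely moves.

```r
spec <- build_plot_spec(estimates_table(fit), fit$random,
                        axis_min = 10, axis_max = 28, tick = 2)
render_forest(spec, "forest.svg")
compose_with_table(spec, estimates_table(fit), "forest_table.svg")
write_results(fit, "results.json")
```

The same run from a shell:

```sh
Rscript inst/cli/descmeta.R --input studies.csv --model both \
  --results results.json --plot forest.svg --leave-one-out
```

where `studies.csv` has a header `study,events,total` (or
`study,estimate,ci_lower,ci_upper` for pre-computed rows). Zero-event
studies are rejected with an actionable error unless
`--zero-correction 0.5` enables the continuity correction.

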