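---
title: "Pooling single-group rates: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling single-group rates: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descmeta)
```

## The problem

Systematic reviews of observational studies often need to pool a
*descriptive* quantity — an incidence or a prevalence — rather than a
comparative effect. Nothing "causes" a prevalence, so the pooled quantity
is a single-group summary, but the statistical machinery is the familiar
inverse-variance one. `descmeta` implements that machinery for raw
`events/total` counts and for pre-computed estimate + CI rows, together
with a forest-plot builder whose geometry is fully exposed and testable.

## Per-study effects

For counts the effect size is the raw rate `es = events/total`. The
default standard error is the rate formula

    SE = es / sqrt(es * n) = sqrt(events) / n,

chosen for comparability with the CMA software's treatment of rates; the
exact binomial form `sqrt(es (1 - es) / n)` is available via
`se_formula = "binomial"`. The two differ by a factor `sqrt(1 - es)` on
the variance, negligible for small rates and conservative (wider) for the
default. We pool raw proportions; logit, arcsine or Freeman–Tukey
transforms are deliberately out of scope — the package pools what its
users enter, and for rates in the 10–30% range the raw scale is both
interpretable and numerically unproblematic.

At `events = 0` (or `events = total`) the rate SE degenerates and the
weight is undefined. The package refuses such records by default with an
error naming the study, because silently "fixing" a zero can mask a data
problem; an explicit continuity correction (`zero_correction = 0.5`, i.e.
`events + 0.5` over `total + 1`) is available and every application of it
is logged.

For pre-computed rows the SE is recovered from the CI width,
`(upper − lower) / (2 z)`, with `z` the exact normal quantile at the
stated level — not the printed 1.96, a deliberate choice that changes CI
widths by under 0.03%. Intervals asymmetric about the estimate by more
than 1% of their width trigger a warning (the full-width formula is still
used): a strongly asymmetric interval usually means the original analysis
worked on a transformed scale, and a symmetric normal SE is then only an
approximation.

## Pooling and heterogeneity

All pooling reduces to four sums over the studies in input order —
`Σw`, `Σ(w·es)`, `Σ(w·es²)`, `Σw²` — accumulated left-to-right with
long-double precision, so results are bit-reproducible for a given input
order. The fixed-effect estimate is `Σ(w·es)/Σw` with SE `sqrt(1/Σw)`.

Cochran's `Q = Σ(w·es²) − (Σ w·es)²/Σw` is referred to a chi-square with
`k − 1` df (`q_reference()` gives the exact critical value and p-value),
and `I² = (Q − df)/Q × 100`. The DerSimonian–Laird between-study variance
is the moment estimator

    v = (Q − (k − 1)) / (Σw − Σw²/Σw),

and random-effects weights are `w_v = 1/(SE² + v)`.

Numerical conventions, all standard but worth stating:

- **Clamping.** Negative `Q` round-off is floored at 0; `I²` and `v` are
  floored at 0 with the raw values retained and reported (`I2_raw`,
  `v_raw`). `Q < df` is common under homogeneity and must not produce
  negative weights downstream.
- **`k = 1`.** Pooling returns the study itself with its own CI;
  heterogeneity is marked not applicable rather than dividing by `df = 0`.
- **CI bounds.** Always `es ∓ z·SE` with the exact quantile; bounds are
  symmetric about the estimate by construction.
- **Post-adjustment diagnostic.** Re-computing Q and I² with the adjusted
  weights `w_v` (a spreadsheet-era tradition) is supported and reported,
  but labelled `diagnostic`: after re-weighting by `1/(SE² + v)` the
  statistic no longer has its chi-square reference and must not be used
  for inference.
- **Leave-one-out** (`k ≥ 3`) re-runs the full pipeline per subset,
  re-estimating `v` each time under the random-effects model.

## The synthetic-study generator

`simulate_studies()` draws, per study, a true proportion
`p_i ~ N(true_p, between_sd)` (optionally on the logit scale), a
denominator uniform on `n_range`, and `events_i ~ Binomial(n_i, p_i)` —
exactly the random-effects premise the DL model assumes, on the proportion
scale because that is the scale the package pools. Draws are truncated to
`[0.001, 0.999]` (logged) so the rate SE stays defined. The generator is
seeded explicitly and restores the global RNG state.

Defaults (`k = 10`, `n_range = c(150, 600)`, `true_p = 0.19`,
`between_sd = 0.03`) emulate a typical ten-study prevalence review whose
rates sit in a 10–28% display window with moderate heterogeneity.
`example_studies()` is one such dataset, generated once from this model
and then frozen: ten studies, Q = 18.61 > 16.919 (the 9-df critical
value), I² = 51.6%.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: publication bias, correlated study
populations, covariate-driven heterogeneity (no meta-regression is
offered), non-binomial overdispersion within studies, and rates near the
boundaries where the raw-proportion normal approximation deteriorates.

Simulation checks in the test suite use these problem sizes: 1000
replicates of k = 50 studies with n = 500 at `true_p = 0.20`,
`between_sd = 0.04` for parameter recovery (mean recovered `v` close to
`0.04² = 0.0016`, 95% CI coverage near nominal), and a few hundred
replicates of the k = 10 default regime for the heterogeneity-monotonicity
and degenerate-limit properties — sizes at which Monte-Carlo error is
small relative to the tolerances tested.

## Forest-plot geometry

The plot is constructed as explicit scatter geometry before any drawing:

- display values are `estimate × 100` by default (percent; `display =
  "raw"` keeps proportions) — scaling is display-only, the analysis always
  runs on `[0, 1]`;
- error bars are stored as *deltas from the estimate* (`display − lower`,
  `upper − display`), which is what makes asymmetric intervals render
  correctly;
- rows get integer ordinates increasing upward, first input study topmost
  (`k + 1`), summary at 1 (bottom), so visual order equals input order;
- the summary is a diamond whose horizontal vertices sit at the CI bounds
  (half-height 0.3 row units), with `paper_style = TRUE` restoring the
  plainer marker-plus-error-bar look; a dashed vertical line marks the
  pooled value across all rows;
- the axis window defaults to `[floor(min CI), ceil(max CI)]` padded by
  one tick, the tick picked from `{1, 2, 5} × 10^m` as the smallest value
  giving at most ten ticks across the unpadded span — a deterministic
  stand-in for hand-picking; both window and tick are overridable, and a
  logarithmic scale (requiring a positive window) is available for
  ratio-type data entered via the precomputed path;
- markers are equal-sized squares by default; `marker_weights` opts into
  area-proportional markers. Equal sizes under-represent precision, which
  is why the CI width remains the primary precision cue;
- values outside the window are clipped to the window edge with a warning
  naming the study — clipping is never silent.

SVG output writes coordinates at 17 significant digits and records the
axis window and plot box as `data-*` attributes on the root element, so
tests (and users) can invert the pixel transform and recover the plotted
intervals exactly; PNG output draws the same geometry through base
graphics. The composed figure (`compose_with_table()`) places text columns
whose row centres coincide with the marker ordinates.

## Known limitations

Only the DerSimonian–Laird estimator is provided (no REML or
Paule–Mandel), CIs are normal-theory (no Knapp–Hartung adjustment, no
prediction interval), and there is no subgroup analysis, meta-regression
or funnel plot. The leave-one-out table is the supported sensitivity
analysis. These bounds keep the package a faithful, auditable
implementation of the classical spreadsheet workflow rather than a
general-purpose meta-analysis framework; for those needs use `metafor`,
which this package's test suite uses as an independent cross-check of its
own arithmetic.
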