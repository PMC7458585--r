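---
title: "Monitoring infodemic monikers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring infodemic monikers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodemic)
```

## The problem

During a fast-moving epidemic, the terms people search for and hashtag —
"infodemic monikers" — range from neutral scientific vocabulary to phrases
that spread misinformation, stigmatize places or ethnicities, or push
opinions. Public-health communicators need three quantitative handles on
this traffic:

1. **How harmful is a term?** A rubric score on an ordinal scale.
2. **How much attention does it get?** A summary of its normalized
   search-volume trajectory, with uncertainty.
3. **Does attention track disease burden?** A country-level association
   between search interest and incidence.

This package implements all three as small, composable estimators plus a
deterministic end-to-end pipeline, together with seeded generators that
produce every input format with known ground truth.

## The I-scale rubric

Each moniker is annotated by a human with 0–2 points in five categories —
*generic*, *misinformative*, *discriminatory*, *deviant* and *other
specificities* — so the total score lies in 0–10. Scores map to five
severity classes that partition the range: 0 (not infodemic), 1
(slightly), 2–4 (moderately), 5–8 (highly), 9–10 (extremely).

The computable core is deliberately only **validation + arithmetic +
classification**. Inferring category points from the keyword text would
put a language model's judgment where the method requires a human's; the
package therefore takes explicit integer points as input and enforces
their range, non-empty monikers, and case-insensitive uniqueness
("corona" and "Corona" are one query to a search engine).

```{r}
ann <- read_annotations(infodemic_example("table1_annotations_synthetic.csv"))
scored <- iscale(ann)
head(as.data.frame(scored)[, 1:3])
```

The bundled annotation tables are *synthetic reconstructions*: the
published sources print only total scores, so the per-category breakdowns
were chosen to be consistent with the rubric's worked examples and to sum
to each printed total (see `inst/extdata/README.txt`).

## RSV and the average peak volume estimator

Search-trend services publish a **relative search volume (RSV)**: an
integer index from 0 to 100 where 100 marks the period/region maximum.
`normalize_rsv()` reproduces this convention from raw counts, with
half-up rounding (`round_half_up()`) because the published indices are
integers and base R's banker's rounding would disagree on ties.
Normalization preserves value ordering and is idempotent on
already-normalized nonzero series; an all-zero series is returned
unchanged and flagged degenerate.

A keyword's headline statistic is the **average peak volume (APC)**. The
published definition is informal, and printed totals exceed the
per-series ceiling of 100, which implies summation across series. The
package's operationalization, chosen once and documented here, is:

* tile the date range into consecutive windows of `window_days`
  (default 7) anchored at the first observation, keeping a trailing
  partial window — a deterministic, reproducible tiling;
* record the maximum RSV in each non-empty window (`extract_peaks()`);
* for geography $g$ with $n_g$ windowed peaks, mean $m_g$ and unbiased
  variance $s_g^2$ (zero when $n_g = 1$),
  $$\mathrm{APC} = \sum_g m_g, \qquad
    \mathrm{halfwidth} = z_{(1+\ell)/2}\,\sqrt{\sum_g s_g^2 / n_g},$$
  with a Gaussian interval $\mathrm{APC} \pm \mathrm{halfwidth}$ floored
  at 0 (default level $\ell = 0.95$, $z_{0.975} = 1.959964$).

Because proprietary search extracts cannot be re-downloaded
deterministically, published APC point values are treated as *inputs*
(transcribed keyword tables), and the estimator itself is validated by
Monte-Carlo: on i.i.d. Gaussian window peaks the 95% interval covers the
true mean at its nominal rate, and the interval half-width halves when
the number of peaks quadruples (checked at $n \in \{25, 100, 400\}$; the
test suite uses 400–1,000 replicates, sizes chosen to make the binomial
error on a coverage estimate a fraction of a percentage point).

```{r}
pk <- data.frame(geo = rep(c("IT", "DE"), each = 3),
                 peak_value = c(60, 70, 65, 30, 40, 35))
apc(pk, keyword = "example")
```

### Breakouts, spikes and events

A **breakout** is a date at which a normalized series attains RSV = 100.
A **spike** is a strict local maximum (endpoints compared to their single
neighbor) at or above a threshold; a flat series has none, a monotone
rise spikes only at its end, and a single observation counts when it
meets the threshold. These are this package's operationalizations — the
source analyses report spike values without defining them. Spikes can be
aligned to a dated event log within a day tolerance (`align_events()`);
equidistant events resolve to the earlier one, and only date alignment is
claimed, never causal attribution.

### Ranking and severity aggregation

`rank_by_apc()` orders keywords by APC total (ties broken
alphabetically). `aggregate_by_severity()` sums keyword APC totals per
severity class and reports class shares. Two details are genuinely open
in the source material and are handled explicitly:

* **Class confidence intervals.** Published class intervals equal
  neither variance propagation nor summed member bounds. The default
  (`ci_method = "variance"`) back-solves each keyword's Gaussian variance
  from its CI half-width and propagates the sum; `"sum_of_bounds"` simply
  adds member bounds. The method used is recorded in the result.
* **Share denominators.** Published class percentages are not consistent
  with a single denominator, so the summary reports shares over the
  grand total *and* over the total excluding the not-infodemic class.

```{r}
est <- read_apc_table(infodemic_example("table1_google_apc.csv"))
aggregate_by_severity(est, scored)
```

## Hashtag shares

`shares()` divides each tag's post count by the table's grand total —
never an external platform total — and displays percentages rounded
half-up to one decimal. Combined shares of a tag subset support two
conventions: `"sum_of_rounded"` adds the individually rounded display
shares (the convention used in published summaries, where 35.6 + 30.5 =
66.1), and `"exact"` rounds the exact combined ratio once (66.2 for the
same pair). The first is labeled paper-compatible; the second is the
numerically honest alternative. Counts are posts, not distinct users, and
the package never converts one into the other. `to_multiples()`
implements the "multiples of 100,000" display convention of country
tables (963,000 → 9.63).

## Search interest vs incidence

`panel_pearson()` computes, from first principles,
$$r = \frac{\sum (x_i-\bar x)(y_i-\bar y)}
           {\sqrt{\sum (x_i-\bar x)^2 \sum (y_i-\bar y)^2}},\qquad
  t = r\sqrt{\frac{n-2}{1-r^2}},$$
with a two-sided p-value from the Student-$t$ distribution on $n-2$
degrees of freedom (base R's `pt()` supplies the tail probability).
P-values are kept at machine precision and displayed as "<.001" below
that threshold. `build_panel()` makes the interest measure explicit —
window-mean RSV by default, APC optionally — because the source analysis
does not state which measure (or which countries) entered its
correlation; a published $R = 0.45$ is therefore a recovery target on
synthetic panels, not a desk-reproducible number.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their scenario and seed (the default
seed, 20200220, is the study-window start date):

* `sim_raw_series()` — baseline + Gaussian noise + triangular spike
  kernels (default half-width 5 days). The triangular kernel makes the
  injected argmax analytic, so spike- and breakout-detection tests are
  exact in the noise-free case.
* `sim_hashtag_table()` — one multinomial draw over tag probabilities;
  counts conserve the total exactly.
* `sim_country_panel()` — a standard bivariate normal pair with latent
  correlation $\rho$ (Cholesky construction). The default transform
  exponentiates both coordinates, giving the right-skewed, positive
  marginals real country panels show; the exponential changes the linear
  correlation, and for unit-variance normals the realized population
  Pearson correlation has the closed form
  $(e^{\rho}-1)/(e-1)$, which the generator attaches as `true_r` and
  `calibrate_rho()` inverts. Because the lognormal pair is heavy-tailed,
  the sample correlation's dispersion exceeds the classical
  $(1-r^2)/\sqrt{n}$; when a test needs that light-tailed bound, the
  `transform = "normal"` option keeps the Gaussian pair (shifted six
  standard deviations into the positive range), for which `true_r` is
  $\rho$ exactly.
* `sim_annotations()` — uniform category points, or exhaustive
  enumeration of all $3^5 = 243$ rubric combinations.

The generators do **not** emulate: the resampling jitter a trend service
applies across repeated extractions, weekly seasonality or long-term
drift, correlated hashtag growth over time, or spatial autocorrelation
between countries. Passing recovery tests on this synthetic family
therefore demonstrates correctness of the estimators under their stated
assumptions, not robustness to those real-data features.

## Numerical and degenerate-input choices

* Half-up rounding everywhere a display value is produced; an epsilon of
  `1e-9` guards binary-representation artifacts.
* Windows anchored at the first observation date; trailing partial
  windows kept.
* All-zero series: normalization returns zeros with a degenerate flag;
  breakout detection returns an empty set.
* Zero-variance APC inputs (one peak per geography) collapse the CI to
  the point estimate rather than erroring.
* Ties: equal APC totals rank alphabetically; equidistant events match
  the earlier event.
* Scores outside 0–10, non-integer points, empty monikers, case-folded
  duplicate monikers or tags, all-zero count tables, panels with fewer
  than 3 countries or zero variance: all are errors, named after the
  offending field or stage.

## The pipeline

`run_pipeline()` composes the stages from a single config (R list or
JSON file), writes per-stage CSVs and one JSON report with stable field
ordering and explicit display precision, logs row counts per stage, and
removes partial outputs on failure so a crashed run leaves no
half-written state. Identical inputs and seed give byte-identical
reports. A thin command-line wrapper with `score`, `trends`, `hashtags`,
`associate`, `simulate` and `report` subcommands ships in
`inst/cli/infodemic.R`.

## Known limitations

* APC depends on the window length and on which geographies are summed;
  published totals are reproducible only from published keyword tables,
  not from re-derived search data.
* The rubric encodes a specific annotation protocol; the package checks
  its arithmetic, not inter-annotator agreement.
* The Pearson analysis is a bivariate screen — no confounder adjustment,
  regression modeling or spatial correlation handling.
* Hashtag shares are relative to the supplied table's universe of tags;
  changing the universe changes every share.
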