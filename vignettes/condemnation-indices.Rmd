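---
title: "Condemnation surveillance indices: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condemnation surveillance indices: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condemnr)
```

## The data and its limitations

A monthly condemnation table records, for one slaughterhouse, how many birds
of each species category (turkey, griller chicken, heavy chicken) were
slaughtered and how many carcasses were condemned per cause at post-mortem
inspection. Two structural features of such registries drive the design of
this package:

* **Partial and total condemnations are indistinguishable.** A condemned
  count is the sum of both dispositions, and a single carcass can in
  principle contribute several partial records. `condemnation_data()`
  therefore warns — but does not reject — when a month's condemned counts
  exceed its head count.
* **Condemnations are not attributable to a species.** When turkeys and
  chickens are slaughtered in the same month, the registry gives one pooled
  condemned count. All rates in this package are therefore computed against
  the *total* head count, and species effects are studied indirectly by
  classifying months into Group A (turkey slaughtered alongside chicken) and
  Group B (heavy chicken only) and comparing the per-month percentage rates
  between groups.

Months flagged as excluded (data inconsistencies) stay in the table but
contribute to no index or inference; whole-period frequency accounting keeps
them by default, because aggregate count registries are published without
that distinction. A missing month is simply absent, which is different from
an excluded one: both reduce the number of years that enter a calendar
month's seasonal average.

## Condemnation Occurrence Index

For condemned count $C$ and head count $N$ in a period,
$\mathrm{COI} = s\,C/N$ with scale $s = 10^6$ by default (condemnations per
million head; $s = 100$ gives a percentage). `period_coi()` pools counts
before dividing — it is a ratio of sums, not a mean of monthly ratios, which
matters when monthly head counts are unbalanced. A zero denominator is an
error, never a silent `NaN`.

## Adjusted Seasonal Index

The ASI is a ratio-to-annual-mean seasonal index built in two stages:

1. **Within-year ratios.** Each usable month's COI is divided by the
   arithmetic mean of its own year's usable monthly COIs. Partial years use
   the months present. By construction the ratios of any complete year
   average to exactly 1, and the whole construction is invariant to
   rescaling the series globally or any single year by a positive constant —
   year-level effects (throughput changes, legislation, detection effort)
   cancel.
2. **Across-year averaging.** The ASI of calendar month $m$ is the
   *unweighted* arithmetic mean of month $m$'s ratios across years, because
   the estimand is "the typical relative level of month $m$", not a
   volume-weighted rate. `n_years` is reported per month: an excluded
   December leaves eleven Decembers' ratios out of twelve years, and the
   average is taken over every usable December rather than any fixed-length
   window.

Only non-technological causes (those involving pathogens, hygiene or
climate: dermatosis, aerosacculitis, arthritis, septicemia, disgusting
aspects, cellulitis, ascitic syndrome) are ASI-eligible in the default
registry: causes driven by process failures have no reason to cycle with the
calendar, and very rare causes (cachexia, contagious epithelioma) yield
unstable ratios. The eligibility flags are configuration, not code: other
plants can supply their own `cause_registry()`.

No moving-average or X-11-style decomposition is offered; the ratio-to-mean
construction is the method this package implements.

## Inference choices

* **Group comparison.** Welch's unequal-variance t test on the per-month
  percentage rates. The groups are strongly unbalanced in realistic
  calendars (on the order of 110 vs 21 months) with visibly different
  spreads, so the pooled-variance assumption is not defensible. The group
  indicator is the 0/1 "categorical" coding; the outcome stays continuous.
* **Effect sizes.** The headline effect size is the rank-biserial
  correlation $2\,\mathrm{AUC} - 1$ derived from the Mann–Whitney U, which
  reaches exactly $\pm 1$ under complete separation (the signature of a
  cause present only in turkey months, e.g. aerosacculitis). The
  point-biserial correlation is computed alongside. Both are signed positive
  when Group A exceeds Group B.
* **Correlation.** Spearman's $\rho$ with average-rank ties on monthly
  per-slaughter ratios, graded by the Mukaka strength bands (lower bound
  inclusive). A constant series has no defined rank correlation; its entries
  are `NA`, never 0 — a zero would assert independence the data cannot show.
* **Calendar-month inference.** One-way ANOVA of the stage-1 ratios with
  calendar month as the factor and years as replicates (the only replicate
  structure the ratio construction provides), followed by Tukey HSD over all
  66 month pairs. Months with fewer than two replicate years are dropped
  with a warning. If the within-month variance is exactly zero the
  studentized range is undefined: adjusted p-values are then 1 for zero mean
  differences and 0 for non-zero ones, so a degenerate input cannot appear
  spuriously significant in either direction.
* **Expectation test.** Each calendar month's ratios are tested against
  $\mu_0 = 1$ (the year's expected level) with a two-sided one-sample
  t test. A zero-variance sample raises a degenerate-sample error rather
  than returning $p \approx 0$.
* $\alpha = 0.05$ throughout. No multiplicity correction is applied across
  causes or variables beyond Tukey's within-cause adjustment; the analysis
  battery mirrors common surveillance practice, and months are treated as
  exchangeable replicates (no autocorrelation modelling).

## The synthetic generator

`simulation_config()` defines a generative model whose estimands coincide
with the package's statistics: cause $c$ in month $t$ has mean
$\mu_{c,t} = \sum_s N_{s,t}\, p_{c,s}\, m_c[\mathrm{month}(t)]\, g^t$ with
Poisson noise (negative binomial optional, for overdispersion experiments —
Poisson is the minimal assumption for count registries). Head counts are
drawn Poisson around a piecewise-constant species schedule. Seasonal
12-vectors are renormalised to arithmetic mean 1 on construction, so the
injected vector is exactly what the ASI estimates when the trend is flat; a
strong trend biases within-year ratios (late months ride higher on the
trend), and the generator exposes `trend` precisely so that tests can
quantify that bias instead of hiding it.

`reference_config()` fixes one realistic set of study conditions: 131 months
(January 2009–November 2019), about six million head per month, turkeys at
~5% of head count until a phase-out (reduced through 2017, last slaughtered
February 2018), griller chickens replaced by heavy chickens from July 2017,
per-head cause probabilities proportioned like a large export plant's
frequency table and scaled so the period-average condemnation sits near 7%
under a 1.003/month upward trend, aerosacculitis concentrated in turkeys,
ascitic syndrome peaking July–October (cold-season metabolic condition) and
aerosacculitis dipping May–September.

What the generator does **not** emulate: within-month reporting artefacts,
serial autocorrelation beyond the smooth trend, inspector-effort changes at
specific dates, and multi-cause dependence (causes are conditionally
independent given the month). Passing recovery tests therefore validates the
arithmetic and the statistical calibration of the pipeline, not the
behaviour of any real plant's data.

## Validation and problem sizes

The test suite validates every statistic against an independent route:
brute-force pair counting for the rank-biserial, an explicit double loop for
the ASI, rank-then-Pearson for Spearman, and closed-form studentized-range
and t formulas for the Tukey and expectation tests (100 random instances
each). Calibration and power use sizes chosen to keep Monte-Carlo error
small at interactive runtimes: seasonal recovery on a 132-month series with
Poisson means around $10^4$ per month (max-abs recovery error well under
0.05); type-I error of the expectation test on 2,016 flat-null month-samples
(42 simulated series × 4 causes × 12 months, observed rate within
$0.05 \pm 0.02$); and detection of a July multiplier of 1.55 against
January–June by Tukey HSD in 100 seeded series (observed rate 100%).

## Known limitations

* Group sizes derived strictly from species head counts need not match
  published group tallies for any real calendar; the rule here is
  deterministic and closed-world (griller-only months are UNCLASSIFIED).
* Published aggregate tables are sometimes internally inconsistent: the
  percent column of a frequency table may only be consistent with the sum of
  the cause counts, not with the printed grand total. The default percent
  denominator is therefore `sum_of_causes`; `reported_total` is available
  and logs the discrepancy it finds.
* The ASI inherits the upward bias of ratio estimators at low counts;
  indices for very rare causes should be read qualitatively.
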