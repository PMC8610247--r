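---
title: "Screening journals for concentrated authorship: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening journals for concentrated authorship: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(journalscreen)
```

## The problem

Most journals spread their output over many authors. A journal in which a
handful of authors — often sitting on its own editorial board — account for a
disproportionate share of everything it publishes raises a different concern
than predatory publishing: favoritism in editorial decision-making.
`journalscreen` computes, from article-level metadata alone, a small set of
screening statistics that make such concentration visible and comparable
across thousands of journals, and flags the extreme tail for manual review.
The indices are screening tools, not verdicts: a flagged journal may simply
host a prolific specialist community or an active staff writer.

## Indices

**PPMP.** For a journal with $N_{tot}$ *authored* articles (articles with at
least one identified author) over the analysis window, and $n_{max}$ the
largest number of those articles carrying any single author identity, the
percentage of papers by the most prolific author is
$$\mathrm{PPMP} = n_{max} / N_{tot}.$$
When several authors tie at $n_{max}$ they are all recorded as most
prolific, but the numerator is counted once. Internally the value is a
fraction; reports multiply by 100.

**Sample-corrected Gini index.** To capture concentration in a *group* of
authors rather than a single one, the per-author article counts
$y_1,\dots,y_n$ (every author identity with at least one article) are
summarised by a Gini coefficient with a small-sample correction. Sorting the
counts in nondecreasing order,
$$G = \left[\frac{2\sum_{i=1}^n i\,y_{(i)}}{n \sum_i y_{(i)}} -
\frac{n+1}{n}\right]\frac{n}{n-1}.$$
$G = 0$ iff all authors published equally often; the correction $n/(n-1)$
makes a total monopoly score 1 at any $n$. The package carries a second,
algebraically identical implementation through pairwise absolute
differences, $G = \frac{\sum_{i,j}|y_i-y_j|}{2n^2\bar y}\cdot\frac{n}{n-1}$,
used exclusively as an independent oracle in the tests; the two agree to
$10^{-12}$ over large random sweeps.

**Lorenz curves.** `lorenz_curve()` returns the cumulative share of
authorships against the cumulative share of authors (sorted least to most
prolific), from $(0,0)$ to $(1,1)$; $1 - 2\times$ the area under it equals
the *uncorrected* Gini, i.e. $G\,(n-1)/n$, which the tests verify by
trapezoid integration to $10^{-9}$.

**Author identity.** Within a journal an author is keyed by family name plus
full given name when available, otherwise family name plus initials;
collective names are identities of their own. Name parts are normalized
(Unicode NFC, case-fold, whitespace collapse, periods stripped, hyphens
kept) — deliberately minimal, merging trivial spelling variants without
attempting disambiguation. Homonym merging and name changes are a known
hazard of any such keying, which is why `key_kind` exposes the share of
initials-only identities and why collective names can be excluded
(`include_collectives = FALSE`) when a staff byline such as an editorial
office would otherwise dominate a tally. Both collective policies are
first-class because both occur in practice.

## Populations and classification

All indices are computed on two nested populations: every authored article
(the principal analysis) and authored *research articles* only (a
sensitivity analysis). A research article carries the publication type
`"Journal Article"`, a non-empty abstract, and none of 31 excluded MEDLINE
labels (editorials, letters, news, errata, biographies, ...). The list ships
as a plain-text data file so it can be audited or overridden. Labels are
compared case-sensitively; unknown labels neither qualify nor exclude. This
rule is simple and reproducible but imperfect — content mislabelled at
indexing time is misclassified here too, which is one reason the research
population is a sensitivity analysis rather than the primary one.

## Eligibility and windowing

A journal enters the analysis when it has at least one Broad Subject Term
(catalogue metadata identifying it as biomedical) and at least 50 authored
articles in the chosen population over the window. The floor is inclusive
(exactly 50 qualifies) and is applied after pooling journals published under
former names — renamings are user-supplied (`alias_of`), never guessed. The
publication year of an article is taken from its journal-issue date, falling
back to the electronic publication date; the source data do not define a
single canonical "publication year", so one rule is fixed and applied
everywhere.

## Publication lag

The lag of an article is the whole number of days from its received date to
its accepted date, when both are reported. Negative differences are treated
as data errors (absent, with a warning); zero-day lags are kept — same-day
acceptance is exactly the kind of signal the metric exists to surface. Per
journal, articles split into those carrying at least one most-prolific
author and the rest; each side is summarised by its median lag over valid
lags (even counts: midpoint of the central pair), and the ratio
MPA/non-MPA is reported when both sides have at least one valid lag.
Journals that do not report history dates are recorded as non-calculable
rather than dropped silently. A descriptive tally counts journals with a
median strictly below 21 days (three weeks — short enough to question
whether substantive peer review occurred) on either or both sides.

## Outlier screening

Per population, a journal is flagged when its PPMP and/or Gini index lies
strictly above the empirical 95th percentile of the eligible journals.
Because the thresholds depend on the quantile rule, it is fixed and named in
the output metadata: linear interpolation between order statistics at
$h = (n-1)q + 1$ (type 7, the default of mainstream statistical
environments). "Above" is a strict inequality: a journal exactly at the
threshold is not flagged. Overlaps between index- and population-specific
flag sets are reported as four-way partitions; Pearson correlations between
indices come with a Fisher-$z$ 95% interval ($\tanh(\operatorname{atanh} r
\pm 1.96/\sqrt{n-3})$). For manual review, `sample_flagged()` sorts the
flagged journals by title and draws a fixed-size sample from a generator
seeded at 42 by default — deterministic within this package, though a
different environment's generator would realise a different sample from the
same seed.

Two citation side-metrics characterise flagged journals when citation data
are supplied: the *self-citation boost* (self-citing articles over
non-self-citing articles, where self-citing means the reference list cites
the same journal within the user-chosen window of the input table) and
*skewness and nonarticle inflation* ((impact factor − median per-article
citations) / median citations, undefined at median 0). The impact factor is
an input, never computed.

## The synthetic corpus generator

Real corpora require a large harvest from a bibliographic database, so the
package ships a generator whose output has known ground truth, making every
pipeline stage testable offline. Per journal it draws an article count from
a log-normal truncated at a floor of 50 (defaults: median 500, $\sigma_{\log}
= 0.97$, matching a five-year survey-scale corpus whose interquartile range
is roughly 260–960); assigns publication types from a mixture (85%
`"Journal Article"`, 4% reviews, the rest editorials, letters, news and
errata, giving a research share near 84%); marks 0.9% of articles
authorless; and fills bylines of mean length 4 from a 500-author background
pool with Zipf-like rank weights (exponent 0.4). Those two background
parameters were chosen once so that the *background* maximal author share
sits in the realistic few-percent range — steep exponents would make every
clean journal look nepotistic. A `round_robin` assignment mode deals
authors cyclically for exact-equality fixtures.

The injected signal is a per-journal *favored author*: with share $p > 0$,
a journal-specific full-named author is placed on exactly
$\operatorname{round}(p \cdot N)$ non-anonymous articles, so measured PPMP
equals the placed share of authored articles exactly whenever no background
author exceeds that count (guaranteed in practice for $p \ge 0.15$ under
the defaults; at $p = 0.05$ the background maximum may legitimately win,
and the truth table records both). Received dates are uniform within the
article's year; accepted dates add a lag drawn log-normally with median 100
days for baseline articles and median 40 for favored ones
($\sigma_{\log} = 0.4$), so the injected per-journal median lag ratio is
0.4. Half the journals report no dates at all
(`journal_reporting_rate = 0.5`), reproducing the non-calculable mechanism;
reporting journals carry dates on 90% of articles. Initials-only recording
is decided per author (10% of the pool) so an identity never splits between
name forms; 0.5% of articles carry an additional collective author.

`recovery_scenario_config()` is the preset used by the recovery tests: 200
journals of which 170 are clean and 10 each carry shares 0.05, 0.15 and
0.30. Injected journals are deliberately rare (15%, with 5% at the strong
share): the screen targets the top 5% of an empirical distribution, and a
corpus where a third of journals were nepotistic would move the percentile
thresholds themselves. Under this preset the test suite verifies that
PPMP is recovered exactly where construction guarantees it, that journals
at $p = 0.30$ are flagged with sensitivity ≥ 0.95, that clean journals are
flagged at ≤ 6% (two indices jointly), and that the lag ratio is recovered
within ±0.1.

What the generator does *not* emulate — so what passing tests do not show
about real data: homonymy and name variants (background identities are
synthetic and unambiguous), authors publishing across journals,
journal-size-dependent authorship patterns, secular trends within the
window, correlated missingness of dates with journal size, and reprinted or
duplicated articles. Recovery results certify the computations, not the
behaviour of the indices under real-world name noise.

## Numerical conventions and degenerate inputs

- A single-author journal has no inequality to measure and the $n/(n-1)$
  correction is undefined; `compute_gini()` returns 0 with a warning.
- Counts of zero or less are rejected; an empty tally is an error for
  `find_most_prolific()`, `compute_ppmp()` and `compute_gini()` (a journal
  with no authored articles has no indices, rather than zeros).
- Sorting ties among equal counts in any stable order leaves the Gini
  unchanged (tested); the formula guards against tiny negative round-off at
  perfect equality by clamping to $[0,1]$.
- The generator and `sample_flagged()` use a locally seeded generator and
  restore the caller's RNG state; identical seeds give byte-identical
  corpora and reports end to end.
- The CSV dialect encodes absent name parts as empty strings, so a file
  round-trip reproduces every field exactly; separator characters inside
  name parts are refused at write time rather than silently corrupted.

## Problem sizes

The default test run exercises the full recovery preset (200 journals,
roughly 160,000 articles and 640,000 author mentions), Gini sweeps of
10,000 random count vectors (lengths 2–500, counts up to 1,000), a
1,000-vector dual-implementation comparison, and smaller fixtures for every
I/O and classification rule; the whole suite completes in about a minute on
one core. These sizes were chosen as the smallest at which the percentile
machinery is meaningful (flag fractions of 4–6% need $\sim 10^3$ journals)
while staying comfortable for routine development.

## Known limitations

Author keys are journal-local and string-based: homonyms merge and name
changes split, biasing both indices in either direction, most strongly for
initials-only identities and large journals. The research-article rule
inherits indexing errors. Lag analysis is conditional on journals reporting
history dates, a self-selected subset. The citation metrics depend entirely
on user-supplied reference and citation tables. None of the indices is
evidence of misconduct on its own; they delimit a tail worth reading
closely.
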