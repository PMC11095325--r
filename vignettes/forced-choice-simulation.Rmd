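---
title: "Simulating forced-choice inventories from Likert ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating forced-choice inventories from Likert ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcsim)
```

## The question the package addresses

Multidimensional forced-choice (MFC) questionnaires ask a respondent to
rank small sets of items drawn from different trait scales — here
triplets, "pick the most and the least typical of you" — instead of
rating each item on a graded (Likert-type) scale.  Because a ranking
carries only relative information, forced choice is often credited with
immunity to rating biases, but also suspected of discarding the
absolute trait levels that Likert ratings capture.  `mfcsim` provides
the machinery to study this question by *simulation*: starting from
single-stimulus ratings (real or synthetic), it constructs the MFC
responses a respondent would have given if their choices were driven by
those ratings, scores the forced-choice data with the simplest possible
(classical, equally weighted) coding, and measures how much of the
original scale-score structure survives.

The key contrast is between **positive-only** item sets, where every
item is keyed in the direction of its trait, and **mixed** sets, where
some items are negatively keyed and their ratings reversed
(`x -> L + 1 - x`).  Positive-only forced choice is ipsative: each
comparison is zero-sum, scores sum to a constant per respondent, and
artifactual negative correlations between scales are unavoidable.
Mixing keys restores absolute-level information — two highly endorsed
items tie, but both then beat their own reversed forms — and the package
quantifies exactly how much.

## The two-item outcome engine

The information content of mixed keying is visible already in a single
pair of items.  With preferences $x, y \in \{1, \dots, L\}$ and both
items present in positive and reversed form, four comparisons are
possible; each win earns $+1$, each loss $-1$, ties $0$, and points won
by an item's reversed form count against it.  The package implements
the resulting outcome sum and its closed form
$2\,[\mathrm{sign}(x - y) + \mathrm{sign}(x + y - L - 1)]$, which the
test suite confirms against brute-force enumeration for
$L = 2, \dots, 10$:

```{r}
pair_outcome(5, 2, mode = "mixed")   # strong vs weak preference
pair_outcome(5, 5, mode = "mixed")   # two top ratings: both gain
pair_outcome(1, 1, mode = "mixed")   # two bottom ratings: both lose
enumerate_outcomes(5, grid = "triangle", mode = "mixed")
```

Over the 15 unordered preference pairs on a 5-level scale the
correlation between an item's rating and its outcome sum is
`r round(rating_outcome_correlation(enumerate_outcomes(5), 1), 2)`;
on the full ordered grid with 100 response levels it is still
`r round(rating_outcome_correlation(enumerate_outcomes(100, "ordered"), 1), 2)`.
A rating-outcome correlation this size is the reason classical scoring
works at all.  For the 100-level figure the package enumerates the full
ordered $L \times L$ grid — the natural population when two item
ratings vary independently; the triangle of unordered pairs gives a
materially lower value, and we treat the ordered grid as the defensible
default.

## The simulation pipeline

A full study is a chain of five modules, each usable on its own.

**1. Likert generation** (`likert_config()`, `simulate_likert()`).
Items are discretized multivariate-normal variables: each scale has a
common factor, scale factors are equicorrelated at `r_between`, and
item loadings are chosen so that two same-scale items correlate
`r_within` on the latent metric.  Ratings are obtained by cutting each
latent variable at `levels - 1` thresholds, by default the equiprobable
normal quantiles, so item means sit at the scale midpoint — the
situation in which forced-choice comparisons are informative, because
no item dominates on popularity alone.  `item_mean_offsets` shift the
thresholds per item to emulate inventories whose items differ in
popularity; large offsets visibly degrade selection ratios (see below).
Discreteness matters: a 5-level discretization attenuates a latent
correlation of .30 to about .27 (factor .896, established by a
one-off 10^6-draw enumeration frozen into the tests), and ties — the
raison d'être of the jitter machinery — only exist with discrete
ratings.  For that reason the generator produces 5-level items by
default rather than continuous scores, with a default sample size of
1000 respondents; recovery correlations are insensitive to `n` at this
scale, and both are exposed in the configuration.

**2. Design construction** (`balanced_design()`).  Scale triples are
cycled in lexicographic order; the placement of scales into set
positions is balanced by a deterministic greedy schedule that assigns
each set's three scales to the positions minimizing the accumulated
position-count imbalance.  Whenever exact balance is arithmetically
attainable (set counts a multiple of `choose(K, 3)` with per-scale
appearance counts divisible by 3) the schedule achieves it exactly, and
it stays within one appearance of perfect balance otherwise.  Position
balance is not cosmetic: the second item of an outcome table
systematically receives lower sums, so unbalanced placement biases
scale means.  Item identities are drawn uniformly *with replacement*
from each scale's pool, and only those draws (plus key draws under
`mixed_random` keying) consume random numbers — two designs with
different seeds share the same scale/position schedule.

**3. Response generation** (`respond()`).  Per respondent and set, slot
keys are applied to the ratings, independent Gaussian noise with mean 0
and SD 0.1 is added, and the jittered values are ranked; the ranking is
coded into three pairwise dummy variables (slot 1 vs 2, 1 vs 3,
2 vs 3).  The noise exists solely to break ties equiprobably — with
5-level ratings ties are common — and any continuous, symmetric,
zero-mean distribution would do; Gaussian is the conventional choice
and the SD is configurable.  Jitter is redrawn at every occurrence of
an item pair, so a respondent facing the same tied comparison twice can
choose differently each time.  Only 6 of the 8 possible dummy patterns
can occur; the two intransitive ones are impossible by construction,
which the tests verify on every generated matrix.

**4. Classical scoring** (`classical_score()`).  Every pairwise
comparison awards the preferred item `+1` times its key to its scale
and the rejected item `-1` times its key — all items weighted equally,
no model fitting.  Raw integer sums are kept (the evaluation
correlates them; any rescaling is monotone and irrelevant).  Tied
comparisons never reach the scorer: the jitter has already resolved
them upstream.  The 0-for-ties convention of the two-item engine above
belongs to that illustrative engine only.

**5. Evaluation** (`recovery_correlations()`, `intercorrelations()`,
`canonical_pillai()`, `selection_ratios()`, `run_replications()`,
`learning_curve()`).  The central diagnostic is the cross-correlation
matrix between forced-choice scores and the original keyed Likert sum
scores: its diagonal holds the same-scale recovery correlations, its
off-diagonal cells the leakage onto other scales.  Canonical
correlation condenses the comparison into the Pillai trace (sum of
squared canonical correlations, at most `K`); the implementation
declares inputs singular beyond a condition-number cutoff of 1e10
rather than silently regularizing, mirroring how degenerate
positive-only designs actually fail.  Selection ratios (share of
pairwise comparisons an item wins) diagnose popularity imbalance.

## A worked run

```{r}
cfg <- likert_config(n_respondents = 1000, n_scales = 5,
                     items_per_scale = 24, levels = 5,
                     r_within = 0.10, r_between = 0)
mix <- run_replications(cfg, n_sets = 80, keying = "mixed_random",
                        n_reps = 10, seed = 1)
pos <- run_replications(cfg, n_sets = 80, keying = "positive_only",
                        n_reps = 10, seed = 2)
mix
pos
```

With mixed keying the recovered scores correlate around .87 with the
original scale scores while other-scale correlations hover near zero.
Positive-only keying recovers less (about .80 here) and, more
tellingly, drags every between-scale correlation to about −.20 — the
ipsative artifact: with `K` scales and truly independent traits the
zero-sum constraint forces an average inter-scale correlation near
$-1/(K-1)$.  The replication harness reports per-replication values and
mean/SD aggregates so such numbers always carry their Monte-Carlo
uncertainty.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `levels` | 5 | Likert response levels; discreteness drives tie frequency |
| `r_within` | .10 | latent same-scale inter-item correlation |
| `r_between` | 0 | equicorrelation of scale factors |
| `n_sets` | — | triplet sets; binary variables = 3 × sets |
| `keying` | — | `positive_only`, `mixed_random`, `factual` |
| `jitter_sd` | 0.1 | SD of the Gaussian tie-breaking noise |
| `n_reps` | 10 | replications aggregated by `run_replications()` |

Recovery grows with `n_sets` (with mixed keying it approaches 1 as the
set count becomes unrealistically large) and with `r_within`; under
positive-only keying it *declines* as `r_between` grows, because
ipsative scores cannot represent a shared positive correlation.  The
learning-curve utility makes the item-economy comparison explicit:
at equal item counts, directly administered Likert subsets recover the
full-inventory scores faster than forced-choice sets built from the
same pool, with mixed sets between the two.  Its `split_half` mode
builds designs from one random half of each scale's items and evaluates
against scores from the other half, so a shortened instrument is judged
on items it never used.

## What the generator does and does not emulate

The synthetic generator reproduces the features that drive
forced-choice behaviour — discrete ratings with controllable within- and
between-scale correlation and controllable item popularity.  It does
not model response styles (acquiescence, extremity, social
desirability), item-specific loading variation, facet structure below
the scale level, or respondent-level choice noise beyond tie-breaking.
Passing recovery tests on synthetic data therefore demonstrates the
information content of the response format itself, not robustness to
those human factors; real inventories can be ingested via
`load_inventory()` (ratings CSV plus item metadata CSV, 0- or 1-based
level coding) and pushed through the identical pipeline.

## Numerical and reproducibility choices

All randomness flows from user-supplied integer seeds; master seeds
derive independent child streams for data generation, item sampling,
and jitter, so any stage can be re-run in isolation.  The design
schedule is deliberately seed-free.  Zero-variance items are excluded
from correlation estimates with a warning rather than producing `NaN`s;
correlation matrices of scores are declared singular past a condition
number of 1e10.  The replicated study sizes used in the package's own
checks (10 replications of 1000 respondents, 5 scales × 24 items, 80
sets) were fixed once from the study design; replication SDs there are
below .01, so these sizes estimate the recovery means to well inside
their reporting precision.

## Limitations

Only triplet blocks are implemented (pairs and quads rest on the same
pairwise logic but are not provided); scoring is classical only — no
Thurstonian SEM or IRT estimation, whose convergence pathologies on
large random designs are well documented; and the balance schedule
optimizes position counts, not the matching of item desirability within
sets, which real inventory construction must also consider.
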