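# mfcsim

Simulation and classical scoring of multidimensional forced-choice
(MFC) personality inventories.

## What it is for

Forced-choice questionnaires make respondents rank small blocks of
items from different trait scales (triplets here: "most typical" and
"least typical" of you) instead of rating each item on a Likert-type
scale.  A long-standing question in psychometrics is how much trait
information such rankings retain: positive-only forced choice is
ipsative (scores are zero-sum within a respondent, forcing artifactual
negative correlations between scales), while blocks that mix positively
and negatively keyed items also encode absolute levels.

`mfcsim` is a toolkit for studying this by simulation, aimed at
psychometricians and survey methodologists.  It

* generates synthetic Likert inventories from a latent factor model
  (`K` scales, configurable within-scale correlation `r_within`,
  between-scale correlation `r_between`, `L`-level discretization,
  per-item popularity offsets);
* builds balanced triplet block designs: scale triples in deterministic
  rotation, positions balanced exactly whenever arithmetically
  possible, items drawn with replacement, keys positive-only, randomly
  mixed, or factual;
* converts ratings to forced-choice responses — key reversal
  `x -> L + 1 - x`, Gaussian tie-breaking jitter (SD 0.1), and binary
  dummy coding of each ranking (slot 1 vs 2, 1 vs 3, 2 vs 3);
* scores the binaries with classical coding: every comparison gives the
  winner `+1` times its key on its scale and the loser `-1` times its
  key, all items weighted equally (no SEM/IRT estimation);
* evaluates recovery of the original structure: cross-correlation
  matrices between MFC and Likert sum scores, inter-scale correlation
  matrices, canonical correlations with the Pillai trace
  (`sum(rho_i^2)`), per-item selection ratios, replicated simulation
  harnesses, and item-count learning curves with a split-half mode.

The information core is the mixed-keying outcome sum of a two-item
comparison, whose closed form is
`2 * (sign(x - y) + sign(x + y - L - 1))`; its correlation with the
underlying rating (.86 on a 5-level scale) is what makes simple
summed scoring recover trait scores.

## Worked example

```r
library(mfcsim)

# a 5-scale, 120-item neutral inventory with nearly independent traits
cfg <- likert_config(n_respondents = 1000, n_scales = 5,
                     items_per_scale = 24, levels = 5,
                     r_within = 0.10, r_between = 0)

mix <- run_replications(cfg, n_sets = 80, keying = "mixed_random",
                        n_reps = 10, seed = 1)
pos <- run_replications(cfg, n_sets = 80, keying = "positive_only",
                        n_reps = 10, seed = 2)
mix
#> MFC recovery simulation: 10 replications, 80 sets, mixed_random keying
#>   mean same-scale recovery r = 0.87 (SD 0.01)
#>   mean other-scale r         = 0.00 (SD 0.02)
pos
#> MFC recovery simulation: 10 replications, 80 sets, positive_only keying
#>   mean same-scale recovery r = 0.80 (SD 0.01)
#>   mean other-scale r         = -0.20 (SD 0.00)
```

With 80 mixed-keyed triplet sets (240 binary variables), classically
summed MFC scores correlate .87 on average with the original Likert
scale scores, and essentially zero with the other scales.  Keying all
items positively recovers less (.80) and pushes every between-scale
correlation to about −.20 even though the generating traits are
independent — the ipsative artifact, approximately `-1/(K-1)`.

The two-item engine behind these numbers:

```r
pair_outcome(c(4, 5, 5, 1), c(2, 2, 5, 1), mode = "mixed")
#>   x y sum1 sum2
#> 1 4 2    2   -2
#> 2 5 2    4    0
#> 3 5 5    2    2
#> 4 1 1   -2   -2
```

Note rows 3–4: two top ratings both gain, two bottom ratings both
lose — the level information a positive-only comparison throws away.

Real inventories enter through CSV (`load_inventory(ratings_csv,
metadata_csv)`, with 0- or 1-based level coding); a tiny synthetic
example lives in `inst/extdata/`.  A command-line wrapper for full
pipeline runs is in `inst/cli/fcsim.R`, and `run_pipeline()` writes all
artifacts (design sheet, binary matrix, scores, evaluation tables) plus
a seed manifest for byte-identical reruns.

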