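# morphorates

Tempo and mode of morphological evolution in fossil clades, from discrete
character matrices and samples of time-calibrated (tip-dated) trees.

Palaeobiologists studying a clade's long-term diversification ask three
linked questions: *when* did rates of anatomical change speed up or slow
down, *how much* morphological variety (disparity) existed at each time,
and how did disparity track taxonomic diversity.  `morphorates`
implements the full analysis chain for these questions on discrete
morphological data, together with a synthetic fossil-clade generator
that makes every stage verifiable by parameter recovery.

## What it computes

**Rates.**  For each tree in a posterior-like sample, ancestral states of
every informative character are reconstructed by maximum likelihood under
the symmetric Mk model (marginal reconstruction; per-character rate fitted
by 1-D ML).  The rate of a branch is

```
rate = changes / (time x proportion of comparable characters)
```

in expected changes per character per Myr, where a character is
*comparable* on a branch when both endpoint states are determinate.
Branches are assigned to chronostratigraphic bins, and each bin is tested
against the pooled remainder with a Poisson likelihood-ratio test
(statistic 2(lnL1 − lnL0), chi-squared with 1 df), with Benjamini-Hochberg
correction across bins at alpha = 0.01.  A bin is classified `HIGH` or
`LOW` when more than 55% of the tree sample agrees on a significant
deviation; otherwise `BACKGROUND`.  Secular trends are summarised by
Spearman's rank correlation of the per-bin rate series against time.

**Disparity and morphospace.**  Pairwise distances use the Gower
coefficient: the proportion of characters codable in both taxa whose
states differ,

```
d_ij = sum_k (1 - S_ijk) delta_ijk / sum_k delta_ijk
```

with delta_ijk = 1 when character k is scored in both i and j.
Disparity of a taxon set is the mean squared pairwise distance, with
1,000-replicate taxon bootstraps for confidence intervals.  Principal
coordinates analysis embeds the distance matrix into a morphospace
(optional additive-constant correction), Brownian-motion ML ancestral
scores give phylomorphospace node positions, and ordination axes can be
correlated against ecological traits (Spearman).

**Diversity dynamics.**  Range-through counts from first/last appearance
bins, Monte-Carlo (bootstrap) intervals, and the diversity-disparity
trajectory: each bin is placed at (range-standardized log diversity,
range-standardized disparity); under constant-rate evolution the
trajectory follows the 1:1 diagonal, and bins are classified
above/on/below the line by a paired bootstrap of the deviation.

**Synthetic clades.**  A constant-rate birth-death process (fossil tips
at extinction ages, survival-conditioned, tip-count window) with
epoch-heterogeneous Mk character evolution: the instantaneous change rate
is `r0 x multiplier(bin)`, sliced exactly at bin boundaries, and every
realized change is recorded in a truth ledger.  Missing data are injected
at a target rate and posterior-like tree samples are produced by
truncated-Gaussian node-age jitter.  Presets emulate a Palaeozoic-scale
clade (origin 453 Ma, 13 bins to 254 Ma, ~60-100 taxa, 92 characters
with 2-5 states, ~20% missing cells, one late bin at multiplier 2.5) and
a scaled-down variant for fast simulation studies.

## Worked example

Simulate a scaled-down fossil clade with a planted rate spike in bin 6,
then run the rate analysis over its 25-tree posterior-like sample:

```r
library(morphorates)

s <- scaled_scenario()                     # 8 bins, 453-254 Ma, spike x2.5 in bin 6
clade <- simulate_clade(s, n_trees = 25, age_jitter_sd = 2, seed = 42)
clade$tree
#> time_tree: 27 tips, root age 447.33 Ma, youngest tip 254.00 Ma
clade$matrix
#> character_matrix: 27 taxa x 40 characters (35 informative)
#> missing cells: 19.5% overall

res <- rate_analysis(clade$trees, clade$matrix, s$timescale)
res$summary[, c("bin", "mean_rate", "lo95", "hi95", "class")]
#>     bin mean_rate      lo95     hi95      class
#> 1 bin01 0.0001585 0.0000000 0.001366 BACKGROUND
#> 2 bin02 0.0023585 0.0018060 0.002673 BACKGROUND
#> 3 bin03 0.0013961 0.0008548 0.001850 BACKGROUND
#> 4 bin04 0.0022466 0.0019954 0.002613 BACKGROUND
#> 5 bin05 0.0025780 0.0024139 0.002746 BACKGROUND
#> 6 bin06 0.0040790 0.0038293 0.004398 BACKGROUND
#> 7 bin07 0.0032249 0.0026885 0.003713 BACKGROUND
#> 8 bin08 0.0032850 0.0030231 0.003589 BACKGROUND
```

Rates are changes per character per Myr; the planted bin-6 spike is
clearly the rate maximum (about 1.6x the background mean here), though at
this clade size the likelihood-ratio classification stays `BACKGROUND` -
see the methods vignette for the power analysis.  The morphospace side:

```r
g <- gower_distance(clade$matrix)
pco(g)
#> pco_ordination: 27 taxa, 14 positive axes (correction: none)
#> axes 1-2 variance: 56.99%
```

`run_pipeline()` chains every stage (simulate or load, rates, disparity,
ordination, diversity, trajectory) from a single seeded configuration
and writes TSV tables plus a `summary.json` tagged with the config hash.

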