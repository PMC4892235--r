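---
title: "Auditing morphological character coverage across a phylogeny: methods"
author: "morphaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing morphological character coverage across a phylogeny: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphaudit)
```

## What the package measures

Combining living and fossil taxa in one phylogeny (the total-evidence
approach) needs discrete morphological characters coded for *living* taxa,
so that fossils — which have only morphology — can be linked to them. This
package audits that resource along two axes.

**Coverage.** For a clade and a taxonomic level (species, genus, family),
coverage is simply `n_scored / n_total`: the proportion of taxa at that
level with at least one coded character, against the reference taxonomy.
A clade is classed *low* below 25% and *high* above 75%, both boundaries
strict (exactly 25% or 75% is *medium*). The low threshold flags clades
where fossil placement is likely unreliable; the high threshold corresponds
to the amount of data reported (in simulation studies of total-evidence
inference) to be needed before missing data stop distorting topology.

**Dispersion.** Coverage alone does not determine the risk: 25% of species
scored evenly across a clade constrains fossil placement far better than
25% concentrated in one subclade. Dispersion of the scored set is measured
with two community-phylogenetics statistics computed on the patristic
distance matrix (sum of branch lengths along the tip-to-tip path):

- **MPD**, the mean distance over all unordered pairs of scored tips, is
  sensitive to structure across the whole tree;
- **MNTD**, the mean distance from each scored tip to its nearest *other
  scored* tip, is sensitive to structure near the tips.

Each observed value is compared with a randomization null: `reps` (default
1000) draws of the same number of tips, uniform without replacement from the
clade's tree, independent across replicates. The standardized effect sizes

$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}
{\mathrm{sd}(\mathrm{MPD}_{null})},\qquad
\mathrm{NTI} = -\frac{\mathrm{MNTD}_{obs} - \overline{\mathrm{MNTD}}_{null}}
{\mathrm{sd}(\mathrm{MNTD}_{null})}$$

are signed so that **positive = clustered** (observed distances smaller than
expected), **negative = overdispersed**. The null standard deviation uses
the sample (n−1) denominator, matching the conventional implementations of
these indices.

## Significance

Published uses of these indices flag significance without always stating the
test construction, so the package adopts the standard two-tailed rank-based
randomization p-value with +1 continuity correction: with $r$ null values
$\le$ the observed one, $q = (r+1)/(reps+1)$ and
$p = 2\min(q,\; 1-q+\tfrac{1}{reps+1})$, capped at 1. This is symmetric in
the clustering and overdispersion directions, never exactly 0, and at 1000
replicates its smallest attainable value is 2/1001. Ties are counted as "at
least as extreme", with a relative tolerance of $10^{-6}$ so that writing a
tree to Newick (decimal branch lengths) and reading it back cannot flip a
tie into a strict inequality. Reports mark `*` for p < 0.05 and `**` for
p < 0.01; no multiple-testing correction is applied across clades, matching
the per-clade reporting convention of this literature.

## Degenerate cases

Indices are reported as `NA`, never $\pm\infty$, when the focal set has
fewer than 2 members in the sampling pool, when it exhausts the pool (the
null is then a point mass), or whenever the null standard deviation is zero;
the `note` field and the report row record the reason. Polytomies and
zero-length branches are accepted as-is: patristic distances are well
defined on both, and only the minimum enters MNTD so nearest-neighbour ties
need no tie-break. Root placement is irrelevant because patristic distance
is a property of the unrooted weighted tree.

## Pipeline design choices

Several aspects of a clade-by-clade audit are genuinely open; the package's
choices are:

- **Sampling pool.** Order-level tests draw the null from the order-pruned
  tree; the class-wide rows use the full tree.
- **Higher-level trees.** A species-level phylogeny does not directly give
  genus or family distances. The package prunes each clade tree to one
  exemplar tip per higher taxon — the alphabetically first species present —
  and relabels it with the higher-taxon name. Under a clock this is an
  unbiased stand-in for the taxon's placement; for very uneven genera the
  exemplar choice slightly perturbs within-genus depth, which the
  randomization null sees equally, so the SES is not systematically shifted.
- **OTUs above species rank.** Source matrices contain OTUs coded at genus
  or family rank. A genus-level OTU certifies its genus (and family) as
  scored, but no particular species; a family-level OTU only its family.
- **Name matching.** All names pass through one canonicalization: trim,
  underscores to spaces, quotes dropped, trailing author/year or rank-suffix
  tokens removed by a configurable regex, first word capitalized. This is a
  declared simplification of full synonym resolution: names that differ by
  true synonymy (not formatting) will not be matched. Unresolvable scored
  names are dropped with a logged audit trail rather than erroring, so a
  single stray fossil name cannot abort an audit.
- **Reproducibility.** One top-level seed; every (clade, level, metric)
  analysis derives its own substream from it, so adding or removing one
  clade never shifts another clade's draws, and null draws are made over the
  lexicographically sorted tip pool so results do not depend on the storage
  order of the tree. Report TSVs (proportions to 4 decimals, indices to 2,
  p-values to 4) are byte-reproducible for a fixed configuration.

## The synthetic-data generator

The generator exists so that every stage — parsing, pruning, distances,
nulls, SES, reporting — can be validated end to end with known truth.

- `simulate_yule(n_tips, birth_rate, seed)`: pure-birth (Yule) tree
  conditioned on the number of extant tips, hence ultrametric (clock-like).
  Pure birth rather than birth–death because it is the simplest clock-like
  stand-in and the dispersion statistics are calibrated against the same
  tree they are computed on, so the extra realism of extinction would not
  change what the tests demonstrate.
- `make_taxonomy(tree, genus_size_mean, family_size_mean)`: partitions the
  cladewise tip order into contiguous genera of near-equal size
  (`round(n/genus_size_mean)` of them), nests genera into families the same
  way, in a single order. The partition is deterministic given the tree:
  a random-size scheme cannot guarantee small worked examples ("4 tips,
  genus size 2, therefore 2 genera") and determinism costs nothing for the
  generator's purpose.
- Samplers at a chosen coverage (scored-set size `round(coverage × n)`,
  minimum 2): `sample_random` draws uniformly; `sample_clustered` takes a
  uniformly chosen centre tip plus its n−1 nearest neighbours by patristic
  distance (a neighbourhood, rather than a clade, so any target size is
  achievable exactly); `sample_overdispersed` is the deterministic greedy
  maximin — start from the most distant pair, repeatedly add the tip whose
  minimum distance to the chosen set is largest, ties broken
  lexicographically.

Default scenario conditions are 64 tips and coverage 0.25 — large enough
that a 16-tip focal set has a stable null, small enough that hundreds of
replicate datasets run in seconds — with mean genus size 4 and mean family
size 4 genera.

What the generator does *not* emulate: real supertrees' polytomies and soft
topology (trees here are binary), heterogeneous clade sizes and taxonomies,
synonymy noise in names, and any correlation between being scored and traits
such as body size or museum representation. Passing the recovery tests
therefore shows the statistics behave correctly for their inputs, not that
real scored sets are unbiased samples.

## Calibration and recovery (what the test suite computes)

- **Oracle equivalence.** Patristic matrices match a per-pair path-walk
  oracle; MPD/MNTD match explicit double loops; Monte-Carlo null means and
  standard deviations match full subset enumeration (all $\binom{T}{n}$
  subsets on trees of up to 10 tips) within 3 standard errors, the standard
  error of the null sd being derived from the exhaustive distribution's
  fourth moment.
- **Null calibration.** Over 500 random-regime datasets (64 tips, 16
  scored, 1000-draw nulls) the two-tailed p < 0.05 rate lies in
  [0.03, 0.07] for both indices and mean NRI/NTI are within 3 standard
  errors of 0.
- **Regime recovery.** Over 200 trees, mean NTI separates the three
  regimes in the right order (clustered > random > overdispersed) with gaps
  of at least 2 pooled standard errors; in a typical run the means are
  roughly +3.0, 0.0 and −3.7 and ~99% of clustered datasets give NTI > 0.

These problem sizes (500 and 200 replicate datasets, 1000-draw nulls) are
the package's chosen calibration conditions; they give binomial/standard
errors narrow enough for the stated bands while keeping a full suite run
around a minute.

## The bundled mammalian census and boundary sensitivity

`mammal_census()` ships published per-order counts (28 orders plus
class-wide totals at three levels) of living mammalian OTUs with coded
anatomical characters, so the coverage arithmetic is exactly reproducible:
class-wide species coverage is 847/5017 ≈ 16.9% (low), and with the strict
boundaries the per-order tallies are 10 low / 7 high at species level,
1 low / 16 high at genus level, and 0 low / 26 high at family level. These
tallies are sensitive to boundary convention in three places: one order
sits at exactly 1/4 scored species (medium under a strict "< 25%" reading,
low if the boundary is included), one at 97/128 ≈ 75.8% scored genera, and
one at 4/5 = 80% in both its genus and family rows. Published summaries of
the same counts that report 11/15/25 must have treated at least one of
these boundary-adjacent cases differently — no single threshold convention
yields all three of those tallies from these counts, which is why the
package fixes the literal strict rule and documents the discrepancy rather
than special-casing any clade.

## Known limitations

- The exemplar-tip construction for genus/family-level trees is one of
  several defensible choices (alternatives: genus-level MRCA trees, or
  averaging over exemplars); results at higher levels should be read with
  that in mind.
- The name normalizer handles formatting, not synonymy.
- Only presence of a coded taxon is audited; the number or kind of
  characters (hard vs soft tissue) is out of scope, so coverage here is an
  upper bound on usable overlap with fossils.
- Abundance-weighted index variants and alternative null models (tip-label
  shuffling restricted to subclades, independent swap) are not implemented;
  the uniform-draw null is the appropriate one for the question "are the
  scored taxa a random subset of the clade".
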