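# morphaudit

Phylogenetic audit of morphological character coverage.

## The problem

Total-evidence phylogenetics places fossils among living species by combining
molecular data (living taxa only) with discrete morphological characters
shared by living and fossil taxa. That only works where living taxa actually
*have* coded anatomical characters in accessible matrices. In practice
morphological coding effort concentrates on fossils, so coverage of living
taxa can be low — and if the taxa that are scored sit clumped in a few clades,
fossils will be attracted to the well-coded clades regardless of where they
belong.

`morphaudit` quantifies both sides of this problem for any clade with a
reference phylogeny, a taxonomy and a set of "scored" OTUs (taxa with at
least one coded character):

1. **Coverage**: for every clade at species, genus and family level, the
   proportion of taxa scored, classed *low* (< 25%), *medium*, or *high*
   (> 75%). Both boundaries are strict.
2. **Dispersion**: are the scored taxa randomly placed on the phylogeny,
   clustered, or overdispersed? Measured with the two standard
   community-phylogenetics indices,

   - NRI (net relatedness index), from the mean pairwise patristic distance
     MPD of the n scored taxa:
     `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`
   - NTI (nearest taxon index), identically built from MNTD, the mean
     distance of each scored taxon to its nearest scored neighbour.

   The null is 1000 draws of n tips taken uniformly without replacement from
   the clade's tree. Positive values mean clustering, negative
   overdispersion; significance comes from a two-tailed rank-based
   randomization p-value with +1 continuity correction (`*` p < 0.05,
   `**` p < 0.01).

A seed-deterministic synthetic-data generator (pure-birth trees, nested
taxonomies, and random / clustered / overdispersed tip samplers) lets the
whole pipeline be calibrated and tested without any external data. A census
of published per-order counts for mammals (847/5017 species scored
class-wide) is bundled so the coverage arithmetic can be reproduced exactly.

## Worked example

```r
library(morphaudit)

# a 64-tip clock-like tree in which 16 species (25%) are scored,
# deliberately clustered around one centre tip
sc <- simulate_scenario(n_tips = 64, coverage = 0.25,
                        regime = "clustered", seed = 42)

report <- run_audit(audit_config(sc$tree, sc$taxonomy, sc$scored,
                                 reps = 1000, seed = 1))
as.data.frame(report)[, c(1:6, 11:12)]
#>      clade   level n_scored n_total proportion coverage_class  nri  nti
#> 1      All species       16      64      0.250         medium 7.38 3.97
#> 2      All   genus        5      16      0.312         medium 3.41 2.56
#> 3      All  family        2       4      0.500         medium 1.35 1.38
#> 4 Simulata species       16      64      0.250         medium 6.64 4.35
#> 5 Simulata   genus        5      16      0.312         medium 3.57 2.55
#> 6 Simulata  family        2       4      0.500         medium 1.39 1.34
```

Coverage is medium everywhere (25–50% of taxa scored), and the clustering is
detected: at species level NTI is strongly positive (3.97, randomization
p = 0.002), weaker after collapsing to genera (2.56) and undetectable with
only 2 of 4 families scored — exactly the expected dilution of signal at
higher taxonomic levels. A single test reads:

```r
dispersion_test(sc$tree, sc$scored, reps = 1000, seed = 1)
#> Phylogenetic dispersion test: n = 16 of 64 tips, reps = 1000
#>   MPD  = 2.64  NRI = 7.42  p = 0.00 **
#>   MNTD = 0.67  NTI = 3.95  p = 0.00 **
```

The bundled mammalian census reproduces the published coverage arithmetic:

```r
cc <- coverage_from_counts(mammal_census())
summarize_counts(cc, class_label = "Mammalia")
#>     level n_low n_medium n_high n_clades
#> 1 species    10       11      7       28
#> 2   genus     1       11     16       28
#> 3  family     0        2     26       28
subset(cc, clade == "Mammalia")
#>      clade   level n_scored n_total proportion coverage_class
#> 1 Mammalia  family      129     148      0.872           high
#> 2 Mammalia   genus      517    1186      0.436         medium
#> 3 Mammalia species      847    5017      0.169            low
```

Only 16.9% of mammal species have any coded anatomical characters (class-wide
coverage is *low*), while 26 of 28 orders are *high* at family level: the
data shortage is a species-level problem. Note the boundary sensitivity
discussed in the methods vignette: with strict thresholds an order sitting at
exactly 25% (1/4 species) is *medium*, so tallies can differ by one from
summaries that treat the boundary as low.

## Command line

```sh
inst/scripts/audit simulate --tips 64 --coverage 0.25 --regime clustered --seed 5 --outdir demo
inst/scripts/audit run --tree demo/tree.nwk --taxonomy demo/taxonomy.csv \
    --scored demo/scored_species.txt --reps 1000 --seed 9 --out report.tsv \
    --annotate annotated.nwk --null-audit nulls.json
```

`report.tsv` is byte-reproducible for a fixed seed; `annotated.nwk` marks
every scored tip with an NHX `scored=1` tag for figure drawing.

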