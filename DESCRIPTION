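Package: morphaudit
Title: Phylogenetic Audit of Morphological Character Coverage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audits the availability of coded morphological (anatomical)
    characters across a phylogeny. Computes per-clade coverage statistics at
    species, genus and family level with a low/medium/high classification,
    and community-phylogenetics dispersion tests: net relatedness index (NRI)
    and nearest taxon index (NTI), the negated standardized effect sizes of
    mean pairwise distance (MPD) and mean nearest taxon distance (MNTD)
    against a randomization null of repeated uniform tip draws, with
    two-tailed randomization p-values. Classifies scored taxa as randomly
    distributed, phylogenetically clustered, or overdispersed. Includes a
    seed-deterministic synthetic-data generator (pure-birth trees, nested
    taxonomies, random/clustered/overdispersed tip samplers) so the whole
    pipeline can be validated end to end, plus a bundled census of
    morphological data availability for mammalian orders.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Encoding: UTF-8
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
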