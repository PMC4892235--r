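# Synthetic data: clock-like trees, nested taxonomies and scored-tip sets
# drawn under known dispersion regimes, so every pipeline stage can be
# exercised and calibrated without external data.

#' Simulate a pure-birth (Yule) tree
#'
#' Ultrametric tree grown under a constant speciation rate with no
#' extinction, conditioned on the number of extant tips; tips are labelled
#' `sp0001`, `sp0002`, ... Reproducible given `seed`.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate (per lineage per unit time; sets the
#'   depth scale only, the topology distribution is rate-free).
#' @param seed integer seed.
#' @return a validated ultrametric `phylo`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 3) {
    stop("n_tips must be a single number >= 3")
  }
  if (!is.numeric(birth_rate) || !is.finite(birth_rate) || birth_rate <= 0) {
    stop("birth_rate must be a positive finite number")
  }
  tree <- with_seed(seed, ape::rphylo(as.integer(n_tips), birth = birth_rate,
                                      death = 0))
  tree$tip.label <- sprintf("sp%04d", seq_len(length(tree$tip.label)))
  validate_phylo(tree)
  tree
}

#' Draw a uniform random tip sample
#'
#' @param tips character vector of tip labels (the pool).
#' @param n sample size, `2 <= n <= length(tips)`.
#' @param seed integer seed.
#' @return sorted character vector of `n` distinct labels.
#' @export
sample_random <- function(tips, n, seed = NULL) {
  tips <- sort(unique(as.character(tips)))
  if (n < 2 || n > length(tips)) {
    stop("n must satisfy 2 <= n <= ", length(tips), ", got ", n)
  }
  sort(with_seed(seed, sample(tips, as.integer(n))))
}

#' Draw a phylogenetically clustered tip sample
#'
#' Picks one centre tip uniformly at random, then returns it together with
#' its `n - 1` nearest tips by patristic distance (ties broken by
#' lexicographic label order). Emulates the worst case for fossil placement:
#' scored taxa concentrated in one neighbourhood of the tree.
#'
#' @param tree a `phylo`.
#' @param n sample size, `2 <= n < Ntip(tree)`.
#' @param seed integer seed (controls the centre tip only).
#' @param dm optional precomputed [patristic_matrix()].
#' @return sorted character vector; the centre tip is in attribute
#'   `"centre"` and always belongs to the sample.
#' @export
sample_clustered <- function(tree, n, seed = NULL, dm = NULL) {
  if (is.null(dm)) dm <- patristic_matrix(tree)
  labels <- sort(rownames(dm))
  if (n < 2 || n >= length(labels)) {
    stop("n must satisfy 2 <= n < ", length(labels), ", got ", n)
  }
  centre <- with_seed(seed, sample(labels, 1L))
  others <- setdiff(labels, centre)
  nearest <- others[order(dm[centre, others], others)][seq_len(n - 1L)]
  out <- sort(c(centre, nearest))
  attr(out, "centre") <- centre
  out
}

#' Draw a phylogenetically overdispersed tip sample
#'
#' Deterministic greedy maximin: start from the pair of tips at maximal
#' patristic distance, then repeatedly add the tip whose minimum distance to
#' the chosen set is largest (all ties broken lexicographically). Emulates
#' the ideal scenario of scored taxa spread evenly across the tree.
#'
#' @inheritParams sample_clustered
#' @param seed accepted for interface symmetry with the other samplers; the
#'   algorithm is deterministic and ignores it.
#' @return sorted character vector of `n` labels.
#' @export
sample_overdispersed <- function(tree, n, seed = NULL, dm = NULL) {
  if (is.null(dm)) dm <- patristic_matrix(tree)
  labels <- sort(rownames(dm))
  if (n < 2 || n >= length(labels)) {
    stop("n must satisfy 2 <= n < ", length(labels), ", got ", n)
  }
  D <- dm[labels, labels]
  hits <- which(D == max(D), arr.ind = TRUE)
  pairs <- unique(t(apply(hits, 1L, sort)))
  keys <- paste(labels[pairs[, 1]], labels[pairs[, 2]])
  chosen <- labels[sort(pairs[order(keys)[1], ])]
  while (length(chosen) < n) {
    rest <- setdiff(labels, chosen)
    mind <- apply(D[rest, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, rest[which.max(mind)])  # rest is sorted: ties -> lexicographic
  }
  sort(chosen)
}

# Tip labels in cladewise traversal order, so contiguous runs of tips are
# (unions of) clades.
tips_cladewise <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  child <- tr$edge[, 2]
  tr$tip.label[child[child <= length(tr$tip.label)]]
}

#' Generate a nested taxonomy over a tree's tips
#'
#' Partitions the cladewise tip order into contiguous genera of near-equal
#' size (count `round(n_tips / genus_size_mean)`), nests genera into
#' families the same way, and places everything in a single order. Every tip
#' appears exactly once; each genus maps to exactly one family. The
#' partition is deterministic given the tree; `seed` is reserved.
#'
#' @param tree a `phylo`.
#' @param genus_size_mean target mean species per genus.
#' @param family_size_mean target mean genera per family.
#' @param seed reserved; the partition is deterministic.
#' @param order_name label for the single order.
#' @return data.frame with columns species, genus, family, order.
#' @export
make_taxonomy <- function(tree, genus_size_mean = 4, family_size_mean = 4,
                          seed = NULL, order_name = "Simulata") {
  stopifnot(genus_size_mean >= 1, family_size_mean >= 1)
  tips <- tips_cladewise(tree)
  n <- length(tips)
  n_gen <- max(1L, as.integer(round(n / genus_size_mean)))
  gidx <- chunk_index(n, n_gen)
  n_fam <- max(1L, as.integer(round(n_gen / family_size_mean)))
  fam_of_gen <- chunk_index(n_gen, n_fam)
  tax <- data.frame(species = tips,
                    genus = sprintf("genus%03d", gidx),
                    family = sprintf("family%02d", fam_of_gen[gidx]),
                    order = order_name, stringsAsFactors = FALSE)
  validate_taxonomy(tax)
  tax
}

# n items into k contiguous chunks with sizes differing by at most 1
chunk_index <- function(n, k) sort(rep_len(seq_len(k), n))

#' Simulate a complete audit scenario
#'
#' Bundles a Yule tree, a nested taxonomy and a scored-species set drawn
#' under one of three regimes — `"random"` (uniform), `"clustered"`
#' (nearest-neighbourhood of a random centre tip) or `"overdispersed"`
#' (greedy maximin) — at a chosen coverage proportion. All randomness is
#' derived from `seed` through independent substreams.
#'
#' @param n_tips tips in the tree (default 64).
#' @param coverage proportion of tips scored, in (0, 1) (default 0.25);
#'   the scored-set size is `max(2, round(coverage * n_tips))`.
#' @param regime sampling regime.
#' @param birth_rate speciation rate for the tree.
#' @param genus_size_mean,family_size_mean taxonomy shape (see
#'   [make_taxonomy()]).
#' @param seed integer seed.
#' @return object of class `audit_scenario`: list with `tree`, `taxonomy`,
#'   `scored`, `dm` (patristic matrix) and `params`.
#' @export
simulate_scenario <- function(n_tips = 64, coverage = 0.25,
                              regime = c("random", "clustered", "overdispersed"),
                              birth_rate = 1,
                              genus_size_mean = 4, family_size_mean = 4,
                              seed = NULL) {
  regime <- match.arg(regime)
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1) {
    stop("coverage must be in (0, 1)")
  }
  n_scored <- max(2L, as.integer(round(coverage * n_tips)))
  if (n_scored >= n_tips) stop("coverage too high: scored set would be the whole tree")
  tree <- simulate_yule(n_tips, birth_rate, derive_seed(seed, "tree"))
  dm <- patristic_matrix(tree)
  scored <- switch(regime,
    random = sample_random(tree$tip.label, n_scored, derive_seed(seed, "sample")),
    clustered = sample_clustered(tree, n_scored, derive_seed(seed, "sample"), dm = dm),
    overdispersed = sample_overdispersed(tree, n_scored, dm = dm))
  taxonomy <- make_taxonomy(tree, genus_size_mean, family_size_mean)
  structure(list(tree = tree, taxonomy = taxonomy,
                 scored = as.character(scored), dm = dm,
                 params = list(n_tips = as.integer(n_tips), coverage = coverage,
                               regime = regime, birth_rate = birth_rate,
                               genus_size_mean = genus_size_mean,
                               family_size_mean = family_size_mean,
                               seed = seed)),
            class = "audit_scenario")
}

#' @export
print.audit_scenario <- function(x, ...) {
  p <- x$params
  cat("Audit scenario:", p$n_tips, "tips,", length(x$scored),
      "scored (", p$regime, "regime, coverage", p$coverage, ")\n")
  invisible(x)
}

#' Write an audit scenario to disk
#'
#' One directory per scenario: `tree.nwk` (Newick), `taxonomy.csv`,
#' `scored_species.txt` (one name per line) and `params.json` — exactly the
#' formats the pipeline consumes.
#'
#' @param scenario an [simulate_scenario()] object.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "audit_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             taxonomy = file.path(dir, "taxonomy.csv"),
             scored = file.path(dir, "scored_species.txt"),
             params = file.path(dir, "params.json"))
  ape::write.tree(scenario$tree, file = paths[["tree"]])
  utils::write.csv(scenario$taxonomy, paths[["taxonomy"]], row.names = FALSE,
                   quote = FALSE)
  writeLines(scenario$scored, paths[["scored"]])
  jsonlite::write_json(scenario$params, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
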