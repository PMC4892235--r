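# Shared fixtures and independent oracles. The oracles deliberately use
# different machinery from the implementation: per-pair node paths instead of
# ape::dist.nodes, explicit double loops instead of matrix algebra, and full
# subset enumeration instead of Monte-Carlo draws.

t4_newick <- "((A:1,B:1):1,(C:1,D:1):1);"
t4 <- function() read_newick(t4_newick)
star3 <- function() read_newick("(A:1,B:2,C:3);")

# brute-force patristic distances: walk the node path of every tip pair and
# sum the branch lengths of consecutive node pairs
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  elen <- rep(NA_real_, max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  is_edge <- function(a, b) any(tree$edge[, 1] == a & tree$edge[, 2] == b)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- ape::nodepath(tree, i, j)
      s <- 0
      for (k in seq_len(length(p) - 1)) {
        a <- p[k]; b <- p[k + 1]
        s <- s + elen[if (is_edge(a, b)) b else a]
      }
      d[i, j] <- d[j, i] <- s
    }
  }
  d
}

oracle_mpd <- function(dm, s) {
  tot <- 0; k <- 0
  for (i in seq_len(length(s) - 1)) {
    for (j in (i + 1):length(s)) {
      tot <- tot + dm[s[i], s[j]]; k <- k + 1
    }
  }
  tot / k
}

oracle_mntd <- function(dm, s) {
  mins <- vapply(seq_along(s), function(i) {
    min(vapply(setdiff(seq_along(s), i), function(j) dm[s[i], s[j]], numeric(1)))
  }, numeric(1))
  mean(mins)
}

# exact null distribution: the metric over every one of the C(T, n) subsets
oracle_exhaustive_null <- function(dm, n, metric) {
  combs <- utils::combn(rownames(dm), n)
  f <- if (metric == "mpd") oracle_mpd else oracle_mntd
  apply(combs, 2L, function(s) f(dm, s))
}

# cherries: internal nodes whose children are exactly two tips
count_cherries <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sum(vapply(kids, function(k) length(k) == 2 && all(k <= ntip), logical(1)))
}

# the frozen six-value exhaustive MPD null of the 4-tip balanced tree
t4_null_n2 <- function() {
  v <- c(2, 2, 4, 4, 4, 4)
  structure(list(metric = "mpd", values = v, reps = length(v), n = 2L,
                 mean = mean(v), sd = stats::sd(v), seed = NULL),
            class = "null_distribution")
}

# two-order taxonomy over one tree, for multi-clade pipeline tests
two_order_taxonomy <- function(tree) {
  tax <- make_taxonomy(tree, genus_size_mean = 4, family_size_mean = 2)
  fams <- sort(unique(tax$family))
  first <- fams[seq_len(ceiling(length(fams) / 2))]
  tax$order <- ifelse(tax$family %in% first, "Ordalpha", "Ordbeta")
  tax
}
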