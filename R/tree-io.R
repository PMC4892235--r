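# Tree input, validation, pruning and patristic distances.
#
# Parsing itself is delegated to ape; this layer enforces the invariants the
# downstream statistics rely on (unique non-empty tip labels, non-negative
# branch lengths, >= 2 tips) and applies the underscore <-> space label
# convention so tree tips, taxonomy rows and matrix OTU names can be matched.

#' Validate a phylogeny
#'
#' Checks the invariants every tree used by this package must satisfy:
#' a `phylo` object with at least `min_tips` unique, non-empty tip labels and
#' no negative branch lengths. Polytomies and zero-length branches are
#' accepted: patristic distances are well defined on both.
#'
#' @param tree an [ape::read.tree()]-style `phylo` object.
#' @param min_tips minimum number of tips required (default 2).
#' @return the tree, invisibly; errors describe the offending labels/edges.
#' @export
validate_phylo <- function(tree, min_tips = 2L) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tips <- tree$tip.label
  if (length(tips) < min_tips) {
    stop("tree has ", length(tips), " tip(s); at least ", min_tips, " required")
  }
  if (anyNA(tips) || any(!nzchar(trimws(tips)))) stop("empty tip label(s) found")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (!is.null(tree$edge.length)) {
    bad <- which(tree$edge.length < 0)
    if (length(bad)) {
      stop("negative branch length on edge(s) ", paste(bad, collapse = ", "),
           " (first value: ", tree$edge.length[bad[1]], ")")
    }
  }
  invisible(tree)
}

#' Read a Newick tree
#'
#' Parses a Newick string or file and validates it. Quoted labels are
#' unquoted by the parser; underscores in labels are converted to single
#' spaces by default (the usual Newick dialect, in which an unquoted
#' underscore stands for a space).
#'
#' @param x a Newick string (must contain `(` and `;`) or a file path.
#' @param underscores_to_spaces convert `_` to a space in tip labels
#'   (default `TRUE`).
#' @param missing_lengths `"error"` (default) to reject trees without branch
#'   lengths, `"zero"` to substitute 0 on every edge.
#' @param min_tips minimum tips accepted (default 2).
#' @return a validated `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' @export
read_newick <- function(x, underscores_to_spaces = TRUE,
                        missing_lengths = c("error", "zero"),
                        min_tips = 2L) {
  missing_lengths <- match.arg(missing_lengths)
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  text <- if (grepl("(", x, fixed = TRUE) && grepl(";", x, fixed = TRUE)) {
    x
  } else {
    if (!file.exists(x)) stop("not a Newick string and file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  n_open <- nchar(gsub("[^(]", "", text))
  n_close <- nchar(gsub("[^)]", "", text))
  if (n_open != n_close) {
    stop("newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')')")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || inherits(tree, "multiPhylo")) {
    if (inherits(tree, "multiPhylo")) stop("expected a single tree, got ", length(tree))
    stop("newick parse error: could not parse input")
  }
  if (underscores_to_spaces) tree$tip.label <- gsub("_", " ", tree$tip.label)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "zero") {
      tree$edge.length <- rep(0, nrow(tree$edge))
    } else {
      stop("tree has no branch lengths (set missing_lengths = \"zero\" to substitute 0)")
    }
  }
  validate_phylo(tree, min_tips = min_tips)
  tree
}

#' Read trees from a NEXUS TREES block
#'
#' Thin wrapper around [ape::read.nexus()] applying the same validation and
#' label conventions as [read_newick()].
#'
#' @inheritParams read_newick
#' @param path path to a NEXUS file with a TREES block.
#' @return a validated `phylo` (single tree) or a list of them.
#' @export
read_nexus_trees <- function(path, underscores_to_spaces = TRUE, min_tips = 2L) {
  trees <- ape::read.nexus(path)
  fix <- function(tr) {
    if (underscores_to_spaces) tr$tip.label <- gsub("_", " ", tr$tip.label)
    validate_phylo(tr, min_tips = min_tips)
    tr
  }
  if (inherits(trees, "phylo")) fix(trees) else lapply(unclass(trees), fix)
}

#' Prune a tree to a set of tips
#'
#' Keeps exactly the tips in `keep`, collapsing degree-2 internal nodes and
#' summing their branch lengths, so path lengths between retained tips are
#' unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (>= 2, all present).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2L) {
    stop("need at least 2 tips to keep, got ", length(keep))
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Patristic distance matrix
#'
#' Tip-to-tip distances measured as the sum of branch lengths along the
#' unique path between each pair of tips. Root placement is irrelevant:
#' patristic distance is a property of the unrooted weighted tree.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a symmetric numeric matrix with zero diagonal; row/column names
#'   are the tip labels in `tree$tip.label` order.
#' @examples
#' patristic_matrix(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
#' @export
patristic_matrix <- function(tree) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}
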