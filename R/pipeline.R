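# Orchestration: run the coverage + dispersion audit over every clade and
# taxonomic level, produce the report table, significance stars, tree
# annotation and deterministic TSV output.

#' Configure an audit run
#'
#' @param tree a `phylo` object or path to a Newick file.
#' @param taxonomy a taxonomy data.frame (columns species, genus, family,
#'   order) or path to its CSV.
#' @param scored scored OTU names: a character vector of names, or paths to
#'   plain-text OTU lists / NEXUS matrices (extension `.nex`/`.nexus`/`.nxs`
#'   triggers [nexus_taxa()], anything else [read_otu_list()]).
#' @param levels taxonomic levels to audit, subset of
#'   `c("species", "genus", "family")`.
#' @param reps null-distribution replicates per test (default 1000).
#' @param seed top-level integer seed; each (clade, level) gets its own
#'   derived substream, so results for one clade are unaffected by the
#'   presence of others.
#' @param low,high coverage classification thresholds (strict; defaults
#'   0.25 and 0.75).
#' @param class_label label for the class-wide (all clades pooled) rows.
#' @param normalize apply [normalize_name()] to tree tips and scored names.
#' @param audit_nulls keep every null distribution in the report attributes
#'   (for [write_null_audit()]).
#' @return an object of class `audit_config`.
#' @export
audit_config <- function(tree, taxonomy, scored,
                         levels = c("species", "genus", "family"),
                         reps = 1000L, seed = NULL,
                         low = 0.25, high = 0.75,
                         class_label = "All", normalize = TRUE,
                         audit_nulls = FALSE) {
  levels <- match.arg(levels, several.ok = TRUE)
  stopifnot(low < high, reps >= 1)
  structure(list(tree = tree, taxonomy = taxonomy, scored = scored,
                 levels = levels, reps = as.integer(reps), seed = seed,
                 low = low, high = high, class_label = class_label,
                 normalize = normalize, audit_nulls = audit_nulls),
            class = "audit_config")
}

load_tree <- function(x, normalize) {
  tree <- if (inherits(x, "phylo")) x else read_newick(x)
  if (normalize) {
    tree$tip.label <- normalize_name(tree$tip.label)
    validate_phylo(tree)
  }
  tree
}

load_taxonomy <- function(x, normalize) {
  if (is.data.frame(x)) {
    tax <- x
    if (normalize) tax$species <- normalize_name(tax$species)
    validate_taxonomy(tax)
    tax
  } else {
    read_taxonomy(x, normalize = normalize)
  }
}

load_scored <- function(x, normalize) {
  if (all(file.exists(x))) {
    nm <- unlist(lapply(x, function(p) {
      if (grepl("\\.(nex|nexus|nxs)$", p, ignore.case = TRUE)) {
        nexus_taxa(p, normalize = normalize)
      } else {
        read_otu_list(p, normalize = normalize)
      }
    }))
  } else {
    nm <- as.character(x)
    if (normalize) nm <- normalize_name(nm)
  }
  sort(unique(nm))
}

# One exemplar tip per higher taxon: prune the clade tree to the
# alphabetically first species of each genus/family present, relabelled to
# the higher-taxon name. NULL when fewer than 2 higher taxa have tips.
make_level_tree <- function(clade_tree, tax_c, level) {
  if (is.null(clade_tree)) return(NULL)
  if (level == "species") return(clade_tree)
  present <- tax_c[tax_c$species %in% clade_tree$tip.label, ]
  if (!nrow(present)) return(NULL)
  reps <- vapply(split(present$species, present[[level]]),
                 function(sp) sort(sp)[1], character(1))
  if (length(reps) < 2L) return(NULL)
  lt <- prune_to_taxa(clade_tree, unname(reps))
  lt$tip.label <- names(reps)[match(lt$tip.label, unname(reps))]
  validate_phylo(lt)
  lt
}

na_dispersion <- function(note) {
  structure(list(n = 0L, n_pool = 0L, focal = character(), reps = NA_integer_,
                 seed = NULL, obs_mpd = NA_real_, obs_mntd = NA_real_,
                 nri = NA_real_, nti = NA_real_, p_nri = NA_real_,
                 p_nti = NA_real_, note = note),
            class = "dispersion_result")
}

#' Run the full coverage and dispersion audit
#'
#' For every clade (each order in the taxonomy, plus one class-wide row
#' pooling all of them) and every requested taxonomic level: computes the
#' coverage record against the taxonomy's reference set, and — whenever at
#' least 2 scored taxa are present in the tree and they do not exhaust the
#' sampling pool — the NRI/NTI dispersion test. Order-level tests use the
#' order-pruned tree as the null sampling pool; class-wide tests use the
#' full tree. Genus- and family-level trees keep one exemplar tip per
#' higher taxon, relabelled to the higher-taxon name.
#'
#' @param config an [audit_config()].
#' @return a data.frame of class `audit_report`, one row per clade x level
#'   (class-wide rows first), with attributes `class_label`, `excluded`
#'   (names dropped during reference filtering), `config` and `details`
#'   (the underlying `dispersion_result` objects).
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  tree <- load_tree(config$tree, config$normalize)
  tax <- load_taxonomy(config$taxonomy, config$normalize)
  scored <- load_scored(config$scored, config$normalize)
  tips <- tree$tip.label

  sp_ref <- tax$species
  gen_ref <- unique(tax$genus)
  fam_ref <- unique(tax$family)
  g2f <- unique(tax[, c("genus", "family")])

  # rank of each scored OTU: species first, then genus, then family;
  # anything unresolvable is excluded (and reported), mirroring the removal
  # of fossils and unmatched names.
  sc_sp <- intersect(scored, sp_ref)
  sc_gen <- intersect(setdiff(scored, sp_ref), gen_ref)
  sc_fam <- intersect(setdiff(scored, c(sp_ref, gen_ref)), fam_ref)
  unresolved <- setdiff(scored, c(sc_sp, sc_gen, sc_fam))
  if (length(unresolved)) {
    message("excluding ", length(unresolved),
            " scored name(s) absent from the taxonomy: ",
            paste(utils::head(unresolved, 10), collapse = ", "),
            if (length(unresolved) > 10) ", ..." else "")
  }
  # species-level OTUs must also be on the tree
  sc_sp <- filter_to_reference(sc_sp, tips, quiet = FALSE)
  dropped_tree <- attr(sc_sp, "excluded")

  # a genus-level OTU certifies its genus and family, but no species;
  # a family-level OTU certifies only its family
  scored_at <- list(
    species = as.character(sc_sp),
    genus = sort(union(lift_to_level(sc_sp, tax, "genus"), sc_gen)),
    family = sort(Reduce(union, list(
      lift_to_level(sc_sp, tax, "family"),
      g2f$family[match(sc_gen, g2f$genus)],
      sc_fam)))
  )

  clades <- c(config$class_label, sort(unique(tax$order)))
  rows <- list()
  details <- list()
  for (clade in clades) {
    is_class <- clade == config$class_label
    tax_c <- if (is_class) tax else tax[tax$order == clade, , drop = FALSE]
    pool_species <- intersect(tax_c$species, tips)
    clade_tree <- if (is_class) {
      tree
    } else if (length(pool_species) >= 2L) {
      prune_to_taxa(tree, pool_species)
    } else {
      NULL
    }
    for (level in config$levels) {
      ref <- sort(unique(tax_c[[level]]))
      scored_cl <- intersect(scored_at[[level]], ref)
      cov <- coverage(focal_set(clade, level, scored_cl, ref),
                      config$low, config$high)
      ltree <- make_level_tree(clade_tree, tax_c, level)
      dt <- if (is.null(ltree)) {
        na_dispersion("sampling pool has fewer than 2 tips at this level")
      } else {
        dispersion_test(ltree, scored_cl, reps = config$reps,
                        seed = derive_seed(config$seed, clade, level),
                        keep_null = config$audit_nulls)
      }
      key <- paste(clade, level, sep = "|")
      details[[key]] <- dt
      rows[[key]] <- cbind(cov,
        data.frame(n_focal = dt$n, n_pool = dt$n_pool,
                   obs_mpd = dt$obs_mpd, obs_mntd = dt$obs_mntd,
                   nri = dt$nri, nti = dt$nti,
                   p_nri = dt$p_nri, p_nti = dt$p_nti,
                   note = dt$note, stringsAsFactors = FALSE))
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(report) <- c("audit_report", "data.frame")
  attr(report, "class_label") <- config$class_label
  attr(report, "excluded") <- sort(unique(c(unresolved, dropped_tree)))
  attr(report, "config") <- config
  attr(report, "details") <- details
  report
}

#' Write an audit report to TSV
#'
#' Deterministic formatting (proportions to 4 decimals, indices to 2,
#' p-values to 4, significance stars `*` p < 0.05 / `**` p < 0.01, `NA` for
#' blank cells), so identical configurations byte-reproduce the file.
#'
#' @param report an [run_audit()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  fm <- function(v, d) ifelse(is.na(v), "NA", formatC(v, format = "f", digits = d))
  out <- data.frame(
    clade = report$clade, level = report$level,
    n_scored = report$n_scored, n_total = report$n_total,
    proportion = fm(report$proportion, 4),
    coverage_class = report$coverage_class,
    n_focal = report$n_focal, n_pool = report$n_pool,
    nri = fm(report$nri, 2), nti = fm(report$nti, 2),
    p_nri = fm(report$p_nri, 4), p_nti = fm(report$p_nti, 4),
    sig_nri = sig_stars(report$p_nri), sig_nti = sig_stars(report$p_nti),
    stringsAsFactors = FALSE)
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(out, sep = "\t")))
  con <- file(path, open = "wb")  # fixed LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Dump null distributions to JSON for audit
#'
#' Requires a report produced with `audit_nulls = TRUE` in the
#' configuration; writes observed values, null draws, means, standard
#' deviations and seeds for every (clade, level) test.
#'
#' @param report an [run_audit()] report.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_null_audit <- function(report, path) {
  details <- attr(report, "details")
  dump <- lapply(details, function(dt) {
    list(n = dt$n, n_pool = dt$n_pool, reps = dt$reps, seed = dt$seed,
         obs_mpd = dt$obs_mpd, obs_mntd = dt$obs_mntd,
         nri = dt$nri, nti = dt$nti, p_nri = dt$p_nri, p_nti = dt$p_nti,
         note = dt$note,
         null_mpd = if (!is.null(dt$null_mpd)) {
           list(mean = dt$null_mpd$mean, sd = dt$null_mpd$sd,
                values = dt$null_mpd$values)
         },
         null_mntd = if (!is.null(dt$null_mntd)) {
           list(mean = dt$null_mntd$mean, sd = dt$null_mntd$sd,
                values = dt$null_mntd$values)
         })
  })
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Audit report:", nrow(x), "rows (",
      length(unique(x$clade)) - 1L, "clades x",
      length(unique(x$level)), "levels + class-wide )\n")
  print.data.frame(utils::head(as.data.frame(x)[, c(
    "clade", "level", "n_scored", "n_total", "proportion",
    "coverage_class", "nri", "nti")], 12), digits = 4)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' Tally coverage classes per taxonomic level
#'
#' Counts how many clades fall in each coverage class at each level,
#' excluding the class-wide rows.
#'
#' @param report an [run_audit()] report, or any data.frame with `clade`,
#'   `level` and `coverage_class` columns (e.g. [coverage_from_counts()]
#'   output).
#' @param class_label clade label to exclude from the tallies; defaults to
#'   the report's own class label.
#' @return data.frame with columns level, n_low, n_medium, n_high, n_clades.
#' @export
summarize_counts <- function(report, class_label = attr(report, "class_label")) {
  df <- as.data.frame(report)
  if (!is.null(class_label)) df <- df[df$clade != class_label, , drop = FALSE]
  lv <- intersect(c("species", "genus", "family"), unique(df$level))
  out <- do.call(rbind, lapply(lv, function(l) {
    cl <- df$coverage_class[df$level == l]
    data.frame(level = l,
               n_low = sum(cl == "low"), n_medium = sum(cl == "medium"),
               n_high = sum(cl == "high"), n_clades = length(cl),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(level = character(), n_low = integer(),
                      n_medium = integer(), n_high = integer(),
                      n_clades = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Annotate a tree with scored/unscored tip states
#'
#' @param tree a `phylo`.
#' @param scored character vector of scored tip labels (subset of the tips).
#' @return object of class `annotated_tree`: the tree plus a named logical
#'   vector `scored` over its tips.
#' @export
annotate_tree <- function(tree, scored) {
  validate_phylo(tree)
  scored <- unique(as.character(scored))
  extra <- setdiff(scored, tree$tip.label)
  if (length(extra)) {
    stop("scored taxa absent from tree: ", paste(extra, collapse = ", "))
  }
  flags <- stats::setNames(tree$tip.label %in% scored, tree$tip.label)
  structure(list(tree = tree, scored = flags), class = "annotated_tree")
}

#' Write an annotated tree as Newick with NHX tip tags
#'
#' Each tip carries `[&&NHX:scored=1]` or `[&&NHX:scored=0]` after its
#' branch length; spaces in labels are written as underscores.
#'
#' @param x an [annotate_tree()] object.
#' @param path output file, or `NULL` to return the string.
#' @return the Newick string, invisibly if written to file.
#' @export
write_annotated_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "annotated_tree"))
  tree <- stats::reorder(x$tree, "cladewise")
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- rep(NA_real_, max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  lab <- gsub(" ", "_", tree$tip.label)
  rec <- function(node) {
    blen <- if (is.na(elen[node])) "" else paste0(":", format(elen[node], digits = 10))
    if (node <= ntip) {
      paste0(lab[node], blen,
             "[&&NHX:scored=", as.integer(x$scored[node]), "]")
    } else {
      paste0("(", paste(vapply(kids[[as.character(node)]], rec, character(1)),
                        collapse = ","), ")", blen)
    }
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (is.null(path)) return(s)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(s, con, sep = "\n")
  invisible(s)
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("Annotated tree:", sum(x$scored), "of", length(x$scored),
      "tips scored\n")
  invisible(x)
}

#' Plot an annotated tree, highlighting scored tip branches
#'
#' Terminal branches leading to scored tips are drawn in blue, the rest in
#' grey.
#'
#' @param x an [annotate_tree()] object.
#' @param scored_col,other_col branch colours.
#' @param ... passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.annotated_tree <- function(x, scored_col = "blue4", other_col = "grey60",
                                ...) {
  tree <- x$tree
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  cols <- rep(other_col, nrow(tree$edge))
  cols[tip_edge[x$scored]] <- scored_col
  ape::plot.phylo(tree, edge.color = cols, ...)
  invisible(x)
}
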