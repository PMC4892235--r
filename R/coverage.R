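# Coverage accounting: name normalization, taxonomy handling, lifting scored
# species to higher taxonomic levels, and the low/medium/high classification.

#' Normalize a taxon name
#'
#' Canonical form used to match OTU names from morphological matrices against
#' tree tips and taxonomy rows: trimmed, underscores become single spaces,
#' quotes dropped, trailing tokens matching `strip_pattern` (by default
#' anything containing digits, parentheses, brackets or commas, i.e. author
#' years and matrix-rank suffixes) are removed, the first word is capitalized
#' and all later words lower-cased. The transformation is idempotent.
#'
#' @param x character vector of raw names.
#' @param strip_pattern regex; trailing tokens matching it are removed (never
#'   the first token).
#' @return character vector of canonical names; empty results are an error.
#' @examples
#' normalize_name(c("Canis_lupus", "  FELIS silvestris ",
#'                  "Canis lupus (Linnaeus, 1758)"))
#' @export
normalize_name <- function(x, strip_pattern = "[][0-9(),]") {
  stopifnot(is.character(x))
  vapply(x, function(nm) {
    if (is.na(nm)) stop("name is NA")
    s <- gsub("_", " ", nm)
    s <- gsub("['\"]", "", s)
    s <- gsub("\\s+", " ", trimws(s))
    tok <- strsplit(s, " ", fixed = TRUE)[[1]]
    while (length(tok) > 1L && grepl(strip_pattern, tok[length(tok)])) {
      tok <- tok[-length(tok)]
    }
    if (!length(tok) || !nzchar(tok[1])) {
      stop("name empty after normalization: '", nm, "'")
    }
    tok[1] <- paste0(toupper(substr(tok[1], 1, 1)), tolower(substring(tok[1], 2)))
    if (length(tok) > 1L) tok[-1] <- tolower(tok[-1])
    paste(tok, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Intersect scored names with a reference set
#'
#' Mirrors the exclusion step of a coverage audit: OTUs absent from the
#' reference (e.g. fossils, or taxa missing from the tree/taxonomy) are
#' dropped, with their count and identity reported.
#'
#' @param scored,reference character vectors of canonical names.
#' @param quiet suppress the exclusion message.
#' @return sorted character vector `scored` intersect `reference`, with the
#'   dropped names in attribute `"excluded"`.
#' @export
filter_to_reference <- function(scored, reference, quiet = FALSE) {
  scored <- unique(as.character(scored))
  reference <- unique(as.character(reference))
  dropped <- sort(setdiff(scored, reference))
  if (length(dropped) && !quiet) {
    shown <- utils::head(dropped, 10L)
    message("excluding ", length(dropped), " name(s) absent from reference: ",
            paste(shown, collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  }
  kept <- sort(intersect(scored, reference))
  attr(kept, "excluded") <- dropped
  kept
}

#' Read a taxonomy table
#'
#' CSV with header `species,genus,family,order`. Species names are
#' normalized; duplicates or empty higher-rank fields are errors, so every
#' species maps to exactly one genus, family and order.
#'
#' @param path CSV file path.
#' @param normalize apply [normalize_name()] to the species column.
#' @return a `data.frame` with columns species, genus, family, order.
#' @export
read_taxonomy <- function(path, normalize = TRUE) {
  tax <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "genus", "family", "order")
  miss <- setdiff(need, names(tax))
  if (length(miss)) stop("taxonomy lacks column(s): ", paste(miss, collapse = ", "))
  tax <- tax[, need]
  if (normalize) tax$species <- normalize_name(tax$species)
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  dup <- unique(tax$species[duplicated(tax$species)])
  if (length(dup)) stop("duplicate species in taxonomy: ", paste(utils::head(dup, 5), collapse = ", "))
  for (col in c("genus", "family", "order")) {
    if (anyNA(tax[[col]]) || any(!nzchar(trimws(tax[[col]])))) {
      stop("empty values in taxonomy column '", col, "'")
    }
  }
  # genus -> family and family -> order must be functions
  g2f <- unique(tax[, c("genus", "family")])
  if (anyDuplicated(g2f$genus)) {
    bad <- g2f$genus[duplicated(g2f$genus)]
    stop("genus mapped to multiple families: ", paste(unique(bad), collapse = ", "))
  }
  f2o <- unique(tax[, c("family", "order")])
  if (anyDuplicated(f2o$family)) {
    bad <- f2o$family[duplicated(f2o$family)]
    stop("family mapped to multiple orders: ", paste(unique(bad), collapse = ", "))
  }
  invisible(tax)
}

#' Lift species names to a higher taxonomic level
#'
#' At `"species"` level this is the identity; at `"genus"`/`"family"` level
#' it returns the distinct higher taxa containing the given species.
#'
#' @param species_names character vector of canonical species names.
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param level `"species"`, `"genus"` or `"family"`.
#' @param strict error (rather than warn and drop) on names absent from the
#'   taxonomy.
#' @return sorted character vector of taxon names at `level`.
#' @export
lift_to_level <- function(species_names, taxonomy,
                          level = c("species", "genus", "family"),
                          strict = FALSE) {
  level <- match.arg(level)
  species_names <- unique(as.character(species_names))
  if (level == "species") return(sort(species_names))
  idx <- match(species_names, taxonomy$species)
  unknown <- species_names[is.na(idx)]
  if (length(unknown)) {
    msg <- paste0(length(unknown), " name(s) not in taxonomy: ",
                  paste(utils::head(unknown, 5), collapse = ", "),
                  if (length(unknown) > 5) ", ..." else "")
    if (strict) stop(msg) else warning(msg, " (dropped)")
  }
  sort(unique(taxonomy[[level]][idx[!is.na(idx)]]))
}

#' Construct a focal set
#'
#' The scored taxa at one taxonomic level within one clade, together with the
#' reference set of all taxa at that level in the clade. Enforces
#' `scored` being a subset of `reference`.
#'
#' @param clade clade label (an order name, or a class-wide label).
#' @param level `"species"`, `"genus"` or `"family"`.
#' @param scored,reference character vectors of taxon names at `level`.
#' @return an object of class `focal_set`.
#' @export
focal_set <- function(clade, level, scored, reference) {
  level <- match.arg(level, c("species", "genus", "family"))
  scored <- sort(unique(as.character(scored)))
  reference <- sort(unique(as.character(reference)))
  extra <- setdiff(scored, reference)
  if (length(extra)) {
    stop("scored taxa absent from reference: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(clade = as.character(clade), level = level,
                 scored = scored, reference = reference),
            class = "focal_set")
}

#' @export
print.focal_set <- function(x, ...) {
  cat("Focal set:", x$clade, "/", x$level, "-", length(x$scored), "of",
      length(x$reference), "taxa scored\n")
  invisible(x)
}

#' Classify a coverage proportion
#'
#' A clade has low coverage when strictly less than `low` (default 25%) of
#' its taxa are scored, high coverage when strictly more than `high`
#' (default 75%) are; otherwise medium. Both boundaries are strict, so
#' exactly 25% or exactly 75% is medium.
#'
#' @param p numeric vector of proportions in \[0, 1\].
#' @param low,high thresholds, `low < high`.
#' @return ordered factor with levels low < medium < high.
#' @examples
#' classify_coverage(c(0.17, 0.25, 0.80))
#' @export
classify_coverage <- function(p, low = 0.25, high = 0.75) {
  stopifnot(is.numeric(p), low < high)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportion outside [0, 1]")
  out <- rep("medium", length(p))
  out[p < low] <- "low"
  out[p > high] <- "high"
  out[is.na(p)] <- NA
  factor(out, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Coverage record for a focal set
#'
#' @param focal a [focal_set()].
#' @param low,high classification thresholds (see [classify_coverage()]).
#' @return one-row data.frame: clade, level, n_scored, n_total, proportion,
#'   coverage_class.
#' @export
coverage <- function(focal, low = 0.25, high = 0.75) {
  stopifnot(inherits(focal, "focal_set"))
  n_total <- length(focal$reference)
  if (n_total < 1L) stop("empty reference set for clade ", focal$clade)
  n_scored <- length(focal$scored)
  p <- n_scored / n_total
  data.frame(clade = focal$clade, level = focal$level,
             n_scored = n_scored, n_total = n_total, proportion = p,
             coverage_class = as.character(classify_coverage(p, low, high)),
             stringsAsFactors = FALSE)
}

#' Coverage records from a table of counts
#'
#' Computes proportions and coverage classes directly from scored/total
#' counts (e.g. a published census), bypassing name resolution.
#'
#' @param counts data.frame with columns clade, level, n_scored, n_total.
#' @param low,high classification thresholds.
#' @return `counts` with proportion and coverage_class columns appended.
#' @export
coverage_from_counts <- function(counts, low = 0.25, high = 0.75) {
  need <- c("clade", "level", "n_scored", "n_total")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts lack column(s): ", paste(miss, collapse = ", "))
  if (any(counts$n_total < 1)) stop("n_total must be >= 1")
  if (any(counts$n_scored < 0 | counts$n_scored > counts$n_total)) {
    stop("n_scored must lie in [0, n_total]")
  }
  counts$proportion <- counts$n_scored / counts$n_total
  counts$coverage_class <- as.character(classify_coverage(counts$proportion, low, high))
  counts
}

#' Read a plain-text OTU list
#'
#' One name per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @param normalize apply [normalize_name()].
#' @return character vector of unique names.
#' @export
read_otu_list <- function(path, normalize = TRUE) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (normalize) x <- normalize_name(x)
  sort(unique(x))
}

#' Extract taxon names from a NEXUS file
#'
#' Reads only the taxon list of a discrete morphological matrix: the
#' TAXLABELS statement if present, otherwise the row labels of the first
#' MATRIX command in a DATA/CHARACTERS block. Character states are never
#' interpreted. Bracketed NEXUS comments are stripped first.
#'
#' @param path NEXUS file path.
#' @param normalize apply [normalize_name()].
#' @return character vector of unique taxon names.
#' @export
nexus_taxa <- function(path, normalize = TRUE) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", " ", txt)  # comments
  taxa <- character()
  m <- regmatches(txt, regexpr("(?is)\\bTAXLABELS\\b(.*?);", txt, perl = TRUE))
  if (length(m)) {
    body <- sub("(?is)^\\s*TAXLABELS\\b", "", m, perl = TRUE)
    body <- sub(";\\s*$", "", body)
    taxa <- nexus_tokens(body)
  } else {
    m <- regmatches(txt, regexpr("(?is)\\bMATRIX\\b(.*?);", txt, perl = TRUE))
    if (length(m)) {
      body <- sub("(?is)^\\s*MATRIX\\b", "", m, perl = TRUE)
      body <- sub(";\\s*$", "", body)
      rows <- trimws(strsplit(body, "\n", fixed = TRUE)[[1]])
      rows <- rows[nzchar(rows)]
      taxa <- vapply(rows, function(r) nexus_tokens(r)[1], character(1),
                     USE.NAMES = FALSE)
    }
  }
  taxa <- taxa[!is.na(taxa) & nzchar(taxa)]
  if (!length(taxa)) stop("no taxon names found in NEXUS file: ", path)
  if (normalize) taxa <- normalize_name(taxa)
  sort(unique(taxa))
}

# Tokenize a NEXUS fragment: single-quoted labels (possibly containing
# spaces) or bare whitespace-delimited words.
nexus_tokens <- function(x) {
  toks <- regmatches(x, gregexpr("'[^']*'|[^\\s']+", x, perl = TRUE))[[1]]
  gsub("^'|'$", "", toks)
}
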