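#' Bundled census of morphological data availability for mammals
#'
#' Published counts of living mammalian operational taxonomic units with at
#' least one coded anatomical character available in public discrete
#' morphological matrices, compiled per mammalian order at family, genus and
#' species level, together with the total number of taxa at each level in
#' the reference taxonomy. Class-wide totals are the rows with clade
#' `"Mammalia"`; the remaining 28 clades are orders. These are counts only —
#' the underlying matrices, supertree and taxonomy are not redistributed —
#' so coverage proportions and classifications can be recomputed exactly,
#' while dispersion statistics cannot.
#'
#' @return data.frame with columns clade, level, n_scored, n_total
#'   (29 clades x 3 levels = 87 rows).
#' @examples
#' cc <- coverage_from_counts(mammal_census())
#' summarize_counts(cc, class_label = "Mammalia")
#' @export
mammal_census <- function() {
  path <- system.file("extdata", "mammal_coverage_census.csv",
                      package = "morphaudit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
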