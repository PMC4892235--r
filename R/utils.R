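# RNG plumbing. Every stochastic entry point takes an explicit integer seed
# and restores the caller's RNG state afterwards, so calling library code is
# side-effect free and independently reproducible.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a top-level seed plus any number of string/numeric
#' tags (clade, taxonomic level, metric, replicate index, ...) to an integer
#' seed below 2^31. Used so that each (clade, level, metric) analysis has its
#' own RNG substream: adding or removing one clade never shifts the draws of
#' another.
#'
#' @param seed integer top-level seed (or `NULL`, returned as `NULL`).
#' @param ... tags coerced to character and mixed into the hash.
#' @return an integer seed, or `NULL` if `seed` is `NULL`.
#' @examples
#' derive_seed(42, "Carnivora", "species", "mntd")
#' @export
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  tags <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                 character(1))
  key <- paste(c(as.character(seed), tags), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483587
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
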