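# Phylogenetic dispersion statistics: MPD, MNTD, their randomization nulls,
# the NRI/NTI standardized effect sizes, and two-tailed randomization
# p-values.
#
# Sign convention: an observed distance BELOW the null mean (focal taxa
# closer together than random draws) gives a POSITIVE index, i.e. positive
# NRI/NTI = phylogenetic clustering, negative = overdispersion.

check_focal <- function(dm, focal) {
  stopifnot(is.matrix(dm))
  if (is.null(rownames(dm))) stop("distance matrix must have row names")
  focal <- unique(as.character(focal))
  miss <- setdiff(focal, rownames(dm))
  if (length(miss)) {
    stop("focal taxa absent from distance matrix: ", paste(miss, collapse = ", "))
  }
  if (length(focal) < 2L) stop("need at least 2 focal taxa, got ", length(focal))
  focal
}

#' Mean pairwise distance (MPD)
#'
#' Mean patristic distance over all unordered pairs of focal tips.
#'
#' @param dm patristic distance matrix from [patristic_matrix()].
#' @param focal character vector of >= 2 tip labels present in `dm`.
#' @return a single number.
#' @examples
#' dm <- patristic_matrix(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
#' mpd(dm, c("A", "B", "C"))  # (2+4+4)/3
#' @export
mpd <- function(dm, focal) {
  focal <- check_focal(dm, focal)
  s <- dm[focal, focal]
  k <- length(focal)
  sum(s) / (k * (k - 1))
}

#' Mean nearest taxon distance (MNTD)
#'
#' For each focal tip, the patristic distance to its nearest *other focal*
#' tip; MNTD is the mean of these minima.
#'
#' @inheritParams mpd
#' @return a single number; always `<=` [mpd()] on the same set.
#' @export
mntd <- function(dm, focal) {
  focal <- check_focal(dm, focal)
  s <- dm[focal, focal]
  diag(s) <- Inf
  mean(apply(s, 1L, min))
}

metric_fun <- function(dm, metric) {
  if (metric == "mpd") {
    function(idx) {
      s <- dm[idx, idx]
      k <- length(idx)
      sum(s) / (k * (k - 1))
    }
  } else {
    function(idx) {
      s <- dm[idx, idx]
      diag(s) <- Inf
      mean(apply(s, 1L, min))
    }
  }
}

#' Randomization null distribution of MPD or MNTD
#'
#' Each replicate draws `n` distinct tips uniformly without replacement from
#' the pool (the rows of `dm`), independently across replicates, and records
#' the metric. The standard deviation uses the sample (n - 1) denominator.
#'
#' @param dm patristic distance matrix (the sampling pool is its tip set).
#' @param n draw size, `2 <= n <= nrow(dm)`.
#' @param metric `"mpd"` or `"mntd"`.
#' @param reps number of replicates (default 1000).
#' @param seed integer seed; identical seeds give identical values.
#' @return object of class `null_distribution`: list with `metric`, `values`,
#'   `reps`, `n`, `mean`, `sd`, `seed`.
#' @export
null_distribution <- function(dm, n, metric = c("mpd", "mntd"),
                              reps = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(dm))
  N <- nrow(dm)
  if (!is.numeric(n) || n < 2 || n > N) {
    stop("draw size n must satisfy 2 <= n <= ", N, ", got ", n)
  }
  if (reps < 1) stop("reps must be >= 1")
  n <- as.integer(n)
  f <- metric_fun(dm, metric)
  # draw over the lexicographically sorted pool so that identical seeds give
  # identical label subsets whatever the storage order of the matrix
  perm <- if (is.null(rownames(dm))) seq_len(N) else order(rownames(dm))
  values <- with_seed(seed, vapply(seq_len(reps),
                                   function(i) f(perm[sample.int(N, n)]),
                                   numeric(1)))
  structure(list(metric = metric, values = values, reps = as.integer(reps),
                 n = n, mean = mean(values), sd = stats::sd(values),
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution of", toupper(x$metric), "- n =", x$n,
      ", reps =", x$reps, "\n  mean =", format(x$mean),
      " sd =", format(x$sd), "\n")
  invisible(x)
}

#' Standardized effect size (NRI/NTI)
#'
#' `-(obs - mean(null)) / sd(null)`: the nearest taxon index when the null is
#' over MNTD, the net relatedness index when it is over MPD. Positive values
#' indicate phylogenetic clustering of the focal taxa, negative values
#' overdispersion. `NA` when the null has zero (or undefined) spread.
#'
#' @param obs observed metric value.
#' @param null a [null_distribution()].
#' @return a single number, or `NA`.
#' @export
ses_index <- function(obs, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.finite(null$sd) || null$sd == 0) return(NA_real_)
  -(obs - null$mean) / null$sd
}

#' Two-tailed randomization p-value
#'
#' Rank-based with +1 continuity correction: with `r` null values `<= obs`,
#' the lower-tail probability is `q = (r + 1) / (reps + 1)` and
#' `p = 2 * min(q, 1 - q + 1/(reps + 1))`, capped at 1. Always in (0, 1]; an
#' observation below every null value at 1000 replicates gives p = 2/1001.
#'
#' On small pools many null draws coincide exactly with the observed value
#' (the same subset redrawn); ties are counted as "at least as extreme", with
#' a small relative tolerance so that decimal serialization of branch lengths
#' cannot flip a tie into a strict inequality.
#'
#' @inheritParams ses_index
#' @param tie_tol relative tolerance for tie detection (default 1e-6).
#' @return a single number in (0, 1].
#' @export
p_value <- function(obs, null, tie_tol = 1e-6) {
  stopifnot(inherits(null, "null_distribution"))
  r <- sum(null$values <= obs + tie_tol * max(1, abs(obs)))
  q <- (r + 1) / (null$reps + 1)
  min(2 * min(q, 1 - q + 1 / (null$reps + 1)), 1)
}

#' Phylogenetic dispersion test for a set of scored tips
#'
#' Computes observed MPD and MNTD for the focal tips, their randomization
#' nulls over the tree's tip pool, the NRI and NTI standardized effect
#' sizes, and two-tailed randomization p-values. When fewer than 2 focal
#' taxa are present in the pool, or the focal set is the whole pool (zero
#' null variance), the indices are `NA` and `$note` records why — these are
#' the blank cells of a coverage report.
#'
#' @param tree a `phylo`; its tips are the null sampling pool. Ignored when
#'   `dm` is supplied.
#' @param focal character vector of tip labels; silently intersected with
#'   the pool.
#' @param reps null replicates (default 1000).
#' @param seed integer seed; per-metric substreams are derived from it, and
#'   identical seeds reproduce the result exactly.
#' @param dm optional precomputed [patristic_matrix()] (avoids recomputation
#'   across many tests on the same tree).
#' @param keep_null store the two null distributions in the result
#'   (default `TRUE`).
#' @return object of class `dispersion_result`.
#' @examples
#' tr <- simulate_yule(32, seed = 1)
#' dispersion_test(tr, sample_clustered(tr, 8, seed = 2), reps = 200, seed = 3)
#' @export
dispersion_test <- function(tree, focal, reps = 1000L, seed = NULL,
                            dm = NULL, keep_null = TRUE) {
  if (is.null(dm)) dm <- patristic_matrix(tree)
  pool <- rownames(dm)
  focal_in <- sort(intersect(unique(as.character(focal)), pool))
  n <- length(focal_in)
  res <- structure(
    list(n = n, n_pool = length(pool), focal = focal_in,
         reps = as.integer(reps), seed = seed,
         obs_mpd = NA_real_, obs_mntd = NA_real_,
         nri = NA_real_, nti = NA_real_,
         p_nri = NA_real_, p_nti = NA_real_, note = NA_character_),
    class = "dispersion_result")
  if (n < 2L) {
    res$note <- "fewer than 2 focal taxa in the sampling pool"
    return(res)
  }
  res$obs_mpd <- mpd(dm, focal_in)
  res$obs_mntd <- mntd(dm, focal_in)
  if (n == length(pool)) {
    res$note <- "focal set equals the pool: null distribution is degenerate"
    return(res)
  }
  null_mpd <- null_distribution(dm, n, "mpd", reps, derive_seed(seed, "mpd"))
  null_mntd <- null_distribution(dm, n, "mntd", reps, derive_seed(seed, "mntd"))
  res$nri <- ses_index(res$obs_mpd, null_mpd)
  res$nti <- ses_index(res$obs_mntd, null_mntd)
  res$p_nri <- p_value(res$obs_mpd, null_mpd)
  res$p_nti <- p_value(res$obs_mntd, null_mntd)
  if (keep_null) {
    res$null_mpd <- null_mpd
    res$null_mntd <- null_mntd
  }
  res
}

#' @export
print.dispersion_result <- function(x, digits = 2, ...) {
  cat("Phylogenetic dispersion test: n =", x$n, "of", x$n_pool,
      "tips, reps =", x$reps, "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  fm <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "f", digits = digits))
  cat("  MPD  =", fm(x$obs_mpd), " NRI =", fm(x$nri),
      " p =", fm(x$p_nri), sig_stars(x$p_nri), "\n")
  cat("  MNTD =", fm(x$obs_mntd), " NTI =", fm(x$nti),
      " p =", fm(x$p_nti), sig_stars(x$p_nti), "\n")
  invisible(x)
}

#' Significance stars for randomization p-values
#'
#' `**` for p < 0.01, `*` for p < 0.05, otherwise empty; `NA` gives empty.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
sig_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out
}
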