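test_that("MPD and MNTD match hand-computed values on the 4-tip tree", {
  dm <- patristic_matrix(t4())
  expect_equal(mpd(dm, c("A", "B", "C")), 10 / 3)
  expect_equal(mpd(dm, c("A", "B")), 2)
  expect_equal(mpd(dm, LETTERS[1:4]), 10 / 3)
  # C's nearest focal tip is A or B at distance 4, not its absent sister D
  expect_equal(mntd(dm, c("A", "B", "C")), 8 / 3)
  expect_equal(mntd(dm, c("A", "B")), 2)

  expect_error(mpd(dm, "A"), "at least 2")
  expect_error(mntd(dm, c("A", "Z")), "absent")
})

test_that("MNTD never exceeds MPD and equals it for pairs", {
  for (i in 1:8) {
    tr <- simulate_yule(20, seed = 700 + i)
    dm <- patristic_matrix(tr)
    f <- sample_random(tr$tip.label, sample(2:10, 1), seed = 800 + i)
    expect_lte(mntd(dm, f), mpd(dm, f) + 1e-12)
    pair <- sample_random(tr$tip.label, 2, seed = 900 + i)
    expect_equal(mntd(dm, pair), mpd(dm, pair))
  }
})

test_that("MPD and MNTD agree with picante on simulated trees", {
  skip_if_not_installed("picante")
  for (i in 1:5) {
    tr <- simulate_yule(20, seed = 40 + i)
    dm <- patristic_matrix(tr)
    f <- sample_random(tr$tip.label, 8, seed = 50 + i)
    samp <- matrix(as.integer(rownames(dm) %in% f), nrow = 1,
                   dimnames = list("pool", rownames(dm)))
    expect_equal(mpd(dm, f), as.numeric(picante::mpd(samp, dm)),
                 tolerance = 1e-10)
    expect_equal(mntd(dm, f), as.numeric(picante::mntd(samp, dm)),
                 tolerance = 1e-10)
  }
})

test_that("null draws are uniform subsets, seed-deterministic, and converge to the exhaustive mean", {
  dm <- patristic_matrix(t4())
  a <- null_distribution(dm, 2, "mpd", reps = 500, seed = 123)
  b <- null_distribution(dm, 2, "mpd", reps = 500, seed = 123)
  expect_identical(a$values, b$values)
  expect_equal(a$mean, mean(a$values))

  # exhaustive n=2 MPD null is {2,2,4,4,4,4}: mean 10/3, population sd known
  v <- oracle_exhaustive_null(dm, 2, "mpd")
  expect_setequal(round(v, 10), c(2, 4))
  mu <- mean(v); sig <- sqrt(mean((v - mu)^2))
  nd <- null_distribution(dm, 2, "mpd", reps = 1000, seed = 7)
  expect_lt(abs(nd$mean - mu), 3 * sig / sqrt(1000))

  # degenerate draw: the whole pool every time
  full <- null_distribution(dm, 4, "mpd", reps = 50, seed = 1)
  expect_equal(full$sd, 0)
  expect_error(null_distribution(dm, 1, "mpd"), "2 <= n")
  expect_error(null_distribution(dm, 5, "mpd"), "2 <= n")
})

test_that("standardized effect sizes follow the clustering-positive sign convention", {
  null <- t4_null_n2()
  expect_equal(ses_index(null$mean, null), 0)
  # A,B are clustered sisters: observed 2 sits below the null mean
  expect_equal(ses_index(2, null), 1.2910, tolerance = 1e-4)
  expect_lt(ses_index(4, null), 0)

  degen <- structure(list(metric = "mpd", values = rep(3, 10), reps = 10L,
                          n = 2L, mean = 3, sd = 0, seed = NULL),
                     class = "null_distribution")
  expect_true(is.na(ses_index(2, degen)))

  # antisymmetry under reflection of the null about its mean
  for (i in 1:5) {
    v <- rnorm(200, 5, 2)
    nd <- structure(list(metric = "mpd", values = v, reps = 200L, n = 3L,
                         mean = mean(v), sd = sd(v), seed = NULL),
                    class = "null_distribution")
    vr <- 2 * mean(v) - v
    ndr <- structure(list(metric = "mpd", values = vr, reps = 200L, n = 3L,
                          mean = mean(vr), sd = sd(vr), seed = NULL),
                     class = "null_distribution")
    obs <- rnorm(1, 5, 3)
    expect_equal(ses_index(obs, nd), -ses_index(2 * mean(v) - obs, ndr),
                 tolerance = 1e-10)
  }
})

test_that("randomization p-values are two-tailed, rank-based, in (0, 1]", {
  null <- t4_null_n2()
  expect_equal(p_value(2, null), 6 / 7, tolerance = 1e-12)

  big <- structure(list(metric = "mpd", values = seq_len(1000) + 10,
                        reps = 1000L, n = 2L, mean = 510.5, sd = 1,
                        seed = NULL), class = "null_distribution")
  expect_equal(p_value(0, big), 2 / 1001, tolerance = 1e-12)
  expect_gt(p_value(median(big$values), big), 0.99)

  for (i in 1:10) {
    v <- rexp(97)
    nd <- structure(list(metric = "mntd", values = v, reps = 97L, n = 4L,
                         mean = mean(v), sd = sd(v), seed = NULL),
                    class = "null_distribution")
    p <- p_value(rexp(1), nd)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("dispersion_test populates indices, handles degenerate sets, and is seed-exact", {
  tr <- simulate_yule(40, seed = 21)
  f <- sample_clustered(tr, 10, seed = 22)
  d1 <- dispersion_test(tr, f, reps = 400, seed = 99)
  d2 <- dispersion_test(tr, f, reps = 400, seed = 99)
  expect_identical(d1, d2)
  expect_gt(d1$nti, 0)  # nearest-neighbourhood sample is clustered
  expect_true(d1$p_nti > 0 && d1$p_nti <= 1)
  expect_false(is.null(d1$null_mpd))

  all_tips <- dispersion_test(tr, tr$tip.label, reps = 50, seed = 1)
  expect_true(is.na(all_tips$nri) && is.na(all_tips$nti))
  expect_match(all_tips$note, "degenerate")
  expect_equal(all_tips$obs_mpd, mpd(patristic_matrix(tr), tr$tip.label))

  tiny <- dispersion_test(tr, c("sp0001", "nonexistent"), reps = 50, seed = 1)
  expect_equal(tiny$n, 1)
  expect_true(is.na(tiny$nri))
  expect_match(tiny$note, "fewer than 2")
})
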