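# Statistical machinery: permutation test, 2D KS, Spearman, Holm.

wc_corpus <- function(word_counts, prefix = "x") {
  corpus(vapply(word_counts, function(k) paste(rep("w", k), collapse = " "),
                character(1)),
         item_id = paste0(prefix, seq_along(word_counts)))
}

test_that("permutation test: identical samples, symmetry, add-one correction", {
  a <- c(1, 2, 3, 4)
  t0 <- permutation_test_1d(a, a, n_permutations = 200, seed = 1)
  expect_identical(t0$statistic, 0)
  expect_identical(t0$p_raw, 1)

  b <- c(2, 3, 4, 6)
  t1 <- permutation_test_1d(a, b, n_permutations = 500, seed = 7)
  t2 <- permutation_test_1d(b, a, n_permutations = 500, seed = 7)
  expect_identical(t1$p_raw, t2$p_raw)
  expect_identical(t1$statistic, t2$statistic)

  # p can never be exactly zero
  t3 <- permutation_test_1d(rep(0, 5), rep(100, 5),
                            n_permutations = 100, seed = 2)
  expect_gte(t3$p_raw, 1 / 101)
  expect_error(permutation_test_1d(numeric(0), 1:3), "nonempty")
})

test_that("permutation test converges to the exhaustive enumeration", {
  a <- c(0, 0, 0)
  b <- c(1, 1, 1)
  exact <- oracle_perm_exhaustive(a, b)  # 2 of the 20 assignments
  expect_identical(exact, 0.1)
  t <- permutation_test_1d(a, b, n_permutations = 20000, seed = 11)
  expect_lt(abs(t$p_raw - exact), 0.01)
})

test_that("2D KS statistic: identity, separation, symmetry, oracle, invariance", {
  set.seed(21)
  s1 <- cbind(rnorm(12), rnorm(12))
  expect_identical(ks2d_statistic(s1, s1), 0)

  # fully separated clouds: centering on a point of the upper-right cloud
  # always keeps that point in its own closed lower/left quadrant, so the
  # finite-sample maximum is 1 - 1/(2 m), reaching 1 only asymptotically
  neg <- cbind(-runif(10) - 1, -runif(10) - 1)
  pos <- cbind(runif(8) + 1, runif(8) + 1)
  D_sep <- ks2d_statistic(neg, pos)
  expect_equal(D_sep, 1 - 1 / (2 * nrow(pos)), tolerance = 1e-12)
  expect_equal(D_sep, oracle_ks2d(neg, pos), tolerance = 1e-12)

  for (k in 1:10) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:12, 1)
    s1 <- cbind(rnorm(n1), rnorm(n1))
    s2 <- cbind(rnorm(n2), rnorm(n2))
    D <- ks2d_statistic(s1, s2)
    expect_identical(D, ks2d_statistic(s2, s1))
    expect_equal(D, oracle_ks2d(s1, s2), tolerance = 1e-12)
    # strictly monotone transform of one coordinate leaves D unchanged
    tr <- function(s) cbind(exp(s[, 1]), s[, 2])
    expect_equal(ks2d_statistic(tr(s1), tr(s2)), D, tolerance = 1e-12)
  }

  # boundary ties: duplicated coordinates follow the closed lower/left rule
  s1 <- cbind(c(0, 0, 1), c(0, 1, 0))
  s2 <- cbind(c(0, 1, 1), c(0, 1, 1))
  expect_equal(ks2d_statistic(s1, s2), oracle_ks2d(s1, s2), tolerance = 1e-15)
})

test_that("2D KS p-values behave in both modes", {
  expect_identical(ks2d_pvalue(0, 50, 50, mode = "analytic")$p, 1)
  set.seed(22)
  s <- cbind(rnorm(15), rnorm(15))
  pv <- ks2d_pvalue(0, mode = "permutation", s1 = s, s2 = s,
                    n_permutations = 99, seed = 3)
  expect_identical(pv$p, 1)

  # identical samples: permutation p near 1
  t <- ks2d_test(s, s + 0, mode = "permutation", n_permutations = 99, seed = 4)
  expect_gt(t$p_raw, 0.5)

  # analytic flags small effective n
  expect_true(ks2d_pvalue(0.5, 5, 5, mode = "analytic")$warning_flag)
  expect_false(ks2d_pvalue(0.5, 100, 100, mode = "analytic")$warning_flag)

  # analytic and permutation p agree for well-separated moderate samples
  set.seed(23)
  g1 <- cbind(rnorm(100), rnorm(100))
  g2 <- cbind(rnorm(100, 1), rnorm(100, 1))
  ta <- ks2d_test(g1, g2, mode = "analytic")
  tp <- ks2d_test(g1, g2, mode = "permutation", n_permutations = 400,
                  seed = 5)
  expect_lt(abs(ta$p_raw - tp$p_raw), 0.05)
})

test_that("spearman matches the rank-formula oracle and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)

  set.seed(31)
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 6, 9)
  s <- spearman(xt, yt)
  expect_equal(s$rho, oracle_spearman_rho(xt, yt), tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)

  cs <- spearman(rep(1, 5), 1:5)
  expect_true(is.na(cs$rho))
  expect_identical(cs$flag, "constant-input")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("Holm adjustment matches the closed-form step-down", {
  expect_identical(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
  set.seed(41)
  for (k in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
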