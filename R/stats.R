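# Two-sample statistical machinery: 1D random permutation test,
# two-dimensional Kolmogorov-Smirnov (Fasano-Franceschini) test, Spearman
# correlation, and Holm correction.

new_two_sample_test <- function(statistic_name, statistic, p_raw,
                                n1, n2, n_permutations = NA_integer_,
                                seed = NA_integer_, p_adjusted = NA_real_,
                                note = NULL, subclass = character(0)) {
  structure(list(
    statistic_name = statistic_name, statistic = statistic,
    p_raw = p_raw, p_adjusted = p_adjusted,
    n1 = n1, n2 = n2, n_permutations = n_permutations, seed = seed,
    note = note
  ), class = c(subclass, "two_sample_test"))
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("Two-sample test (%s)\n", x$statistic_name))
  cat(sprintf("  statistic = %.6g   p = %.4g", x$statistic, x$p_raw))
  if (!is.na(x$p_adjusted)) cat(sprintf("   p(Holm) = %.4g", x$p_adjusted))
  cat(sprintf("\n  n1 = %d, n2 = %d", x$n1, x$n2))
  if (!is.na(x$n_permutations)) {
    cat(sprintf(", %d permutations (seed %s)", x$n_permutations,
                format(x$seed)))
  }
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Random permutation test for a difference in means
#'
#' Two-sided test of the null that two one-dimensional samples come from the
#' same distribution, using the absolute difference of sample means as the
#' statistic. The null distribution is built by randomly reassigning the
#' pooled values to groups of the original sizes; the p-value uses the
#' add-one correction `p = (1 + #{null >= observed}) / (1 + B)` so it is
#' never exactly zero.
#'
#' @param a,b numeric samples (nonempty).
#' @param n_permutations number of random reassignments (B, >= 1).
#' @param seed integer seed; the test is fully reproducible given the seed.
#' @return a `two_sample_test` with `statistic_name = "mean_diff"`.
#' @export
permutation_test_1d <- function(a, b, n_permutations = 10000L, seed = 1L) {
  check_that(is.numeric(a) && length(a) >= 1L, "sample a must be nonempty")
  check_that(is.numeric(b) && length(b) >= 1L, "sample b must be nonempty")
  check_that(n_permutations >= 1L, "n_permutations must be >= 1")
  n1 <- length(a)
  n2 <- length(b)
  # sorting the pool makes the seeded null draws invariant to the argument
  # order, so test(a, b) and test(b, a) agree exactly for equal group sizes
  pool <- sort(c(a, b))
  n <- n1 + n2
  sum_pool <- sum(pool)
  observed <- abs(mean(a) - mean(b))
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      s1 <- sum(pool[sample.int(n, n1)])
      abs(s1 / n1 - (sum_pool - s1) / n2)
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= observed)) / (1 + n_permutations)
  new_two_sample_test("mean_diff", observed, p, n1, n2,
                      n_permutations = as.integer(n_permutations),
                      seed = as.integer(seed), subclass = "perm_test")
}

# Quadrant fractions helper: for center (cx, cy) and points (x, y), the
# fraction of points in each closed-lower/left quadrant. Points exactly on a
# boundary count in the lower/left-closed quadrant (x <= cx, y <= cy side).
quadrant_fracs <- function(cx, cy, x, y) {
  le_x <- x <= cx
  le_y <- y <= cy
  n <- length(x)
  c(sum(le_x & le_y), sum(le_x & !le_y),
    sum(!le_x & le_y), sum(!le_x & !le_y)) / n
}

as_points <- function(s) {
  if (is.data.frame(s)) s <- as.matrix(s[, 1:2])
  check_that(is.matrix(s) && ncol(s) >= 2 && nrow(s) >= 1,
             "samples must be two-column matrices or data frames")
  storage.mode(s) <- "double"
  check_that(all(is.finite(s[, 1:2])), "point coordinates must be finite")
  s[, 1:2, drop = FALSE]
}

#' Two-dimensional Kolmogorov-Smirnov statistic (Fasano-Franceschini)
#'
#' For each data point of each sample, the plane is divided into four
#' quadrants centered at that point (boundaries closed on the lower/left
#' side) and the maximal absolute difference between the two empirical
#' quadrant fractions is taken. `D_k` is this maximum over the points of
#' sample `k`; the returned statistic is `D = (D_1 + D_2) / 2`, in `[0, 1]`.
#'
#' Because a center point always lies in its own closed lower/left quadrant,
#' two perfectly separated finite clouds attain `1 - 1/(2 m)` (with `m` the
#' size of the upper-right cloud), approaching 1 asymptotically.
#'
#' @param s1,s2 two-column matrices or data frames of (x, y) points.
#' @return the statistic `D` (numeric scalar).
#' @export
ks2d_statistic <- function(s1, s2) {
  s1 <- as_points(s1)
  s2 <- as_points(s2)
  max_over <- function(centers) {
    m <- 0
    for (i in seq_len(nrow(centers))) {
      f1 <- quadrant_fracs(centers[i, 1], centers[i, 2], s1[, 1], s1[, 2])
      f2 <- quadrant_fracs(centers[i, 1], centers[i, 2], s2[, 1], s2[, 2])
      m <- max(m, abs(f1 - f2))
    }
    m
  }
  (max_over(s1) + max_over(s2)) / 2
}

# Asymptotic Kolmogorov survival function Q_KS(lambda).
q_ks <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' P-value for the two-dimensional KS statistic
#'
#' Analytic mode uses the large-sample Fasano-Franceschini approximation with
#' effective sample size `n = n1 n2 / (n1 + n2)` and a correction for the
#' average within-sample Pearson correlation `r`:
#' \deqn{p = Q_{KS}\!\left(\frac{\sqrt{n}\,D}{1 + \sqrt{1-r^2}\,(0.25 - 0.75/\sqrt{n})}\right).}
#' Permutation mode pools the points of both samples, re-splits them at the
#' original sizes, recomputes `D`, and applies the add-one correction. The
#' analytic approximation is flagged as unreliable when the effective sample
#' size is below 20.
#'
#' @param D observed statistic in `[0, 1]` (ignored in permutation mode when
#'   `s1`/`s2` are supplied, where it is recomputed).
#' @param n1,n2 sample sizes (analytic mode).
#' @param mode `"analytic"` or `"permutation"`.
#' @param r average of the two within-sample Pearson correlation
#'   coefficients (analytic mode); supply 0 if unknown.
#' @param s1,s2 the samples (required for permutation mode).
#' @param n_permutations,seed permutation-mode controls.
#' @return a list with `p`, `mode`, and `warning_flag` (TRUE when the
#'   analytic approximation is outside its reliable range).
#' @export
ks2d_pvalue <- function(D, n1 = NULL, n2 = NULL,
                        mode = c("analytic", "permutation"),
                        r = 0, s1 = NULL, s2 = NULL,
                        n_permutations = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  check_that(is.numeric(D) && D >= 0 && D <= 1, "D must lie in [0, 1]")
  if (mode == "analytic") {
    check_that(!is.null(n1) && !is.null(n2), "analytic mode needs n1 and n2")
    neff <- n1 * n2 / (n1 + n2)
    lambda <- sqrt(neff) * D /
      (1 + sqrt(max(0, 1 - r^2)) * (0.25 - 0.75 / sqrt(neff)))
    return(list(p = q_ks(lambda), mode = "analytic",
                warning_flag = neff < 20))
  }
  check_that(!is.null(s1) && !is.null(s2),
             "permutation mode needs the samples s1 and s2")
  s1 <- as_points(s1)
  s2 <- as_points(s2)
  pool <- rbind(s1, s2)
  n1 <- nrow(s1)
  n <- nrow(pool)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, n1)
      ks2d_statistic(pool[idx, , drop = FALSE],
                     pool[-idx, , drop = FALSE])
    }, numeric(1))
  })
  list(p = (1 + sum(null_stats >= D)) / (1 + n_permutations),
       mode = "permutation", warning_flag = FALSE)
}

#' Two-dimensional KS test on bivariate samples
#'
#' Convenience wrapper computing [ks2d_statistic()] and its p-value in one
#' call (the within-sample correlation correction for the analytic mode is
#' computed from the data).
#'
#' @inheritParams ks2d_statistic
#' @param mode,n_permutations,seed see [ks2d_pvalue()].
#' @return a `two_sample_test` with `statistic_name = "D2"`.
#' @export
ks2d_test <- function(s1, s2, mode = c("analytic", "permutation"),
                      n_permutations = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  s1 <- as_points(s1)
  s2 <- as_points(s2)
  D <- ks2d_statistic(s1, s2)
  safe_cor <- function(s) {
    if (nrow(s) < 2 || stats::sd(s[, 1]) == 0 || stats::sd(s[, 2]) == 0) {
      return(0)
    }
    stats::cor(s[, 1], s[, 2])
  }
  if (mode == "analytic") {
    r <- mean(c(safe_cor(s1), safe_cor(s2)))
    pv <- ks2d_pvalue(D, nrow(s1), nrow(s2), mode = "analytic", r = r)
  } else {
    pv <- ks2d_pvalue(D, mode = "permutation", s1 = s1, s2 = s2,
                      n_permutations = n_permutations, seed = seed)
  }
  new_two_sample_test(
    "D2", D, pv$p, nrow(s1), nrow(s2),
    n_permutations = if (mode == "permutation") {
      as.integer(n_permutations)
    } else {
      NA_integer_
    },
    seed = if (mode == "permutation") as.integer(seed) else NA_integer_,
    note = if (isTRUE(pv$warning_flag)) {
      "analytic approximation unreliable: effective n < 20"
    } else {
      NULL
    },
    subclass = "ks2d"
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average (tie-adjusted) ranks; the p-value comes
#' from the standard large-sample t approximation with `n - 2` degrees of
#' freedom. Constant input yields an `NA` coefficient with a flag rather
#' than an error.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return a list with `rho`, `p`, `n` and `flag` (`"constant-input"` or
#'   `NULL`).
#' @export
spearman <- function(x, y) {
  check_that(is.numeric(x) && is.numeric(y) && length(x) == length(y),
             "x and y must be numeric vectors of equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  check_that(n >= 3L, "need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                flag = "constant-input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(list(rho = rho, p = 0, n = n, flag = NULL))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n,
       flag = NULL)
}

#' Holm step-down adjustment of p-values
#'
#' Familywise-error control by the Holm step-down procedure: with the raw
#' p-values sorted ascending, the i-th adjusted value is
#' `max_{j <= i} min(1, (m - j + 1) p_(j))`, returned in the original order.
#' Input is validated to lie in `[0, 1]`; the adjustment itself is delegated
#' to `stats::p.adjust(method = "holm")`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  check_that(is.numeric(p_values) && length(p_values) >= 1L,
             "p_values must be a nonempty numeric vector")
  check_that(all(is.finite(p_values)) &&
               all(p_values >= 0) && all(p_values <= 1),
             "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}
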