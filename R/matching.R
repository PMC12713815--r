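# Distribution-matched subsampling: iterative random-search selection of the
# word-count-matched subset, and range-matched sampling on perplexity for
# small-group contrasts.

#' Iterative distribution-matched subsampling
#'
#' Draws `n_iterations` uniform random subsets of the pool, each of the
#' reference corpus's size (without replacement within a draw; draws are
#' independent across iterations), compares each candidate's word-count
#' distribution to the reference with the 1D permutation test, and returns
#' the least diverging candidate — operationalised as the one with the
#' largest permutation p-value (ties broken by smaller observed statistic,
#' then by earliest iteration). Fully reproducible under `seed`.
#'
#' @param pool a `corpus` at least as large as `reference`.
#' @param reference a `corpus` whose word-count distribution is the target.
#' @param n_iterations number of candidate subsets (>= 1).
#' @param seed integer seed.
#' @param n_permutations permutations per candidate comparison.
#' @param stat_fn optional override: `function(candidate, reference, seed)`
#'   returning `list(statistic=, p_value=)`; defaults to the word-count
#'   permutation test.
#' @return an object of class `match_result`: `selected` (the chosen
#'   sub-corpus), `candidate_stats` (data frame with `iteration`,
#'   `statistic`, `p_value`), `selected_iteration`, `seed`, `n_iterations`.
#' @export
matched_subsample <- function(pool, reference, n_iterations = 250L,
                              seed = 1L, n_permutations = 1000L,
                              stat_fn = NULL) {
  check_that(inherits(pool, "corpus") && inherits(reference, "corpus"),
             "pool and reference must be corpus objects")
  check_that(nrow(pool) >= nrow(reference),
             "pool must be at least as large as reference")
  check_that(n_iterations >= 1L, "n_iterations must be >= 1")
  k <- nrow(reference)
  if (is.null(stat_fn)) {
    ref_wc <- reference$word_count
    stat_fn <- function(candidate, reference, seed) {
      t <- permutation_test_1d(candidate$word_count, ref_wc,
                               n_permutations = n_permutations, seed = seed)
      list(statistic = t$statistic, p_value = t$p_raw)
    }
  }
  # all subset draws come from one seeded stream so the iteration count alone
  # determines which subsets are considered
  subsets <- with_seed(seed, {
    lapply(seq_len(n_iterations), function(i) sample.int(nrow(pool), k))
  })
  stats_df <- data.frame(iteration = seq_len(n_iterations),
                         statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(n_iterations)) {
    cand <- keep_corpus(pool, seq_len(nrow(pool)) %in% subsets[[i]])
    res <- stat_fn(cand, reference, child_seed(seed, i))
    stats_df$statistic[i] <- res$statistic
    stats_df$p_value[i] <- res$p_value
  }
  best <- order(-stats_df$p_value, stats_df$statistic,
                stats_df$iteration)[1L]
  structure(list(
    selected = keep_corpus(pool, seq_len(nrow(pool)) %in% subsets[[best]]),
    candidate_stats = stats_df,
    selected_iteration = best,
    seed = as.integer(seed),
    n_iterations = as.integer(n_iterations)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d candidates, selected iteration %d\n",
              x$n_iterations, x$selected_iteration))
  i <- x$selected_iteration
  cat(sprintf("  selected: n = %d, statistic = %.4g, p = %.4g\n",
              nrow(x$selected), x$candidate_stats$statistic[i],
              x$candidate_stats$p_value[i]))
  invisible(x)
}

#' Serialize a match result for audit
#'
#' Writes seed, iteration log and selected item ids as JSON.
#'
#' @param x a `match_result`.
#' @param path output path.
#' @export
write_match_result <- function(x, path) {
  jsonlite::write_json(list(
    seed = x$seed, n_iterations = x$n_iterations,
    selected_iteration = x$selected_iteration,
    selected_item_ids = x$selected$item_id,
    candidate_stats = x$candidate_stats
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Range-matched sample on perplexity
#'
#' For contrasts against a small group, draws a uniform random sample from
#' the pool restricted to records whose perplexity lies within the inclusive
#' `[min, max]` perplexity range of the target group. The sample size equals
#' the target group's size.
#'
#' @param pool a `ppl_table` (majority-group records).
#' @param target_group a `ppl_table` (small-group records) defining the range
#'   and the sample size.
#' @param seed integer seed.
#' @return a `ppl_table` subset of `pool` with `nrow(target_group)` rows.
#' @export
range_matched_sample <- function(pool, target_group, seed = 1L) {
  check_that(is.data.frame(pool) && nrow(pool) >= 1L, "pool must be nonempty")
  check_that(is.data.frame(target_group) && nrow(target_group) >= 1L,
             "target_group must be nonempty")
  rng <- range(target_group$ppl, finite = TRUE)
  eligible <- which(pool$ppl >= rng[1] & pool$ppl <= rng[2])
  if (length(eligible) == 0L) {
    stop("no pool record falls within the target perplexity range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]", call. = FALSE)
  }
  k <- nrow(target_group)
  if (length(eligible) < k) {
    stop("only ", length(eligible), " pool records fall within the target ",
         "perplexity range; cannot draw ", k, " without replacement",
         call. = FALSE)
  }
  idx <- with_seed(seed, sample(eligible, k))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pool)
  out
}
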