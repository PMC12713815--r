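# End-to-end analyses: corpus comparison and group contrasts, producing a
# classed study report with raw and Holm-adjusted p-values.

#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analyses. `holm_family` names the
#' tests whose p-values form one familywise-error family; every p-value
#' surfaced in a report belongs to exactly this family.
#'
#' @param lm the scoring `language_model`.
#' @param window a [window_config()] used for whole-corpus scoring.
#' @param lo,hi inclusive word-count filter band.
#' @param n_match_iterations candidate subsets for distribution matching.
#' @param n_permutations permutations for the 1D tests.
#' @param n_match_permutations permutations inside the matching loop (kept
#'   separate so matching can be cheaper than the final tests).
#' @param alpha nominal significance level in (0, 1) (reported, not used to
#'   gate anything).
#' @param ks_mode `"analytic"` or `"permutation"` p-value for the 2D test.
#' @param holm_family test identifiers forming the Holm family.
#' @param range_match apply perplexity-range matching for small-group
#'   contrasts (vision / clinical).
#' @param corpus_ppl also compute whole-corpus concatenated perplexities in
#'   [compare_corpora()].
#' @param seed master seed; stage seeds are derived from it.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(lm, window = window_config(512L, 512L),
                            lo = 30L, hi = 250L,
                            n_match_iterations = 250L,
                            n_permutations = 1000L,
                            n_match_permutations = 200L,
                            alpha = 0.05,
                            ks_mode = c("analytic", "permutation"),
                            holm_family = c("peacock", "ppl", "word_count"),
                            range_match = TRUE,
                            corpus_ppl = TRUE,
                            seed = 1L) {
  check_that(inherits(lm, "language_model"), "lm must be a language_model")
  check_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(
    lm = lm, window = window, lo = lo, hi = hi,
    n_match_iterations = as.integer(n_match_iterations),
    n_permutations = as.integer(n_permutations),
    n_match_permutations = as.integer(n_match_permutations),
    alpha = alpha, ks_mode = match.arg(ks_mode),
    holm_family = holm_family,
    range_match = isTRUE(range_match),
    corpus_ppl = isTRUE(corpus_ppl),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

config_hash <- function(config) {
  fields <- config[setdiff(names(config), "lm")]
  lm <- config$lm
  lm_desc <- paste(class(lm)[1], lm$vocab_size, lm$max_context,
                   if (is.null(lm$order)) "" else lm$order,
                   if (is.null(lm$alpha)) "" else lm$alpha)
  fnv1a32(paste(c(lm_desc, vapply(fields, function(f) {
    paste(deparse(f), collapse = "")
  }, character(1))), collapse = "|"))
}

# rbind two data frames on the union of their columns (NA-filled).
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (nm in setdiff(cols, names(a))) a[[nm]] <- NA
  for (nm in setdiff(cols, names(b))) b[[nm]] <- NA
  rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE])
}

new_study_report <- function(analysis, per_item, tests, group_summary,
                             corpus_ppl = NULL, config, stages = list()) {
  structure(list(
    analysis = analysis,
    per_item = per_item,
    tests = tests,
    group_summary = group_summary,
    corpus_ppl = corpus_ppl,
    alpha = config$alpha,
    holm_family = config$holm_family,
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages
  ), class = "study_report")
}

# Assemble the tests data frame and apply Holm across the declared family.
finalize_tests <- function(test_list, family) {
  df <- do.call(rbind, lapply(names(test_list), function(nm) {
    t <- test_list[[nm]]
    data.frame(test = nm, statistic_name = t$statistic_name,
               statistic = t$statistic, p_raw = t$p_raw,
               n1 = t$n1, n2 = t$n2,
               n_permutations = t$n_permutations,
               stringsAsFactors = FALSE)
  }))
  in_family <- df$test %in% family
  df$p_holm <- NA_real_
  if (any(in_family)) {
    df$p_holm[in_family] <- holm_adjust(df$p_raw[in_family])
  }
  rownames(df) <- NULL
  df
}

summarize_groups <- function(per_item, group_col) {
  groups <- split(per_item$ppl, per_item[[group_col]])
  df <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_ppl = vapply(groups, mean, numeric(1)),
    sd_ppl = vapply(groups, stats::sd, numeric(1)),
    mean_word_count = vapply(split(per_item$word_count,
                                   per_item[[group_col]]),
                             mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

run_2d_and_1d_tests <- function(p1, p2, config) {
  s1 <- cbind(p1$word_count, p1$ppl)
  s2 <- cbind(p2$word_count, p2$ppl)
  list(
    peacock = ks2d_test(s1, s2, mode = config$ks_mode,
                        n_permutations = config$n_permutations,
                        seed = child_seed(config$seed, 21L)),
    ppl = permutation_test_1d(p1$ppl, p2$ppl,
                              n_permutations = config$n_permutations,
                              seed = child_seed(config$seed, 22L)),
    word_count = permutation_test_1d(p1$word_count, p2$word_count,
                                     n_permutations = config$n_permutations,
                                     seed = child_seed(config$seed, 23L))
  )
}

#' Compare two corpora on word count and perplexity
#'
#' Runs the full corpus-comparison analysis: word-count filtering of both
#' corpora, distribution-matched subsampling of the larger corpus down to
#' the smaller one's size, per-document perplexity under the configured
#' model, the two-dimensional KS test on (word count, perplexity) pairs, 1D
#' permutation tests on perplexity and on word count, and Holm adjustment
#' across the declared family. Optionally also the whole-corpus concatenated
#' perplexity of each side.
#'
#' @param corpus_a,corpus_b two `corpus` objects.
#' @param config an [analysis_config()].
#' @return a `study_report`.
#' @export
compare_corpora <- function(corpus_a, corpus_b, config) {
  check_that(inherits(config, "analysis_config"),
             "config must be an analysis_config")
  stages <- list()
  fa <- filter_word_count(filter_nonempty(corpus_a), config$lo, config$hi)
  fb <- filter_word_count(filter_nonempty(corpus_b), config$lo, config$hi)
  check_that(nrow(fa) > 0 && nrow(fb) > 0,
             "comparison stage: both corpora empty after filtering")
  stages$filter <- c(a_in = nrow(corpus_a), a_out = nrow(fa),
                     b_in = nrow(corpus_b), b_out = nrow(fb))
  # subsample the larger corpus down to the smaller one's size
  if (nrow(fa) > nrow(fb)) {
    mr <- matched_subsample(fa, fb, config$n_match_iterations,
                            seed = child_seed(config$seed, 11L),
                            n_permutations = config$n_match_permutations)
    fa <- mr$selected
    stages$match <- c(side = "a", p = mr$candidate_stats$p_value[
      mr$selected_iteration])
  } else if (nrow(fb) > nrow(fa)) {
    mr <- matched_subsample(fb, fa, config$n_match_iterations,
                            seed = child_seed(config$seed, 11L),
                            n_permutations = config$n_match_permutations)
    fb <- mr$selected
    stages$match <- c(side = "b", p = mr$candidate_stats$p_value[
      mr$selected_iteration])
  }
  pa <- ppl_per_item(fa, config$lm)
  pb <- ppl_per_item(fb, config$lm)
  pa <- pa[!pa$flagged & is.finite(pa$ppl), , drop = FALSE]
  pb <- pb[!pb$flagged & is.finite(pb$ppl), , drop = FALSE]
  check_that(nrow(pa) > 0 && nrow(pb) > 0,
             "scoring stage: no finite perplexities")
  pa$side <- "a"
  pb$side <- "b"
  tests <- finalize_tests(run_2d_and_1d_tests(pa, pb, config),
                          config$holm_family)
  per_item <- rbind_fill(pa, pb)
  class(per_item) <- c("ppl_table", "data.frame")
  corpus_ppl <- NULL
  if (config$corpus_ppl) {
    corpus_ppl <- data.frame(
      side = c("a", "b"),
      ppl = c(ppl_corpus_concat(fa, config$lm, config$window)$ppl,
              ppl_corpus_concat(fb, config$lm, config$window)$ppl)
    )
  }
  new_study_report("corpus comparison", per_item, tests,
                   summarize_groups(per_item, "side"),
                   corpus_ppl = corpus_ppl, config = config,
                   stages = stages)
}

#' Two-group contrast within one corpus
#'
#' Splits the scored documents by a metadata field with exactly two
#' non-missing levels and tests the groups on (word count, perplexity): the
#' 2D KS test, a 1D permutation test on perplexity, and a 1D permutation
#' test on word count, Holm-adjusted across the family. For the small-group
#' contrasts (`vision`, `clinical`) the majority group is first reduced by
#' [range_matched_sample()] to the minority group's perplexity range and
#' size (disable with `config$range_match = FALSE`).
#'
#' @param corpus a `corpus` carrying the grouping field.
#' @param group_field one of `"gender"`, `"vision"`, `"clinical"`, `"group"`.
#' @param ppl_records optional precomputed `ppl_table` for `corpus`; computed
#'   with the configured model when omitted.
#' @param config an [analysis_config()].
#' @return a `study_report`.
#' @export
group_analysis <- function(corpus, group_field, ppl_records = NULL, config) {
  check_that(inherits(config, "analysis_config"),
             "config must be an analysis_config")
  check_that(group_field %in% names(corpus),
             paste0("corpus has no '", group_field, "' field"))
  if (is.null(ppl_records)) ppl_records <- ppl_per_item(corpus, config$lm)
  rec <- ppl_records[!ppl_records$flagged & is.finite(ppl_records$ppl), ,
                     drop = FALSE]
  g <- rec[[group_field]]
  rec <- rec[!is.na(g), , drop = FALSE]
  levels <- unique(rec[[group_field]])
  check_that(length(levels) == 2L,
             paste0("group field '", group_field,
                    "' must have exactly 2 non-missing levels, found ",
                    length(levels)))
  n_by <- table(rec[[group_field]])
  minority <- names(n_by)[which.min(n_by)]
  majority <- setdiff(names(n_by), minority)[1]
  p_min <- rec[rec[[group_field]] == minority, , drop = FALSE]
  p_maj <- rec[rec[[group_field]] == majority, , drop = FALSE]
  stages <- list(groups = c(minority = nrow(p_min), majority = nrow(p_maj)))
  if (config$range_match && group_field %in% c("vision", "clinical")) {
    p_maj <- range_matched_sample(p_maj, p_min,
                                  seed = child_seed(config$seed, 31L))
    stages$range_match <- c(majority_after = nrow(p_maj))
  }
  tests <- finalize_tests(run_2d_and_1d_tests(p_min, p_maj, config),
                          config$holm_family)
  per_item <- rbind(p_min, p_maj)  # same source table, columns align
  class(per_item) <- c("ppl_table", "data.frame")
  new_study_report(paste0("group contrast: ", group_field,
                          " (", minority, " vs ", majority, ")"),
                   per_item, tests,
                   summarize_groups(per_item, group_field),
                   config = config, stages = stages)
}

#' Spearman correlation of collection year with perplexity
#'
#' Documents without a parsed year are excluded; at least three dated,
#' finitely scored documents are required.
#'
#' @param corpus a `corpus` with a `year_mid` column (see [convert_year()]).
#' @param ppl_records a `ppl_table` for the corpus.
#' @return list with `rho`, `p`, `n`.
#' @export
year_correlation <- function(corpus, ppl_records) {
  check_that("year_mid" %in% names(corpus),
             "corpus has no year_mid column; parse year_raw first")
  idx <- match(ppl_records$item_id, corpus$item_id)
  year <- as.numeric(corpus$year_mid[idx])
  ok <- !is.na(year) & is.finite(ppl_records$ppl)
  check_that(sum(ok) >= 3L, "need at least 3 dated, scored documents")
  spearman(year[ok], ppl_records$ppl[ok])
}

#' Spearman correlation of word count with perplexity
#'
#' @param ppl_records a `ppl_table` with `word_count` and `ppl` columns.
#' @return list with `rho`, `p`, `n`.
#' @export
length_correlation <- function(ppl_records) {
  ok <- is.finite(ppl_records$ppl) & is.finite(ppl_records$word_count)
  check_that(sum(ok) >= 3L, "need at least 3 scored documents")
  spearman(ppl_records$word_count[ok], ppl_records$ppl[ok])
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report —", x$analysis, "\n")
  cat(sprintf("  %d scored documents; seed %d; config %s\n",
              nrow(x$per_item), x$seed, x$config_hash))
  cat("\nGroup summary:\n")
  print(x$group_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$corpus_ppl)) {
    cat("\nWhole-corpus perplexity:\n")
    print(x$corpus_ppl, row.names = FALSE, digits = 4)
  }
  cat("\nTests (Holm family:", paste(x$holm_family, collapse = ", "), "):\n")
  print(x$tests[, c("test", "statistic", "p_raw", "p_holm")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  sig <- object$tests$p_holm < object$alpha
  sig[is.na(sig)] <- FALSE
  cat(sprintf("\n%d of %d family tests significant at alpha = %g (Holm)\n",
              sum(sig), sum(!is.na(object$tests$p_holm)), object$alpha))
  invisible(object)
}

#' Plot mean perplexity against word count
#'
#' Binned mean-and-standard-error curves of per-document perplexity by word
#' count, one curve per side/group, in base graphics.
#'
#' @param x a `study_report`.
#' @param bins number of word-count bins.
#' @param ... passed to `plot`.
#' @export
plot.study_report <- function(x, bins = 20L, ...) {
  per <- x$per_item
  group_col <- if ("side" %in% names(per)) "side" else {
    setdiff(names(per), c("item_id", "ppl", "n_scored_tokens", "flagged",
                          "word_count", "source"))[1]
  }
  groups <- unique(per[[group_col]])
  brks <- pretty(per$word_count, n = bins)
  cols <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728")
  graphics::plot(NULL, xlim = range(per$word_count),
                 ylim = range(per$ppl, finite = TRUE),
                 xlab = "word count", ylab = "perplexity", ...)
  for (gi in seq_along(groups)) {
    sub <- per[per[[group_col]] == groups[gi], , drop = FALSE]
    bin <- cut(sub$word_count, brks, include.lowest = TRUE)
    mids <- (brks[-1] + brks[-length(brks)]) / 2
    mu <- tapply(sub$ppl, bin, mean)
    se <- tapply(sub$ppl, bin, function(v) {
      stats::sd(v) / sqrt(length(v))
    })
    ok <- !is.na(mu)
    graphics::lines(mids[ok], mu[ok], col = cols[gi], lwd = 2)
    graphics::arrows(mids[ok], (mu - se)[ok], mids[ok], (mu + se)[ok],
                     angle = 90, code = 3, length = 0.02, col = cols[gi])
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Serialize a study report as JSON
#'
#' Deterministic given the configuration and seed: one config + seed yields
#' byte-identical output.
#'
#' @param x a `study_report`.
#' @param path output path.
#' @export
write_study_report <- function(x, path) {
  jsonlite::write_json(list(
    analysis = x$analysis,
    seed = x$seed, config_hash = x$config_hash, alpha = x$alpha,
    holm_family = x$holm_family,
    group_summary = x$group_summary,
    corpus_ppl = x$corpus_ppl,
    tests = x$tests,
    per_item = x$per_item,
    stages = x$stages
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
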