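# Perplexity scoring: single-window, strided sliding-window, whole-corpus
# concatenation, and per-item tables.
#
# Perplexity of a token sequence x_1..x_N under model p is
#   PPL = exp( -(1/N) * sum_i log p(x_i | x_{<i}) ),
# natural log throughout. Every token is scored, the first one conditioned on
# start-symbol padding supplied by the model. Zero-probability events yield an
# infinite perplexity carried as a flagged record rather than an error.

#' Sliding-window configuration
#'
#' @param max_length window size in tokens (context plus target).
#' @param stride window advance in tokens; `1 <= stride <= max_length`.
#' @return an object of class `window_config`.
#' @export
window_config <- function(max_length = 512L, stride = 512L) {
  check_that(is.numeric(max_length) && max_length >= 1,
             "max_length must be a positive integer")
  check_that(is.numeric(stride) && stride >= 1 && stride <= max_length,
             "stride must satisfy 1 <= stride <= max_length")
  structure(list(max_length = as.integer(max_length),
                 stride = as.integer(stride)),
            class = "window_config")
}

as_token_sequence <- function(x, lm) {
  if (is.character(x) && length(x) == 1L && !is.na(x)) {
    lm$tokenize(x)
  } else if (is.character(x)) {
    x
  } else {
    stop("expected a token character vector or a single text string",
         call. = FALSE)
  }
}

new_ppl_record <- function(item_id, ppl, n_scored_tokens, mode,
                           window = NULL, flagged = FALSE,
                           n_windows = NA_integer_,
                           n_input_tokens = NA_integer_) {
  structure(list(
    item_id = item_id, ppl = ppl, n_scored_tokens = n_scored_tokens,
    mode = mode,
    max_length = if (is.null(window)) NA_integer_ else window$max_length,
    stride = if (is.null(window)) NA_integer_ else window$stride,
    flagged = flagged, n_windows = n_windows,
    n_input_tokens = n_input_tokens
  ), class = "ppl_record")
}

#' @export
print.ppl_record <- function(x, ...) {
  cat(sprintf("<ppl_record %s> ppl = %.4f over %d tokens (%s mode)%s\n",
              x$item_id, x$ppl, x$n_scored_tokens, x$mode,
              if (isTRUE(x$flagged)) " [zero-probability event]" else ""))
  invisible(x)
}

#' Perplexity of a single sequence in one window
#'
#' Scores every token of the sequence conditioned on all preceding in-sequence
#' tokens (the model pads with its start symbol where the context is shorter
#' than its order needs) and returns the exponentiated mean negative
#' log-likelihood.
#'
#' @param seq token character vector, or a single text string to be tokenized
#'   by the model.
#' @param lm a `language_model`.
#' @param item_id identifier stored in the record.
#' @return a `ppl_record` with `mode = "single"`. A zero-probability token
#'   gives `ppl = Inf` with `flagged = TRUE`.
#' @examples
#' ppl_single(c("w1", "w2", "w3"), make_uniform_lm(4))$ppl  # 4
#' @export
ppl_single <- function(seq, lm, item_id = "seq") {
  tokens <- as_token_sequence(seq, lm)
  check_that(length(tokens) >= 1L, "sequence must contain at least one token")
  if (length(tokens) > lm$max_context) {
    stop("sequence of ", length(tokens), " tokens exceeds max_context (",
         lm$max_context, "); use ppl_strided()", call. = FALSE)
  }
  # accumulate exactly as the strided scorer does, so the single-window
  # reduction is bit-identical
  total_nll <- 0
  flagged <- FALSE
  for (i in seq_along(tokens)) {
    lp <- lm$log_prob(tokens[i], tokens[seq_len(i - 1L)])
    if (!is.finite(lp)) flagged <- TRUE
    total_nll <- total_nll - lp
  }
  new_ppl_record(item_id, exp(total_nll / length(tokens)), length(tokens),
                 "single", flagged = flagged,
                 n_windows = 1L, n_input_tokens = length(tokens))
}

#' Strided sliding-window perplexity
#'
#' Evaluates a long sequence in fixed-size windows of `max_length` tokens
#' advanced by `stride` tokens. Within each window only tokens not scored by
#' a previous window contribute, each conditioned on all preceding tokens
#' inside the window (the first window additionally sees start-symbol
#' padding). The total negative log-likelihood is divided by the total number
#' of scored tokens — every token of the sequence — and exponentiated. When
#' the sequence fits in one window the result equals [ppl_single()] exactly.
#'
#' @inheritParams ppl_single
#' @param window a [window_config()].
#' @return a `ppl_record` with `mode = "strided"`; `n_windows` and
#'   `n_input_tokens` record the evaluation cost (tokens fed across windows),
#'   which decreases as the stride grows.
#' @export
ppl_strided <- function(seq, lm, window = window_config(), item_id = "seq") {
  tokens <- as_token_sequence(seq, lm)
  check_that(length(tokens) >= 1L, "sequence must contain at least one token")
  check_that(inherits(window, "window_config"), "window must be window_config")
  L <- min(window$max_length, lm$max_context)
  s <- min(window$stride, L)
  n <- length(tokens)
  total_nll <- 0
  flagged <- FALSE
  prev_end <- 0L
  begin <- 1L
  n_windows <- 0L
  n_input <- 0L
  while (prev_end < n) {
    end <- min(begin + L - 1L, n)
    for (i in (prev_end + 1L):end) {
      ctx <- if (i > begin) tokens[begin:(i - 1L)] else character(0)
      lp <- lm$log_prob(tokens[i], ctx)
      if (!is.finite(lp)) flagged <- TRUE
      total_nll <- total_nll - lp
    }
    n_windows <- n_windows + 1L
    n_input <- n_input + (end - begin + 1L)
    prev_end <- end
    begin <- begin + s
  }
  new_ppl_record(item_id, exp(total_nll / n), n, "strided",
                 window = window, flagged = flagged,
                 n_windows = n_windows, n_input_tokens = n_input)
}

#' Whole-corpus perplexity by concatenation
#'
#' Concatenates all documents of a corpus into one long token sequence — with
#' a single newline token between consecutive documents — and scores it with
#' [ppl_strided()]. This is the "corpus considered as a single string"
#' summary number. The separator token is mapped to the model's unknown
#' symbol unless the vocabulary contains it.
#'
#' @param items a `corpus` object or character vector of documents.
#' @param lm a `language_model`.
#' @param window a [window_config()].
#' @param sep separator token inserted between documents.
#' @return a `ppl_record` with `item_id = "corpus"`.
#' @export
ppl_corpus_concat <- function(items, lm, window = window_config(),
                              sep = "\n") {
  texts <- if (inherits(items, "corpus")) items$text else items
  check_that(length(texts) >= 1L, "corpus must be nonempty")
  tok_lists <- lapply(texts, lm$tokenize)
  tok_lists <- tok_lists[lengths(tok_lists) > 0L]
  check_that(length(tok_lists) >= 1L, "corpus contains no tokens")
  joined <- tok_lists[[1L]]
  if (length(tok_lists) > 1L) {
    for (k in 2L:length(tok_lists)) joined <- c(joined, sep, tok_lists[[k]])
  }
  ppl_strided(joined, lm, window, item_id = "corpus")
}

#' Per-document perplexity table
#'
#' Scores each document of a corpus independently with [ppl_single()]
#' (single-window mode: the documents are assumed to fit within the model's
#' maximum context, as dream reports and short articles do). Documents whose
#' token count exceeds the maximum context are recorded as flagged `NA`
#' entries; the remaining documents are still scored. Order is preserved.
#'
#' @param items a `corpus` object (word counts and metadata are carried into
#'   the result) or a character vector of documents.
#' @param lm a `language_model`.
#' @param window reserved for future strided per-item scoring; only recorded.
#' @return a `data.frame` of class `ppl_table` with columns `item_id`, `ppl`,
#'   `n_scored_tokens`, `word_count`, `flagged`, plus any corpus metadata
#'   columns (`gender`, `year_mid`, ...).
#' @export
ppl_per_item <- function(items, lm, window = NULL) {
  is_corpus <- inherits(items, "corpus")
  texts <- if (is_corpus) items$text else items
  ids <- if (is_corpus) items$item_id else {
    paste0("item", seq_along(texts))
  }
  check_that(length(texts) >= 1L, "corpus must be nonempty")
  rows <- lapply(seq_along(texts), function(k) {
    toks <- lm$tokenize(texts[k])
    if (length(toks) == 0L) {
      return(data.frame(item_id = ids[k], ppl = NA_real_,
                        n_scored_tokens = 0L, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    if (length(toks) > lm$max_context) {
      return(data.frame(item_id = ids[k], ppl = NA_real_,
                        n_scored_tokens = length(toks), flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    r <- ppl_single(toks, lm, item_id = ids[k])
    data.frame(item_id = ids[k], ppl = r$ppl,
               n_scored_tokens = r$n_scored_tokens, flagged = r$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$word_count <- count_words(texts)
  if (is_corpus) {
    meta <- items[, setdiff(names(items), c("text", "word_count")),
                  drop = FALSE]
    meta <- meta[, setdiff(names(meta), names(out)), drop = FALSE]
    out <- cbind(out, as.data.frame(meta, stringsAsFactors = FALSE))
  }
  class(out) <- c("ppl_table", "data.frame")
  out
}

#' Write / read per-item perplexity records as JSON-lines
#'
#' One JSON object per line with the record fields; round-trips a
#' `ppl_table`.
#'
#' @param records a `ppl_table`.
#' @param path file path.
#' @export
write_ppl_records <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, , drop = FALSE]), auto_unbox = TRUE,
                     digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ppl_records
#' @export
read_ppl_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    obj[vapply(obj, is.null, logical(1))] <- NA
    as.data.frame(obj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ppl_table", "data.frame")
  out
}
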