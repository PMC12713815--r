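# Language-model contract and the self-contained reference models.
#
# Every model is an S3 object of class "language_model" exposing:
#   vocab        character vector of scorable symbols (includes the reserved
#                unknown symbol; never the start symbol)
#   vocab_size   length(vocab)
#   max_context  maximum number of tokens a conditional may see
#   log_prob     function(target, context) -> natural-log probability
#   tokenize     deterministic function(text) -> token character vector
#   bos          start-of-sequence symbol used only as context padding
#   unk          reserved unknown symbol, part of vocab
#
# All probabilities are natural-log. For any fixed context the conditional
# distribution over `vocab` sums to one; the start symbol is never a target.

BOS_TOKEN <- "<s>"
UNK_TOKEN <- "unk"
EOS_TOKEN <- "<eos>"

new_language_model <- function(vocab, max_context, log_prob, tokenize,
                               bos = BOS_TOKEN, unk = UNK_TOKEN,
                               subclass = character(0), extra = list()) {
  check_that(is.character(vocab) && length(vocab) >= 1L,
             "vocab must be a nonempty character vector")
  check_that(is.function(log_prob), "log_prob must be a function")
  check_that(is.function(tokenize), "tokenize must be a function")
  check_that(is.numeric(max_context) && max_context >= 1,
             "max_context must be a positive integer")
  lm <- c(list(
    vocab = vocab,
    vocab_size = length(vocab),
    max_context = as.integer(max_context),
    log_prob = log_prob,
    tokenize = tokenize,
    bos = bos,
    unk = unk
  ), extra)
  class(lm) <- c(subclass, "language_model")
  lm
}

#' Uniform language model
#'
#' A model assigning probability `1/vocab_size` to every target regardless of
#' context. Its perplexity on any sequence equals `vocab_size` exactly, which
#' makes it the analytic anchor for the scoring machinery.
#'
#' @param vocab_size number of symbols in the vocabulary (>= 1).
#' @param max_context maximum context length in tokens.
#' @return an object of class `c("uniform_lm", "language_model")`.
#' @examples
#' lm <- make_uniform_lm(4)
#' exp(lm$log_prob("w1", c("w2", "w3")))  # 0.25
#' @export
make_uniform_lm <- function(vocab_size, max_context = 1024L) {
  check_that(is.numeric(vocab_size) && length(vocab_size) == 1L &&
               vocab_size >= 1, "vocab_size must be >= 1")
  vocab_size <- as.integer(vocab_size)
  vocab <- if (vocab_size == 1L) UNK_TOKEN else {
    c(paste0("w", seq_len(vocab_size - 1L)), UNK_TOKEN)
  }
  lp <- -log(vocab_size)
  new_language_model(
    vocab = vocab, max_context = max_context,
    log_prob = function(target, context = character(0)) lp,
    tokenize = ppl_tokenize,
    subclass = "uniform_lm",
    extra = list(next_dist = function(context = character(0)) {
      stats::setNames(rep(1 / vocab_size, vocab_size), vocab)
    })
  )
}

# Map tokens outside the model vocabulary to the reserved unknown symbol.
map_unk <- function(tokens, vocab_env, unk, bos) {
  if (length(tokens) == 0L) return(tokens)
  known <- vapply(tokens, function(t) {
    t == bos || !is.null(vocab_env[[t]])
  }, logical(1), USE.NAMES = FALSE)
  tokens[!known] <- unk
  tokens
}

# Context keys carry a "k" prefix so the empty (order-1) context is a valid
# environment key.
ngram_context_key <- function(tokens, order, bos) {
  if (order == 1L) return("k")
  n <- length(tokens)
  ctx <- if (n >= order - 1L) tokens[(n - order + 2L):n] else {
    c(rep(bos, order - 1L - n), tokens)
  }
  paste0("k", paste(ctx, collapse = "\x1f"))
}

#' Fit an additively smoothed n-gram language model
#'
#' Estimates conditional next-token probabilities
#' \deqn{p(t \mid c) = \frac{n(c, t) + \alpha}{n(c) + \alpha V}}
#' from a training corpus, where \eqn{n(c, t)} counts occurrences of target
#' `t` after context `c`, \eqn{n(c)} counts occurrences of the context,
#' \eqn{\alpha} is the additive smoothing mass and \eqn{V} the vocabulary
#' size. Each document is padded with `order - 1` start symbols so the first
#' real token has a defined conditional, and closed with an end-of-sequence
#' symbol, so document-final contexts keep proper conditionals: the context
#' count equals the sum of its continuation counts and every conditional
#' distribution over the vocabulary sums to one exactly. Tokens absent from
#' the training vocabulary are mapped to a reserved unknown symbol that is
#' part of the vocabulary (as are the end symbol, but never the start
#' symbol). With `alpha = 0` an unseen (context, target) event scores `-Inf`
#' log-probability; downstream scoring flags rather than aborts on such
#' events.
#'
#' This model family is the package's self-contained stand-in for large
#' pretrained autoregressive models: it honours the same scoring contract at
#' desk scale.
#'
#' @param corpus a `corpus` object (see [read_corpus()]), or a character
#'   vector of documents.
#' @param order n-gram order (>= 1); the conditional sees `order - 1` tokens.
#' @param alpha additive smoothing mass (>= 0). Must be positive if the model
#'   will score events unseen in training.
#' @param vocab optional explicit vocabulary; defaults to all training tokens
#'   plus the unknown symbol.
#' @param max_context maximum context length accepted by the scoring contract.
#' @return an object of class `c("ngram_lm", "language_model")`.
#' @examples
#' lm <- fit_ngram_lm(c("a b a b a"), order = 2, alpha = 0)
#' exp(lm$log_prob("b", "a"))  # 2/3
#' @export
fit_ngram_lm <- function(corpus, order = 2L, alpha = 1,
                         vocab = NULL, max_context = 1024L) {
  texts <- if (inherits(corpus, "corpus")) corpus$text else corpus
  check_that(is.character(texts) && length(texts) >= 1L,
             "corpus must be nonempty")
  check_that(is.numeric(order) && order >= 1L, "order must be >= 1")
  check_that(is.numeric(alpha) && alpha >= 0, "alpha must be nonnegative")
  order <- as.integer(order)

  tok_lists <- lapply(texts, ppl_tokenize)
  check_that(sum(lengths(tok_lists)) > 0L,
             "corpus must contain at least one token")
  if (is.null(vocab)) vocab <- sort(unique(unlist(tok_lists)))
  vocab <- setdiff(vocab, c(BOS_TOKEN, EOS_TOKEN, UNK_TOKEN))
  vocab <- c(vocab, UNK_TOKEN, EOS_TOKEN)
  vocab_env <- new.env(hash = TRUE, parent = emptyenv())
  for (v in vocab) vocab_env[[v]] <- TRUE

  # Accumulate (context, target) and context counts over all documents.
  all_pairs <- character(0)
  all_ctx <- character(0)
  for (toks in tok_lists) {
    if (length(toks) == 0L) next
    toks <- map_unk(toks, vocab_env, UNK_TOKEN, BOS_TOKEN)
    padded <- c(rep(BOS_TOKEN, order - 1L), toks, EOS_TOKEN)
    m <- length(padded)
    targets <- padded[order:m]
    ctx_key <- if (order == 1L) rep("k", length(targets)) else {
      cols <- lapply(seq_len(order - 1L) - 1L, function(j) {
        padded[(1L + j):(m - order + 1L + j)]
      })
      paste0("k", do.call(paste, c(cols, sep = "\x1f")))
    }
    all_pairs <- c(all_pairs, paste(ctx_key, targets, sep = "\x1f"))
    all_ctx <- c(all_ctx, ctx_key)
  }
  pair_tab <- table(all_pairs)
  ctx_tab <- table(all_ctx)
  pair_env <- list2env(as.list(pair_tab), hash = TRUE, parent = emptyenv())
  ctx_env <- list2env(as.list(ctx_tab), hash = TRUE, parent = emptyenv())
  rebuild_ngram_lm(vocab, order, alpha, max_context, pair_env, ctx_env)
}

#' Wrap a pretrained external language model behind the scoring contract
#'
#' Adapter for pretrained autoregressive models (for example GPT-2-family
#' checkpoints served by a host ML runtime). The adapter itself carries no
#' weights: a loader must be registered via
#' `options(dreamppl.lm_loader = function(model_name, device) ...)` and must
#' return a list with fields `vocab` (or `vocab_size`), `max_context`,
#' `log_prob` and `tokenize`. Absent weights or an unregistered loader fail
#' loudly; the adapter never silently substitutes another model. The wrapped
#' `log_prob` enforces the contract at call time: contexts longer than
#' `max_context` and positive log-probabilities raise contract-violation
#' errors.
#'
#' @param model_name identifier understood by the registered loader.
#' @param device device identifier passed through to the loader.
#' @return an object of class `c("external_lm", "language_model")`.
#' @export
external_lm_adapter <- function(model_name, device = "cpu") {
  loader <- getOption("dreamppl.lm_loader")
  if (is.null(loader)) {
    stop("no external language-model loader registered; set ",
         "options(dreamppl.lm_loader = ...) to a function resolving ",
         "pretrained weights. Refusing to substitute a different model.",
         call. = FALSE)
  }
  raw <- loader(model_name, device)
  check_that(is.list(raw) && is.function(raw[["log_prob"]]) &&
               is.function(raw[["tokenize"]]),
             paste0("loader for '", model_name,
                    "' did not return a log_prob/tokenize pair"))
  vocab <- raw[["vocab"]]
  if (is.null(vocab)) {
    check_that(is.numeric(raw[["vocab_size"]]) && raw[["vocab_size"]] >= 1,
               "loader must supply vocab or vocab_size")
    vocab <- c(paste0("w", seq_len(raw[["vocab_size"]] - 1L)), UNK_TOKEN)
  }
  max_context <- raw[["max_context"]]
  check_that(is.numeric(max_context) && max_context >= 1,
             "loader must supply the model's maximum sequence length")
  inner_lp <- raw[["log_prob"]]
  guarded_lp <- function(target, context = character(0)) {
    if (length(context) + 1L > max_context) {
      stop("contract violation: context plus target exceeds max_context (",
           max_context, " tokens); use strided scoring", call. = FALSE)
    }
    lp <- inner_lp(target, context)
    if (!is.na(lp) && lp > 1e-12) {
      stop("contract violation: external model returned a positive ",
           "log-probability", call. = FALSE)
    }
    lp
  }
  new_language_model(
    vocab = vocab, max_context = max_context,
    log_prob = guarded_lp, tokenize = raw[["tokenize"]],
    bos = if (is.null(raw[["bos"]])) BOS_TOKEN else raw[["bos"]],
    subclass = "external_lm",
    extra = list(model_name = model_name, device = device)
  )
}

#' @export
print.language_model <- function(x, ...) {
  kind <- setdiff(class(x), "language_model")[1]
  cat("<language_model:", kind, ">\n")
  cat("  vocabulary size:", x$vocab_size, "\n")
  cat("  max context    :", x$max_context, "tokens\n")
  if (!is.null(x$order)) cat("  n-gram order   :", x$order,
                             " (alpha =", x$alpha, ")\n")
  if (!is.null(x$model_name)) cat("  external model :", x$model_name, "\n")
  invisible(x)
}

#' Next-token distribution of a language model
#'
#' @param object a `language_model`.
#' @param context character vector of preceding tokens (not raw text).
#' @param ... unused.
#' @return named numeric vector of next-token probabilities over the model
#'   vocabulary (sums to one).
#' @export
predict.language_model <- function(object, context = character(0), ...) {
  if (!is.null(object$next_dist)) return(object$next_dist(context))
  p <- vapply(object$vocab, function(t) exp(object$log_prob(t, context)),
              numeric(1))
  stats::setNames(p, object$vocab)
}

#' Sample text from a language model
#'
#' Generates `nsim` documents of `length` tokens each by ancestral sampling
#' from the model's conditional distributions, starting from start-symbol
#' padding. Tokens are joined with single spaces.
#'
#' @param object a `language_model` exposing a next-token distribution.
#' @param nsim number of documents.
#' @param seed integer seed (required for reproducibility).
#' @param length token count per document (scalar or vector of length `nsim`).
#' @param ... unused.
#' @return character vector of `nsim` documents.
#' @export
simulate.language_model <- function(object, nsim = 1, seed = 1L,
                                    length = 50L, ...) {
  lens <- rep_len(as.integer(length), nsim)
  with_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      toks <- character(lens[i])
      ctx <- character(0)
      for (j in seq_len(lens[i])) {
        p <- predict(object, ctx)
        # fixed-length sampling conditions on non-termination
        p <- p[names(p) != EOS_TOKEN]
        toks[j] <- sample(names(p), 1L, prob = p)
        ctx <- c(ctx, toks[j])
      }
      paste(toks, collapse = " ")
    }, character(1))
  })
}

#' Serialize / restore an n-gram language model as JSON
#'
#' Writes the vocabulary, order, smoothing mass and the raw
#' (context, target) count tables to a JSON file, and restores an equivalent
#' model. Round-tripping preserves `log_prob` exactly.
#'
#' @param lm an `ngram_lm`.
#' @param path file path.
#' @return `write_ngram_lm` returns `path` invisibly; `read_ngram_lm` returns
#'   an `ngram_lm`.
#' @export
write_ngram_lm <- function(lm, path) {
  check_that(inherits(lm, "ngram_lm"), "lm must be an ngram_lm")
  obj <- list(
    vocab = lm$vocab, order = lm$order, alpha = lm$alpha,
    max_context = lm$max_context,
    pair_counts = as.list(lm$.pair_env),
    ctx_counts = as.list(lm$.ctx_env)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ngram_lm
#' @export
read_ngram_lm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pair_env <- list2env(as.list(obj$pair_counts), hash = TRUE,
                       parent = emptyenv())
  ctx_env <- list2env(as.list(obj$ctx_counts), hash = TRUE,
                      parent = emptyenv())
  rebuild_ngram_lm(obj$vocab, obj$order, obj$alpha, obj$max_context,
                   pair_env, ctx_env)
}

# Build an ngram_lm directly from count environments (used by read_ngram_lm).
rebuild_ngram_lm <- function(vocab, order, alpha, max_context,
                             pair_env, ctx_env) {
  vocab_env <- new.env(hash = TRUE, parent = emptyenv())
  for (v in vocab) vocab_env[[v]] <- TRUE
  V <- length(vocab)
  lookup_counts <- function(context) {
    context <- map_unk(context, vocab_env, UNK_TOKEN, BOS_TOKEN)
    key <- ngram_context_key(context, order, BOS_TOKEN)
    tot <- ctx_env[[key]]
    list(key = key, total = if (is.null(tot)) 0 else as.numeric(tot))
  }
  log_prob <- function(target, context = character(0)) {
    if (is.null(vocab_env[[target]])) target <- UNK_TOKEN
    cc <- lookup_counts(context)
    cnt <- pair_env[[paste(cc$key, target, sep = "\x1f")]]
    cnt <- if (is.null(cnt)) 0 else as.numeric(cnt)
    num <- cnt + alpha
    if (num == 0) return(-Inf)
    log(num) - log(cc$total + alpha * V)
  }
  next_dist <- function(context = character(0)) {
    cc <- lookup_counts(context)
    cnt <- vapply(vocab, function(t) {
      x <- pair_env[[paste(cc$key, t, sep = "\x1f")]]
      if (is.null(x)) 0 else as.numeric(x)
    }, numeric(1))
    p <- (cnt + alpha) / (cc$total + alpha * V)
    if (all(!is.finite(p)) || sum(p) == 0) p <- rep(1 / V, V)
    stats::setNames(p, vocab)
  }
  new_language_model(
    vocab = vocab, max_context = max_context,
    log_prob = log_prob, tokenize = ppl_tokenize,
    subclass = "ngram_lm",
    extra = list(order = as.integer(order), alpha = alpha,
                 next_dist = next_dist,
                 .pair_env = pair_env, .ctx_env = ctx_env)
  )
}
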