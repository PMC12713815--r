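# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops, direct formulas, no environments or keys.

# Additive-smoothed n-gram probability computed directly from token lists.
# Convention under test: each document is padded with (order-1) start symbols
# and closed with an end symbol; context counts are occurrence counts of the
# (order-1)-gram, so they equal the sum of continuation counts.
oracle_ngram_prob <- function(train_tok_lists, order, alpha, vocab,
                              target, context) {
  bos <- "<s>"
  eos <- "<eos>"
  unk <- "unk"
  map <- function(t) ifelse(t %in% c(vocab, bos), t, unk)
  ctx <- map(context)
  ctx <- if (length(ctx) >= order - 1) {
    utils::tail(ctx, order - 1)
  } else {
    c(rep(bos, order - 1 - length(ctx)), ctx)
  }
  tgt <- map(target)
  n_pair <- 0
  n_ctx <- 0
  for (toks in train_tok_lists) {
    padded <- c(rep(bos, order - 1), map(toks), eos)
    for (i in seq_len(length(padded) - order + 1)) {
      window <- padded[i:(i + order - 1)]
      this_ctx <- window[seq_len(order - 1)]
      if (order == 1 || all(this_ctx == ctx)) {
        n_ctx <- n_ctx + 1
        if (window[order] == tgt) n_pair <- n_pair + 1
      }
    }
  }
  (n_pair + alpha) / (n_ctx + alpha * length(vocab))
}

# Direct single-window perplexity from a log-probability function.
oracle_ppl <- function(tokens, log_prob) {
  nll <- numeric(length(tokens))
  for (i in seq_along(tokens)) {
    ctx <- if (i == 1) character(0) else tokens[1:(i - 1)]
    nll[i] <- -log_prob(tokens[i], ctx)
  }
  exp(sum(nll) / length(tokens))
}

# Strided-window perplexity by explicit window enumeration: windows start at
# 1, 1+s, 1+2s, ...; a token is scored in the first window containing it,
# conditioned on the tokens of that window that precede it.
oracle_ppl_strided <- function(tokens, log_prob, max_length, stride) {
  n <- length(tokens)
  starts <- seq(1, max(n, 1), by = stride)
  scored <- rep(FALSE, n)
  total <- 0
  for (b in starts) {
    e <- min(b + max_length - 1, n)
    for (i in b:e) {
      if (!scored[i]) {
        ctx <- if (i == b) character(0) else tokens[b:(i - 1)]
        total <- total - log_prob(tokens[i], ctx)
        scored[i] <- TRUE
      }
    }
    if (e == n) break
  }
  exp(total / n)
}

# Two-dimensional KS statistic by double loop over every point and the four
# closed-lower/left quadrants.
oracle_ks2d <- function(s1, s2) {
  frac <- function(s, cx, cy, qx, qy) {
    cnt <- 0
    for (i in seq_len(nrow(s))) {
      in_x <- if (qx == "le") s[i, 1] <= cx else s[i, 1] > cx
      in_y <- if (qy == "le") s[i, 2] <= cy else s[i, 2] > cy
      if (in_x && in_y) cnt <- cnt + 1
    }
    cnt / nrow(s)
  }
  dmax <- function(centers) {
    m <- 0
    for (i in seq_len(nrow(centers))) {
      for (qx in c("le", "gt")) {
        for (qy in c("le", "gt")) {
          d <- abs(frac(s1, centers[i, 1], centers[i, 2], qx, qy) -
                     frac(s2, centers[i, 1], centers[i, 2], qx, qy))
          if (d > m) m <- d
        }
      }
    }
    m
  }
  (dmax(s1) + dmax(s2)) / 2
}

# Exhaustive two-sample permutation p-value for the absolute mean difference
# (enumerates every assignment of the pooled values to group 1).
oracle_perm_exhaustive <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx_sets <- utils::combn(length(pool), n1)
  stats <- apply(idx_sets, 2, function(idx) {
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  mean(stats >= obs)
}

# Closed-form Holm step-down computed by an explicit loop.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Spearman rho from the explicit average-rank formula.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small random training corpus for n-gram fitting in property tests.
random_toy_corpus <- function(n_docs, vocab_size, len_range, seed) {
  set.seed(seed)
  letters_pool <- letters[seq_len(vocab_size)]
  vapply(seq_len(n_docs), function(i) {
    paste(sample(letters_pool, sample(len_range, 1), replace = TRUE),
          collapse = " ")
  }, character(1))
}
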