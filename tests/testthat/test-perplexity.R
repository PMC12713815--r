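# Perplexity scoring: analytic anchors, strided windows, corpus modes.

test_that("uniform model gives ppl = V for any sequence and window config", {
  set.seed(401)
  for (V in c(2, 4, 10)) {
    lm <- make_uniform_lm(V)
    toks <- sample(lm$vocab, 25, replace = TRUE)
    expect_equal(ppl_single(toks, lm)$ppl, V, tolerance = 1e-12)
    for (w in list(window_config(8, 8), window_config(8, 3),
                   window_config(30, 1))) {
      expect_equal(ppl_strided(toks, lm, w)$ppl, V, tolerance = 1e-12)
    }
  }
})

test_that("a certainty model gives ppl = 1", {
  lm <- make_uniform_lm(1)
  toks <- rep(lm$vocab[1], 1000)
  expect_equal(ppl_single(toks[1:50], lm)$ppl, 1)
  expect_equal(ppl_strided(toks, lm, window_config(16, 8))$ppl, 1)
})

test_that("strided equals single-window when the sequence fits one window", {
  corp <- random_toy_corpus(5, 4, 10:30, seed = 402)
  lm <- fit_ngram_lm(corp, order = 2, alpha = 0.5)
  set.seed(403)
  for (k in 1:10) {
    toks <- sample(letters[1:4], sample(3:8, 1), replace = TRUE)
    r1 <- ppl_single(toks, lm)
    r2 <- ppl_strided(toks, lm, window_config(8, sample(1:8, 1)))
    expect_identical(r2$ppl, r1$ppl)
  }
})

test_that("single and strided scoring match the brute-force oracle", {
  set.seed(404)
  for (k in 1:10) {
    corp <- random_toy_corpus(4, 5, 8:25, seed = 500 + k)
    lm <- fit_ngram_lm(corp, order = sample(1:3, 1), alpha = runif(1, .1, 2))
    toks <- sample(letters[1:5], sample(5:15, 1), replace = TRUE)
    expect_equal(ppl_single(toks, lm)$ppl, oracle_ppl(toks, lm$log_prob),
                 tolerance = 1e-9)
    L <- sample(3:6, 1)
    s <- sample(seq_len(L), 1)
    expect_equal(ppl_strided(toks, lm, window_config(L, s))$ppl,
                 oracle_ppl_strided(toks, lm$log_prob, L, s),
                 tolerance = 1e-9)
  }
  # the worked 6-token case at max_length 3, stride 2
  bg <- fit_ngram_lm("a b a b a", order = 2, alpha = 0.5)
  toks <- c("a", "b", "a", "a", "b", "a")
  expect_equal(ppl_strided(toks, bg, window_config(3, 2))$ppl,
               oracle_ppl_strided(toks, bg$log_prob, 3, 2),
               tolerance = 1e-12)
})

test_that("evaluation cost decreases as the stride grows", {
  lm <- make_uniform_lm(3)
  toks <- sample(lm$vocab, 300, replace = TRUE)
  costs <- vapply(c(1, 4, 8, 16), function(s) {
    ppl_strided(toks, lm, window_config(16, s))$n_input_tokens
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("zero-probability events flag the record instead of erroring", {
  bg <- fit_ngram_lm("a b a b a", order = 2, alpha = 0)
  r <- ppl_single(c("a", "b", "b"), bg)  # (b|b) unseen
  expect_identical(r$ppl, Inf)
  expect_true(r$flagged)
  r2 <- ppl_strided(c("a", "b", "b", "a"), bg, window_config(2, 2))
  expect_identical(r2$ppl, Inf)
  expect_true(r2$flagged)
})

test_that("sequence longer than max_context demands strided mode", {
  lm <- make_uniform_lm(4, max_context = 10)
  toks <- sample(lm$vocab, 20, replace = TRUE)
  expect_error(ppl_single(toks, lm), "ppl_strided")
  expect_equal(ppl_strided(toks, lm, window_config(10, 5))$ppl, 4,
               tolerance = 1e-12)
  expect_error(ppl_strided(character(0), lm), "at least one token")
})

test_that("corpus concatenation reduces to single-item scoring and matches the oracle", {
  corp <- random_toy_corpus(5, 4, 10:20, seed = 405)
  lm <- fit_ngram_lm(corp, order = 2, alpha = 0.5)

  one <- corpus("a b a b", provenance = "toy")
  expect_equal(ppl_corpus_concat(one, lm, window_config(64, 64))$ppl,
               ppl_single(ppl_tokenize("a b a b"), lm)$ppl,
               tolerance = 1e-12)

  lm1 <- make_uniform_lm(1)
  two <- corpus(c("x x x", "x x x"))
  expect_equal(ppl_corpus_concat(two, lm1, window_config(16, 16))$ppl, 1)

  three <- corpus(c("a b a", "b a c", "c c a"))
  joined <- c(ppl_tokenize("a b a"), "\n", ppl_tokenize("b a c"), "\n",
              ppl_tokenize("c c a"))
  expect_equal(ppl_corpus_concat(three, lm, window_config(4, 2))$ppl,
               oracle_ppl_strided(joined, lm$log_prob, 4, 2),
               tolerance = 1e-9)
})

test_that("per-item scoring preserves order, carries metadata, and isolates failures", {
  corp <- corpus(c("a b a b a", "b b b a", "a a", "b a b a b a b"),
                 gender = c("f", "m", "f", "m"))
  lm <- fit_ngram_lm("a b a b a b b a", order = 2, alpha = 1)
  tab <- ppl_per_item(corp, lm)
  expect_identical(tab$item_id, corp$item_id)
  expect_identical(tab$gender, corp$gender)
  loop <- vapply(corp$text, function(t) {
    ppl_single(ppl_tokenize(t), lm)$ppl
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(tab$ppl, loop, tolerance = 1e-12)

  # permuting items permutes records identically
  perm <- c(3, 1, 4, 2)
  tab2 <- ppl_per_item(corp[perm, ], lm)
  expect_equal(tab2$ppl, tab$ppl[perm], tolerance = 1e-15)

  # an over-length item is flagged, the rest still scored
  lm_small <- fit_ngram_lm("a b a b a", order = 2, alpha = 1,
                           max_context = 4)
  tab3 <- ppl_per_item(corp, lm_small)
  expect_true(tab3$flagged[1])   # 5 tokens > max_context 4
  expect_true(is.na(tab3$ppl[1]))
  expect_false(tab3$flagged[3])
  expect_true(is.finite(tab3$ppl[3]))
})

test_that("identical items score identically and records round-trip as JSONL", {
  corp <- corpus(rep("a b a b", 3))
  lm <- fit_ngram_lm("a b a b", order = 2, alpha = 1)
  tab <- ppl_per_item(corp, lm)
  expect_true(all(tab$ppl == tab$ppl[1]))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_ppl_records(tab, f)
  back <- read_ppl_records(f)
  expect_equal(back$ppl, tab$ppl, tolerance = 1e-12)
  expect_identical(back$item_id, tab$item_id)
})
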