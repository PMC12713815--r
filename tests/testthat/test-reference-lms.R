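# Language-model contract: uniform model, smoothed n-gram fitting, adapter.

test_that("uniform model is exactly uniform, degenerate at V = 1, and proper", {
  lm <- make_uniform_lm(4)
  expect_identical(lm$log_prob("w1", c("w2", "w3")), log(0.25))
  expect_identical(lm$log_prob("anything", character(0)), log(0.25))

  lm1 <- make_uniform_lm(1)
  expect_identical(lm1$log_prob(lm1$vocab[1]), 0)

  lm10 <- make_uniform_lm(10)
  total <- sum(vapply(lm10$vocab, function(t) exp(lm10$log_prob(t, "w1")),
                      numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)

  expect_error(make_uniform_lm(0), "vocab_size")
})

test_that("n-gram conditionals match the closed-form additive-smoothing oracle", {
  # unigram with alpha = 1 on token counts {a:3, b:1}
  u1 <- fit_ngram_lm("a a a b", order = 1, alpha = 1)
  toks <- list(c("a", "a", "a", "b"))
  expect_equal(exp(u1$log_prob("a")),
               oracle_ngram_prob(toks, 1, 1, u1$vocab, "a", character(0)))
  # documented convention: V = {a, b, unk, eos}, context count 5 (4 tokens
  # plus the end event) -> p(a) = (3+1)/(5+4)
  expect_equal(exp(u1$log_prob("a")), 4 / 9)

  # bigram, alpha = 0: two of the three continuations of "a" are "b"
  bg <- fit_ngram_lm("a b a b a", order = 2, alpha = 0)
  expect_equal(exp(bg$log_prob("b", "a")), 2 / 3)
  expect_equal(exp(bg$log_prob("b", "a")),
               oracle_ngram_prob(list(c("a", "b", "a", "b", "a")), 2, 0,
                                 bg$vocab, "b", "a"))

  # alpha = 0 with an unseen event gives -Inf
  expect_identical(bg$log_prob("a", "a"), -Inf)

  expect_error(fit_ngram_lm(character(0)), "nonempty")
})

test_that("fitted n-gram distributions are proper for random contexts", {
  corp <- random_toy_corpus(6, 5, 8:20, seed = 301)
  for (order in c(1L, 2L, 3L)) {
    lm <- fit_ngram_lm(corp, order = order, alpha = 0.7)
    set.seed(302)
    for (k in 1:5) {
      ctx <- sample(c(letters[1:5], "zzz"), sample(0:3, 1), replace = TRUE)
      total <- sum(vapply(lm$vocab, function(t) exp(lm$log_prob(t, ctx)),
                          numeric(1)))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("large smoothing pulls the n-gram model monotonically toward uniform", {
  corp <- "a a a a b a b a a a"
  queries <- list(c("b", "a"), c("a", "a"), c("b", "b"))
  alphas <- c(0.1, 1, 10, 100, 1e4)
  for (q in queries) {
    devs <- vapply(alphas, function(al) {
      lm <- fit_ngram_lm(corp, order = 2, alpha = al)
      abs(exp(lm$log_prob(q[1], q[2])) - 1 / lm$vocab_size)
    }, numeric(1))
    expect_true(all(diff(devs) <= 1e-12))
  }
})

test_that("fitting is deterministic and survives JSON round-trip", {
  corp <- random_toy_corpus(4, 4, 5:15, seed = 303)
  lm1 <- fit_ngram_lm(corp, order = 2, alpha = 0.5)
  lm2 <- fit_ngram_lm(corp, order = 2, alpha = 0.5)
  probe <- list(c("a", "b"), c("c", character(0)), c("d", "a"))
  for (p in probe) {
    expect_identical(lm1$log_prob(p[1], p[-1]), lm2$log_prob(p[1], p[-1]))
  }
  f <- withr::local_tempfile(fileext = ".json")
  write_ngram_lm(lm1, f)
  lm3 <- read_ngram_lm(f)
  for (p in probe) {
    expect_equal(lm3$log_prob(p[1], p[-1]), lm1$log_prob(p[1], p[-1]),
                 tolerance = 1e-12)
  }
  expect_identical(lm3$vocab, lm1$vocab)
})

test_that("tokenizer is deterministic and splits punctuation", {
  txt <- "The cat, the DOG; ran."
  expect_identical(ppl_tokenize(txt), ppl_tokenize(txt))
  expect_identical(ppl_tokenize(txt),
                   c("the", "cat", ",", "the", "dog", ";", "ran", "."))
  expect_identical(ppl_tokenize("   "), character(0))
  expect_identical(count_words(c("a b  c", "", " x ")), c(3L, 0L, 1L))
})

test_that("external adapter fails loudly without a loader and enforces the contract", {
  withr::local_options(dreamppl.lm_loader = NULL)
  expect_error(external_lm_adapter("gpt2"), "no external language-model loader")

  fake_loader <- function(model_name, device) {
    if (model_name != "tiny-uniform") stop("unknown model: ", model_name)
    list(vocab_size = 8, max_context = 6,
         log_prob = function(target, context) {
           if (identical(target, "bad")) 0.5 else -log(8)
         },
         tokenize = function(text) strsplit(tolower(text), " ")[[1]])
  }
  withr::local_options(dreamppl.lm_loader = fake_loader)
  expect_error(external_lm_adapter("no-such-weights"), "unknown model")

  lm <- external_lm_adapter("tiny-uniform")
  expect_s3_class(lm, "external_lm")
  expect_identical(lm$max_context, 6L)
  expect_true(lm$log_prob("x", c("a", "b")) <= 0)
  expect_identical(lm$tokenize("A b C"), lm$tokenize("A b C"))
  expect_error(lm$log_prob("x", letters[1:10]), "contract violation")
  expect_error(lm$log_prob("bad", "a"), "positive log-probability")
})
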