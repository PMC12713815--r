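# Synthetic corpus generator: determinism, length law, entropy control.

test_that("the generator is seed-deterministic and respects the length band", {
  sp <- synthetic_spec(vocab_size = 15, n_items = 25,
                       length_law = list(kind = "uniform", lo = 30, hi = 60),
                       seed = 61)
  c1 <- generate_corpus(sp)
  c2 <- generate_corpus(sp)
  expect_identical(c1$text, c2$text)
  expect_true(all(c1$word_count >= 30 & c1$word_count <= 60))
  expect_identical(nrow(generate_corpus(synthetic_spec(n_items = 0))), 0L)

  # a different stream draws different items from the same source
  c3 <- generate_corpus(sp, stream = 1L)
  expect_false(identical(c1$text, c3$text))
  expect_true(all(c3$word_count >= 30 & c3$word_count <= 60))

  # the truncated lognormal law also stays inside the band
  spl <- synthetic_spec(vocab_size = 10, n_items = 40,
                        length_law = list(kind = "lognormal", mu = 4,
                                          sigma = 0.6, lo = 30, hi = 250),
                        seed = 62)
  expect_true(all(generate_corpus(spl)$word_count >= 30))
  expect_true(all(generate_corpus(spl)$word_count <= 250))
})

test_that("generated text round-trips the tokenizer with matching counts", {
  sp <- synthetic_spec(vocab_size = 12, n_items = 10,
                       length_law = list(kind = "uniform", lo = 30, hi = 50),
                       seed = 63)
  co <- generate_corpus(sp)
  src <- make_source(sp)
  for (t in co$text[1:3]) {
    toks <- ppl_tokenize(t)
    expect_identical(length(toks), count_words(t))
    expect_true(all(toks %in% src$vocab))
  }
})

test_that("source tables are proper, reproducible, and entropy tracks concentration", {
  sp <- synthetic_spec(vocab_size = 20, seed = 64)
  s1 <- make_source(sp)
  s2 <- make_source(sp)
  expect_identical(s1$probs, s2$probs)
  expect_true(all(abs(rowSums(s1$probs) - 1) < 1e-12))

  # near-zero concentration: near-one-hot rows; the source scores its own
  # text close to certainty
  spd <- synthetic_spec(vocab_size = 20, concentration = 1e-4,
                        n_items = 5,
                        length_law = list(kind = "uniform", lo = 30, hi = 40),
                        seed = 65)
  srcd <- make_source(spd)
  cod <- generate_corpus(spd)
  ppl_self <- ppl_per_item(cod, srcd)$ppl
  expect_true(all(ppl_self < 1.5))

  # vocab 2, flat prior: empirical unigram entropy of a long sample is close
  # to 1 bit
  spb <- synthetic_spec(vocab_size = 2, source_order = 1,
                        concentration = 1e4, n_items = 50,
                        length_law = list(kind = "uniform", lo = 200,
                                          hi = 200),
                        seed = 66)
  toks <- unlist(lapply(generate_corpus(spb)$text, ppl_tokenize))
  p <- table(toks) / length(toks)
  entropy_bits <- -sum(p * log2(p))
  expect_lt(abs(entropy_bits - 1), 0.05)
})

test_that("mean perplexity under a pooled-text model increases with concentration", {
  concs <- c(0.2, 1, 5)
  reps <- 6
  means <- matrix(NA_real_, reps, length(concs))
  for (r in seq_len(reps)) {
    for (j in seq_along(concs)) {
      sp <- synthetic_spec(vocab_size = 25, concentration = concs[j],
                           n_items = 20,
                           length_law = list(kind = "uniform", lo = 30,
                                             hi = 60),
                           seed = 700 + r)
      held <- generate_corpus(sp, stream = 1L)
      lm <- fit_ngram_lm(held$text, order = 2, alpha = 0.5)
      means[r, j] <- mean(ppl_per_item(generate_corpus(sp), lm)$ppl)
    }
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) > 0))
})

test_that("scoring by the true source leaves length and perplexity uncorrelated", {
  # the generator itself couples no entropy to length: under the generating
  # model the length-perplexity correlation is null
  sp <- synthetic_spec(vocab_size = 20, n_items = 300,
                       length_law = list(kind = "uniform", lo = 30, hi = 250),
                       seed = 67)
  co <- generate_corpus(sp)
  src <- make_source(sp)
  lc <- length_correlation(ppl_per_item(co, src))
  expect_lt(abs(lc$rho), 0.1)
})

test_that("paired studies share a vocabulary and degenerate to identity", {
  spa <- synthetic_spec(vocab_size = 15, n_items = 10,
                        length_law = list(kind = "uniform", lo = 30, hi = 50),
                        seed = 68)
  pair <- generate_paired_study(spa, spa)
  expect_identical(pair$dream$text, pair$reference$text)
  expect_identical(pair$dream$source[1], "dream")
  expect_identical(pair$reference$source[1], "reference")
  spb <- synthetic_spec(vocab_size = 99, n_items = 5)
  expect_error(generate_paired_study(spa, spb), "vocabulary")
})

test_that("group effects split items evenly and carry the chosen field", {
  sp <- synthetic_spec(
    vocab_size = 15, n_items = 30,
    length_law = list(kind = "uniform", lo = 30, hi = 60),
    group_effects = list(
      male = list(concentration_multiplier = 0.5, length_shift = -10),
      female = list(concentration_multiplier = 1, length_shift = 0)
    ),
    group_field = "gender", seed = 69
  )
  co <- generate_corpus(sp)
  expect_identical(as.integer(table(co$gender)[c("male", "female")]),
                   c(15L, 15L))
  expect_lt(mean(co$word_count[co$gender == "male"]),
            mean(co$word_count[co$gender == "female"]))
})
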