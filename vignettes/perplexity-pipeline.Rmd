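---
title: "How dreamppl measures corpus predictability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How dreamppl measures corpus predictability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The question and the measurement

Quantitative sleep-and-dream research increasingly treats dream reports as
text to be modelled. A basic question is whether such reports are *harder to
predict* for a language model than ordinary expository prose. `dreamppl`
operationalises predictability with perplexity: for a token sequence
$X = (x_1, \dots, x_t)$ and an autoregressive model $p_\theta$,

$$\mathrm{PPL}(X) \;=\; \exp\!\Big\{-\tfrac1t \sum_{i=1}^{t}
\log p_\theta(x_i \mid x_{<i})\Big\},$$

with natural logarithms throughout. Low perplexity means the model finds the
text predictable. The package scores each document of two corpora, matches
their word-count distributions so that length cannot masquerade as a
predictability difference, and compares the resulting per-document
(word count, perplexity) distributions with nonparametric tests.

## The model contract and the reference models

All scoring goes through a minimal language-model contract: a vocabulary, a
maximum context length, a deterministic tokenizer, and a conditional
log-probability `log_prob(target, context)` whose distribution over the
vocabulary sums to one for every context. Two reference families implement
the contract without any pretrained weights:

* **Uniform** (`make_uniform_lm`): every conditional is $1/V$. Its
  perplexity is exactly $V$ on any input, which anchors the scoring code
  analytically.
* **Additively smoothed n-gram** (`fit_ngram_lm`): conditionals
  $(n(c,t) + \alpha) / (n(c) + \alpha V)$. Each training document is padded
  with `order - 1` start symbols and closed with an end-of-sequence symbol.
  The end symbol matters: it makes the context count $n(c)$ equal the sum of
  its continuation counts, so conditionals stay exactly normalised even for
  contexts observed at a document's end. Out-of-vocabulary tokens map to a
  reserved unknown symbol that is part of $V$ (as is the end symbol; the
  start symbol is never a target). With $\alpha = 0$ an unseen event scores
  $-\infty$; perplexity records carry this as a flag rather than an error.

Pretrained transformer models plug in through `external_lm_adapter`, which
wraps a user-registered loader behind the same contract and refuses to
substitute anything when weights cannot be resolved. The desk-scale test
surface never depends on external weights.

The reference tokenizer lower-cases, splits punctuation into separate
tokens, and divides on whitespace. Word counts used by filters and matching
are deliberately tokenizer-independent: whitespace chunks of the raw text.

## Scoring long sequences

Documents that fit the model's maximum context are scored in a single
window, every token conditioned on all preceding in-document tokens (the
first on start-symbol padding). Longer sequences — in practice only the
whole-corpus concatenation — use the strided sliding window of
`ppl_strided`: windows of `max_length` tokens advance by `stride`; within a
window only tokens not previously scored contribute, each conditioned on
the tokens of that window that precede it. The total negative
log-likelihood divided by the total token count is exponentiated once at
the end. When a sequence fits one window the strided result is
bit-identical to single-window scoring, and the two accumulate in the same
order to keep that reduction exact. Whole-corpus mode concatenates
documents with a single newline token (scored as unknown unless the
vocabulary contains it); the choice is arbitrary but fixed and recorded in
the perplexity record.

## Filters, matching, and metadata

Two filters mirror common corpus-preparation steps: `filter_nonempty` drops
documents that are empty or consist only of a leading heading line, and
`filter_word_count` keeps documents inside an inclusive word-count band,
30–250 words by default — the band in which short personal reports and
short encyclopedia articles overlap.

`matched_subsample` equalises word-count distributions by random search: it
draws `n_iterations` (default 250) uniform subsets of the larger corpus at
the smaller corpus's size, compares each to the reference with the
permutation test below, and keeps the candidate with the largest p-value
(ties: smaller observed statistic, then earliest iteration). "Least
diverging" is thus operationalised as "maximal permutation p"; the full
candidate log is returned for audit. For contrasts against a small group
(for instance blind versus sighted dreamers), `range_matched_sample`
instead draws an equal-sized uniform sample from the majority records whose
perplexity lies within the minority group's observed range; requesting more
records than fall inside the range is an explicit error, not a silent
shrinkage.

Collection-year labels arrive as heterogeneous strings ("1962",
"1949–1964", "Mid-1980s", "?"). `convert_year` maps spans to the floor of
their midpoint, decades to their start, "Mid-"/"Late " decades to +5/+8,
and unparsable labels to `NA`. Two published conversion-table rows that
contradict the averaging rule are reproduced through an explicit exception
map (`"1999"` and `"1940s-1950s & 1990s"`); setting `exceptions = FALSE`
gives the pure rules. The exceptions are reproduced rather than
rationalised because downstream correlations should match the published
metadata exactly.

## The statistical suite

* **1D permutation test** (`permutation_test_1d`): the statistic is the
  absolute difference of means — the minimal-assumption default, since
  nothing stronger is warranted — with the null built by re-assigning the
  pooled values to groups of the original sizes and the add-one correction
  $p = (1 + \#\{D_{\mathrm{null}} \ge D\}) / (1 + B)$ so p is never zero.
  The pool is sorted before the seeded draws, which makes the result
  invariant to argument order for equal group sizes.
* **2D Kolmogorov–Smirnov** (`ks2d_statistic`, `ks2d_test`): the
  Fasano–Franceschini point-centered variant. For every data point of each
  sample the plane is split into four quadrants with closed lower/left
  boundaries; $D_k$ is the maximal absolute difference of the two empirical
  quadrant fractions over the points of sample $k$, and
  $D = (D_1 + D_2)/2$. Because a center point occupies its own closed
  quadrant, perfectly separated finite clouds attain $1 - 1/(2m)$, reaching
  1 only asymptotically. P-values come either from the large-sample
  approximation with effective size $n_1 n_2/(n_1+n_2)$ and the
  within-sample correlation correction (flagged as unreliable below
  effective size 20) or from a pooled permutation null.
* **Spearman correlation** (`spearman`): Pearson correlation of average
  ranks with the large-sample t approximation; constant input returns a
  flagged `NA`.
* **Holm correction** (`holm_adjust`): input validation plus the standard
  step-down adjustment. Which p-values form a family is a configuration
  choice (`holm_family`); the pipeline defaults to one family per analysis
  containing the 2D test, the perplexity test and the word-count test, and
  every p-value surfaced in a report belongs to exactly that family.

Every stochastic operation takes an explicit seed and is reproducible from
it; stage seeds inside the pipeline are derived from the master seed.

## The synthetic-data generator

Real dream-report collections cannot ship with a package, so validation
runs on corpora whose statistical structure is controlled. A source is an
n-gram model whose per-context next-token distributions are independent
draws from a symmetric Dirichlet: the concentration parameter tunes source
entropy continuously (small values give peaked, predictable text; large
values approach uniform noise). Document lengths follow a uniform or
truncated-lognormal law on a band, 30–250 words by default, and length is
generated independently of content, so any measured length–perplexity
coupling is introduced by scoring, never by the generator. Group structure
attaches labels (gender, vision, clinical, or generic) carrying a
concentration multiplier and a length shift. Groups with the same
multiplier share one realized source — so equal-parameter configurations
are genuinely null — while distinct multipliers get independent draws.
`generate_corpus(spec, stream = k)` yields independent samples from the
same sources, which is how held-out training text for scoring models is
produced without leakage.

The generator makes no attempt at linguistic realism: its symbols are
abstract word-like tokens. What passing tests establish is that the
*pipeline* detects the effects it is designed to detect at the stated
sizes, and stays at nominal false-positive rates when no effect exists —
not that any particular real corpus behaves like the synthetic one.

## What the validation suite establishes

The test suite pins the machinery to independent oracles and to analytic
identities: uniform-model perplexity equals the vocabulary size exactly;
strided scoring reduces bit-identically to single-window scoring; random
n-gram scoring matches a brute-force reimplementation to $10^{-9}$
relative; the 2D statistic equals an independent quadrant-loop oracle on
random samples including boundary ties; the permutation p agrees with
exhaustive enumeration on toy inputs and its type-I error at $\alpha=0.05$
stays within [0.03, 0.07] over 1000 null replicates ($n = 30$ per group);
Holm matches the closed-form step-down.

End to end, with two-group corpora whose sources differ only in
concentration (multipliers 0.2 versus 5, 60 items of 30–60 words per
replicate, an order-2 scoring model fit on a held-out stream), the
lower-entropy group shows lower mean perplexity with a significant
permutation test in at least 95 of 100 replicates, while identical-source
configurations reject in 2–8% of 200 replicates. Matched subsampling with
100 candidate iterations recovers a subset whose permutation p exceeds
0.05 in at least 95 of 100 runs when pool and reference share a
distribution. These problem sizes were chosen as the smallest at which the
effects are unambiguous; the same code runs unchanged at larger sizes.

One qualitative phenomenon of per-document scoring is reproduced by
construction rather than assumed: scoring variable-length documents from a
single stationary source with a fixed n-gram model fit on one continuous
held-out stream yields a *negative* Spearman correlation between word
count and perplexity. The mechanism is context poverty at document starts:
the first `order - 1` tokens are conditioned on padding the scoring model
never saw, and their excess surprisal is averaged over fewer tokens in
short documents. (A mean-preserving noise mechanism cannot explain a rank
correlation: Spearman is invariant to the monotone exponential, so only
genuine shifts in mean log-perplexity register.) Scoring the same corpus
with its true generating source — which models document starts perfectly —
shows no correlation, confirming that the effect arises from scoring, not
generation. Only the sign is claimed; the magnitude depends on vocabulary,
order and training volume.

## Numerical and degenerate-input choices

Zero-probability events propagate as flagged infinite-perplexity records
instead of aborting corpus runs. Over-length documents in per-item scoring
become flagged `NA` rows while the rest of the corpus is still scored.
Permutation p-values use the add-one correction; the analytic 2D p clamps
its series tail to [0, 1] and returns 1 below $\lambda = 10^{-3}$.
Dirichlet rows that underflow to zero at extreme concentrations fall back
to a one-hot draw. Seeds must be integers below $2^{31}$; derived stage
seeds stay below that bound.

## Limitations

The reference n-gram models honour the scoring contract of large
autoregressive models but not their capacity: absolute perplexities from
n-grams are not comparable to transformer numbers, and reproducing
published transformer results requires the corresponding pretrained
weights and corpora, which are deliberately outside this package's test
surface. The 2D analytic p-value is a large-sample approximation; use the
permutation mode near the flagged regime. The matching procedure is the
published random-search selection, not an optimal-assignment method, and
inherits its variance at small iteration counts.
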