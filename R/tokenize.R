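#' Reference whitespace-and-punctuation tokenizer
#'
#' Deterministic tokenizer used by the built-in reference language models:
#' the text is lower-cased, punctuation characters are split off as their own
#' tokens, and the result is divided on whitespace. It carries no vocabulary;
#' mapping of out-of-vocabulary tokens to the reserved unknown symbol happens
#' inside each model.
#'
#' @param text character scalar (or vector; vectors are tokenized elementwise
#'   and returned as a list).
#' @return character vector of tokens (a list of such vectors for vector
#'   input). Empty or whitespace-only text yields `character(0)`.
#' @examples
#' ppl_tokenize("The cat sat, quietly.")
#' @export
ppl_tokenize <- function(text) {
  if (length(text) != 1L) {
    return(lapply(text, ppl_tokenize))
  }
  if (is.na(text)) {
    return(character(0))
  }
  x <- tolower(text)
  x <- gsub("([[:punct:]])", " \\1 ", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  if (!nzchar(x)) {
    return(character(0))
  }
  strsplit(x, " ", fixed = TRUE)[[1L]]
}

#' Whitespace word count of raw text
#'
#' Tokenizer-independent word count: the number of whitespace-delimited
#' chunks of the raw, unmodified text. This is the "number of words" used by
#' the corpus filters and the length-matching machinery, deliberately kept
#' separate from model tokenization.
#'
#' @param text character vector.
#' @return integer vector of word counts (0 for empty or `NA` text).
#' @export
count_words <- function(text) {
  vapply(text, function(t) {
    if (is.na(t)) return(0L)
    t <- trimws(t)
    if (!nzchar(t)) return(0L)
    length(strsplit(t, "[[:space:]]+")[[1L]])
  }, integer(1), USE.NAMES = FALSE)
}
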