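# Corpus container, JSON-lines / text-directory I/O, filters, and
# year-of-collection parsing for dream-report metadata.
#
# A corpus is a plain data.frame of class "corpus" with one row per document:
# columns item_id, text, word_count, source, and optional metadata columns
# gender, year_raw, year_mid, series, vision, clinical. Provenance is kept in
# an attribute.

CORPUS_META <- c("gender", "year_raw", "year_mid", "series",
                 "vision", "clinical", "group")

#' Construct a corpus from texts and metadata
#'
#' @param text character vector of documents.
#' @param item_id identifiers (default `doc1`, `doc2`, ...); must be unique.
#' @param source provenance category per item: `dream`, `reference` or
#'   `synthetic`.
#' @param provenance free-text label stored as an attribute.
#' @param ... optional metadata vectors recycled to the number of documents
#'   (`gender`, `year_raw`, `series`, `vision`, `clinical`, `group`).
#'   A supplied `year_raw` is parsed into `year_mid` via [convert_year()].
#' @return a `data.frame` of class `corpus`; `word_count` is the whitespace
#'   word count of the raw text.
#' @export
corpus <- function(text, item_id = NULL, source = "reference",
                   provenance = "", ...) {
  check_that(is.character(text), "text must be a character vector")
  n <- length(text)
  if (is.null(item_id)) {
    item_id <- if (n == 0L) character(0) else paste0("doc", seq_len(n))
  }
  check_that(length(item_id) == n && !anyDuplicated(item_id),
             "item_id must be unique and match the number of documents")
  out <- data.frame(item_id = as.character(item_id), text = text,
                    word_count = count_words(text),
                    source = rep_len(source, n),
                    stringsAsFactors = FALSE)
  meta <- list(...)
  bad <- setdiff(names(meta), CORPUS_META)
  check_that(length(bad) == 0,
             paste("unknown metadata fields:", paste(bad, collapse = ", ")))
  for (nm in names(meta)) out[[nm]] <- rep_len(meta[[nm]], n)
  if (!is.null(out$year_raw) && is.null(out$year_mid)) {
    out$year_mid <- convert_year(out$year_raw)
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("corpus", "data.frame")
  out
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat(" —", prov)
  cat("\n")
  if (nrow(x) > 0) {
    cat(sprintf("  word count: min %d, median %d, max %d\n",
                min(x$word_count), as.integer(stats::median(x$word_count)),
                max(x$word_count)))
    meta <- intersect(CORPUS_META, names(x))
    if (length(meta)) cat("  metadata  :", paste(meta, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.corpus <- function(object, ...) {
  cat(sprintf("corpus of %d documents\n", nrow(object)))
  print(summary(object$word_count))
  for (m in intersect(c("gender", "vision", "clinical", "group"),
                      names(object))) {
    cat("\n", m, ":\n", sep = "")
    print(table(object[[m]], useNA = "ifany"))
  }
  invisible(object)
}

#' Read a corpus from JSON-lines or a directory of text files
#'
#' The JSON-lines dialect is UTF-8, one object per line, with a mandatory
#' `text` field and optional `item_id`, `source`, `gender`, `year_raw`,
#' `series`, `vision`, `clinical`, `group` fields. A directory of `.txt`
#' files yields one document per file with the filename stem as `item_id`.
#' Word counts are recomputed on read; empty documents are preserved (they
#' are removed later by [filter_nonempty()]).
#'
#' @param path file (jsonl) or directory (text_dir) path.
#' @param format `"jsonl"` or `"text_dir"`.
#' @return a `corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "text_dir")) {
  format <- match.arg(format)
  if (format == "text_dir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    check_that(length(files) > 0, paste("no .txt files under", path))
    texts <- vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1), USE.NAMES = FALSE)
    return(corpus(texts, item_id = sub("\\.txt$", "", basename(files)),
                  provenance = path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  check_that(length(lines) > 0, paste("no records in", path))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      stop("malformed JSON record at line ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (is.null(obj$text)) {
      stop("record at line ", i, " has no \"text\" field", call. = FALSE)
    }
    recs[[i]] <- obj
  }
  get_field <- function(nm, default = NULL) {
    vals <- lapply(recs, function(r) r[[nm]])
    if (all(vapply(vals, is.null, logical(1)))) return(default)
    vapply(vals, function(v) {
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
    }, character(1))
  }
  ids <- get_field("item_id", paste0("doc", seq_along(recs)))
  out <- corpus(get_field("text"), item_id = ids,
                source = {
                  s <- get_field("source", "reference")
                  s[is.na(s)] <- "reference"
                  s
                },
                provenance = path)
  for (nm in setdiff(CORPUS_META, "year_mid")) {
    v <- get_field(nm)
    if (!is.null(v)) out[[nm]] <- v
  }
  if (!is.null(out$year_raw)) out$year_mid <- convert_year(out$year_raw)
  out
}

#' Write a corpus as JSON-lines
#'
#' @param x a `corpus`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_corpus <- function(x, path) {
  check_that(inherits(x, "corpus"), "x must be a corpus")
  cols <- setdiff(names(x), c("word_count", "year_mid"))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    rec <- as.list(x[i, cols, drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v) || is.null(v), logical(1))]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Remove empty and title-only documents
#'
#' Drops documents whose text is empty after stripping a leading heading
#' line: a document consisting only of a single heading (its first line) and
#' whitespace is considered to have no body. Mirrors the removal of
#' reference-corpus entries that consist of a bare article title.
#'
#' @param x a `corpus`.
#' @return the filtered `corpus` (stable order); idempotent.
#' @export
filter_nonempty <- function(x) {
  check_that(inherits(x, "corpus"), "x must be a corpus")
  has_body <- vapply(x$text, function(t) {
    if (is.na(t)) return(FALSE)
    t <- trimws(t)
    if (!nzchar(t)) return(FALSE)
    lines <- strsplit(t, "\n", fixed = TRUE)[[1L]]
    # a leading heading-style line ("= Title =" or "# Title") is not body
    heading <- grepl("^\\s*(=+.*=+\\s*$|#+\\s)", lines[1L])
    if (!heading) return(TRUE)
    nzchar(trimws(paste(lines[-1L], collapse = " ")))
  }, logical(1), USE.NAMES = FALSE)
  keep_corpus(x, has_body)
}

#' Keep documents within a word-count band
#'
#' @param x a `corpus`.
#' @param lo,hi inclusive word-count bounds (`lo <= hi`). The analysis
#'   default band for report-length matching is 30–250 words.
#' @return the filtered `corpus` (stable order); idempotent.
#' @export
filter_word_count <- function(x, lo = 30L, hi = 250L) {
  check_that(inherits(x, "corpus"), "x must be a corpus")
  check_that(lo <= hi, "lo must not exceed hi")
  keep_corpus(x, x$word_count >= lo & x$word_count <= hi)
}

keep_corpus <- function(x, keep) {
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- c("corpus", "data.frame")
  out
}

# Exceptions reproducing the published conversion table where it deviates
# from its own averaging rule; kept explicit rather than generalised.
YEAR_EXCEPTIONS <- c("1999" = 2010, "1940s-1950s & 1990s" = 1960)

#' Convert a year-of-collection label to an integer year
#'
#' Dream-report collections carry heterogeneous date labels. The conversion
#' rules are:
#' \itemize{
#'   \item a single year maps to itself;
#'   \item a span `"A-B"` maps to `floor((A + B) / 2)`;
#'   \item a decade `"1990s"` maps to its start (1990);
#'   \item `"Mid-YYYYs"` maps to mid-decade (+5), `"Late YYYYs"` to
#'     late-decade (+8);
#'   \item a span of decades (`"1940s-1950s"`) maps to the floor-average of
#'     the decade starts;
#'   \item `"?"` or anything unparsable maps to `NA`.
#' }
#' Two published table rows that contradict the averaging rule
#' (`"1999" -> 2010` and `"1940s-1950s & 1990s" -> 1960`) are reproduced via
#' an explicit exception map so the full published conversion is matched
#' verbatim; set `exceptions = FALSE` for the pure rules.
#'
#' En and em dashes are treated as hyphens.
#'
#' @param year_raw character vector of labels.
#' @param exceptions apply the published-table exception map (default TRUE).
#' @return integer vector (`NA` where unparsable).
#' @examples
#' convert_year(c("1897-1918", "Mid-1980s", "1990s", "?"))
#' @export
convert_year <- function(year_raw, exceptions = TRUE) {
  vapply(as.character(year_raw), function(y) {
    if (is.na(y)) return(NA_integer_)
    y <- trimws(gsub("–|—", "-", y))
    if (exceptions && y %in% names(YEAR_EXCEPTIONS)) {
      return(as.integer(YEAR_EXCEPTIONS[[y]]))
    }
    if (grepl("^[0-9]{4}$", y)) return(as.integer(y))
    # span of plain years: "1897-1918"
    m <- regmatches(y, regexec("^([0-9]{4})-([0-9]{4})$", y))[[1L]]
    if (length(m) == 3L) {
      return(as.integer(floor((as.integer(m[2]) + as.integer(m[3])) / 2)))
    }
    # mid / late decade: "Mid-1980s", "Late 1990s"
    ylc <- tolower(y)
    m <- regmatches(ylc, regexec("^(mid|late)[- ]([0-9]{4})s$", ylc))[[1L]]
    if (length(m) == 3L) {
      base <- as.integer(m[3])
      return(base + if (m[2] == "mid") 5L else 8L)
    }
    # span of decades: "1940s-1950s"
    m <- regmatches(y, regexec("^([0-9]{4})s-([0-9]{4})s$", y))[[1L]]
    if (length(m) == 3L) {
      return(as.integer(floor((as.integer(m[2]) + as.integer(m[3])) / 2)))
    }
    # bare decade: "1990s"
    m <- regmatches(y, regexec("^([0-9]{4})s$", y))[[1L]]
    if (length(m) == 2L) return(as.integer(m[2]))
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}
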