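# Two normalization pipelines: an aggressive one for performance-status
# extraction and a sentence-preserving one for the progression pipeline.

#' Normalize text for performance-status extraction
#'
#' Lowercases and strips all whitespace and all punctuation/symbols except
#' `"."` and `","` (which separate sentences and clauses). Collapsing
#' `"WHO 1"`, `"who:1"`, `"W H O 1"` onto the single form `"who1"` lets one
#' compact regular expression cover the many ways a PS is written. Digits and
#' letter order are preserved; non-ASCII letters are lowercased, not
#' stripped. Idempotent.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
normalize_for_ps <- function(text) {
  x <- tolower(text)
  gsub("[^\\p{L}\\p{N}.,]+", "", x, perl = TRUE)
}

#' Build an abbreviation map
#'
#' Ordered (short form, full form) pairs matched on word boundaries,
#' longest short form first, in a single pass: produced text is never
#' re-expanded. Period-bearing short forms (`"mg."`) are supported; expanding
#' them removes periods that would otherwise look sentence-final to the
#' splitter.
#'
#' @param entries named character vector or named list, short -> full.
#' @return an `abbrev_map` object.
#' @export
abbrev_map <- function(entries) {
  entries <- unlist(entries)
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("abbrev_map: entries must be named (short form -> full form)")
  short <- tolower(names(entries)); full <- tolower(unname(entries))
  if (any(short == full)) stop("abbrev_map: an entry expands to itself")
  ord <- order(-nchar(short), short)
  structure(list(short = short[ord], full = full[ord]), class = "abbrev_map")
}

expand_abbreviations <- function(x, map) {
  if (length(map$short) == 0) return(x)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", map$short)
  pat <- paste0("(?<![\\p{L}\\p{N}])(?:", paste(esc, collapse = "|"),
                ")(?![\\p{L}\\p{N}])")
  # one pass over the input: all matches located first, then replaced, so an
  # expansion can never trigger another entry
  m <- gregexpr(pat, x, perl = TRUE)
  regmatches(x, m) <- lapply(regmatches(x, m), function(hits) {
    map$full[match(hits, map$short)]
  })
  x
}

remove_stopwords <- function(x, removable, protected = character()) {
  removable <- setdiff(tolower(removable), tolower(protected))
  if (!length(removable)) return(x)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", removable)
  pat <- paste0("(?<![\\p{L}\\p{N}])(?:", paste(esc, collapse = "|"),
                ")(?![\\p{L}\\p{N}])[ ]?")
  x <- gsub(pat, "", x, perl = TRUE)
  # a removed word at end of a segment can leave a trailing space
  gsub("[ ]+(?=\\n|$)", "", x, perl = TRUE)
}

#' Normalize text for the progression pipeline
#'
#' Lowercases, expands abbreviations (including drug shorthands such as
#' `"osi"` -> `"osimertinib"`) on word boundaries, and removes only the
#' configured removable stop words (articles). Negation and hedging words
#' are never removed: dropping a word like "no" or "maybe" would flip the
#' meaning of a progression sentence. Newlines and multi-space runs are
#' preserved because the sentence splitter uses them as boundaries.
#'
#' @param text character vector.
#' @param abbrev an [abbrev_map()], a named vector/list of entries, or
#'   `NULL` for no expansion.
#' @param stopwords list with `removable` and `protected` character vectors
#'   (see [default_rules()]), or `NULL` to skip stop-word removal.
#' @return character vector of the same length.
#' @export
normalize_for_pfs <- function(text, abbrev = NULL, stopwords = NULL) {
  x <- tolower(text)
  if (!is.null(abbrev)) {
    if (!inherits(abbrev, "abbrev_map")) abbrev <- abbrev_map(abbrev)
    x <- expand_abbreviations(x, abbrev)
  }
  if (!is.null(stopwords) && length(stopwords$removable))
    x <- remove_stopwords(x, stopwords$removable, stopwords$protected)
  x
}
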