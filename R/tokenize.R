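# Sentence segmentation for punctuation-poor clinical text, plus n-gram and
# keyword-in-context utilities for rule discovery.

#' Split normalized clinical text into sentences
#'
#' Clinical notes often lack terminal punctuation; authors separate
#' statements with new lines or runs of spaces instead. Boundaries are:
#' \enumerate{
#'   \item `"."`, `"?"` or `"!"` followed by whitespace or end of text
#'     (a period between two digits, as in `"1.5"`, is never a boundary);
#'   \item any newline;
#'   \item a run of `min_space_run` or more consecutive spaces (default 3;
#'     double spaces from manual edits are not boundaries).
#' }
#' Boundary characters are not part of the sentence text; empty fragments
#' are discarded. Input is expected to have passed [normalize_for_pfs()], so
#' period-bearing abbreviations are already expanded.
#'
#' @param text character scalar or vector of normalized note texts.
#' @param min_space_run integer, length of a space run that acts as a
#'   boundary.
#' @return for scalar input, a character vector of sentences; for vector
#'   input, a list of such vectors.
#' @export
split_sentences <- function(text, min_space_run = 3L) {
  stopifnot(min_space_run >= 1L)
  pat <- sprintf("[.?!]+(?=\\s|$)|\\n| {%d,}", as.integer(min_space_run))
  out <- lapply(strsplit(text, pat, perl = TRUE), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
  if (length(text) == 1L) out[[1L]] else out
}

#' Tokenize a corpus into a sentence table
#'
#' Runs [normalize_for_pfs()] then [split_sentences()] over every note.
#'
#' @param corpus a `note_corpus`.
#' @param rules a `clinotext_rules` list (for abbreviations/stop words), or
#'   `NULL` for raw splitting.
#' @param min_space_run see [split_sentences()].
#' @return data frame `patient_id`, `date`, `note_row`, `sentence_idx`,
#'   `text` — one row per sentence, note order preserved.
#' @export
tokenize_corpus <- function(corpus, rules = NULL, min_space_run = 3L) {
  if (nrow(corpus) == 0)
    return(data.frame(patient_id = character(), date = as.Date(character()),
                      note_row = integer(), sentence_idx = integer(),
                      text = character(), stringsAsFactors = FALSE))
  txt <- corpus$text
  if (!is.null(rules))
    txt <- normalize_for_pfs(txt, rules$abbreviations, rules$stopwords)
  sent <- split_sentences(txt, min_space_run)
  if (!is.list(sent)) sent <- list(sent)
  n <- lengths(sent)
  data.frame(patient_id = rep(corpus$patient_id, n),
             date = rep(corpus$date, n),
             note_row = rep(seq_len(nrow(corpus)), n),
             sentence_idx = sequence(n),
             text = unlist(sent, use.names = FALSE),
             stringsAsFactors = FALSE)
}

tokenize_words <- function(x) strsplit(trimws(x), "\\s+", perl = TRUE)

#' Count n-grams across sentences
#'
#' Tokens are whitespace-delimited; every contiguous window of `n` tokens is
#' counted. The operational tool behind rule discovery: frequent n-grams in
#' sentences around known progression dates suggest patterns worth encoding.
#'
#' @param sentences character vector of (normalized) sentences, or the
#'   sentence table from [tokenize_corpus()].
#' @param n window length, integer >= 1.
#' @return data frame `ngram`, `count`, sorted by decreasing count then
#'   ngram; class `ngram_table`.
#' @export
ngram_counts <- function(sentences, n = 2L) {
  if (is.data.frame(sentences)) sentences <- sentences$text
  if (!is.numeric(n) || length(n) != 1L || n < 1L)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  toks <- tokenize_words(sentences)
  grams <- unlist(lapply(toks, function(tk) {
    L <- length(tk)
    if (L < n) return(character())
    vapply(seq_len(L - n + 1L),
           function(i) paste(tk[i:(i + n - 1L)], collapse = " "), "")
  }), use.names = FALSE)
  if (!length(grams)) {
    out <- data.frame(ngram = character(), count = integer())
  } else {
    tab <- table(grams)
    out <- data.frame(ngram = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$ngram), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n") <- n
  class(out) <- c("ngram_table", "data.frame")
  out
}

#' Keyword-in-context concordance listing
#'
#' Lists every regular-expression match with up to `window` tokens of
#' context on each side — the audit view used to refine extraction rules
#' (e.g. inspect all uses of "progress" before writing a PP pattern).
#'
#' @param sentences sentence table from [tokenize_corpus()] (columns
#'   `patient_id`, `date`, `text`), or a character vector.
#' @param pattern perl regular expression.
#' @param window integer, context tokens per side.
#' @return data frame `patient_id`, `date`, `left`, `match`, `right` — one
#'   row per match (overlapping matches of the same pattern are reported at
#'   each distinct start position found by repeated scanning).
#' @export
kwic <- function(sentences, pattern, window = 4L) {
  ok <- tryCatch({ suppressWarnings(grepl(pattern, "", perl = TRUE)); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("invalid pattern: ", conditionMessage(ok))
  if (is.character(sentences))
    sentences <- data.frame(patient_id = NA_character_,
                            date = as.Date(NA), text = sentences,
                            stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(sentences))) {
    s <- sentences$text[i]
    # scan from every position so overlapping matches each get a row
    starts <- integer(); lens <- integer(); from <- 1L
    repeat {
      m <- regexpr(pattern, substr(s, from, nchar(s)), perl = TRUE)
      if (m == -1L) break
      st <- from + as.integer(m) - 1L
      starts <- c(starts, st)
      lens <- c(lens, attr(m, "match.length"))
      from <- st + 1L
    }
    for (k in seq_along(starts)) {
      st <- starts[k]; en <- st + lens[k] - 1L
      # widen the span to whole tokens, the usual keyword-in-context view
      while (st > 1L && !grepl("\\s", substr(s, st - 1L, st - 1L))) st <- st - 1L
      while (en < nchar(s) && !grepl("\\s", substr(s, en + 1L, en + 1L)))
        en <- en + 1L
      left_txt <- substr(s, 1L, st - 1L)
      right_txt <- substr(s, en + 1L, nchar(s))
      lt <- tokenize_words(left_txt)[[1]]
      rt <- tokenize_words(right_txt)[[1]]
      lt <- lt[nzchar(lt)]; rt <- rt[nzchar(rt)]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sentences$patient_id[i], date = sentences$date[i],
        left = paste(utils::tail(lt, window), collapse = " "),
        match = substr(s, st, en),
        right = paste(utils::head(rt, window), collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), date = as.Date(character()),
                      left = character(), match = character(),
                      right = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
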