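# The rule engine: performance-status extraction from aggressively
# normalized text, and BP/PP/AP phase classification of sentences.

ps_obs_df <- function(patient_id = character(), date = as.Date(character()),
                      score = integer(), secondary_score = integer(),
                      source = character(), evidence = character(),
                      note_source = character()) {
  data.frame(patient_id = patient_id, date = date, score = score,
             secondary_score = secondary_score, source = source,
             evidence = evidence, note_source = note_source,
             stringsAsFactors = FALSE)
}

phase_obs_df <- function(patient_id = character(), date = as.Date(character()),
                         phase = character(), rule_id = character(),
                         evidence = character()) {
  data.frame(patient_id = patient_id, date = date, phase = phase,
             rule_id = rule_id, evidence = evidence, stringsAsFactors = FALSE)
}

#' Extract performance-status mentions from normalized text
#'
#' One compact pattern covers the many surface forms after
#' [normalize_for_ps()]: a keyword (`"ps"`, `"who"`, `"ecog"`, ...)
#' immediately followed by one or two digits, each a valid ECOG score (0-5).
#' Two digits encode a clinician's range (`"WHO 1-2"` normalizes to
#' `"who12"`): the first digit is the score, the second the secondary score.
#' A second digit more than 2 apart from the first is not a plausible range
#' and is left unconsumed. Matches are non-overlapping, leftmost first.
#'
#' Faithful by construction to the known failure modes of the approach:
#' `"whoo"` (the letter O written for the number 0) and `"psis2"` (words
#' between keyword and score) yield no observation under the default strict
#' pattern. Setting `allow_intervening` permits up to `max_gap_chars`
#' letters between keyword and score, trading those misses for a looser
#' match.
#'
#' @param text PS-normalized text (character vector).
#' @param keywords lowercase keyword strings (longest matched first).
#' @param date,patient_id,note_source metadata attached to each observation
#'   (recycled).
#' @param allow_intervening logical, see above.
#' @param max_gap_chars maximum number of intervening letters when
#'   `allow_intervening` is on.
#' @return a PS-observation data frame: `patient_id`, `date`, `score`,
#'   `secondary_score` (NA when absent), `source = "mined"`, `evidence`
#'   (matched span), `note_source`.
#' @export
extract_ps_mentions <- function(text, keywords = c("ps", "who", "ecog"),
                                date = as.Date(NA), patient_id = NA_character_,
                                note_source = NA_character_,
                                allow_intervening = FALSE,
                                max_gap_chars = 8L) {
  keywords <- tolower(keywords)
  keywords <- keywords[order(-nchar(keywords), keywords)]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keywords)
  gap <- if (allow_intervening)
    sprintf("[\\p{L},.]{0,%d}?", as.integer(max_gap_chars)) else ""
  pat <- paste0("(?:", paste(esc, collapse = "|"), ")", gap, "([0-5])([0-5]?)")
  date <- rep(as.Date(date), length.out = length(text))
  patient_id <- rep(patient_id, length.out = length(text))
  note_source <- rep(note_source, length.out = length(text))
  out <- list()
  for (i in seq_along(text)) {
    m <- gregexpr(pat, text[i], perl = TRUE)[[1]]
    if (m[1] == -1L) next
    spans <- regmatches(text[i], gregexpr(pat, text[i], perl = TRUE))[[1]]
    starts <- attr(m, "capture.start"); lens <- attr(m, "capture.length")
    for (k in seq_along(spans)) {
      d1 <- as.integer(substr(text[i], starts[k, 1], starts[k, 1]))
      d2 <- if (lens[k, 2] > 0)
        as.integer(substr(text[i], starts[k, 2], starts[k, 2])) else NA_integer_
      if (!is.na(d2) && abs(d2 - d1) > 2L) {
        d2 <- NA_integer_
        spans[k] <- substr(spans[k], 1L, nchar(spans[k]) - 1L)
      }
      out[[length(out) + 1L]] <- ps_obs_df(
        patient_id = patient_id[i], date = date[i], score = d1,
        secondary_score = d2, source = "mined", evidence = spans[k],
        note_source = note_source[i])
    }
  }
  if (!length(out)) return(ps_obs_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

compile_drug_start_pattern <- function(drugs) {
  aliases <- tolower(unlist(drugs$post_progression, use.names = FALSE))
  starts <- tolower(drugs$start_patterns)
  if (!length(aliases) || !length(starts)) return(NULL)
  a <- paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", aliases), collapse = "|")
  s <- paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", starts), collapse = "|")
  # verb before drug ("start carboplatin") or drug before verb
  # ("carboplatine gestart"), at most a few words apart
  sprintf("(?:\\b(?:%s)\\b[^.\\n]{0,40}?\\b(?:%s)\\b)|(?:\\b(?:%s)\\b[^.\\n]{0,40}?\\b(?:%s)\\b)",
          s, a, a, s)
}

#' Classify one or more sentences into progression phases
#'
#' Rules are evaluated in descending priority; among equal priorities the
#' lexicographically lower `rule_id` wins. The first matching rule assigns
#' the phase (BP = before, PP = around, AP = after progression). In
#' addition, a built-in rule assigns AP to any sentence in which a
#' post-progression drug is started — a new anticancer line implies
#' progression has occurred; it participates with priority
#' `drug_start_priority`. Unmatched sentences get phase `NA`.
#'
#' @param sentences sentence table from [tokenize_corpus()] or character
#'   vector of normalized sentences.
#' @param rules a `clinotext_rules` list, or a phase-rule data frame from
#'   [phase_rule_table()].
#' @param lexicon drug lexicon (`rules$drugs`) used for the built-in
#'   drug-start rule; `NULL` disables it.
#' @param drug_start_priority priority of the built-in rule (default 15).
#' @return phase-observation data frame (`patient_id`, `date`, `phase`,
#'   `rule_id`, `evidence`), one row per *classified* sentence.
#' @export
classify_sentences <- function(sentences, rules, lexicon = NULL,
                               drug_start_priority = 15L) {
  if (inherits(rules, "clinotext_rules")) {
    if (is.null(lexicon)) lexicon <- rules$drugs
    rules <- phase_rule_table(rules)
  }
  if (is.character(sentences))
    sentences <- data.frame(patient_id = NA_character_, date = as.Date(NA),
                            text = sentences, stringsAsFactors = FALSE)
  if (!is.null(lexicon)) {
    dp <- compile_drug_start_pattern(lexicon)
    if (!is.null(dp))
      rules <- rbind(rules,
                     data.frame(rule_id = "ap_drug_start", phase = "AP",
                                pattern = dp,
                                priority = as.integer(drug_start_priority)))
  }
  rules <- rules[order(-rules$priority, rules$rule_id), , drop = FALSE]
  n <- nrow(sentences)
  phase <- rep(NA_character_, n); rid <- rep(NA_character_, n)
  unmatched <- rep(TRUE, n)
  for (j in seq_len(nrow(rules))) {
    if (!any(unmatched)) break
    hit <- unmatched & grepl(rules$pattern[j], sentences$text, perl = TRUE)
    phase[hit] <- rules$phase[j]
    rid[hit] <- rules$rule_id[j]
    unmatched[hit] <- FALSE
  }
  keep <- !is.na(phase)
  phase_obs_df(patient_id = sentences$patient_id[keep],
               date = sentences$date[keep], phase = phase[keep],
               rule_id = rid[keep], evidence = sentences$text[keep])
}

#' Run the full extraction over a corpus
#'
#' Drives normalize -> (tokenize ->) extract over every note and merges in
#' structured observations, each row carrying its provenance.
#'
#' @param corpus a `note_corpus`. For `mode = "pfs"` it should already have
#'   passed [filter_pre_treatment()].
#' @param mode `"ps"` (performance-status observations) or `"pfs"` (phase
#'   observations).
#' @param rules a `clinotext_rules` list.
#' @param structured optional structured observations of the matching kind
#'   (from [read_structured_observations()]), merged into the output.
#' @return observations data frame sorted by patient and date: PS
#'   observations for `"ps"`, phase observations for `"pfs"`.
#' @export
mine_corpus <- function(corpus, mode = c("ps", "pfs"), rules = default_rules(),
                        structured = NULL) {
  mode <- match.arg(mode)
  validate_rules(rules)
  if (mode == "ps") {
    if (nrow(corpus)) {
      norm <- normalize_for_ps(corpus$text)
      mined <- extract_ps_mentions(norm, keywords = rules$ps$keywords,
                                   date = corpus$date,
                                   patient_id = corpus$patient_id,
                                   note_source = corpus$source,
                                   allow_intervening = isTRUE(rules$ps$allow_intervening),
                                   max_gap_chars = rules$ps$max_gap_chars %||% 8L)
    } else mined <- ps_obs_df()
    if (!is.null(structured)) {
      structured$note_source <- "structured"
      mined <- rbind(mined, structured[, names(mined)])
    }
  } else {
    sent <- tokenize_corpus(corpus, rules)
    mined <- classify_sentences(sent, rules)
    if (!is.null(structured))
      mined <- rbind(mined, structured[, names(mined)])
  }
  mined <- mined[order(mined$patient_id, mined$date), , drop = FALSE]
  rownames(mined) <- NULL
  mined
}

`%||%` <- function(a, b) if (is.null(a)) b else a
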