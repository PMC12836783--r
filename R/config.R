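# Rule/lexicon configuration: PS keywords, abbreviation map, stop-word
# policy, phase rules, drug lexicon. Lives as a plain nested list so it can
# round-trip through YAML or JSON untouched.

#' Default extraction rule set
#'
#' Starter lexicons for English (`"en"`) and Dutch (`"nl"`). These are
#' deliberately small: the rule-discovery workflow ([ngram_counts()],
#' [kwic()]) exists precisely so users grow them against their own corpus.
#'
#' The configuration is a nested list with keys:
#' \describe{
#'   \item{ps}{`keywords` (lowercase strings that announce a performance
#'     status), `allow_intervening` (logical; permit a short non-digit gap
#'     between keyword and score, off by default), `max_gap_chars`.}
#'   \item{abbreviations}{named list, short form -> full form; includes the
#'     drug shorthands (e.g. `osi` -> `osimertinib`) and period-bearing
#'     abbreviations that would otherwise break sentence splitting.}
#'   \item{stopwords}{`removable` (only articles by default) and `protected`
#'     (negation/hedging words that must never be removed).}
#'   \item{phases}{`bp`/`pp`/`ap`: lists of rules
#'     `(rule_id, pattern, priority)`; higher priority wins, ties go to the
#'     lexicographically lower rule_id.}
#'   \item{drugs}{`of_interest` (canonical + aliases),
#'     `post_progression` (named list canonical -> aliases),
#'     `start_patterns` (verbs that announce starting a drug).}
#' }
#'
#' @param language `"en"` or `"nl"`.
#' @return a `clinotext_rules` list.
#' @export
default_rules <- function(language = c("en", "nl")) {
  language <- match.arg(language)
  common <- list(
    ps = list(keywords = c("ps", "who", "ecog", "performance status",
                           "performancestatus"),
              allow_intervening = FALSE,
              max_gap_chars = 8L),
    drugs = list(
      of_interest = list(canonical = "osimertinib",
                         aliases = c("osimertinib", "tagrisso", "osi")),
      post_progression = list(
        carboplatin  = c("carboplatin", "carboplatine", "carbo"),
        pemetrexed   = c("pemetrexed", "alimta"),
        lorlatinib   = c("lorlatinib", "lorviqua"),
        docetaxel    = c("docetaxel")),
      start_patterns = c("start", "started", "starting", "gestart",
                         "begonnen met", "switch to", "switched to"))
  )
  if (language == "en") {
    cfg <- c(common, list(
      abbreviations = list(
        "osi" = "osimertinib", "crizo" = "crizotinib", "carbo" = "carboplatin",
        "pt." = "patient", "mg." = "mg", "ct." = "ct", "prog." = "progression",
        "w/o" = "without"),
      stopwords = list(removable = c("the"),
                       protected = c("no", "not", "without", "maybe",
                                     "possible", "possibly", "suspected")),
      phases = list(
        bp = list(
          list(rule_id = "bp_no_progression",
               pattern = "(no|without) (signs? of )?(progression|growth)",
               priority = 20L),
          list(rule_id = "bp_stable",
               pattern = "stable (disease|situation|imaging)|remission|good partial response",
               priority = 10L)),
        pp = list(
          list(rule_id = "pp_progression",
               pattern = "progressi(on|ve)( of (the )?disease)?",
               priority = 10L),
          list(rule_id = "pp_new_lesion",
               pattern = "new (lesions?|metastas[ie]s)",
               priority = 10L)),
        ap = list(
          list(rule_id = "ap_after_progression",
               pattern = "after progression|since progression|post-progression",
               priority = 12L)))))
  } else {
    cfg <- c(common, list(
      abbreviations = list(
        "osi" = "osimertinib", "crizo" = "crizotinib", "carbo" = "carboplatine",
        "pat." = "patient", "mg." = "mg", "ivm" = "in verband met",
        "tgv" = "ten gevolge van"),
      stopwords = list(removable = c("de", "het"),
                       protected = c("geen", "niet", "zonder", "misschien",
                                     "mogelijk", "mogelijke", "verdenking")),
      phases = list(
        bp = list(
          list(rule_id = "bp_geen_progressie",
               pattern = "geen (aanwijzingen voor |tekenen van )?(progressie|groei)",
               priority = 20L),
          list(rule_id = "bp_stabiel",
               pattern = "stabiel(e)? (beeld|ziekte|situatie)|remissie|goede partiele respons",
               priority = 10L)),
        pp = list(
          list(rule_id = "pp_progressie",
               pattern = "progressie(f| van (de )?ziekte)?",
               priority = 10L),
          list(rule_id = "pp_nieuwe_laesie",
               pattern = "nieuwe (laesies?|metastasen?)",
               priority = 10L)),
        ap = list(
          list(rule_id = "ap_na_progressie",
               pattern = "na (de )?progressie|sinds progressie",
               priority = 12L)))))
  }
  cfg$language <- language
  class(cfg) <- c("clinotext_rules", "list")
  validate_rules(cfg)
}

#' Validate a rule configuration
#'
#' Checks the invariants the extraction engine relies on: every phase
#' pattern compiles, rule ids are unique, no removable stop word is also
#' protected (negation words are never removable), no drug alias belongs to
#' both the drug of interest and the post-progression group, and no
#' abbreviation expands to itself.
#'
#' @param cfg a rules list as produced by [default_rules()] or [read_rules()].
#' @return `cfg` invisibly classed `clinotext_rules`; errors describe the
#'   offending field.
#' @export
validate_rules <- function(cfg) {
  stopifnot(is.list(cfg))
  ab <- cfg$abbreviations
  if (length(ab) && any(tolower(names(ab)) == tolower(unlist(ab))))
    stop("abbreviations: an entry expands to itself")
  bad <- intersect(cfg$stopwords$removable, cfg$stopwords$protected)
  if (length(bad))
    stop("stopwords: removable words also listed as protected: ",
         paste(bad, collapse = ", "))
  rules <- phase_rule_table(cfg)
  if (anyDuplicated(rules$rule_id))
    stop("phases: duplicate rule_id: ",
         paste(unique(rules$rule_id[duplicated(rules$rule_id)]), collapse = ", "))
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({
      suppressWarnings(grepl(rules$pattern[i], "x", perl = TRUE)); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("phase rule '", rules$rule_id[i], "': pattern does not compile: ",
           conditionMessage(ok))
  }
  doi <- tolower(cfg$drugs$of_interest$aliases)
  pp  <- tolower(unlist(cfg$drugs$post_progression, use.names = FALSE))
  both <- intersect(doi, pp)
  if (length(both))
    stop("drugs: alias in both of_interest and post_progression: ",
         paste(both, collapse = ", "))
  class(cfg) <- c("clinotext_rules", "list")
  invisible(cfg)
}

#' Flatten the phase rules of a config into one table
#'
#' @param cfg a rules list.
#' @return data frame `rule_id`, `phase`, `pattern`, `priority`, sorted by
#'   descending priority then rule_id (the engine's evaluation order).
#' @export
phase_rule_table <- function(cfg) {
  rows <- list()
  for (ph in c("bp", "pp", "ap")) {
    for (r in cfg$phases[[ph]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        rule_id = r$rule_id, phase = toupper(ph), pattern = r$pattern,
        priority = as.integer(r$priority), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rule_id = character(), phase = character(),
                      pattern = character(), priority = integer())
  out <- out[order(-out$priority, out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a rule configuration (YAML or JSON)
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return [read_rules()]: validated `clinotext_rules` list.
#' @export
read_rules <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  # yaml reads the phase rule lists as unnamed lists of named lists already
  validate_rules(cfg)
  class(cfg) <- c("clinotext_rules", "list")
  cfg
}

#' @rdname read_rules
#' @param cfg a rules list.
#' @export
write_rules <- function(cfg, path) {
  cfg <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.clinotext_rules <- function(x, ...) {
  rt <- phase_rule_table(x)
  cat("<clinotext_rules> language:", x$language, "\n",
      " ps keywords:", paste(x$ps$keywords, collapse = ", "), "\n",
      " abbreviations:", length(x$abbreviations), "entries\n",
      " phase rules:", nrow(rt),
      sprintf("(BP %d / PP %d / AP %d)\n", sum(rt$phase == "BP"),
              sum(rt$phase == "PP"), sum(rt$phase == "AP")))
  invisible(x)
}
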