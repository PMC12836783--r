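# Reading/writing the tabular interchange files and the pre-treatment filter.

#' Parse calendar dates written in a clinical export dialect
#'
#' Clinical exports mix ISO `yyyy-mm-dd` with European `dd-mm-yyyy` and
#' occasionally American `mm-dd-yyyy` (slashed variants included).
#' `dialect = "auto"` accepts all three, preferring ISO then day-first, and
#' *flags* literals such as `"03-04-2020"` whose day and month readings both
#' parse to different dates, rather than guessing silently.
#'
#' @param x character vector of date literals.
#' @param dialect one of `"iso"` (`yyyy-mm-dd`), `"dmy"` (`dd-mm-yyyy`),
#'   `"mdy"` (`mm-dd-yyyy`) or `"auto"`.
#' @return a list with `date` (a `Date` vector, `NA` where unparseable) and
#'   `ambiguous` (logical; only ever `TRUE` under `dialect = "auto"`).
#' @export
parse_note_dates <- function(x, dialect = c("auto", "iso", "dmy", "mdy")) {
  dialect <- match.arg(dialect)
  x <- trimws(as.character(x))
  x_norm <- gsub("/", "-", x, fixed = TRUE)
  # gate each format on its shape first: strptime() silently ignores
  # trailing text, so "03-04-2020" would otherwise "parse" as year 3
  gated <- function(shape, fmt) {
    out <- as.Date(rep(NA_character_, length(x_norm)))
    sel <- grepl(shape, x_norm)
    out[sel] <- as.Date(x_norm[sel], format = fmt, optional = TRUE)
    out
  }
  iso <- gated("^\\d{4}-\\d{1,2}-\\d{1,2}$", "%Y-%m-%d")
  dmy <- gated("^\\d{1,2}-\\d{1,2}-\\d{4}$", "%d-%m-%Y")
  mdy <- gated("^\\d{1,2}-\\d{1,2}-\\d{4}$", "%m-%d-%Y")
  # an invalid calendar date like 31-02-2020 is NA under every format
  out <- switch(dialect,
    iso = iso,
    dmy = dmy,
    mdy = mdy,
    auto = {
      d <- iso
      d[is.na(d)] <- dmy[is.na(d)]
      d[is.na(d)] <- mdy[is.na(d)]
      d
    }
  )
  ambiguous <- if (dialect == "auto") {
    is.na(iso) & !is.na(dmy) & !is.na(mdy) & dmy != mdy
  } else rep(FALSE, length(x))
  list(date = out, ambiguous = ambiguous)
}

validate_date_range <- function(dates, range = c("1990-01-01", "2100-12-31")) {
  lo <- as.Date(range[1]); hi <- as.Date(range[2])
  !is.na(dates) & dates >= lo & dates <= hi
}

#' Read a note table into a note corpus
#'
#' Expects columns `patient_id`, `date`, `source`, `text` (names remappable
#' via `columns`). Rows whose date does not parse, falls outside the
#' plausible range, or whose patient id is empty are *reported*, never
#' silently dropped: they are returned in the `rejects` attribute and, if
#' `rejects_path` is given, written there as CSV.
#'
#' @param path CSV file path.
#' @param dialect date dialect, see [parse_note_dates()].
#' @param columns named character vector mapping canonical names
#'   (`patient_id`, `date`, `source`, `text`) to the file's column names.
#' @param rejects_path optional path for the side report of rejected rows.
#' @param date_range plausible date range, character length 2.
#' @return a `note_corpus` (see [note_corpus()]), with attribute `rejects`.
#' @export
read_note_table <- function(path, dialect = "auto",
                            columns = c(patient_id = "patient_id",
                                        date = "date", source = "source",
                                        text = "text"),
                            rejects_path = NULL,
                            date_range = c("1990-01-01", "2100-12-31")) {
  if (!file.exists(path)) stop("note table not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- c("patient_id", "date", "source", "text")
  for (nm in needed) {
    col <- if (nm %in% names(columns)) columns[[nm]] else nm
    if (!col %in% names(raw))
      stop("note table is missing required column '", col, "' (maps to '",
           nm, "')")
  }
  df <- data.frame(patient_id = raw[[columns[["patient_id"]]]],
                   date_raw   = raw[[columns[["date"]]]],
                   source     = raw[[columns[["source"]]]],
                   text       = raw[[columns[["text"]]]],
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("note table ", path, " is empty")
    return(note_corpus(empty_notes_df()))
  }
  parsed <- parse_note_dates(df$date_raw, dialect)
  ok <- validate_date_range(parsed$date, date_range) & nzchar(df$patient_id)
  reason <- rep(NA_character_, nrow(df))
  reason[!nzchar(df$patient_id)] <- "empty patient_id"
  reason[is.na(parsed$date)] <- "unparseable date"
  reason[!is.na(parsed$date) & !validate_date_range(parsed$date, date_range)] <-
    "date outside plausible range"
  rejects <- cbind(df[!ok, , drop = FALSE],
                   reason = reason[!ok])
  ambiguous <- df$date_raw[ok & parsed$ambiguous]
  if (length(ambiguous))
    warning("ambiguous day/month literals parsed under dialect='auto': ",
            paste(unique(ambiguous), collapse = ", "))
  if (nrow(rejects))
    message(nrow(rejects), " note row(s) rejected; see the rejects report")
  if (!is.null(rejects_path))
    utils::write.csv(rejects, rejects_path, row.names = FALSE)
  notes <- data.frame(patient_id = df$patient_id[ok],
                      date = parsed$date[ok],
                      source = df$source[ok],
                      text = df$text[ok],
                      stringsAsFactors = FALSE)
  corpus <- note_corpus(notes)
  attr(corpus, "rejects") <- rejects
  corpus
}

empty_notes_df <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
              source = character(), text = character(),
              stringsAsFactors = FALSE)
}

#' Construct a note corpus
#'
#' A `note_corpus` is a data frame of dated documentation events
#' (`patient_id`, `date`, `source`, `text`), kept per patient in ascending
#' date order with input order preserved among equal dates.
#'
#' @param notes data frame with columns `patient_id`, `date` (`Date`),
#'   `source`, `text`.
#' @return object of class `note_corpus`.
#' @export
note_corpus <- function(notes) {
  stopifnot(all(c("patient_id", "date", "source", "text") %in% names(notes)))
  notes$date <- as.Date(notes$date)
  if (any(is.na(notes$date))) stop("note_corpus: NA dates are not allowed")
  if (any(!nzchar(notes$patient_id))) stop("note_corpus: empty patient_id")
  # stable sort: patient, then date, then original order
  ord <- order(notes$patient_id, notes$date)  # order() is stable in R
  notes <- notes[ord, , drop = FALSE]
  rownames(notes) <- NULL
  class(notes) <- c("note_corpus", "data.frame")
  notes
}

#' @export
print.note_corpus <- function(x, ...) {
  cat("<note_corpus>: ", nrow(x), " notes, ",
      length(unique(x$patient_id)), " patients\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Write a note corpus back to CSV
#'
#' Round-trips exactly with [read_note_table()] under `dialect = "iso"`.
#'
#' @param corpus a `note_corpus`.
#' @param path output CSV path.
#' @export
write_note_table <- function(corpus, path) {
  df <- as.data.frame(corpus)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the treatment-initiation table
#'
#' One record per (patient, drug); duplicate rows keep the earliest
#' initiation date with a warning.
#'
#' @param path CSV with columns `patient_id`, `drug`, `init_date`.
#' @param dialect date dialect, see [parse_note_dates()].
#' @return data frame `patient_id`, `drug`, `init_date` (`Date`).
#' @export
read_treatment_table <- function(path, dialect = "auto") {
  raw <- utils::read.csv(path, colClasses = "character")
  for (col in c("patient_id", "drug", "init_date"))
    if (!col %in% names(raw))
      stop("treatment table is missing required column '", col, "'")
  raw$init_date <- parse_note_dates(raw$init_date, dialect)$date
  if (any(is.na(raw$init_date)))
    stop("treatment table contains unparseable init_date values")
  key <- paste(raw$patient_id, raw$drug, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (patient_id, drug) rows; keeping earliest init_date")
    raw <- raw[order(key, raw$init_date), ]
    raw <- raw[!duplicated(paste(raw$patient_id, raw$drug, sep = "\r")), ]
  }
  rownames(raw) <- NULL
  raw[, c("patient_id", "drug", "init_date")]
}

#' Remove all notes dated before treatment initiation
#'
#' Per patient, keeps notes with `date >= init_date` (the initiation day
#' itself is kept: baseline visits are often same-day and progression cannot
#' precede day 0). Patients without a treatment record are dropped and
#' reported via the `excluded_patients` attribute; patients whose notes all
#' precede initiation are *retained* with zero notes and listed in the
#' `no_followup` attribute.
#'
#' @param corpus a `note_corpus`.
#' @param treatments treatment table from [read_treatment_table()].
#' @return filtered `note_corpus` with attributes `excluded_patients` and
#'   `no_followup`.
#' @export
filter_pre_treatment <- function(corpus, treatments) {
  pts <- unique(corpus$patient_id)
  init <- treatments$init_date[match(corpus$patient_id, treatments$patient_id)]
  has_rx <- !is.na(init)
  excluded <- setdiff(pts, treatments$patient_id)
  keep <- has_rx & corpus$date >= init
  out <- as.data.frame(corpus)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("note_corpus", "data.frame")
  treated <- intersect(pts, treatments$patient_id)
  no_followup <- setdiff(treated, unique(out$patient_id))
  attr(out, "excluded_patients") <- excluded
  attr(out, "no_followup") <- no_followup
  out
}

#' Read structured PS or progression observations
#'
#' PS rows become performance-status observations with `source =
#' "structured"`; closed-question progression rows map to a timeline phase
#' (`remission`/`stable` wordings to BP, `progression` wordings to PP) via
#' `value_map`. PS values outside 0-5 are rejected and reported.
#'
#' @param path CSV with columns `patient_id`, `date`, `value`.
#' @param kind `"ps"` or `"progression"`.
#' @param dialect date dialect.
#' @param value_map named character vector mapping progression answers to
#'   phases; defaults cover Dutch and English wordings.
#' @return for `kind = "ps"` a PS-observation data frame
#'   (`patient_id, date, score, secondary_score, source, evidence`); for
#'   `kind = "progression"` a phase-observation data frame
#'   (`patient_id, date, phase, rule_id, evidence`). Rejected rows are in the
#'   `rejects` attribute.
#' @export
read_structured_observations <- function(path, kind = c("ps", "progression"),
                                         dialect = "auto",
                                         value_map = c(remissie = "BP",
                                                       remission = "BP",
                                                       stabiel = "BP",
                                                       stable = "BP",
                                                       progressie = "PP",
                                                       progression = "PP")) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, colClasses = "character")
  for (col in c("patient_id", "date", "value"))
    if (!col %in% names(raw))
      stop("structured table is missing required column '", col, "'")
  raw$date <- parse_note_dates(raw$date, dialect)$date
  bad_date <- is.na(raw$date)
  if (kind == "ps") {
    score <- suppressWarnings(as.integer(raw$value))
    ok <- !bad_date & !is.na(score) & score >= 0 & score <= 5
    out <- data.frame(patient_id = raw$patient_id[ok], date = raw$date[ok],
                      score = score[ok], secondary_score = NA_integer_,
                      source = "structured", evidence = raw$value[ok],
                      stringsAsFactors = FALSE)
  } else {
    phase <- unname(value_map[tolower(trimws(raw$value))])
    ok <- !bad_date & !is.na(phase)
    out <- data.frame(patient_id = raw$patient_id[ok], date = raw$date[ok],
                      phase = phase[ok], rule_id = "structured",
                      evidence = raw$value[ok], stringsAsFactors = FALSE)
  }
  rejects <- raw[!ok, , drop = FALSE]
  if (nrow(rejects))
    message(nrow(rejects), " structured ", kind, " row(s) rejected")
  attr(out, "rejects") <- rejects
  out
}

#' Read the scan-date table
#'
#' @param path CSV with columns `patient_id`, `scan_date` and optionally
#'   `modality`.
#' @param dialect date dialect.
#' @return data frame `patient_id`, `scan_date` (`Date`), `modality`.
#' @export
read_scan_table <- function(path, dialect = "auto") {
  raw <- utils::read.csv(path, colClasses = "character")
  for (col in c("patient_id", "scan_date"))
    if (!col %in% names(raw))
      stop("scan table is missing required column '", col, "'")
  raw$scan_date <- parse_note_dates(raw$scan_date, dialect)$date
  if (!"modality" %in% names(raw)) raw$modality <- NA_character_
  raw <- raw[!is.na(raw$scan_date), c("patient_id", "scan_date", "modality")]
  rownames(raw) <- NULL
  raw
}
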