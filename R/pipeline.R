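# End-to-end drivers: notes + treatments in, baseline-PS table and survival
# table out, plus the evaluation wrapper comparing the text-mined arm to a
# reference arm.

#' Extract the baseline performance status per patient
#'
#' Mines PS observations from the full corpus (structured observations
#' merged in when given) and matches each treated patient's baseline PS to
#' treatment initiation: nearest within 30 days before, else earliest within
#' 14 days after.
#'
#' @param corpus a [note_corpus()] (not pre-treatment filtered: pre-baseline
#'   notes are exactly where the baseline PS lives).
#' @param treatments treatment table (`patient_id`, `drug`, `init_date`).
#' @param rules a `clinotext_rules` list.
#' @param structured_ps optional structured PS observations
#'   (from [read_structured_observations()]).
#' @param before_days,after_days matching windows, see [match_baseline_ps()].
#' @return data frame `patient_id`, `date`, `score`, `secondary_score`,
#'   `source`, `evidence` — one row per matched patient. Attribute
#'   `unmatched` lists treated patients without an in-window observation;
#'   attribute `observations` carries the full mined observation table.
#' @export
extract_baseline_ps <- function(corpus, treatments, rules = default_rules(),
                                structured_ps = NULL,
                                before_days = 30L, after_days = 14L) {
  obs <- mine_corpus(corpus, "ps", rules, structured = structured_ps)
  rows <- list(); unmatched <- character()
  for (i in seq_len(nrow(treatments))) {
    pid <- treatments$patient_id[i]
    o <- obs[obs$patient_id == pid, , drop = FALSE]
    hit <- match_baseline_ps(o, treatments$init_date[i],
                             before_days = before_days,
                             after_days = after_days)
    if (is.null(hit)) unmatched <- c(unmatched, pid)
    else rows[[length(rows) + 1L]] <- hit
  }
  out <- if (length(rows)) do.call(rbind, rows) else ps_obs_df()
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  attr(out, "observations") <- obs
  out
}

#' Extract progression-free survival per patient
#'
#' Runs the progression pipeline: pre-treatment filter, sentence-preserving
#' normalization, sentence splitting, phase classification, per-patient
#' timeline, progression/censor call, scan-date realignment, and the
#' days-to-months conversion. An optional deaths table turns a death date
#' into a progression event per the PFS definition (time to first
#' progression or death from any cause); by default no deaths table is used.
#'
#' @param corpus a [note_corpus()].
#' @param treatments treatment table; an empty table is an error.
#' @param rules a `clinotext_rules` list.
#' @param scans optional scan table (`patient_id`, `scan_date`).
#' @param structured_progression optional structured phase observations.
#' @param deaths optional data frame `patient_id`, `death_date`.
#' @param confirm_window_days see [call_progression()].
#' @param max_lag_days see [align_event_to_scan()].
#' @return a `pfs_run`: list with `survival` (`patient_id`, `time_months`,
#'   `event`; resolved patients only), `calls` (`patient_id`, `status`,
#'   `event_date`, `basis`), `status` (`patient_id`, `status` in
#'   resolved/unresolved/no_followup — the cohort-flow categories),
#'   `manual_review` (patients needing manual curation and why), and
#'   `observations` (the classified sentence table).
#' @export
extract_pfs <- function(corpus, treatments, rules = default_rules(),
                        scans = NULL, structured_progression = NULL,
                        deaths = NULL, confirm_window_days = 30L,
                        max_lag_days = 14L) {
  if (is.null(treatments) || nrow(treatments) == 0)
    stop("extract_pfs: the treatment table is empty; ",
         "PFS is measured from treatment initiation")
  filtered <- filter_pre_treatment(corpus, treatments)
  no_fu <- attr(filtered, "no_followup")
  obs <- mine_corpus(filtered, "pfs", rules,
                     structured = structured_progression)
  surv <- list(); calls <- list(); status <- list(); review <- list()
  for (i in seq_len(nrow(treatments))) {
    pid <- treatments$patient_id[i]
    init <- treatments$init_date[i]
    if (pid %in% no_fu) {
      status[[pid]] <- "no_followup"
      review[[length(review) + 1L]] <- data.frame(
        patient_id = pid, reason = "no follow-up notes after initiation",
        stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- data.frame(
        patient_id = pid, status = "no_followup",
        event_date = as.Date(NA), basis = "none", stringsAsFactors = FALSE)
      next
    }
    o <- obs[obs$patient_id == pid, , drop = FALSE]
    cl <- call_progression(timeline(o, pid, init),
                           confirm_window_days = confirm_window_days)
    if (cl$status == "progressed" && !is.null(scans)) {
      sd <- scans$scan_date[scans$patient_id == pid]
      cl$event_date <- align_event_to_scan(cl$event_date, sd,
                                           max_lag_days = max_lag_days)
    }
    if (!is.null(deaths)) {
      dd <- deaths$death_date[deaths$patient_id == pid]
      if (length(dd) && !is.na(dd <- min(as.Date(dd)))) {
        if (cl$status != "progressed" || dd < cl$event_date) {
          cl$status <- "progressed"
          cl$event_date <- max(dd, init)
          cl$basis <- "death"
        }
      }
    }
    calls[[length(calls) + 1L]] <- data.frame(
      patient_id = pid, status = cl$status, event_date = cl$event_date,
      basis = cl$basis, stringsAsFactors = FALSE)
    if (cl$status %in% c("progressed", "censored")) {
      status[[pid]] <- "resolved"
      surv[[length(surv) + 1L]] <- compute_pfs(cl, init)
    } else {
      status[[pid]] <- "unresolved"
      review[[length(review) + 1L]] <- data.frame(
        patient_id = pid, reason = "conflicting or absent phase evidence",
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, empty) if (length(x)) do.call(rbind, x) else empty
  res <- list(
    survival = bind(surv, data.frame(patient_id = character(),
                                     time_months = numeric(),
                                     event = logical())),
    calls = bind(calls, data.frame(patient_id = character(),
                                   status = character(),
                                   event_date = as.Date(character()),
                                   basis = character())),
    status = data.frame(patient_id = names(status),
                        status = unlist(status, use.names = FALSE),
                        stringsAsFactors = FALSE),
    manual_review = bind(review, data.frame(patient_id = character(),
                                            reason = character())),
    observations = obs)
  rownames(res$survival) <- rownames(res$calls) <- NULL
  class(res) <- "pfs_run"
  res
}

#' @export
print.pfs_run <- function(x, ...) {
  tab <- table(factor(x$status$status,
                      c("resolved", "unresolved", "no_followup")))
  cat("<pfs_run>", nrow(x$status), "patients:",
      tab[["resolved"]], "resolved,", tab[["unresolved"]], "unresolved,",
      tab[["no_followup"]], "without follow-up\n")
  if (nrow(x$survival))
    cat(sprintf("  events %d / censored %d; median follow-up input via km_estimate()\n",
                sum(x$survival$event), sum(!x$survival$event)))
  invisible(x)
}

#' Compare the text-mined arm to a reference arm
#'
#' The full evaluation in one call: PS confusion matrix and weighted F1,
#' Kaplan-Meier estimates of both arms, Harrell's C-index with the reference
#' arm as outcome, ratio-based discrepancy flags, the scatter table, and the
#' cohort-flow accounting.
#'
#' @param tm_ps,ref_ps baseline PS tables (`patient_id`, `score`).
#' @param tm_surv,ref_surv survival tables (`patient_id`, `time_months`,
#'   `event`).
#' @param patients optional full cohort id vector for the flow table
#'   (default: union of the reference tables).
#' @param tm_status,ref_status optional status tables for [cohort_flow()];
#'   when omitted, every patient present in an arm's survival table counts
#'   as resolved there.
#' @return an `evaluation_report`: list with `ps` (a [ps_metrics()] result),
#'   `km_tm`, `km_ref`, `concordance`, `flags`, `scatter`, `flow`.
#' @export
evaluate_extraction <- function(tm_ps, ref_ps, tm_surv, ref_surv,
                                patients = NULL, tm_status = NULL,
                                ref_status = NULL) {
  if (is.null(patients))
    patients <- unique(c(ref_surv$patient_id, ref_ps$patient_id,
                         tm_surv$patient_id))
  as_status <- function(st, surv) {
    if (!is.null(st)) return(st)
    data.frame(patient_id = surv$patient_id, status = "resolved",
               stringsAsFactors = FALSE)
  }
  structure(list(
    ps = ps_metrics(tm_ps, ref_ps),
    km_tm = km_estimate(tm_surv),
    km_ref = km_estimate(ref_surv),
    concordance = concordance_index(tm_surv, ref_surv),
    flags = flag_discrepancies(tm_surv, ref_surv),
    scatter = pfs_scatter(tm_surv, ref_surv),
    flow = cohort_flow(patients, as_status(tm_status, tm_surv),
                       as_status(ref_status, ref_surv))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$ps)
  cat("\nText-mined arm:    "); print(x$km_tm)
  cat("Reference arm:     "); print(x$km_ref)
  cat("\n"); print(x$concordance)
  nf <- sum(x$flags$flagged)
  cat(nf, "patient(s) flagged with a PFS ratio > 3 or < 1/3\n")
  invisible(x)
}
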