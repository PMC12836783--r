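# Temporal resolution: baseline-PS matching, scan-date realignment,
# per-patient timelines, and the progression/censor call.

DAYS_PER_MONTH <- 30.44

#' Match a baseline performance status to treatment initiation
#'
#' Among observations dated within the 30 days up to and including
#' initiation, the one closest to initiation wins. Only if that window is
#' empty is a PS up to 14 days *after* initiation allowed (the earliest
#' such). Same-day ties: structured source beats mined, then the lower
#' (better-documented, conservative) score.
#'
#' @param observations PS-observation data frame for one patient.
#' @param init_date treatment initiation date.
#' @param before_days,after_days window widths in days (defaults 30 and 14).
#' @return one-row PS-observation data frame, or `NULL` if no observation
#'   falls in either window.
#' @export
match_baseline_ps <- function(observations, init_date,
                              before_days = 30L, after_days = 14L) {
  if (is.null(observations) || nrow(observations) == 0) return(NULL)
  if (length(unique(observations$patient_id)) > 1)
    stop("match_baseline_ps expects observations of a single patient")
  init_date <- as.Date(init_date)
  off <- as.numeric(observations$date - init_date)
  before <- which(off >= -before_days & off <= 0)
  cand <- if (length(before)) {
    best_off <- max(off[before])
    before[off[before] == best_off]
  } else {
    after <- which(off > 0 & off <= after_days)
    if (!length(after)) return(NULL)
    best_off <- min(off[after])
    after[off[after] == best_off]
  }
  if (length(cand) > 1) {   # same-day tie-break
    o <- observations[cand, ]
    ord <- order(o$source != "structured", o$score)
    cand <- cand[ord[1]]
  }
  observations[cand[1], , drop = FALSE]
}

#' Realign an event date to the nearest preceding scan
#'
#' Progression is typically documented at the outpatient visit a few days
#' after the CT/MRI scan that shows it; the scan date is the more accurate
#' event date. Returns the latest scan date within `max_lag_days` before (or
#' on) the event date; with no such scan the event date is unchanged.
#'
#' @param event_date event (visit) date.
#' @param scan_dates scan dates of the same patient (`Date` vector).
#' @param max_lag_days lookback window in days (default 14).
#' @return a `Date`.
#' @export
align_event_to_scan <- function(event_date, scan_dates, max_lag_days = 14L) {
  event_date <- as.Date(event_date)
  if (is.null(scan_dates) || !length(scan_dates)) return(event_date)
  scan_dates <- as.Date(scan_dates)
  lag <- as.numeric(event_date - scan_dates)
  ok <- !is.na(lag) & lag >= 0 & lag <= max_lag_days
  if (!any(ok)) return(event_date)
  max(scan_dates[ok])
}

#' Build a per-patient timeline of phase observations
#'
#' @param phase_obs phase-observation data frame for one patient.
#' @param patient_id,init_date patient metadata.
#' @return a `timeline` object: observations sorted ascending by date
#'   (stable), all dated on/after `init_date`.
#' @export
timeline <- function(phase_obs, patient_id, init_date) {
  init_date <- as.Date(init_date)
  if (nrow(phase_obs)) {
    if (any(phase_obs$date < init_date))
      stop("timeline: observation dated before treatment initiation")
    phase_obs <- phase_obs[order(phase_obs$date), , drop = FALSE]
    rownames(phase_obs) <- NULL
  }
  structure(list(patient_id = patient_id, init_date = init_date,
                 observations = phase_obs), class = "timeline")
}

#' @export
print.timeline <- function(x, ...) {
  cat("<timeline> patient", x$patient_id, "init", format(x$init_date),
      "-", nrow(x$observations), "observations\n")
  if (nrow(x$observations)) print.data.frame(x$observations)
  invisible(x)
}

#' Call the progression or censor date from a timeline
#'
#' The chronological overview of BP/PP/AP labels is resolved to one call:
#' \itemize{
#'   \item The earliest PP observation is the candidate progression date. It
#'     is \emph{confirmed} — and becomes the event date — if no BP follows
#'     within `confirm_window_days`, or if another PP/AP on or after it
#'     precedes the first contradicting BP.
#'   \item A candidate contradicted by a BP within the window is retracted;
#'     the next PP after that BP is then evaluated the same way.
#'   \item With no (confirmed) PP but an AP present after the last
#'     contradicting BP, the first such AP date is the event date
#'     (`basis = "ap_only"`): a post-progression treatment line implies the
#'     event occurred at or before it.
#'   \item Only BP observations: censored at the last BP date.
#'   \item An empty timeline, or a retracted PP never re-asserted:
#'     `unresolved`, routed to manual review.
#' }
#'
#' @param tl a [timeline()].
#' @param confirm_window_days days a later BP can retract a PP (default 30).
#' @return a `progression_call`: list with `patient_id`, `status`
#'   (`progressed`/`censored`/`unresolved`), `event_date`, `basis`
#'   (`pp_confirmed`, `ap_only`, `structured`, `censor_last_note`, `none`)
#'   and `evidence` (the defining observation row, if any).
#' @export
call_progression <- function(tl, confirm_window_days = 30L) {
  stopifnot(inherits(tl, "timeline"))
  obs <- tl$observations
  mkcall <- function(status, event_date = as.Date(NA), basis = "none",
                     evidence = NULL) {
    structure(list(patient_id = tl$patient_id, status = status,
                   event_date = as.Date(event_date), basis = basis,
                   evidence = evidence), class = "progression_call")
  }
  if (is.null(obs) || nrow(obs) == 0) return(mkcall("unresolved"))
  pp_idx <- which(obs$phase == "PP")
  bp_dates <- obs$date[obs$phase == "BP"]
  search_from <- as.Date(-Inf, origin = "1970-01-01")
  while (length(pp_idx)) {
    i <- pp_idx[obs$date[pp_idx] >= search_from][1]
    if (is.na(i)) break
    cand <- obs$date[i]
    bp_after <- bp_dates[bp_dates > cand &
                         bp_dates <= cand + confirm_window_days]
    if (!length(bp_after)) {
      basis <- if (identical(obs$rule_id[i], "structured")) "structured"
               else "pp_confirmed"
      return(mkcall("progressed", cand, basis, obs[i, , drop = FALSE]))
    }
    first_bp <- min(bp_after)
    reassert <- which((obs$phase %in% c("PP", "AP")) & obs$date >= cand &
                      obs$date < first_bp)
    reassert <- setdiff(reassert, i)
    if (length(reassert)) {
      basis <- if (identical(obs$rule_id[i], "structured")) "structured"
               else "pp_confirmed"
      return(mkcall("progressed", cand, basis, obs[i, , drop = FALSE]))
    }
    # retracted: move past the contradicting BP
    search_from <- first_bp
    pp_idx <- pp_idx[obs$date[pp_idx] >= search_from]
  }
  # no confirmed PP; an AP after the last retraction point still implies the
  # event happened
  ap_idx <- which(obs$phase == "AP" & obs$date >= search_from)
  if (length(ap_idx)) {
    i <- ap_idx[1]
    return(mkcall("progressed", obs$date[i], "ap_only",
                  obs[i, , drop = FALSE]))
  }
  had_pp <- any(obs$phase == "PP")
  if (!had_pp && any(obs$phase == "BP"))
    return(mkcall("censored", max(bp_dates), "censor_last_note"))
  mkcall("unresolved")
}

#' @export
print.progression_call <- function(x, ...) {
  cat("<progression_call>", x$patient_id, "-", x$status,
      if (!is.na(x$event_date)) paste("at", format(x$event_date)) else "",
      paste0("(basis: ", x$basis, ")\n"))
  invisible(x)
}

#' Convert a resolved progression call to a survival record
#'
#' PFS is the time from treatment initiation to the first sign of disease
#' progression (or the censor date), in months of 30.44 days.
#'
#' @param call a `progression_call` with status `progressed` or `censored`.
#' @param init_date treatment initiation date.
#' @return one-row data frame `patient_id`, `time_months`, `event`.
#' @export
compute_pfs <- function(call, init_date) {
  stopifnot(inherits(call, "progression_call"))
  if (!call$status %in% c("progressed", "censored"))
    stop("compute_pfs: call status '", call$status,
         "' has no survival representation; resolve or exclude the patient")
  init_date <- as.Date(init_date)
  if (call$event_date < init_date)
    stop("compute_pfs: event date precedes treatment initiation")
  days <- as.numeric(call$event_date - init_date)
  data.frame(patient_id = call$patient_id,
             time_months = days / DAYS_PER_MONTH,
             event = call$status == "progressed",
             stringsAsFactors = FALSE)
}
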