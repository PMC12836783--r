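# Evaluation of the text-mined output against reference data: confusion
# matrix and weighted F1 for PS, Kaplan-Meier median PFS with CI, Harrell's
# concordance index, ratio-based discrepancy flags, cohort-flow accounting.

#' Class-wise and weighted F1 for performance status
#'
#' Scores are computed over patients present in both tables (unmatched
#' patients are counted, not scored). Precision, recall and F1 are reported
#' per class on the 0-100% scale; the weighted F1 is the support-weighted
#' mean of class F1 (supports taken from the truth column). A class that is
#' never predicted gets precision 0 with a warning, keeping the weighted
#' total defined.
#'
#' @param predicted data frame `patient_id`, `score` (text-mined baseline PS).
#' @param truth data frame `patient_id`, `score` (reference PS).
#' @return a `ps_metrics` object: list with `confusion` (true x predicted
#'   matrix), `per_class` (precision/recall/f1/support), `weighted_f1`,
#'   `accuracy`, `n_scored`, `n_pred_only`, `n_truth_only`.
#' @export
ps_metrics <- function(predicted, truth) {
  common <- intersect(predicted$patient_id, truth$patient_id)
  if (!length(common))
    stop("ps_metrics: no overlapping patients between predicted and truth")
  p <- predicted$score[match(common, predicted$patient_id)]
  t <- truth$score[match(common, truth$patient_id)]
  classes <- sort(unique(c(p, t)))
  cm <- table(truth = factor(t, classes), predicted = factor(p, classes))
  tp <- diag(cm)
  pred_n <- colSums(cm); true_n <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  if (any(pred_n == 0 & true_n > 0))
    warning("class(es) never predicted: precision set to 0 for ",
            paste(classes[pred_n == 0 & true_n > 0], collapse = ", "))
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes,
                          precision = 100 * precision,
                          recall = 100 * recall,
                          f1 = 100 * f1,
                          support = as.integer(true_n))
  rownames(per_class) <- NULL
  weighted_f1 <- sum(per_class$f1 * per_class$support) / sum(per_class$support)
  structure(list(confusion = cm, per_class = per_class,
                 weighted_f1 = weighted_f1,
                 accuracy = 100 * sum(tp) / length(common),
                 n_scored = length(common),
                 n_pred_only = length(setdiff(predicted$patient_id, common)),
                 n_truth_only = length(setdiff(truth$patient_id, common))),
            class = "ps_metrics")
}

#' @export
print.ps_metrics <- function(x, digits = 1, ...) {
  cat("Performance-status agreement on", x$n_scored, "patients",
      sprintf("(%d reference-only, %d text-mined-only excluded)\n",
              x$n_truth_only, x$n_pred_only))
  print(x$confusion)
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <- round(pc[c("precision", "recall", "f1")], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("weighted F1: %.*f%%   accuracy: %.*f%%\n",
              digits, x$weighted_f1, digits, x$accuracy))
  invisible(x)
}

#' Kaplan-Meier estimate of the PFS curve and its median
#'
#' Product-limit estimate with Greenwood standard errors and log-log
#' pointwise confidence bands; the median and its 95% CI are read off where
#' the curve (and its band) first drop to 0.5 or below
#' (Brookmeyer-Crowley-style inversion, as `survival::survfit` implements).
#' With every record censored the curve never reaches 0.5 and the median and
#' CI are `NA`, not an error.
#'
#' @param records data frame `time_months` (>= 0), `event` (logical).
#' @param conf_level confidence level for the bands (default 0.95).
#' @return a `km_estimate`: list with `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n_event`, `median`, `median_ci` (length 2), `n`, and the
#'   underlying `survfit` object in `fit`.
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  stopifnot(nrow(records) >= 1, all(records$time_months >= 0))
  fit <- survival::survfit(
    survival::Surv(records$time_months, as.integer(records$event)) ~ 1,
    conf.type = "log-log", conf.int = conf_level)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  ci <- c(unname(stats::quantile(fit, probs = 0.5)$lower),
          unname(stats::quantile(fit, probs = 0.5)$upper))
  structure(list(time = fit$time, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = med, median_ci = ci, n = nrow(records),
                 conf_level = conf_level, fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate, n = %d, events = %d\n",
              x$n, sum(x$n_event)))
  if (is.na(x$median)) {
    cat("median: not reached\n")
  } else {
    cat(sprintf("median %.2f months (%.0f%% CI %.2f-%.2f)\n", x$median,
                100 * x$conf_level, x$median_ci[1], x$median_ci[2]))
  }
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, xlab = "Months", ylab = "PFS probability",
                             ...) {
  plot(x$fit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Harrell's concordance index between text-mined and reference PFS
#'
#' All patient pairs are enumerated. A pair is \emph{comparable} when the
#' reference arm can order it under censoring: the shorter reference time
#' carries an event (equal reference times are not orderable). A comparable
#' pair is \emph{concordant} when the text-mined times order the same way;
#' ties in the text-mined times count 0.5. Comparability is decided on the
#' reference arm only; censored text-mined times enter at their recorded
#' value.
#'
#' @param tm data frame `patient_id`, `time_months`, `event` (text-mined).
#' @param reference same schema (reference arm, treated as the outcome).
#' @return a `concordance_result`: list with `c_index`, `concordant`,
#'   `discordant`, `tied`, `comparable`, `n`. Fewer than 2 comparable pairs
#'   gives `c_index = NA` with a warning.
#' @export
concordance_index <- function(tm, reference) {
  common <- intersect(tm$patient_id, reference$patient_id)
  xt <- tm$time_months[match(common, tm$patient_id)]
  rt <- reference$time_months[match(common, reference$patient_id)]
  re <- as.logical(reference$event[match(common, reference$patient_id)])
  n <- length(common)
  # pair (i, j): comparable iff the earlier reference time is an event
  dt <- outer(rt, rt, "-")             # rt_i - rt_j
  ev_i <- matrix(re, n, n)             # event flag of i, by row
  comparable <- (dt < 0 & ev_i)        # i strictly earlier and an event
  dx <- outer(xt, xt, "-")
  conc <- sum(comparable & dx < 0)
  disc <- sum(comparable & dx > 0)
  tied <- sum(comparable & dx == 0)
  ncomp <- conc + disc + tied
  ci <- if (ncomp >= 2) (conc + 0.5 * tied) / ncomp else {
    warning("fewer than 2 comparable pairs; C-index undefined")
    NA_real_
  }
  structure(list(c_index = ci, concordant = conc, discordant = disc,
                 tied = tied, comparable = ncomp, n = n),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.3f over %d comparable pairs (%d patients; %d concordant / %d discordant / %d tied)\n",
              x$c_index, x$comparable, x$n, x$concordant, x$discordant,
              x$tied))
  invisible(x)
}

#' Flag large discrepancies between text-mined and reference PFS
#'
#' For every patient with a time in both arms the ratio text-mined /
#' reference is computed; ratios above 3 or below 1/3 are flagged for
#' root-cause review. A reference time of zero makes the ratio undefined;
#' such rows are flagged too. Output is sorted by |log ratio| descending.
#'
#' @param tm,reference data frames `patient_id`, `time_months`.
#' @param upper flag threshold (default 3; lower threshold is its
#'   reciprocal).
#' @return data frame `patient_id`, `tm_months`, `ref_months`, `ratio`,
#'   `flagged`.
#' @export
flag_discrepancies <- function(tm, reference, upper = 3) {
  common <- intersect(tm$patient_id, reference$patient_id)
  xt <- tm$time_months[match(common, tm$patient_id)]
  rt <- reference$time_months[match(common, reference$patient_id)]
  ratio <- ifelse(rt > 0, xt / rt, NA_real_)
  flagged <- is.na(ratio) | ratio > upper | ratio < 1 / upper
  out <- data.frame(patient_id = common, tm_months = xt, ref_months = rt,
                    ratio = ratio, flagged = flagged,
                    stringsAsFactors = FALSE)
  key <- abs(log(out$ratio))
  key[is.na(key) | !is.finite(key)] <- Inf
  out <- out[order(-key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort-flow accounting across the two arms
#'
#' Tallies, per arm, how every patient ended up: `resolved` (a usable event
#' or censor time), `unresolved` (conflicting evidence routed to manual
#' review), `no_followup` (no notes after initiation), `unmatched` (absent
#' from the arm). Categories partition the cohort; the function errors if
#' they do not.
#'
#' @param patients character vector of all cohort patient ids.
#' @param status named list or data frame mapping `patient_id` to a status
#'   string per arm; see `tm_status`/`ref_status` arguments.
#' @param tm_status,ref_status data frames `patient_id`, `status` with
#'   status in `c("resolved", "unresolved", "no_followup")`; patients absent
#'   from a table are `unmatched` in that arm.
#' @return a `cohort_flow` data frame: one row per category, columns
#'   `category`, `tm`, `reference`; attribute `n` is the cohort size.
#' @export
cohort_flow <- function(patients, tm_status, ref_status) {
  cats <- c("resolved", "unresolved", "no_followup", "unmatched")
  tally <- function(tab) {
    st <- tab$status[match(patients, tab$patient_id)]
    st[is.na(st)] <- "unmatched"
    if (!all(st %in% cats))
      stop("cohort_flow: unknown status value(s): ",
           paste(setdiff(unique(st), cats), collapse = ", "))
    table(factor(st, cats))
  }
  out <- data.frame(category = cats,
                    tm = as.integer(tally(tm_status)),
                    reference = as.integer(tally(ref_status)),
                    stringsAsFactors = FALSE)
  stopifnot(sum(out$tm) == length(patients),
            sum(out$reference) == length(patients))
  attr(out, "n") <- length(patients)
  class(out) <- c("cohort_flow", "data.frame")
  out
}

#' Scatter table of text-mined versus reference PFS
#'
#' One point per patient resolved in both arms, the numbers behind the
#' TM-vs-manual scatterplot.
#'
#' @param tm,reference data frames `patient_id`, `time_months`.
#' @return data frame `patient_id`, `tm_months`, `ref_months`.
#' @export
pfs_scatter <- function(tm, reference) {
  common <- intersect(tm$patient_id, reference$patient_id)
  data.frame(patient_id = common,
             tm_months = tm$time_months[match(common, tm$patient_id)],
             ref_months = reference$time_months[match(common, reference$patient_id)],
             stringsAsFactors = FALSE)
}
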