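# Synthetic cohorts with known ground truth, rendered as clinical-note
# corpora with configurable, documented noise modes. The generator is the
# oracle for all end-to-end tests: every planted PS mention and the planted
# progression/censor date are recorded in the ground truth.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a real-world advanced-NSCLC cohort on a targeted agent:
#' baseline PS mass concentrated on 0-2, progression-free survival
#' exponential with a single-digit median in months, routine follow-up
#' visits about every six weeks, and a CT/MRI scan a few days before the
#' visit at which progression is discussed.
#'
#' Noise rates reproduce the documented failure modes of rule-based PS/PFS
#' extraction: `p_misspell_zero` renders a PS of 0 as the letter O
#' (`"WHO O"`), `p_intervening` puts words between keyword and score
#' (`"PS is 2"`), `p_vague_progression` describes the progression visit in
#' symptom language outside the rule lexicon, `p_abbrev` writes drug
#' shorthands (`"osi"`), and `p_missing_ps_mention` drops a planted PS
#' mention altogether.
#'
#' @param n_patients cohort size.
#' @param ps_probs probability vector over PS 0-5 (normalized internally).
#' @param pfs_dist `"exponential"` or `"weibull"`.
#' @param median_months median of the PFS distribution, months.
#' @param weibull_shape shape when `pfs_dist = "weibull"`.
#' @param censoring_prob marginal probability a patient is censored before
#'   progression (independent exponential censoring).
#' @param max_followup_months administrative cutoff; `Inf` disables it.
#' @param visit_interval_days,visit_jitter_days follow-up visit cadence.
#' @param scan_lead_days integer range (length 2) of days the scan precedes
#'   the progression visit.
#' @param n_ap_visits follow-up visits rendered after the progression visit.
#' @param p_misspell_zero,p_intervening,p_vague_progression,p_abbrev,p_missing_ps_mention
#'   noise rates in \[0, 1\].
#' @param language `"en"` or `"nl"` note templates.
#' @param seed integer RNG seed; the whole cohort (text included) is a pure
#'   function of the config.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 300L,
                             ps_probs = c(90, 163, 51, 22, 0, 0) / 326,
                             pfs_dist = c("exponential", "weibull"),
                             median_months = 8.0,
                             weibull_shape = 1.2,
                             censoring_prob = 0.2,
                             max_followup_months = Inf,
                             visit_interval_days = 42,
                             visit_jitter_days = 10,
                             scan_lead_days = c(2L, 7L),
                             n_ap_visits = 2L,
                             p_misspell_zero = 0,
                             p_intervening = 0,
                             p_vague_progression = 0,
                             p_abbrev = 0,
                             p_missing_ps_mention = 0,
                             language = c("en", "nl"),
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              ps_probs = ps_probs / sum(ps_probs),
              pfs_dist = match.arg(pfs_dist),
              median_months = median_months,
              weibull_shape = weibull_shape,
              censoring_prob = censoring_prob,
              max_followup_months = max_followup_months,
              visit_interval_days = visit_interval_days,
              visit_jitter_days = visit_jitter_days,
              scan_lead_days = as.integer(scan_lead_days),
              n_ap_visits = as.integer(n_ap_visits),
              p_misspell_zero = p_misspell_zero,
              p_intervening = p_intervening,
              p_vague_progression = p_vague_progression,
              p_abbrev = p_abbrev,
              p_missing_ps_mention = p_missing_ps_mention,
              language = match.arg(language),
              seed = as.integer(seed))
  bad <- character()
  if (cfg$n_patients < 1) bad <- c(bad, "n_patients must be >= 1")
  if (length(cfg$ps_probs) != 6 || any(cfg$ps_probs < 0))
    bad <- c(bad, "ps_probs must be 6 nonnegative weights (PS 0-5)")
  if (cfg$median_months <= 0) bad <- c(bad, "median_months must be > 0")
  probs <- c("censoring_prob", "p_misspell_zero", "p_intervening",
             "p_vague_progression", "p_abbrev", "p_missing_ps_mention")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad <- c(bad, paste(p, "must be in [0, 1]"))
  if (cfg$censoring_prob >= 1) bad <- c(bad, "censoring_prob must be < 1")
  if (length(cfg$scan_lead_days) != 2 || any(cfg$scan_lead_days < 0))
    bad <- c(bad, "scan_lead_days must be two nonnegative integers")
  if (length(bad)) stop("invalid synthetic_config:\n  ",
                        paste(bad, collapse = "\n  "))
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

draw_pfs_months <- function(n, cfg) {
  if (cfg$pfs_dist == "exponential") {
    stats::rexp(n, rate = log(2) / cfg$median_months)
  } else {
    scale <- cfg$median_months / log(2)^(1 / cfg$weibull_shape)
    stats::rweibull(n, shape = cfg$weibull_shape, scale = scale)
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, per patient: an initiation date, a baseline PS, a latent PFS time
#' from the configured distribution, an independent exponential censoring
#' time calibrated so the marginal censoring probability equals
#' `censoring_prob` (plus an administrative cutoff when
#' `max_followup_months` is finite), and the follow-up visit schedule. The
#' visit grid determines the *reference* (chart-detectable) dates: an event
#' is referenced at the scan taken a few days before the first visit on or
#' after the latent progression date; a censored patient is referenced at
#' the last visit before the latent censor time.
#'
#' @param config a [synthetic_config()].
#' @return a `ground_truth` object: list with `patients` (one row per
#'   patient: ids, dates, latent and reference times), `visits` (one row per
#'   scheduled visit with its phase), `scans`, `treatments`, and the config.
#'   Fully reproducible from `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  id <- sprintf("P%04d", seq_len(n))
  init <- as.Date("2019-01-01") + sample.int(365, n, replace = TRUE)
  ps <- sample(0:5, n, replace = TRUE, prob = config$ps_probs)
  t_lat <- draw_pfs_months(n, config)
  rate_t <- log(2) / config$median_months
  c_lat <- if (config$censoring_prob > 0) {
    rate_c <- rate_t * config$censoring_prob / (1 - config$censoring_prob)
    stats::rexp(n, rate = rate_c)
  } else rep(Inf, n)
  c_lat <- pmin(c_lat, config$max_followup_months)
  event <- t_lat <= c_lat
  obs_months <- pmin(t_lat, c_lat)

  patients <- data.frame(patient_id = id, init_date = init, true_ps = ps,
                         latent_months = obs_months, event = event,
                         stringsAsFactors = FALSE)
  visits <- vector("list", n)
  scans <- vector("list", n)
  ref_date <- as.Date(rep(NA, n))
  for (i in seq_len(n)) {
    end_day <- obs_months[i] * DAYS_PER_MONTH
    pre <- -(5L + sample.int(6L, 1L))          # one pre-treatment visit
    days <- c(pre, 0)
    t <- 0
    repeat {
      step <- max(7, round(stats::rnorm(1, config$visit_interval_days,
                                        config$visit_jitter_days)))
      t <- t + step
      if (event[i]) {
        days <- c(days, t)
        if (t >= end_day) break                # the progression visit
      } else {
        if (t > end_day) break                 # follow-up ends at censoring
        days <- c(days, t)
      }
    }
    if (event[i]) {
      prog_visit <- t
      lead <- config$scan_lead_days[1] +
        sample.int(config$scan_lead_days[2] - config$scan_lead_days[1] + 1L,
                   1L) - 1L
      scan_day <- max(0, prog_visit - lead)
      ref_date[i] <- init[i] + scan_day
      ap <- numeric(config$n_ap_visits)
      tt <- prog_visit
      for (k in seq_len(config$n_ap_visits)) {
        tt <- tt + max(7, round(stats::rnorm(1, config$visit_interval_days,
                                             config$visit_jitter_days)))
        ap[k] <- tt
      }
      days <- c(days, ap)
      phase <- ifelse(days < prog_visit, "BP",
                      ifelse(days == prog_visit, "PP", "AP"))
      scans[[i]] <- data.frame(patient_id = id[i],
                               scan_date = init[i] + scan_day,
                               modality = "CT", stringsAsFactors = FALSE)
    } else {
      ref_date[i] <- init[i] + max(days[days >= 0])
      phase <- rep("BP", length(days))
      scans[[i]] <- NULL
    }
    visits[[i]] <- data.frame(patient_id = id[i], day = days,
                              date = init[i] + days, phase = phase,
                              stringsAsFactors = FALSE)
  }
  patients$ref_event_date <- ref_date
  patients$ref_months <-
    as.numeric(patients$ref_event_date - patients$init_date) / DAYS_PER_MONTH
  truth <- list(patients = patients,
                visits = do.call(rbind, visits),
                scans = do.call(rbind, scans),
                treatments = data.frame(patient_id = id,
                                        drug = "osimertinib",
                                        init_date = init,
                                        stringsAsFactors = FALSE),
                config = config)
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  p <- x$patients
  cat("<ground_truth>", nrow(p), "patients,",
      sum(p$event), "events /", sum(!p$event), "censored;",
      nrow(x$visits), "visits\n")
  invisible(x)
}

note_templates <- function(language) {
  if (language == "en") list(
    ps_forms = c("WHO %d", "ECOG %d", "PS %d", "who %d", "ECOG: %d"),
    ps_intervening = c("PS is %d", "WHO score is %d", "ECOG of about %d"),
    ps_misspell = c("WHO O", "who O"),
    bp = c("stable disease on the ct scan",
           "no signs of progression",
           "remission of the known lesions"),
    pp = c("ct shows progression of the disease",
           "new lesions in the left lower lobe",
           "clear progression of the known metastasis"),
    vague = c("growth of a metastasis, puncture planned to determine the resistance mechanism",
              "increasing complaints, further analysis planned"),
    ap_start = c("start %s next week", "switch to %s"),
    ap = c("treated with %s after progression",
           "second cycle of %s since progression"),
    intro = c("follow-up visit", "outpatient visit", "telephone consult"),
    baseline = c("start %s today", "initiation of %s 80 mg"))
  else list(
    ps_forms = c("WHO %d", "ECOG %d", "PS %d", "who %d", "ECOG: %d"),
    ps_intervening = c("PS is %d", "WHO is nu %d", "ECOG van ongeveer %d"),
    ps_misspell = c("WHO O", "who O"),
    bp = c("stabiel beeld op de ct",
           "geen aanwijzingen voor progressie",
           "remissie van bekende laesies"),
    pp = c("ct toont progressie van de ziekte",
           "nieuwe laesies in de linker onderkwab",
           "duidelijke progressie van bekende metastasen"),
    vague = c("groei van een metastase, punctie gepland voor resistentiemechanisme",
              "toenemende klachten, verdere analyse gepland"),
    ap_start = c("start %s volgende week", "wissel naar %s"),
    ap = c("behandeling met %s na progressie",
           "tweede kuur %s sinds progressie"),
    intro = c("controle", "polikliniekbezoek", "telefonisch consult"),
    baseline = c("start %s vandaag", "start %s 80 mg"))
}

pick <- function(u, k) as.integer(floor(u * k)) + 1L

#' Render a ground-truth cohort as a clinical-note corpus
#'
#' Each scheduled visit becomes one dated note. Visit notes before the
#' progression visit carry before-progression (BP) sentences, the
#' progression visit a PP sentence (or a vague symptom description with
#' probability `p_vague_progression`), and later visits AP sentences
#' including the start of a post-progression drug. Each visit note also
#' carries a PS mention with probability `1 - p_missing_ps_mention`,
#' rendered adversarially per the noise rates. Corruption decisions use
#' common random numbers: the same seed at a higher noise rate corrupts a
#' superset of mentions, so degradation is monotone by construction.
#'
#' @param truth a `ground_truth` from [generate_cohort()].
#' @param config the same [synthetic_config()] (noise rates may differ from
#'   the one inside `truth`; the visit schedule is taken from `truth`).
#' @return list with `corpus` (a [note_corpus()]), `treatments`, `scans`,
#'   and `mention_ledger` (one row per planted PS mention: date, rendered
#'   form, adversarial mode, whether it is extractable by the strict rule).
#' @export
render_notes <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  tpl <- note_templates(config$language)
  post_drugs <- c("carboplatin", "pemetrexed", "docetaxel")
  if (config$language == "nl") post_drugs[1] <- "carboplatine"
  set.seed(config$seed + 1L)
  v <- truth$visits
  p <- truth$patients
  true_ps <- p$true_ps[match(v$patient_id, p$patient_id)]
  init <- p$init_date[match(v$patient_id, p$patient_id)]
  nv <- nrow(v)
  U <- matrix(stats::runif(nv * 8L), nv, 8L)  # fixed draw count per visit
  notes <- character(nv)
  ledger <- vector("list", nv)
  for (i in seq_len(nv)) {
    u <- U[i, ]
    lines <- tpl$intro[pick(u[1], length(tpl$intro))]
    # PS mention
    mention <- u[2] >= config$p_missing_ps_mention
    if (mention) {
      ps <- true_ps[i]
      misspell <- ps == 0 && u[3] < config$p_misspell_zero
      interv <- !misspell && u[4] < config$p_intervening
      form <- if (misspell) tpl$ps_misspell[pick(u[5], length(tpl$ps_misspell))]
        else if (interv)
          sprintf(tpl$ps_intervening[pick(u[5], length(tpl$ps_intervening))], ps)
        else sprintf(tpl$ps_forms[pick(u[5], length(tpl$ps_forms))], ps)
      lines <- c(lines, form)
      ledger[[i]] <- data.frame(
        patient_id = v$patient_id[i], date = v$date[i], score = ps,
        form = form,
        adversarial = if (misspell) "misspell_zero"
                      else if (interv) "intervening" else "none",
        extractable = !misspell && !interv, stringsAsFactors = FALSE)
    }
    # phase sentence
    day <- v$day[i]
    drug_alias <- if (config$language == "nl") "osi" else "osi"
    doi <- if (u[6] < config$p_abbrev) drug_alias else "osimertinib"
    phase_line <- if (day < 0) {
      tpl$bp[pick(u[7], length(tpl$bp))]
    } else if (day == 0) {
      # the baseline note also documents disease status, so a patient whose
      # follow-up ends before the first control visit still censors cleanly
      paste(sprintf(tpl$baseline[pick(u[7], length(tpl$baseline))], doi),
            tpl$bp[pick(u[8], length(tpl$bp))], sep = "\n")
    } else if (v$phase[i] == "BP") {
      tpl$bp[pick(u[7], length(tpl$bp))]
    } else if (v$phase[i] == "PP") {
      if (u[8] < config$p_vague_progression)
        tpl$vague[pick(u[7], length(tpl$vague))]
      else tpl$pp[pick(u[7], length(tpl$pp))]
    } else {
      pd <- post_drugs[pick(u[7], length(post_drugs))]
      is_first_ap <- day == min(v$day[v$patient_id == v$patient_id[i] &
                                      v$phase == "AP"])
      if (is_first_ap) sprintf(tpl$ap_start[pick(u[8], length(tpl$ap_start))], pd)
      else sprintf(tpl$ap[pick(u[8], length(tpl$ap))], pd)
    }
    lines <- c(lines, phase_line)
    notes[i] <- paste(lines, collapse = "\n")
  }
  corpus <- note_corpus(data.frame(patient_id = v$patient_id, date = v$date,
                                   source = "outpatient", text = notes,
                                   stringsAsFactors = FALSE))
  ledger <- do.call(rbind, ledger)
  list(corpus = corpus, treatments = truth$treatments, scans = truth$scans,
       mention_ledger = ledger)
}

#' Reference tables derived from the ground truth
#'
#' The reference arm stands in for manual chart curation: its PS is the true
#' baseline PS and its event/censor dates are the chart-detectable ones (the
#' pre-progression scan date for events, the last visit for censored
#' patients). `time = "latent"` returns the latent simulated times instead
#' (the generator's distribution before visit-grid discretization), which is
#' what distribution-recovery checks should use.
#'
#' @param truth a `ground_truth`.
#' @param time `"reference"` (chart-detectable, default) or `"latent"`.
#' @return list with `ps` (`patient_id`, `score`) and `survival`
#'   (`patient_id`, `time_months`, `event`), the schemas the evaluation
#'   layer consumes.
#' @export
truth_tables <- function(truth, time = c("reference", "latent")) {
  time <- match.arg(time)
  p <- truth$patients
  tm <- if (time == "reference") p$ref_months else p$latent_months
  list(ps = data.frame(patient_id = p$patient_id, score = p$true_ps,
                       stringsAsFactors = FALSE),
       survival = data.frame(patient_id = p$patient_id, time_months = tm,
                             event = p$event, stringsAsFactors = FALSE))
}
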