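# Small builders used across the suite. Fixtures are constructed in code;
# nothing is read from disk except through temp files written here.

make_corpus <- function(patient_id, date, text, source = "outpatient") {
  note_corpus(data.frame(patient_id = patient_id, date = as.Date(date),
                         source = rep(source, length.out = length(patient_id)),
                         text = text, stringsAsFactors = FALSE))
}

make_treatments <- function(patient_id, init_date, drug = "osimertinib") {
  data.frame(patient_id = patient_id, drug = drug,
             init_date = as.Date(init_date), stringsAsFactors = FALSE)
}

make_ps_obs <- function(date, score, patient_id = "p1", source = "mined") {
  data.frame(patient_id = patient_id, date = as.Date(date),
             score = as.integer(score), secondary_score = NA_integer_,
             source = source, evidence = paste0("who", score),
             note_source = "outpatient", stringsAsFactors = FALSE)
}

make_phase_obs <- function(day, phase, patient_id = "p1",
                           origin = as.Date("2020-01-01")) {
  data.frame(patient_id = rep(patient_id, length.out = length(day)),
             date = origin + day, phase = phase,
             rule_id = tolower(phase), evidence = phase,
             stringsAsFactors = FALSE)
}

make_survival <- function(patient_id, time_months, event) {
  data.frame(patient_id = patient_id, time_months = time_months,
             event = event, stringsAsFactors = FALSE)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Independent re-statement of the baseline-matching contract, used as the
# exhaustive oracle: nearest within [init-30, init], else earliest within
# (init, init+14].
brute_force_baseline <- function(obs, init, before = 30, after = 14) {
  off <- as.numeric(obs$date - as.Date(init))
  best <- NULL
  for (i in seq_len(nrow(obs))) {
    if (off[i] >= -before && off[i] <= 0) {
      if (is.null(best) || off[i] > best$off) best <- list(i = i, off = off[i])
    }
  }
  if (is.null(best)) {
    for (i in seq_len(nrow(obs))) {
      if (off[i] > 0 && off[i] <= after) {
        if (is.null(best) || off[i] < best$off) best <- list(i = i, off = off[i])
      }
    }
  }
  if (is.null(best)) NULL else obs[best$i, , drop = FALSE]
}

# Naive pairwise Harrell's C used as the oracle in the acceptance suite.
naive_c_index <- function(tm, ref) {
  common <- intersect(tm$patient_id, ref$patient_id)
  xt <- tm$time_months[match(common, tm$patient_id)]
  rt <- ref$time_months[match(common, ref$patient_id)]
  re <- ref$event[match(common, ref$patient_id)]
  conc <- disc <- tied <- 0
  for (i in seq_along(common)) for (j in seq_along(common)) {
    if (i == j) next
    if (rt[i] < rt[j] && re[i]) {
      if (xt[i] < xt[j]) conc <- conc + 1
      else if (xt[i] > xt[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}
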