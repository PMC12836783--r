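test_that("class-wise metrics match the hand-computed 4-patient example", {
  truth <- data.frame(patient_id = paste0("p", 1:4), score = c(0, 0, 1, 1))
  pred  <- data.frame(patient_id = paste0("p", 1:4), score = c(0, 1, 1, 1))
  m <- ps_metrics(pred, truth)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == 0], 100)
  expect_equal(pc$recall[pc$class == 0], 50)
  expect_equal(pc$f1[pc$class == 0], 200 / 3, tolerance = 1e-10)
  expect_equal(pc$precision[pc$class == 1], 200 / 3, tolerance = 1e-10)
  expect_equal(pc$recall[pc$class == 1], 100)
  expect_equal(pc$f1[pc$class == 1], 80)
  expect_equal(m$weighted_f1, (2 * 200 / 3 + 2 * 80) / 4, tolerance = 1e-10)
  expect_equal(round(m$weighted_f1, 1), 73.3)
})

test_that("perfect agreement scores 100 and disjoint cohorts are an error", {
  tab <- data.frame(patient_id = paste0("p", 1:10),
                    score = rep(0:1, 5))
  m <- ps_metrics(tab, tab)
  expect_equal(m$per_class$f1, c(100, 100))
  expect_equal(m$weighted_f1, 100)
  other <- data.frame(patient_id = paste0("q", 1:10), score = rep(0:1, 5))
  expect_error(ps_metrics(tab, other), "no overlapping patients")
})

test_that("a class never predicted gets precision 0 with a warning, keeping weighted F1 defined", {
  truth <- data.frame(patient_id = paste0("p", 1:4), score = c(0, 0, 1, 2))
  pred  <- data.frame(patient_id = paste0("p", 1:4), score = c(0, 0, 1, 1))
  expect_warning(m <- ps_metrics(pred, truth), "never predicted")
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == 2], 0)
  expect_false(is.na(m$weighted_f1))
})

test_that("weighted F1 equals an independent support-weighted recomputation", {
  set.seed(23)
  for (i in 1:10) {
    n <- 40
    truth <- data.frame(patient_id = paste0("p", 1:n),
                        score = sample(0:3, n, replace = TRUE))
    pred <- data.frame(patient_id = paste0("p", 1:n),
                       score = sample(0:3, n, replace = TRUE))
    m <- suppressWarnings(ps_metrics(pred, truth))
    # recompute from raw pairs
    wf <- 0
    for (cl in sort(unique(c(truth$score, pred$score)))) {
      tp <- sum(truth$score == cl & pred$score == cl)
      prec <- if (sum(pred$score == cl) > 0) tp / sum(pred$score == cl) else 0
      rec <- if (sum(truth$score == cl) > 0) tp / sum(truth$score == cl) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      wf <- wf + 100 * f1 * sum(truth$score == cl) / n
    }
    expect_equal(m$weighted_f1, wf, tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier matches the manual product-limit table", {
  # no censoring, odd n: steps of 0.2 and the sample median
  km <- km_estimate(make_survival(paste0("p", 1:5), 1:5, rep(TRUE, 5)))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
  # all censored: S == 1 everywhere, median undefined but no error
  kc <- km_estimate(make_survival(paste0("p", 1:3), 1:3, rep(FALSE, 3)))
  expect_true(all(kc$surv == 1))
  expect_true(is.na(kc$median))
  # hand-computed table with censoring: times 1, 2+, 3, 4, 5+, 6
  km2 <- km_estimate(make_survival(paste0("p", 1:6), 1:6,
                                   c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)))
  s <- km2$surv[match(c(1, 3, 4, 6), km2$time)]
  expect_equal(s, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(km2$median, 4)
})

test_that("without censoring the KM curve is one minus the empirical CDF", {
  set.seed(3)
  t <- round(rexp(40, 0.1), 2)
  km <- km_estimate(make_survival(paste0("p", 1:40), t, rep(TRUE, 40)))
  for (k in seq_along(km$time))
    expect_equal(km$surv[k], mean(t > km$time[k]), tolerance = 1e-12)
})

test_that("concordance index: identity, reversal, and the package oracle", {
  ids <- paste0("p", 1:3)
  ref <- make_survival(ids, 1:3, rep(TRUE, 3))
  expect_equal(concordance_index(ref, ref)$c_index, 1.0)
  rev <- make_survival(ids, 3:1, rep(TRUE, 3))
  expect_equal(concordance_index(rev, ref)$c_index, 0.0)

  # censored random tables agree with survival::concordance
  set.seed(41)
  ids <- paste0("p", 1:30)
  ref <- make_survival(ids, rexp(30, 0.1), runif(30) < 0.7)
  tm <- make_survival(ids, ref$time_months * exp(rnorm(30, 0, 0.4)),
                      ref$event)
  mine <- concordance_index(tm, ref)
  sv <- survival::concordance(
    survival::Surv(ref$time_months, ref$event) ~ tm$time_months)
  expect_equal(mine$c_index, unname(sv$concordance), tolerance = 1e-12)
  expect_equal(mine$comparable,
               mine$concordant + mine$discordant + mine$tied)
})

test_that("C is invariant under monotone transforms and flips under reversal", {
  set.seed(47)
  ids <- paste0("p", 1:25)
  ref <- make_survival(ids, rexp(25, 0.1), runif(25) < 0.8)
  tm <- make_survival(ids, rexp(25, 0.1), rep(TRUE, 25))
  c0 <- concordance_index(tm, ref)$c_index
  tm_log <- tm; tm_log$time_months <- log1p(tm$time_months)
  expect_equal(concordance_index(tm_log, ref)$c_index, c0)
  tm_neg <- tm; tm_neg$time_months <- max(tm$time_months) - tm$time_months
  res <- concordance_index(tm_neg, ref)
  expect_equal(res$tied, 0)
  expect_equal(res$c_index, 1 - c0)
})

test_that("too few comparable pairs yields NA with a warning", {
  ref <- make_survival(c("a", "b"), c(1, 2), c(FALSE, FALSE))
  tm <- make_survival(c("a", "b"), c(1, 2), c(TRUE, TRUE))
  expect_warning(res <- concordance_index(tm, ref), "comparable")
  expect_true(is.na(res$c_index))
})

test_that("discrepancy flags fire beyond ratio 3 or 1/3 and sort by severity", {
  tm <- make_survival(paste0("p", 1:4), c(9, 10, 1, 5), rep(TRUE, 4))
  ref <- make_survival(paste0("p", 1:4), c(3.1, 2, 4, 0), rep(TRUE, 4))
  fl <- flag_discrepancies(tm, ref)
  expect_equal(fl$flagged[fl$patient_id == "p1"], FALSE)  # ratio 2.9
  expect_equal(fl$flagged[fl$patient_id == "p2"], TRUE)   # ratio 5
  expect_equal(fl$flagged[fl$patient_id == "p3"], TRUE)   # ratio 0.25
  expect_true(fl$flagged[fl$patient_id == "p4"])          # ref time 0
  expect_true(is.na(fl$ratio[fl$patient_id == "p4"]))
  finite <- fl[!is.na(fl$ratio), ]
  expect_equal(finite$ratio, finite$ratio[order(-abs(log(finite$ratio)))])
})

test_that("cohort flow partitions the cohort and rejects unknown statuses", {
  pts <- paste0("p", 1:10)
  tm_status <- data.frame(patient_id = pts[1:8], status = "resolved")
  ref_status <- data.frame(patient_id = pts,
                           status = c(rep("resolved", 7), "unresolved",
                                      "no_followup", "resolved"))
  fl <- cohort_flow(pts, tm_status, ref_status)
  expect_equal(sum(fl$tm), 10)
  expect_equal(sum(fl$reference), 10)
  expect_equal(fl$tm[fl$category == "unmatched"], 2L)
  bad <- data.frame(patient_id = pts[1], status = "whatever")
  expect_error(cohort_flow(pts, bad, ref_status), "unknown status")
})

test_that("the scatter table has one point per doubly-resolved patient", {
  tm <- make_survival(paste0("p", 1:5), 1:5, rep(TRUE, 5))
  ref <- make_survival(paste0("p", 3:8), 3:8, rep(TRUE, 6))
  sc <- pfs_scatter(tm, ref)
  expect_equal(nrow(sc), 3)
  expect_setequal(sc$patient_id, paste0("p", 3:5))
})
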