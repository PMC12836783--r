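init <- as.Date("2020-06-01")

test_that("baseline PS matching: nearest in the 30 days before, else earliest within 14 after", {
  # nearest before wins
  obs <- make_ps_obs(init + c(-25, -10), c(1, 2))
  expect_equal(match_baseline_ps(obs, init)$date, init - 10)
  # after-window only used when the before-window is empty
  obs <- make_ps_obs(init + 10, 1)
  expect_equal(match_baseline_ps(obs, init)$date, init + 10)
  obs <- make_ps_obs(init + c(-5, 1), c(1, 2))
  expect_equal(match_baseline_ps(obs, init)$date, init - 5)
  # both observations out of window: none
  expect_null(match_baseline_ps(make_ps_obs(init + c(-45, 20), c(1, 1)), init))
  expect_null(match_baseline_ps(make_ps_obs(init + 15, 1), init))
  expect_null(match_baseline_ps(ps_obs <- make_ps_obs(Sys.Date(), 1)[0, ], init))
})

test_that("baseline matching agrees with brute force for every offset in -60..60", {
  for (off in -60:60) {
    obs <- make_ps_obs(init + off, 1)
    got <- match_baseline_ps(obs, init)
    want <- brute_force_baseline(obs, init)
    if (is.null(want)) expect_null(got, label = paste("offset", off))
    else expect_equal(got$date, want$date, label = paste("offset", off))
  }
  # and for random multi-observation sets
  set.seed(31)
  for (i in 1:40) {
    obs <- make_ps_obs(init + sample(-60:60, sample(1:6, 1)), 1)
    got <- match_baseline_ps(obs, init)
    want <- brute_force_baseline(obs, init)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$date, want$date)
  }
})

test_that("same-day ties prefer structured source, then the lower score", {
  obs <- rbind(make_ps_obs(init, 2, source = "mined"),
               make_ps_obs(init, 3, source = "structured"))
  hit <- match_baseline_ps(obs, init)
  expect_equal(hit$source, "structured")
  obs2 <- rbind(make_ps_obs(init, 3), make_ps_obs(init, 1))
  expect_equal(match_baseline_ps(obs2, init)$score, 1L)
})

test_that("event dates snap to the latest scan within the lag window", {
  d0 <- as.Date("2020-01-01")
  expect_equal(align_event_to_scan(d0 + 200, d0 + 196), d0 + 196)
  expect_equal(align_event_to_scan(d0 + 200, d0 + 150), d0 + 200)
  expect_equal(align_event_to_scan(d0 + 200, NULL), d0 + 200)
  # latest qualifying scan wins; future scans never match
  expect_equal(align_event_to_scan(d0 + 200, d0 + c(190, 195, 202)), d0 + 195)
})

test_that("progression calls resolve the four canonical timelines", {
  tl <- function(days, phases)
    timeline(make_phase_obs(days, phases, origin = init), "p1", init)
  a <- call_progression(tl(c(30, 90, 180, 200), c("BP", "BP", "PP", "AP")))
  expect_equal(a$status, "progressed")
  expect_equal(a$event_date, init + 180)
  expect_equal(a$basis, "pp_confirmed")

  b <- call_progression(tl(c(30, 200), c("BP", "BP")))
  expect_equal(b$status, "censored")
  expect_equal(b$event_date, init + 200)
  expect_equal(b$basis, "censor_last_note")

  c_ <- call_progression(tl(c(100, 110), c("PP", "BP")))
  expect_equal(c_$status, "unresolved")

  d <- call_progression(tl(150, "AP"))
  expect_equal(d$status, "progressed")
  expect_equal(d$event_date, init + 150)
  expect_equal(d$basis, "ap_only")

  e <- call_progression(timeline(make_phase_obs(numeric(0), character(0)),
                                 "p1", init))
  expect_equal(e$status, "unresolved")
})

test_that("a retracted candidate falls through to later re-assertions", {
  tl <- function(days, phases)
    timeline(make_phase_obs(days, phases, origin = init), "p1", init)
  # PP retracted by BP in window, later PP stands
  f <- call_progression(tl(c(100, 110, 200), c("PP", "BP", "PP")))
  expect_equal(f$status, "progressed")
  expect_equal(f$event_date, init + 200)
  # PP re-asserted before the contradicting BP stands at the original date
  g <- call_progression(tl(c(100, 105, 110), c("PP", "PP", "BP")))
  expect_equal(g$event_date, init + 100)
  # BP outside the confirmation window does not retract
  h <- call_progression(tl(c(100, 140), c("PP", "BP")),
                        confirm_window_days = 30)
  expect_equal(h$status, "progressed")
  expect_equal(h$event_date, init + 100)
})

test_that("deleting a BP observation never delays the progression date", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:7, 1)
    days <- sort(sample(0:400, n))
    phases <- sample(c("BP", "PP", "AP"), n, replace = TRUE)
    obs <- make_phase_obs(days, phases, origin = init)
    full <- call_progression(timeline(obs, "p1", init))
    bp_rows <- which(phases == "BP")
    if (!length(bp_rows) || full$status != "progressed") next
    drop <- sample(bp_rows, 1)
    reduced <- call_progression(timeline(obs[-drop, ], "p1", init))
    expect_equal(reduced$status, "progressed")
    expect_true(reduced$event_date <= full$event_date)
  }
})

test_that("PFS conversion uses 30.44-day months and enforces the time origin", {
  call <- call_progression(timeline(make_phase_obs(244, "PP", origin = init),
                                    "p1", init))
  rec <- compute_pfs(call, init)
  expect_equal(rec$time_months, 244 / 30.44, tolerance = 1e-12)
  expect_equal(round(rec$time_months, 2), 8.02)
  expect_true(rec$event)

  cens <- call_progression(timeline(make_phase_obs(0, "BP", origin = init),
                                    "p1", init))
  rec0 <- compute_pfs(cens, init)
  expect_equal(rec0$time_months, 0)
  expect_false(rec0$event)

  expect_error(compute_pfs(call, init + 300), "precedes")
  unres <- call_progression(timeline(make_phase_obs(numeric(0), character(0)),
                                     "p1", init))
  expect_error(compute_pfs(unres, init), "no survival representation")
})
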