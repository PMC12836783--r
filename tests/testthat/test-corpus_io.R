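test_that("note table parses valid rows and sorts per patient by date", {
  df <- data.frame(patient_id = c("p2", "p1", "p1"),
                   date = c("2020-05-01", "2020-03-02", "2020-01-15"),
                   source = "outpatient",
                   text = c("a", "b", "c"))
  corpus <- read_note_table(write_temp_csv(df))
  expect_s3_class(corpus, "note_corpus")
  expect_equal(nrow(corpus), 3)
  p1 <- corpus[corpus$patient_id == "p1", ]
  expect_equal(p1$text, c("c", "b"))  # ascending date
  expect_equal(nrow(attr(corpus, "rejects")), 0)
})

test_that("invalid calendar dates are rejected into the side report, not dropped silently", {
  df <- data.frame(patient_id = c("p1", "p1"),
                   date = c("31-02-2020", "13-02-2020"),
                   source = "note", text = c("bad", "good"))
  rej_path <- tempfile(fileext = ".csv")
  expect_message(
    corpus <- read_note_table(write_temp_csv(df), rejects_path = rej_path),
    "rejected")
  expect_equal(nrow(corpus), 1)
  rejects <- attr(corpus, "rejects")
  expect_equal(rejects$date_raw, "31-02-2020")
  expect_equal(rejects$reason, "unparseable date")
  expect_true(file.exists(rej_path))
})

test_that("mixed date dialects parse under auto and ambiguous literals are flagged", {
  p <- parse_note_dates(c("2020-04-03", "03-04-2020", "13-04-2020"), "auto")
  expect_equal(p$date,
               as.Date(c("2020-04-03", "2020-04-03", "2020-04-13")))
  expect_equal(p$ambiguous, c(FALSE, TRUE, FALSE))  # 03-04 could be mdy
  # explicit dialects resolve without flags
  expect_equal(parse_note_dates("03-04-2020", "dmy")$date, as.Date("2020-04-03"))
  expect_equal(parse_note_dates("03-04-2020", "mdy")$date, as.Date("2020-03-04"))
  expect_false(any(parse_note_dates("03-04-2020", "dmy")$ambiguous))
  df <- data.frame(patient_id = "p1", date = "03-04-2020",
                   source = "note", text = "x")
  expect_warning(read_note_table(write_temp_csv(df)), "ambiguous")
})

test_that("missing required columns and empty files are reported by name", {
  df <- data.frame(patient_id = "p1", date = "2020-01-01", text = "x")
  expect_error(read_note_table(write_temp_csv(df)), "source")
  empty <- data.frame(patient_id = character(), date = character(),
                      source = character(), text = character())
  expect_warning(corpus <- read_note_table(write_temp_csv(empty)), "empty")
  expect_equal(nrow(corpus), 0)
})

test_that("write then read round-trips a corpus exactly", {
  corpus <- make_corpus(c("p1", "p2"), c("2020-01-05", "2020-02-01"),
                        c("WHO 1, stabiel.", "geen progressie"))
  path <- tempfile(fileext = ".csv")
  write_note_table(corpus, path)
  back <- read_note_table(path, dialect = "iso")
  expect_equal(as.data.frame(back)[c("patient_id", "date", "source", "text")],
               as.data.frame(corpus)[c("patient_id", "date", "source", "text")])
})

test_that("treatment table keeps earliest init_date on duplicates and warns", {
  df <- data.frame(patient_id = c("p1", "p2", "p2"),
                   drug = "osimertinib",
                   init_date = c("2020-01-01", "2020-03-01", "2020-02-01"))
  expect_warning(tr <- read_treatment_table(write_temp_csv(df)), "duplicate")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$init_date[tr$patient_id == "p2"], as.Date("2020-02-01"))
})

test_that("pre-treatment filter keeps the initiation day and flags patients without follow-up", {
  init <- as.Date("2020-02-01")
  corpus <- make_corpus(rep("p1", 3), init + c(-10, 0, 5), c("a", "b", "c"))
  tr <- make_treatments("p1", init)
  out <- filter_pre_treatment(corpus, tr)
  expect_equal(out$text, c("b", "c"))  # inclusive at init
  # idempotent
  expect_equal(as.data.frame(filter_pre_treatment(out, tr)),
               as.data.frame(out))
  # all notes precede init: patient retained with 0 notes, flagged
  early <- make_corpus("p9", init - 30, "old note")
  out2 <- filter_pre_treatment(early, make_treatments("p9", init))
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "no_followup"), "p9")
  # patient without a treatment record is excluded and reported
  out3 <- filter_pre_treatment(corpus, make_treatments("other", init))
  expect_equal(attr(out3, "excluded_patients"), "p1")
  expect_equal(nrow(filter_pre_treatment(make_corpus(character(0),
    as.Date(character(0)), character(0)), tr)), 0)
})

test_that("structured observations map PS values and closed-question answers", {
  ps <- data.frame(patient_id = c("p1", "p2"), date = "2020-01-01",
                   value = c("2", "7"))
  expect_message(obs <- read_structured_observations(write_temp_csv(ps), "ps"),
                 "rejected")
  expect_equal(nrow(obs), 1)
  expect_equal(obs$score, 2L)
  expect_equal(obs$source, "structured")
  expect_equal(attr(obs, "rejects")$value, "7")

  prog <- data.frame(patient_id = c("p1", "p1"), date = "2020-01-01",
                     value = c("progressie", "remissie"))
  pobs <- read_structured_observations(write_temp_csv(prog), "progression")
  expect_equal(sort(pobs$phase), c("BP", "PP"))
  expect_equal(unique(pobs$rule_id), "structured")
})
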