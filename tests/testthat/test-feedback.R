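targets <- dash_targets()

test_that("best/struggle selection ranks by relative distance with caps of 2", {
  p <- perfect_profile()
  s <- score_day(p, targets)
  cls <- classify_components(s, targets, p)
  expect_length(cls$best, 2)
  expect_length(cls$struggle, 0)

  w <- worst_profile()
  cls0 <- classify_components(score_day(w, targets), targets, w)
  expect_length(cls0$best, 0)
  expect_length(cls0$struggle, 2)

  m <- midrange_profile()
  clsm <- classify_components(score_day(m, targets), targets, m)
  # no full credits: best backfills from the half-credit pool, closest call
  # first (protein 16 vs 18 -> 11%, calcium 494.4 vs 590 -> 16%)
  expect_equal(clsm$best, c("protein", "calcium"))
  # zero-credit pool ranked by largest relative distance: cholesterol
  # (172.2 vs 71.4 -> 141%) then saturated fat (12.6 vs 6 -> 110%)
  expect_equal(clsm$struggle, c("cholesterol", "saturated_fat"))
  expect_length(intersect(clsm$best, clsm$struggle), 0)
})

test_that("best/struggle selection ignores component ordering in the input", {
  withr::with_seed(31, {
    for (k in 1:10) {
      p <- random_profile()
      s <- score_day(p, targets)
      shuffled <- p[sample(names(p))]
      expect_identical(classify_components(s, targets, p),
                       classify_components(s, targets, shuffled))
    }
  })
})

test_that("daily feedback bodies carry greeting, score and a tip", {
  bank <- load_tip_bank()
  msg <- compose_daily_message("p1", "Dana", 5.5,
                               best = c("saturated_fat", "fiber"),
                               struggle = c("potassium", "magnesium"),
                               tip_bank = bank, study_day = 1)
  expect_match(msg$body, "Hello, Dana!", fixed = TRUE)
  expect_match(msg$body, "Your DASH score yesterday was 5.5", fixed = TRUE)
  expect_match(msg$body, "potassium")
  expect_match(msg$body, "magnesium")
  expect_true(grepl(bank$potassium[1], msg$body, fixed = TRUE))

  none <- compose_daily_message("p1", "Dana", NA_real_, tip_bank = bank,
                                study_day = 2)
  expect_match(none$body, "Hello, Dana!", fixed = TRUE)
  expect_false(grepl("DASH score yesterday was", none$body))
  expect_match(none$body, "Log everything")

  top <- compose_daily_message("p1", "Dana", 9,
                               best = c("fiber", "sodium"),
                               struggle = character(), tip_bank = bank,
                               study_day = 3)
  expect_match(top$body, "Your DASH score yesterday was 9.0", fixed = TRUE)
  expect_match(top$body, "every DASH target")
  expect_false(grepl("struggle", top$body))
})

test_that("message bodies never leak template placeholders", {
  bank <- load_tip_bank()
  msgs <- dplyr::bind_rows(
    compose_daily_message("p", "Ada", 4.5, "fiber", "sodium", bank, 5),
    compose_daily_message("p", "Ada", NA_real_, tip_bank = bank),
    compose_topic_message(3),
    auto_reply(list(participant_id = "p", kind = "inbound"),
               tibble::tibble(participant_id = "p")))
  expect_false(any(grepl("[{}]|%s|%d|%\\.1f|\\[name\\]", msgs$body)))
})

test_that("tip selection cycles deterministically with the study day", {
  bank <- load_tip_bank()
  m1 <- compose_daily_message("p", "A", 3, character(), "fiber", bank, 1)
  m2 <- compose_daily_message("p", "A", 3, character(), "fiber", bank, 2)
  m3 <- compose_daily_message("p", "A", 3, character(), "fiber", bank, 3)
  expect_true(grepl(bank$fiber[1], m1$body, fixed = TRUE))
  expect_true(grepl(bank$fiber[2], m2$body, fixed = TRUE))
  expect_identical(m3$body, m1$body)  # bank of 2 wraps
})

test_that("schedules follow the daily-then-weekly cadence with Sunday topics", {
  s <- build_schedule(as.Date("2017-09-01"), 90)
  daily <- s[s$kind == "daily_feedback", ]
  weekly <- s[s$kind == "weekly_feedback", ]
  topics <- s[s$kind == "topic", ]
  expect_equal(daily$study_day, 1:14)
  expect_equal(nrow(weekly), floor((90 - 14) / 7))  # 10
  expect_true(all(format(daily$scheduled_time, "%H:%M") == "12:00"))
  expect_true(all(format(topics$scheduled_time, "%H:%M") == "15:00"))
  expect_true(all(weekdays(topics$date) == "Sunday"))
  # day 3 has its daily message; day 20 has no feedback of either kind
  expect_equal(sum(daily$study_day == 3), 1)
  expect_equal(sum(s$kind != "topic" & s$study_day == 20), 0)
})

test_that("cadence invariants hold across random enrollment dates", {
  withr::with_seed(41, {
    starts <- as.Date("2017-07-01") + sample(0:365, 8)
    for (d0 in as.list(starts)) {
      s <- build_schedule(d0, 90)
      fb <- s[s$kind != "topic", ]
      # one daily per day 1-14, none after
      expect_equal(fb$study_day[fb$kind == "daily_feedback"], 1:14)
      # weekly messages land on the enrollment weekday after day 14
      wk <- fb[fb$kind == "weekly_feedback", ]
      expect_true(all(wk$study_day > 14))
      expect_true(all(weekdays(wk$date) == weekdays(d0)))
      expect_true(all(diff(wk$study_day) == 7))
      # no duplicated kind on any day; one topic per 7-day block
      expect_false(any(duplicated(s[, c("study_day", "kind")])))
      tp <- s$study_day[s$kind == "topic"]
      expect_true(all(table((tp - 1) %/% 7) == 1))
      # determinism
      expect_identical(s, build_schedule(d0, 90))
    }
  })
})

test_that("schedule construction validates its inputs", {
  expect_error(build_schedule(as.Date("2017-09-01"), 10), ">= 14")
  expect_error(build_schedule(as.Date("2017-09-01"), 90, tz = "Mars/Olympus"),
               "timezone")
})

test_that("topic messages rotate through the bank and wrap", {
  bank <- load_topic_bank()
  m1 <- compose_topic_message(1, bank)
  expect_match(m1$body, "Dining out on DASH", fixed = TRUE)
  wrapped <- compose_topic_message(nrow(bank) + 1, bank)
  expect_identical(wrapped$body, m1$body)
  expect_error(compose_topic_message(0, bank), "week_index")
  expect_error(compose_topic_message(1, bank[0, ]), "empty")
})

test_that("auto replies go only to enrolled senders and never loop", {
  roster <- tibble::tibble(participant_id = c("p1", "p2"))
  r <- auto_reply(list(participant_id = "p1", kind = "inbound"), roster)
  expect_equal(r$kind, "auto_reply")
  expect_match(r$body, "email")
  # replying to an auto-reply must not produce another message
  expect_null(auto_reply(as.list(r[, c("participant_id", "kind")]), roster))
  expect_message(
    expect_null(auto_reply(list(participant_id = "zz", kind = "inbound"),
                           roster)),
    "unknown sender")
})

test_that("the outbox serializes messages as JSON lines", {
  bank <- load_tip_bank()
  msgs <- dplyr::bind_rows(
    compose_daily_message("p1", "Ada", 5.5, "fiber", "sodium", bank, 1),
    compose_daily_message("p2", "Bo", NA_real_, tip_bank = bank))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_messages(msgs, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  rec1 <- jsonlite::fromJSON(lines[1])
  expect_equal(rec1$referenced_score, 5.5)
  expect_equal(jsonlite::fromJSON(lines[2])$referenced_score, "no score")
})
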