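test_that("valid-day rule: present with at least 600 kcal", {
  expect_true(is_valid_tracking_day(TRUE, 600))
  expect_false(is_valid_tracking_day(TRUE, 550))
  expect_false(is_valid_tracking_day(TRUE, NA))
  expect_false(is_valid_tracking_day(FALSE, 2000))
})

test_that("weekly engagement counts valid days in randomization-anchored blocks", {
  roster <- tibble::tibble(participant_id = "p1",
                           randomization_date = as.Date("2017-09-04"))
  days <- week_intake("p1", as.Date("2017-09-04"))
  eng <- weekly_engagement(days, roster, study_weeks = 1)
  expect_equal(eng$weekly$valid_days, 5)  # 550 kcal and missing day dropped
  expect_equal(eng$summary$mean_days_per_week, 5)
  expect_true(eng$summary$meets_5plus)
})

test_that("engagement summaries hit the floor and ceiling cases", {
  roster <- tibble::tibble(participant_id = c("full", "none"),
                           randomization_date = as.Date("2017-09-04"))
  full_days <- week_intake("full", as.Date("2017-09-04"),
                           energies = rep(2000, 7))
  for (w in 1:11) {
    full_days <- dplyr::bind_rows(
      full_days, week_intake("full", as.Date("2017-09-04") + 7 * w,
                             energies = rep(2000, 7)))
  }
  eng <- weekly_engagement(full_days, roster, study_weeks = 12)
  s <- eng$summary
  expect_equal(s$mean_days_per_week[s$participant_id == "full"], 7)
  expect_true(s$meets_5plus[s$participant_id == "full"])
  expect_equal(s$mean_days_per_week[s$participant_id == "none"], 0)
  expect_false(s$meets_5plus[s$participant_id == "none"])
  expect_true(all(eng$weekly$valid_days >= 0 & eng$weekly$valid_days <= 7))
})

test_that("pre-randomization logs are excluded and duplicates deduplicated", {
  roster <- tibble::tibble(participant_id = "p1",
                           randomization_date = as.Date("2017-09-04"))
  days <- week_intake("p1", as.Date("2017-09-01"), energies = rep(2000, 7))
  expect_warning(eng <- weekly_engagement(days, roster, study_weeks = 1),
                 "precede randomization")
  expect_equal(eng$weekly$valid_days, 4)  # only Sep 4-7 fall after anchor
  dup <- dplyr::bind_rows(days, days, days[sample(nrow(days)), ])
  expect_warning(eng2 <- weekly_engagement(dup, roster, study_weeks = 1))
  expect_identical(eng2$weekly$valid_days, eng$weekly$valid_days)
})

test_that("a deterministic linear decline is recovered exactly", {
  weeks <- 1:7
  panel <- dplyr::bind_rows(lapply(sprintf("p%02d", 1:6), function(pid) {
    tibble::tibble(participant_id = pid,
                   arm = if (pid > "p03") "intervention" else "comparator",
                   week = weeks, valid_days = 7 - (weeks - 1))
  }))
  fit <- suppressWarnings(fit_engagement_trend(panel))  # zero-variance fit
  expect_equal(fit$fixed$estimate[fit$fixed$term == "week"], -1,
               tolerance = 1e-6)
  expect_equal(fit$arm_decline$decline, c(1, 1), tolerance = 1e-6)
  expect_equal(
    fit$fixed$estimate[fit$fixed$term == "week:armintervention"], 0,
    tolerance = 1e-6)
})

test_that("trend fitting requires two arms and two weeks", {
  one_arm <- tibble::tibble(participant_id = rep(c("a", "b"), each = 3),
                            arm = "intervention", week = rep(1:3, 2),
                            valid_days = 4)
  expect_error(fit_engagement_trend(one_arm), "both arms")
  one_week <- tibble::tibble(participant_id = c("a", "b"),
                             arm = c("comparator", "intervention"),
                             week = 1, valid_days = 4)
  expect_error(fit_engagement_trend(one_week), "two distinct weeks")
})

test_that("a null decline yields interaction CIs that cover zero", {
  covered <- 0L
  for (s in 1:10) {
    panel <- simulate_engagement_panel(
      50, weeks = 8,
      tracking_decline = c(intervention = 0, comparator = 0), seed = 100 + s)
    fit <- fit_engagement_trend(panel)
    row <- fit$fixed[fit$fixed$term == "week:armintervention", ]
    covered <- covered + (row$lower <= 0 && row$upper >= 0)
  }
  expect_gte(covered, 8L)  # nominal 95% coverage, 10 replicates
})

test_that("the simulated steeper intervention decline is recovered", {
  panel <- simulate_engagement_panel(200, weeks = 12, seed = 77)
  fit <- fit_engagement_trend(panel)
  int <- fit$arm_decline[fit$arm_decline$arm == "intervention", ]
  expect_true(int$lower <= 0.23 && 0.23 <= int$upper)
  comp <- fit$arm_decline[fit$arm_decline$arm == "comparator", ]
  expect_true(comp$lower <= 0 && 0 <= comp$upper)
  expect_equal(fit$diagnostics$residual_structure, "independent")
})

test_that("recall validity applies all five protocol rules", {
  mk <- function(dates, kcal) {
    tibble::tibble(recall_date = as.Date(dates), energy_kcal = kcal)
  }
  ok <- assess_recall_validity(mk(c("2017-09-02", "2017-09-05"),
                                  c(2100, 1900)))
  expect_true(ok$valid)
  expect_length(ok$failure_reasons, 0)
  expect_equal(ok$mean_kcal, 2000)

  two_weekdays <- assess_recall_validity(mk(c("2017-09-05", "2017-09-07"),
                                            c(2000, 2000)))
  expect_false(two_weekdays$valid)
  expect_equal(two_weekdays$failure_reasons, "no-weekend")

  far <- assess_recall_validity(mk(c("2017-09-02", "2017-09-22"),
                                   c(2000, 2000)))
  expect_false(far$valid)
  expect_equal(far$failure_reasons, "gap>14d")

  low <- assess_recall_validity(mk(c("2017-09-02", "2017-09-05"),
                                   c(400, 500)))
  expect_false(low$valid)
  expect_equal(low$failure_reasons, "kcal<600")

  high <- assess_recall_validity(mk(c("2017-09-02", "2017-09-05"),
                                    c(3600, 3800)))
  expect_equal(high$failure_reasons, "kcal>3500")
})

test_that("recall validity truth table: every rule combination detected", {
  # weekend presence x weekday presence x gap x energy level
  base_dates <- list(
    both = c("2017-09-02", "2017-09-05"),
    no_weekend = c("2017-09-05", "2017-09-07"),
    no_weekday = c("2017-09-02", "2017-09-03"),
    far = c("2017-09-02", "2017-09-22"))
  energies <- list(ok = c(2000, 2200), low = c(450, 500),
                   high = c(3700, 4000))
  for (dk in names(base_dates)) {
    for (ek in names(energies)) {
      res <- assess_recall_validity(
        tibble::tibble(recall_date = as.Date(base_dates[[dk]]),
                       energy_kcal = energies[[ek]]))
      want <- character()
      if (dk == "no_weekend") want <- c(want, "no-weekend")
      if (dk == "no_weekday") want <- c(want, "no-weekday")
      if (dk == "far") want <- c(want, "gap>14d")
      if (ek == "low") want <- c(want, "kcal<600")
      if (ek == "high") want <- c(want, "kcal>3500")
      expect_setequal(res$failure_reasons, want)
      expect_equal(res$valid, length(want) == 0)
    }
  }
})

test_that("fewer than two recalls is never valid", {
  withr::with_seed(51, {
    for (k in 1:10) {
      n <- sample(0:1, 1)
      r <- tibble::tibble(
        recall_date = as.Date("2017-09-01") + sample(0:13, n),
        energy_kcal = runif(n, 1500, 2500))
      res <- assess_recall_validity(r)
      expect_false(res$valid)
      expect_true("too-few-recalls" %in% res$failure_reasons)
    }
  })
})

test_that("more than two recalls: earliest weekend + earliest weekday pair used", {
  r <- tibble::tibble(
    recall_date = as.Date(c("2017-09-12", "2017-09-02", "2017-09-09",
                            "2017-09-05")),
    energy_kcal = c(9000, 2000, 9000, 1800))
  res <- assess_recall_validity(r)
  expect_true(res$valid)  # extreme energies on later recalls never used
  expect_equal(sort(res$used$recall_date),
               as.Date(c("2017-09-02", "2017-09-05")))
  expect_equal(res$mean_kcal, 1900)
})

test_that("table-level recall assessment groups by participant-timepoint", {
  recalls <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 2),
    timepoint = "baseline",
    recall_date = as.Date(c("2017-09-02", "2017-09-05",
                            "2017-09-05", "2017-09-07")),
    energy_kcal = c(2000, 2000, 2000, 2000))
  out <- assess_recalls(recalls)
  expect_equal(out$valid, c(TRUE, FALSE))
  expect_equal(out$failure_reasons[2], "no-weekend")
})
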