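#' Is a tracking day valid?
#'
#' A valid tracked day is one with any log submitted and a reported energy of
#' at least 600 kcal; a day with no log or under 600 kcal is treated as not
#' having complete tracking data.
#'
#' @param present Logical: was any log submitted that day?
#' @param energy_kcal Reported energy, `NA` when absent.
#' @param min_kcal Validity threshold (default 600 kcal).
#' @return Logical vector.
#' @export
#' @examples
#' is_valid_tracking_day(TRUE, c(600, 550, NA))  # TRUE FALSE FALSE
is_valid_tracking_day <- function(present, energy_kcal, min_kcal = 600) {
  present & !is.na(energy_kcal) & energy_kcal >= min_kcal
}

#' Weekly engagement summary
#'
#' Counts valid tracked days in consecutive 7-day blocks anchored at each
#' participant's randomization date. Partial terminal weeks are dropped. The
#' summary reports mean valid days per week and whether the participant
#' averaged at least 5 days per week.
#'
#' @param days Tibble with `participant_id`, `date`, `energy_kcal` - one row
#'   per day with a submitted log (absent days are simply absent rows).
#'   Duplicate participant-day rows are deduplicated (first kept).
#' @param roster Tibble with `participant_id` and `randomization_date` (or
#'   `enrollment_date`).
#' @param study_weeks Number of complete weeks to summarize (default 12).
#' @param min_kcal Valid-day threshold.
#' @return List with `weekly` (participant_id, week_index, valid_days) and
#'   `summary` (participant_id, mean_days_per_week, meets_5plus).
#' @export
weekly_engagement <- function(days, roster, study_weeks = 12L,
                              min_kcal = 600) {
  anchor_col <- if ("randomization_date" %in% names(roster))
    "randomization_date" else "enrollment_date"
  roster <- dplyr::distinct(roster[, c("participant_id", anchor_col)])
  names(roster)[2] <- "anchor"
  days <- dplyr::distinct(days, .data$participant_id, .data$date,
                          .keep_all = TRUE)
  days <- dplyr::inner_join(days, roster, by = "participant_id")
  days$offset <- as.integer(days$date - as.Date(days$anchor))
  early <- days$offset < 0
  if (any(early)) {
    warn(sprintf("%d log day(s) precede randomization; excluded",
                 sum(early)))
    days <- days[!early, ]
  }
  days$week_index <- days$offset %/% 7L + 1L
  days <- days[days$week_index <= study_weeks, ]
  days$valid <- is_valid_tracking_day(TRUE, days$energy_kcal, min_kcal)

  grid <- tidyr::expand_grid(participant_id = roster$participant_id,
                             week_index = seq_len(study_weeks))
  counts <- dplyr::summarise(
    dplyr::group_by(days, .data$participant_id, .data$week_index),
    valid_days = sum(.data$valid), .groups = "drop")
  weekly <- dplyr::left_join(grid, counts,
                             by = c("participant_id", "week_index"))
  weekly$valid_days[is.na(weekly$valid_days)] <- 0L
  summary <- dplyr::summarise(
    dplyr::group_by(weekly, .data$participant_id),
    mean_days_per_week = mean(.data$valid_days), .groups = "drop")
  summary$meets_5plus <- summary$mean_days_per_week >= 5
  list(weekly = as_tibble(weekly), summary = as_tibble(summary))
}

#' Fit the engagement trend mixed model
#'
#' Random-intercept linear mixed model of weekly valid tracking days on time
#' (weeks, continuous), treatment arm, and their interaction:
#' `valid_days ~ week * arm + (1 | participant_id)`. The per-arm weekly
#' decline is reported as a positive magnitude: the negated time slope for
#' the reference (comparator) arm and the negated slope + interaction for the
#' intervention arm. Confidence intervals are Wald-type from the estimated
#' fixed-effect covariance.
#'
#' Residuals are modeled as independent within participant (the
#' random-intercept fallback); the `diagnostics` element records this.
#'
#' @param panel Tibble with `participant_id`, `arm` (`"comparator"` /
#'   `"intervention"`), `week` (1-based), `valid_days`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `dash_trend_fit`: list with `fixed` (term,
#'   estimate, se, lower, upper, p), `arm_decline` (per-arm decline with CI),
#'   `ranef_var`, `diagnostics`, and the `model`.
#' @export
fit_engagement_trend <- function(panel, conf_level = 0.95) {
  need <- c("participant_id", "arm", "week", "valid_days")
  if (!all(need %in% names(panel))) {
    abort(paste0("panel needs columns: ", paste(need, collapse = ", ")))
  }
  if (length(unique(panel$arm)) < 2) {
    abort("identifiability: both arms are required to estimate the interaction")
  }
  if (length(unique(panel$week)) < 2) {
    abort("identifiability: at least two distinct weeks are required")
  }
  panel$arm <- factor(panel$arm, levels = c("comparator", "intervention"))
  fit <- suppressMessages(
    lme4::lmer(valid_days ~ week * arm + (1 | participant_id),
               data = panel, REML = TRUE))
  est <- lme4::fixef(fit)
  vc <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                 error = function(e) NULL)
  vcov_fallback <- is.null(vc) || anyNA(vc)
  if (vcov_fallback) {
    # degenerate (zero-variance) fits: fall back to the OLS covariance of
    # the same fixed-effect structure
    vc <- stats::vcov(stats::lm(valid_days ~ week * arm, data = panel))
  }
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fixed <- tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    lower = unname(est - z * se), upper = unname(est + z * se),
    p = unname(2 * stats::pnorm(-abs(est / se))))

  w <- "week"; i <- "week:armintervention"
  comp_slope <- est[[w]]
  comp_se <- se[[w]]
  int_slope <- est[[w]] + est[[i]]
  int_se <- sqrt(vc[w, w] + vc[i, i] + 2 * vc[w, i])
  arm_decline <- tibble(
    arm = c("comparator", "intervention"),
    decline = c(-comp_slope, -int_slope),
    lower = c(-comp_slope - z * comp_se, -int_slope - z * int_se),
    upper = c(-comp_slope + z * comp_se, -int_slope + z * int_se))

  vcr <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed = fixed, arm_decline = arm_decline,
    ranef_var = vcr$vcov[vcr$grp == "participant_id"],
    diagnostics = list(residual_structure = "independent",
                       vcov_fallback = vcov_fallback,
                       residual_var = vcr$vcov[vcr$grp == "Residual"],
                       n_obs = nrow(panel),
                       n_participants = length(unique(panel$participant_id)),
                       converged = length(fit@optinfo$conv$lme4) == 0),
    model = fit), class = "dash_trend_fit")
}

#' @export
print.dash_trend_fit <- function(x, ...) {
  cat("Engagement trend (random-intercept mixed model)\n")
  cat(sprintf("  %d observations, %d participants\n",
              x$diagnostics$n_obs, x$diagnostics$n_participants))
  print(x$fixed)
  cat("Per-arm weekly decline in valid tracking days:\n")
  print(x$arm_decline)
  invisible(x)
}

#' Apply the recall-protocol validity rules
#'
#' A participant-timepoint's recall set is valid when it contains at least
#' two recalls covering one weekend day and one weekday, collected no more
#' than 14 days apart, with mean daily energy between 600 and 3500 kcal.
#' When more than two recalls exist, the earliest weekend and earliest
#' weekday recall form the pair that is assessed. All rules are always
#' evaluated; failures accumulate as reasons rather than errors.
#'
#' @param recalls Tibble of one participant-timepoint's recalls with
#'   `recall_date` and `energy_kcal` (a `day_class` column is derived if
#'   absent).
#' @param min_kcal,max_kcal Mean-energy bounds (600, 3500).
#' @param max_gap_days Maximum calendar gap between the recalls used (14).
#' @return List: `valid` flag, `failure_reasons` (subset of
#'   `too-few-recalls`, `no-weekend`, `no-weekday`, `gap>14d`, `kcal<600`,
#'   `kcal>3500`), `used` (the rows assessed), `mean_kcal`.
#' @export
assess_recall_validity <- function(recalls, min_kcal = 600, max_kcal = 3500,
                                   max_gap_days = 14L) {
  if (!"day_class" %in% names(recalls)) {
    recalls$day_class <- classify_recall_day(recalls$recall_date)
  }
  reasons <- character()
  if (nrow(recalls) < 2) reasons <- c(reasons, "too-few-recalls")
  wkend <- recalls[recalls$day_class == "weekend", ]
  wkday <- recalls[recalls$day_class == "weekday", ]
  if (nrow(wkend) == 0) reasons <- c(reasons, "no-weekend")
  if (nrow(wkday) == 0) reasons <- c(reasons, "no-weekday")

  if (nrow(wkend) > 0 && nrow(wkday) > 0) {
    used <- dplyr::bind_rows(
      wkend[which.min(wkend$recall_date), ],
      wkday[which.min(wkday$recall_date), ])
  } else {
    used <- recalls
  }
  if (nrow(used) >= 2) {
    gap <- as.integer(max(used$recall_date) - min(used$recall_date))
    if (gap > max_gap_days) {
      reasons <- c(reasons, sprintf("gap>%dd", max_gap_days))
    }
  }
  mean_kcal <- if (nrow(used) > 0) mean(used$energy_kcal) else NA_real_
  if (!is.na(mean_kcal) && mean_kcal < min_kcal) {
    reasons <- c(reasons, sprintf("kcal<%d", min_kcal))
  }
  if (!is.na(mean_kcal) && mean_kcal > max_kcal) {
    reasons <- c(reasons, sprintf("kcal>%d", max_kcal))
  }
  list(valid = length(reasons) == 0, failure_reasons = reasons,
       used = used, mean_kcal = mean_kcal)
}

#' Assess recall validity for every participant-timepoint in a table
#'
#' @param recalls Recall tibble with `participant_id`, `timepoint`,
#'   `recall_date`, `energy_kcal`.
#' @inheritParams assess_recall_validity
#' @return Tibble: one row per participant-timepoint with `valid`,
#'   `failure_reasons` (semicolon-joined), `mean_kcal`, `n_recalls`.
#' @export
assess_recalls <- function(recalls, min_kcal = 600, max_kcal = 3500,
                           max_gap_days = 14L) {
  if (!"timepoint" %in% names(recalls)) recalls$timepoint <- "all"
  groups <- dplyr::group_split(
    dplyr::group_by(recalls, .data$participant_id, .data$timepoint))
  dplyr::bind_rows(lapply(groups, function(g) {
    res <- assess_recall_validity(g, min_kcal, max_kcal, max_gap_days)
    tibble(participant_id = g$participant_id[1], timepoint = g$timepoint[1],
           n_recalls = nrow(g), valid = res$valid,
           failure_reasons = paste(res$failure_reasons, collapse = ";"),
           mean_kcal = res$mean_kcal)
  }))
}
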