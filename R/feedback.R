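NO_SCORE <- NA_real_  # "no score" token for untracked days

#' Load the tip bank
#'
#' Tips are keyed by nutrient; each nutrient has one or more short behavioral
#' suggestions. Selection by the feedback composer is deterministic (cycling
#' by study day), never random.
#'
#' @param path YAML file of `nutrient: [tips...]`; defaults to the shipped
#'   bank.
#' @return Named list of character vectors.
#' @export
load_tip_bank <- function(path = system.file("extdata", "tips.yaml",
                                             package = "dashtrack",
                                             mustWork = TRUE)) {
  bank <- yaml::read_yaml(path)
  bank <- lapply(bank, as.character)
  missing_nu <- setdiff(dash_nutrients(), names(bank))
  if (length(missing_nu) > 0) {
    abort(paste0("tip bank missing nutrient(s): ",
                 paste(missing_nu, collapse = ", ")))
  }
  if (any(vapply(bank, length, integer(1)) == 0)) {
    abort("every nutrient needs at least one tip")
  }
  bank
}

#' Load the weekly topic bank
#'
#' @param path YAML file: list of `{title, link}` entries; defaults to the
#'   shipped bank.
#' @return Tibble with `title` and `link` columns.
#' @export
load_topic_bank <- function(path = system.file("extdata", "topics.yaml",
                                               package = "dashtrack",
                                               mustWork = TRUE)) {
  lst <- yaml::read_yaml(path)
  out <- dplyr::bind_rows(lapply(lst, as_tibble))
  if (nrow(out) == 0) abort("topic bank is empty")
  out
}

rel_distance <- function(value, target) abs(value - target) / target

#' Pick the best and struggle components for a feedback message
#'
#' `best` holds up to `cap` components with full credit, the closest calls
#' (smallest relative margin to target) first; `struggle` holds up to `cap`
#' zero-credit components, the furthest from target first. Half-credit
#' components fill either list only when its cap is unfilled (struggle picks
#' first, so the two lists never overlap).
#'
#' @param score Result of [score_day()].
#' @param targets Targets tibble.
#' @param profile The standardized profile that was scored.
#' @param cap Maximum entries per list (default 2).
#' @return List with character vectors `best` and `struggle` (nutrient keys).
#' @export
classify_components <- function(score, targets = dash_targets(), profile,
                                cap = 2L) {
  targets <- validate_targets(targets)
  credits <- score$credits
  if (is.null(credits) || length(credits) != 9L) {
    abort("no score: a complete 9-component score is required")
  }
  nus <- dash_nutrients()
  vals <- vapply(nus, function(nu) as.numeric(profile[[nu]]), numeric(1))
  dist <- rel_distance(vals, targets$target[match(nus, targets$nutrient)])
  rank_of <- function(keys, decreasing) {
    keys[order(dist[keys], match(keys, nus),
               decreasing = c(decreasing, FALSE), method = "radix")]
  }
  full  <- rank_of(nus[credits[nus] == 1], decreasing = FALSE)
  zero  <- rank_of(nus[credits[nus] == 0], decreasing = TRUE)
  halves_for_struggle <- rank_of(nus[credits[nus] == 0.5], decreasing = TRUE)

  struggle <- utils::head(zero, cap)
  if (length(struggle) < cap) {
    struggle <- c(struggle,
                  utils::head(halves_for_struggle, cap - length(struggle)))
  }
  halves_left <- setdiff(nus[credits[nus] == 0.5], struggle)
  best <- utils::head(full, cap)
  if (length(best) < cap) {
    best <- c(best, utils::head(rank_of(halves_left, decreasing = FALSE),
                                cap - length(best)))
  }
  list(best = best, struggle = struggle)
}

label_list <- function(keys) {
  labs <- unname(nutrient_labels[keys])
  if (length(labs) <= 1) return(labs)
  paste(paste(labs[-length(labs)], collapse = ", "), "and", labs[length(labs)])
}

pick_tip <- function(nutrient, tip_bank, study_day) {
  tips <- tip_bank[[nutrient]]
  tips[((study_day - 1L) %% length(tips)) + 1L]
}

message_row <- function(participant_id, kind, scheduled_time, body,
                        referenced_score = NA_real_,
                        best = character(), struggle = character()) {
  tibble(participant_id = as.character(participant_id), kind = kind,
         scheduled_time = scheduled_time, body = body,
         referenced_score = referenced_score,
         best_components = list(best), struggle_components = list(struggle))
}

#' Compose a daily (or weekly) feedback message
#'
#' The body opens with a personalized greeting, reports the previous day's
#' DASH score to one decimal (or a tracked-nothing prompt when there is no
#' score), names the best and struggle components, and closes with one
#' behavioral tip aimed at the top struggle component. Tip selection cycles
#' deterministically with the study day.
#'
#' @param participant_id Identifier used in the outbox.
#' @param name First name for the greeting.
#' @param score_total Daily DASH total, or `NA` for an untracked day.
#' @param best,struggle Nutrient keys from [classify_components()].
#' @param tip_bank From [load_tip_bank()].
#' @param study_day 1-based study day (drives tip cycling).
#' @param scheduled_time `POSIXct` send time.
#' @param kind `"daily_feedback"` or `"weekly_feedback"`.
#' @return One-row message tibble.
#' @export
compose_daily_message <- function(participant_id, name, score_total,
                                  best = character(), struggle = character(),
                                  tip_bank = load_tip_bank(), study_day = 1L,
                                  scheduled_time = Sys.time(),
                                  kind = "daily_feedback") {
  if (is.na(name) || !nzchar(name)) abort("unknown participant: no roster name")
  greeting <- sprintf("Hello, %s!", name)
  period <- if (kind == "weekly_feedback") "this past week" else "yesterday"
  tip_target <- if (length(struggle) > 0) struggle[1]
                else if (length(best) > 0) best[1]
                else dash_nutrients()[((study_day - 1L) %% 9L) + 1L]
  tip <- pick_tip(tip_target, tip_bank, study_day)
  if (is.na(score_total)) {
    body <- paste(
      greeting,
      "We didn't see any food logged yesterday, so there is no DASH score",
      "to share. Log everything you eat and drink today to get back on",
      sprintf("track. Tip: %s", tip))
  } else {
    score_txt <- sprintf("Your DASH score %s was %.1f.", period, score_total)
    if (length(struggle) == 0) {
      middle <- paste(
        "Fantastic work - you met every DASH target",
        sprintf("%s! Keep it up.", period))
    } else {
      best_part <- if (length(best) > 0) {
        sprintf("You did best with %s", label_list(best))
      } else {
        "Every nutrient has room to improve"
      }
      middle <- sprintf("%s and seemed to struggle with %s.",
                        best_part, label_list(struggle))
    }
    body <- paste(greeting, score_txt, middle, sprintf("Tip: %s", tip))
  }
  message_row(participant_id, kind, scheduled_time, body,
              referenced_score = score_total, best = best, struggle = struggle)
}

#' Build a participant's message schedule
#'
#' Feedback is scheduled daily at 12:00 study time for study days 1-14, then
#' weekly (same weekday as enrollment, 12:00, summarizing the preceding
#' 7 days) for the remainder; a topic message goes out every Sunday afternoon
#' (15:00 by default).
#'
#' @param enrollment_date `Date`; study day 1.
#' @param study_length_days Total days (default 90; must be at least 14).
#' @param tz Olson timezone of the study (default `"America/New_York"`).
#' @param topic_time Clock time for Sunday topic messages.
#' @return Tibble with `study_day`, `date`, `kind`, `scheduled_time`, ordered
#'   by time.
#' @export
#' @examples
#' s <- build_schedule(as.Date("2017-09-01"))
#' table(s$kind)  # 14 daily, 10 weekly, 12-13 topic
build_schedule <- function(enrollment_date, study_length_days = 90L,
                           tz = "America/New_York", topic_time = "15:00:00") {
  if (!tz %in% OlsonNames()) abort(paste0("invalid timezone: ", tz))
  if (study_length_days < 14) abort("study_length_days must be >= 14")
  enrollment_date <- as.Date(enrollment_date)
  days <- seq_len(study_length_days)
  dates <- enrollment_date + days - 1L
  at <- function(d, clock) as.POSIXct(paste(d, clock), tz = tz)

  daily <- tibble(study_day = days[days <= 14], kind = "daily_feedback")
  # first weekly send is day 22 (the enrollment weekday after the daily
  # period), each send summarizing the preceding complete 7-day block
  weekly_days <- days[days >= 22 & (days %% 7L) == 1L]
  weekly <- tibble(study_day = weekly_days, kind = "weekly_feedback")
  sunday_days <- days[as.POSIXlt(dates)$wday == 0L]
  topics <- tibble(study_day = sunday_days, kind = "topic")

  out <- dplyr::bind_rows(daily, weekly, topics)
  out$date <- enrollment_date + out$study_day - 1L
  out$scheduled_time <- at(out$date,
                           ifelse(out$kind == "topic", topic_time, "12:00:00"))
  out <- dplyr::arrange(out, .data$scheduled_time, .data$kind)
  out[, c("study_day", "date", "kind", "scheduled_time")]
}

#' Compose a Sunday topic message
#'
#' Topics rotate through the bank in order, wrapping to the start when the
#' bank is exhausted.
#'
#' @param week_index 1-based study week.
#' @param topic_bank From [load_topic_bank()].
#' @param participant_id Identifier for the outbox row.
#' @param scheduled_time `POSIXct` send time (a Sunday afternoon slot).
#' @return One-row message tibble.
#' @export
compose_topic_message <- function(week_index, topic_bank = load_topic_bank(),
                                  participant_id = NA_character_,
                                  scheduled_time = Sys.time()) {
  if (is.na(week_index) || week_index < 1) abort("week_index must be >= 1")
  if (nrow(topic_bank) == 0) abort("topic bank is empty")
  i <- ((as.integer(week_index) - 1L) %% nrow(topic_bank)) + 1L
  body <- sprintf("This week's DASH topic: %s. Watch: %s",
                  topic_bank$title[i], topic_bank$link[i])
  message_row(participant_id, "topic", scheduled_time, body)
}

#' Automatic reply to an inbound participant text
#'
#' Participants are not expected to respond; any inbound message from an
#' enrolled participant gets one fixed reply pointing to staff email. Replies
#' are never generated for unknown senders (logged and dropped) or for
#' auto-replies themselves, so no loops can form.
#'
#' @param inbound List or one-row tibble with at least `participant_id` and
#'   `kind` (`kind = "auto_reply"` is never answered).
#' @param roster Tibble with a `participant_id` column of enrolled ids.
#' @param support_email Address given in the reply body.
#' @return One-row message tibble, or `NULL` when no reply is sent.
#' @export
auto_reply <- function(inbound, roster,
                       support_email = "dashstudy-support@example.org") {
  pid <- as.character(inbound$participant_id)
  if (length(pid) != 1 || is.na(pid) || !pid %in% roster$participant_id) {
    inform("auto_reply: unknown sender, message dropped")
    return(NULL)
  }
  if (!is.null(inbound$kind) && identical(as.character(inbound$kind),
                                          "auto_reply")) {
    return(NULL)
  }
  body <- paste("Thanks for your message! This number is not monitored.",
                sprintf("For support, email the study team at %s.",
                        support_email))
  message_row(pid, "auto_reply", Sys.time(), body)
}

#' Write messages to a JSON Lines outbox
#'
#' @param messages Message tibble (rows from the composers above).
#' @param path Destination `.jsonl` file.
#' @return `path`, invisibly.
#' @export
write_messages <- function(messages, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(messages))) {
    row <- messages[i, ]
    rec <- list(
      participant_id = row$participant_id, kind = row$kind,
      scheduled_time = format(row$scheduled_time, "%Y-%m-%dT%H:%M:%S%z"),
      body = row$body,
      referenced_score = if (is.na(row$referenced_score)) "no score"
                         else row$referenced_score)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
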