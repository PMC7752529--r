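#' Simulator parameters
#'
#' All knobs of the synthetic-cohort generator, with defaults calibrated to
#' the feasibility-study conditions: baseline adherence latent mean 2.3 (SD
#' 1.3, censored to the 0-9 score range), a +0.8-point 3-month adherence
#' change in both arms, tracking starting at 4.6 valid days/week with the
#' intervention arm declining 0.23 days/week per week faster than the (flat)
#' comparator, baseline blood pressure 122.9 (14.2) / 80.2 (8.8) mmHg, and
#' follow-up blood pressure coupled to the measured DASH-score change at
#' -2.5 (systolic) and -1.6 (diastolic) mmHg per score unit.
#'
#' @param n_participants Cohort size (default 59).
#' @param block_sizes Even permuted-block sizes (default 4, 6, 8).
#' @param baseline_adherence_mean,baseline_adherence_sd Latent baseline DASH
#'   score distribution, censored to `[0, 9]`.
#' @param adherence_change Named per-arm mean 3-month change in the latent
#'   score.
#' @param adherence_change_sd Participant-level SD of that change.
#' @param tracking_initial Named per-arm initial valid days/week.
#' @param tracking_decline Named per-arm weekly decline in days/week.
#' @param invalid_day_rate Fraction of logged days contaminated with <600
#'   kcal energies (invalid tracking days).
#' @param energy_mean,energy_sd,energy_range Daily energy draw (kcal),
#'   normal censored to the range.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Baseline blood pressure.
#' @param sbp_coupling,dbp_coupling mmHg change per unit of measured DASH
#'   change (negative = improvement lowers BP).
#' @param sbp_residual_sd,dbp_residual_sd Residual SD of the 3-month BP
#'   around the coupled mean (defaults reproduce study-scale correlations of
#'   about -0.34 and -0.27).
#' @param bp_arm_effect_sbp,bp_arm_effect_dbp Additional mean 3-month BP
#'   shift in the intervention arm beyond the coupling (default 0).
#' @param followup_missing_rate Fraction missing the 3-month visit.
#' @param recall_invalid_rate Fraction of participant-timepoints whose recall
#'   pair is contaminated to violate a (randomly chosen) validity rule.
#' @param study_days,weeks Study length in days and complete weeks.
#' @param enrollment_start First enrollment date; enrollments are staggered
#'   uniformly over the following 6 weeks.
#' @param include_daily Generate the daily intake stream (the slowest output;
#'   turn off when only recalls/outcomes are needed).
#' @param seed Master seed; every participant gets a stream derived from
#'   (seed, participant index).
#' @return A validated list of class `dash_cohort_params`.
#' @export
cohort_params <- function(
    n_participants = 59L,
    block_sizes = c(4L, 6L, 8L),
    baseline_adherence_mean = 2.3, baseline_adherence_sd = 1.3,
    adherence_change = c(intervention = 0.8, comparator = 0.8),
    adherence_change_sd = 1.0,
    tracking_initial = c(intervention = 4.6, comparator = 4.6),
    tracking_decline = c(intervention = 0.23, comparator = 0),
    invalid_day_rate = 0,
    energy_mean = 2000, energy_sd = 350, energy_range = c(1200, 3200),
    sbp_mean = 122.9, sbp_sd = 14.2, dbp_mean = 80.2, dbp_sd = 8.8,
    sbp_coupling = -2.5, dbp_coupling = -1.6,
    sbp_residual_sd = 6.9, dbp_residual_sd = 5.7,
    bp_arm_effect_sbp = 0, bp_arm_effect_dbp = 0,
    followup_missing_rate = 0.1,
    recall_invalid_rate = 0,
    study_days = 90L, weeks = 12L,
    enrollment_start = as.Date("2017-08-01"),
    include_daily = TRUE,
    seed = 1L) {
  p <- as.list(environment())
  if (any(p$block_sizes %% 2 != 0)) {
    abort("block sizes must be even for a two-arm permuted block design")
  }
  sds <- c(p$baseline_adherence_sd, p$adherence_change_sd, p$energy_sd,
           p$sbp_sd, p$dbp_sd)
  if (any(sds <= 0)) abort("all standard deviations must be positive")
  if (p$sbp_residual_sd < 0 || p$dbp_residual_sd < 0) {
    abort("residual sds must be non-negative")
  }
  for (nm in c("adherence_change", "tracking_initial", "tracking_decline")) {
    if (!all(c("intervention", "comparator") %in% names(p[[nm]]))) {
      abort(paste0(nm, " needs named 'intervention' and 'comparator' entries"))
    }
  }
  if (any(p$tracking_initial < 0 | p$tracking_initial > 7)) {
    abort("tracking_initial must lie in [0, 7] days/week")
  }
  rates <- c(p$invalid_day_rate, p$followup_missing_rate,
             p$recall_invalid_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  p$enrollment_start <- as.Date(p$enrollment_start)
  structure(p, class = "dash_cohort_params")
}

participant_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 7919) %% 2147483647)
}

#' Permuted-block randomization
#'
#' Assigns `n` participants to two arms in blocks whose sizes are drawn
#' uniformly from `block_sizes`; every completed block is exactly balanced.
#'
#' @param n Number of participants.
#' @param block_sizes Even block sizes (default 4, 6, 8).
#' @param seed Optional seed for a reproducible sequence.
#' @return Character vector of `"intervention"` / `"comparator"`, length `n`.
#' @export
permuted_block_randomize <- function(n, block_sizes = c(4L, 6L, 8L),
                                     seed = NULL) {
  if (any(block_sizes %% 2 != 0)) abort("block sizes must be even")
  if (n < 0) abort("n must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  arms <- character(0)
  while (length(arms) < n) {
    s <- if (length(block_sizes) == 1) block_sizes else sample(block_sizes, 1)
    arms <- c(arms, sample(rep(c("intervention", "comparator"), s / 2)))
  }
  arms[seq_len(n)]
}

# outer sampling bounds for each component's standardized value: the
# full-credit band is capped at a 2x target margin, the zero-credit band at a
# fixed physiologic limit
sim_bounds <- function(targets) {
  phys <- c(total_fat = 60, saturated_fat = 20, protein = 36,
            cholesterol = 400, fiber = 29.6, magnesium = 476,
            calcium = 1180, potassium = 4476, sodium = 8000)
  lo <- c(total_fat = 13.5, saturated_fat = 2, protein = 4,
          cholesterol = 20, fiber = 0, magnesium = 40,
          calcium = 80, potassium = 350, sodium = 800)
  tb <- validate_targets(targets)
  tb$band_lo <- unname(lo[tb$nutrient])
  tb$band_hi <- unname(phys[tb$nutrient])
  bad <- (tb$direction == "min" &
            (tb$band_lo >= tb$intermediate | tb$band_hi <= tb$target)) |
         (tb$direction == "max" &
            (tb$band_lo >= tb$target | tb$band_hi <= tb$intermediate))
  if (any(bad)) abort("sampling bounds do not bracket the thresholds")
  tb
}

# allocate a latent total L in [0,9] to 9 component credits in {0,.5,1}:
# total half-credits = floor(2L) + Bernoulli(frac(2L)), spread evenly with
# the remainder going to a random subset of components; E[sum credits] = L
draw_credits <- function(n, latent) {
  latent <- rep_len(latent, n)
  if (any(latent < 0 | latent > 9)) abort("latent adherence must be in [0, 9]")
  h2 <- 2 * latent
  H <- floor(h2) + stats::rbinom(n, 1, h2 - floor(h2))
  base <- H %/% 9L
  rem <- H %% 9L
  credits <- matrix(rep(base, 9L), nrow = n, ncol = 9L)
  need <- which(rem > 0L)
  if (length(need) > 0) {
    u <- matrix(stats::runif(length(need) * 9L), nrow = length(need))
    rk <- t(apply(u, 1L, rank, ties.method = "first"))
    credits[need, ] <- credits[need, ] + (rk <= rem[need])
  }
  colnames(credits) <- dash_nutrients()
  credits / 2
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# draw standardized values inside each chosen credit's band, then convert to
# raw amounts at the given energies; uses the current RNG stream. The drawn
# per-day credit totals (which scoring the output reproduces exactly) are
# attached as attribute "dash_total". `targets` may be a precomputed
# sim_bounds() table to avoid re-validation in tight loops.
sim_intake_days <- function(latent, energy_kcal, targets = dash_targets()) {
  n <- length(energy_kcal)
  tb <- if ("band_lo" %in% names(targets)) targets else sim_bounds(targets)
  credits <- draw_credits(n, latent)
  vals <- matrix(NA_real_, n, 9L, dimnames = list(NULL, dash_nutrients()))
  for (j in seq_len(9L)) {
    nu <- tb$nutrient[j]
    cr <- credits[, nu]
    if (tb$direction[j] == "min") {
      lo <- ifelse(cr == 1, tb$target[j],
                   ifelse(cr == 0.5, tb$intermediate[j], tb$band_lo[j]))
      hi <- ifelse(cr == 1, tb$band_hi[j],
                   ifelse(cr == 0.5, tb$target[j], tb$intermediate[j]))
    } else {
      lo <- ifelse(cr == 1, tb$band_lo[j],
                   ifelse(cr == 0.5, tb$target[j], tb$intermediate[j]))
      hi <- ifelse(cr == 1, tb$target[j],
                   ifelse(cr == 0.5, tb$intermediate[j], tb$band_hi[j]))
    }
    if (nu == "saturated_fat") hi <- pmin(hi, vals[, "total_fat"])
    vals[, j] <- lo + (hi - lo) * stats::runif(n)
  }
  e <- energy_kcal
  out <- tibble::new_tibble(list(
    energy_kcal = e,
    total_fat_g = vals[, "total_fat"] * e / (100 * ATWATER_FAT),
    saturated_fat_g = vals[, "saturated_fat"] * e / (100 * ATWATER_FAT),
    protein_g = vals[, "protein"] * e / (100 * ATWATER_PROTEIN),
    cholesterol_mg = vals[, "cholesterol"] * e / 1000,
    fiber_g = vals[, "fiber"] * e / 1000,
    magnesium_mg = vals[, "magnesium"] * e / 1000,
    calcium_mg = vals[, "calcium"] * e / 1000,
    potassium_mg = vals[, "potassium"] * e / 1000,
    sodium_mg = vals[, "sodium"]
  ), nrow = n)
  attr(out, "dash_total") <- unname(rowSums(credits))
  out
}

# prepend id/date columns to an intake block without tibble() overhead
with_ids <- function(di, participant_id, date, extra = NULL) {
  cols <- c(list(participant_id = rep(participant_id, nrow(di)),
                 date = date),
            as.list(di), extra)
  tibble::new_tibble(cols, nrow = nrow(di))
}

#' Generate a daily intake matching a latent adherence level
#'
#' Inverse model of the DASH scorer: component credits are drawn so their
#' expected sum equals the latent adherence, a standardized value is sampled
#' uniformly inside each chosen credit's band, and the values are converted
#' back to raw amounts at a drawn energy. Scoring the emitted intake with the
#' same target set reproduces the drawn credits exactly.
#'
#' @param latent Latent adherence in `[0, 9]` (scalar or length `n`).
#' @param n Number of days.
#' @param targets Targets tibble.
#' @param energy_kcal Optional energy vector; drawn from N(2000, 350) censored
#'   to \[1200, 3200\] kcal when `NULL`.
#' @param seed Optional seed.
#' @return Tibble of `n` intake rows (raw-amount columns, no identifiers).
#' @export
#' @examples
#' d <- generate_daily_intake(9, seed = 1)
#' score_days(compute_densities(cbind(participant_id = "x",
#'                                    date = Sys.Date(), d)))$dash_total  # 9
generate_daily_intake <- function(latent, n = 1L, targets = dash_targets(),
                                  energy_kcal = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(energy_kcal)) {
    energy_kcal <- rtrunc_norm(n, 2000, 350, 1200, 3200)
  }
  sim_intake_days(latent, energy_kcal, targets)
}

#' Simulate diet-tracking presence with a linear weekly decline
#'
#' Each day of week `w` is logged independently with probability
#' `clamp((initial_rate - decline * (w - 1)) / 7, 0, 1)`, so the expected
#' valid-day count declines by `decline` days/week per week until clamped.
#'
#' @param weeks Number of 7-day blocks.
#' @param initial_rate Expected days/week in week 1 (0-7).
#' @param decline Weekly decline in days/week.
#' @param seed Optional seed.
#' @return Tibble with `day` (1-based), `week`, `present`.
#' @export
simulate_tracking <- function(weeks, initial_rate, decline, seed = NULL) {
  if (initial_rate < 0 || initial_rate > 7) {
    abort("initial_rate must lie in [0, 7]")
  }
  if (!is.null(seed)) set.seed(seed)
  week <- rep(seq_len(weeks), each = 7L)
  p <- pmin(pmax((initial_rate - decline * (week - 1)) / 7, 0), 1)
  tibble::new_tibble(list(day = seq_len(weeks * 7L), week = week,
                          present = stats::runif(weeks * 7L) < p),
                     nrow = weeks * 7L)
}

#' Simulate follow-up blood pressure coupled to DASH change
#'
#' @param baseline_bp Baseline BP, mmHg.
#' @param delta_dash Measured DASH-score change.
#' @param coupling mmHg per DASH unit (negative couples improvement to a
#'   decrease).
#' @param residual_sd Residual SD, mmHg.
#' @param seed Optional seed.
#' @return Numeric vector of 3-month BP values.
#' @export
simulate_bp <- function(baseline_bp, delta_dash, coupling, residual_sd,
                        seed = NULL) {
  if (residual_sd < 0) abort("residual_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(baseline_bp)
  baseline_bp + coupling * delta_dash + stats::rnorm(n, 0, residual_sd)
}

#' Simulate a weekly engagement panel for both arms
#'
#' Direct panel generator for the engagement trend model: weekly valid-day
#' counts are Binomial(7, p_w) with the per-arm linear decline of
#' [simulate_tracking()].
#'
#' @param n_per_arm Participants per arm.
#' @param weeks Number of weeks (default 12).
#' @param tracking_initial,tracking_decline Named per-arm parameters (see
#'   [cohort_params()]).
#' @param seed Seed.
#' @return Tibble: `participant_id`, `arm`, `week`, `valid_days`.
#' @export
simulate_engagement_panel <- function(
    n_per_arm, weeks = 12L,
    tracking_initial = c(intervention = 4.6, comparator = 4.6),
    tracking_decline = c(intervention = 0.23, comparator = 0),
    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(c("comparator", "intervention"), function(a) {
    p_w <- pmin(pmax((tracking_initial[[a]] -
                        tracking_decline[[a]] * (seq_len(weeks) - 1)) / 7,
                     0), 1)
    tibble(
      participant_id = rep(sprintf("%s_%04d", substr(a, 1, 4),
                                   seq_len(n_per_arm)), each = weeks),
      arm = a,
      week = rep(seq_len(weeks), times = n_per_arm),
      valid_days = stats::rbinom(n_per_arm * weeks, 7L,
                                 rep(p_w, times = n_per_arm)))
  })
  dplyr::bind_rows(out)
}

empty_cohort <- function() {
  intake <- daily_intake(character(0), as.Date(character(0)), numeric(0))
  recalls <- intake
  recalls$recall_date <- as.Date(character(0))
  recalls$timepoint <- character(0)
  list(
    intake = intake,
    recalls = recalls,
    roster = tibble(participant_id = character(0), arm = character(0),
                    enrollment_date = as.Date(character(0)),
                    baseline_sbp = numeric(0), baseline_dbp = numeric(0),
                    month3_sbp = numeric(0), month3_dbp = numeric(0)),
    outcomes = tibble(participant_id = character(0), arm = character(0),
                      baseline_dash = numeric(0), month3_dash = numeric(0),
                      baseline_sbp = numeric(0), month3_sbp = numeric(0),
                      baseline_dbp = numeric(0), month3_dbp = numeric(0),
                      baseline_dash_valid = logical(0),
                      month3_dash_valid = logical(0)))
}

next_weekday_class <- function(from, want_weekend) {
  for (k in 0:6) {
    d <- from + k
    if ((classify_recall_day(d) == "weekend") == want_weekend) return(d)
  }
  from
}

make_recall_pair <- function(anchor, invalid_kind = "none") {
  sat <- next_weekday_class(anchor, want_weekend = TRUE)
  wk <- sat + 3  # a Tuesday or Wednesday; gap 3 days
  dates <- c(sat, wk)
  if (invalid_kind == "no-weekend") {
    dates <- c(next_weekday_class(anchor, FALSE),
               next_weekday_class(anchor, FALSE) + 1)
    dates[2] <- if (classify_recall_day(dates[2]) == "weekend")
      dates[2] + 2 else dates[2]
  } else if (invalid_kind == "gap") {
    dates <- c(sat, sat + 17)
    dates[2] <- next_weekday_class(dates[2], FALSE)
  }
  dates
}

#' Generate a complete synthetic cohort
#'
#' Produces an internally consistent dataset exercising every analysis path:
#' permuted-block randomization, staggered enrollment, a daily diet-tracking
#' stream whose presence declines linearly per arm, recall pairs at baseline
#' and 3 months generated at each participant's latent adherence, DASH
#' outcomes scored from those recalls, and 3-month blood pressure coupled to
#' the measured DASH change. Re-running with identical parameters is
#' reproducible row for row.
#'
#' @param params A [cohort_params()] object.
#' @param outdir Optional directory; when given, `intake.csv`, `recalls.csv`,
#'   `roster.csv` and `outcomes.csv` are written there.
#' @param targets Targets tibble used by the intake generator.
#' @return List of tibbles: `intake`, `recalls`, `roster`, `outcomes`.
#' @export
generate_cohort <- function(params = cohort_params(), outdir = NULL,
                            targets = dash_targets()) {
  if (!inherits(params, "dash_cohort_params")) {
    abort("params must come from cohort_params()")
  }
  n <- params$n_participants
  if (n == 0) {
    out <- empty_cohort()
  } else {
    tb <- sim_bounds(targets)
    arms <- permuted_block_randomize(n, params$block_sizes,
                                     seed = participant_seed(params$seed, 0L))
    set.seed(participant_seed(params$seed, n + 1L))
    enroll_offset <- sample(0:41, n, replace = TRUE)
    ids <- sprintf("P%04d", seq_len(n))

    intake_l <- vector("list", n)
    recall_l <- vector("list", n)
    enroll_v <- params$enrollment_start + enroll_offset
    base_dash <- m3_dash <- sbp0_v <- sbp3_v <- dbp0_v <- dbp3_v <-
      rep(NA_real_, n)
    base_valid <- m3_valid <- rep(TRUE, n)
    for (i in seq_len(n)) {
      set.seed(participant_seed(params$seed, i))
      arm <- arms[i]
      enroll <- enroll_v[i]

      base_lat <- rtrunc_norm(1, params$baseline_adherence_mean,
                              params$baseline_adherence_sd, 0, 9)
      change <- stats::rnorm(1, params$adherence_change[[arm]],
                             params$adherence_change_sd)
      m3_lat <- min(max(base_lat + change, 0), 9)

      # daily tracking stream
      if (params$include_daily) {
        pres <- simulate_tracking(params$weeks,
                                  params$tracking_initial[[arm]],
                                  params$tracking_decline[[arm]])
        pd <- pres$day[pres$present]
        if (length(pd) > 0) {
          e <- rtrunc_norm(length(pd), params$energy_mean, params$energy_sd,
                           params$energy_range[1], params$energy_range[2])
          bad <- stats::runif(length(pd)) < params$invalid_day_rate
          e[bad] <- stats::runif(sum(bad), 100, 599)
          lat_day <- base_lat + (m3_lat - base_lat) *
            (pd - 1) / max(params$study_days - 1, 1)
          di <- sim_intake_days(lat_day, e, tb)
          intake_l[[i]] <- with_ids(di, ids[i], enroll + pd - 1)
        }
      }

      # recall pairs at both timepoints
      rec_tp <- list(baseline = enroll, month3 = enroll + 84)
      rec_rows <- list()
      dash_meas <- c(baseline = NA_real_, month3 = NA_real_)
      dash_valid <- c(baseline = TRUE, month3 = TRUE)
      for (tp in names(rec_tp)) {
        contam <- stats::runif(1) < params$recall_invalid_rate
        kind <- "none"
        kcal_shift <- 0
        if (contam) {
          kind <- sample(c("no-weekend", "gap", "kcal-low", "kcal-high"), 1)
          if (kind == "kcal-low") kcal_shift <- -1
          if (kind == "kcal-high") kcal_shift <- 1
        }
        dates <- make_recall_pair(rec_tp[[tp]],
                                  if (kind %in% c("no-weekend", "gap"))
                                    kind else "none")
        e <- rtrunc_norm(2, params$energy_mean, params$energy_sd,
                         params$energy_range[1], params$energy_range[2])
        if (kcal_shift < 0) e <- stats::runif(2, 300, 550)
        if (kcal_shift > 0) e <- stats::runif(2, 3600, 4500)
        lat <- if (tp == "baseline") base_lat else m3_lat
        ri <- sim_intake_days(rep(lat, 2), e, tb)
        # the drawn credits are what scoring the emitted recalls reproduces
        dash_meas[[tp]] <- mean(attr(ri, "dash_total"))
        dash_valid[[tp]] <- !contam
        rec_rows[[tp]] <- with_ids(ri, ids[i], dates,
                                   extra = list(recall_date = dates,
                                                timepoint = rep(tp, 2)))
      }
      recall_l[[i]] <- rec_rows

      # blood pressure coupled to the measured DASH change
      sbp0 <- stats::rnorm(1, params$sbp_mean, params$sbp_sd)
      dbp0 <- stats::rnorm(1, params$dbp_mean, params$dbp_sd)
      dd <- dash_meas[["month3"]] - dash_meas[["baseline"]]
      arm_fx <- if (arm == "intervention")
        c(params$bp_arm_effect_sbp, params$bp_arm_effect_dbp) else c(0, 0)
      sbp3 <- simulate_bp(sbp0, dd, params$sbp_coupling,
                          params$sbp_residual_sd) + arm_fx[1]
      dbp3 <- simulate_bp(dbp0, dd, params$dbp_coupling,
                          params$dbp_residual_sd) + arm_fx[2]

      missing3 <- stats::runif(1) < params$followup_missing_rate
      if (missing3) {
        dash_meas[["month3"]] <- NA_real_
        sbp3 <- NA_real_
        dbp3 <- NA_real_
      }
      base_dash[i] <- dash_meas[["baseline"]]
      m3_dash[i] <- dash_meas[["month3"]]
      sbp0_v[i] <- sbp0; sbp3_v[i] <- sbp3
      dbp0_v[i] <- dbp0; dbp3_v[i] <- dbp3
      base_valid[i] <- dash_valid[["baseline"]]
      m3_valid[i] <- dash_valid[["month3"]]
    }
    intake_l <- intake_l[!vapply(intake_l, is.null, logical(1))]
    out <- list(
      intake = if (length(intake_l) > 0) dplyr::bind_rows(intake_l)
               else empty_cohort()$intake,
      recalls = dplyr::bind_rows(unlist(recall_l, recursive = FALSE)),
      roster = tibble(participant_id = ids, arm = arms,
                      enrollment_date = enroll_v,
                      baseline_sbp = sbp0_v, baseline_dbp = dbp0_v,
                      month3_sbp = sbp3_v, month3_dbp = dbp3_v),
      outcomes = tibble(participant_id = ids, arm = arms,
                        baseline_dash = base_dash, month3_dash = m3_dash,
                        baseline_sbp = sbp0_v, month3_sbp = sbp3_v,
                        baseline_dbp = dbp0_v, month3_dbp = dbp3_v,
                        baseline_dash_valid = base_valid,
                        month3_dash_valid = m3_valid))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$intake, file.path(outdir, "intake.csv"))
    readr::write_csv(out$recalls, file.path(outdir, "recalls.csv"))
    readr::write_csv(out$roster, file.path(outdir, "roster.csv"))
    readr::write_csv(out$outcomes, file.path(outdir, "outcomes.csv"))
  }
  out
}
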