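#' Score one nutrient against its DASH standard
#'
#' Awards the component credit of the nutrient-based DASH adherence index:
#' 1 for meeting the full target, 0.5 for reaching the intermediate
#' threshold, 0 otherwise. For a "min" nutrient (more is better) a value at
#' or above the target earns 1 and a value at or above the intermediate earns
#' 0.5; for a "max" nutrient (less is better) the comparisons flip. Boundary
#' ties resolve toward the better credit.
#'
#' @param value Standardized amount(s) on the nutrient's basis; non-negative.
#' @param spec One row of a targets tibble (see [dash_targets()]).
#' @return Numeric vector of credits in \{0, 0.5, 1\}.
#' @export
#' @examples
#' fiber <- dplyr::filter(dash_targets(), nutrient == "fiber")
#' score_component(c(14.8, 10, 9.1), fiber)  # 1, 0.5, 0
score_component <- function(value, spec) {
  if (nrow(spec) != 1L) abort("spec must be a single target row")
  if (any(is.na(value)) || any(value < 0)) {
    abort("standardized values must be present and non-negative")
  }
  if (spec$direction == "min") {
    ifelse(value >= spec$target, 1, ifelse(value >= spec$intermediate, 0.5, 0))
  } else {
    ifelse(value <= spec$target, 1, ifelse(value <= spec$intermediate, 0.5, 0))
  }
}

#' Score one day's standardized profile
#'
#' Applies [score_component()] to all nine components and sums the credits to
#' the 0-9 daily DASH adherence total (multiples of 0.5; 9 = full adherence).
#'
#' @param profile Named list or one-row tibble holding the nine standardized
#'   values (names as in [dash_nutrients()]).
#' @param targets Targets tibble; default [dash_targets()].
#' @return List with `credits` (named numeric, length 9) and `total`.
#' @export
#' @examples
#' p <- list(total_fat = 25, saturated_fat = 5, protein = 19,
#'           cholesterol = 60, fiber = 15, magnesium = 250, calcium = 600,
#'           potassium = 2300, sodium = 2000)
#' score_day(p)$total  # 9
score_day <- function(profile, targets = dash_targets()) {
  targets <- validate_targets(targets)
  missing_comp <- setdiff(dash_nutrients(), names(profile))
  if (length(missing_comp) > 0) {
    abort(paste0("incomplete profile; missing component(s): ",
                 paste(missing_comp, collapse = ", ")))
  }
  credits <- vapply(dash_nutrients(), function(nu) {
    score_component(as.numeric(profile[[nu]]),
                    targets[targets$nutrient == nu, ])
  }, numeric(1))
  list(credits = credits, total = sum(credits))
}

#' Score many standardized profiles at once
#'
#' Data-frame version of [score_day()]: one input row per participant-day.
#'
#' @param profiles Tibble from [compute_densities()] (identifier columns are
#'   carried through).
#' @param targets Targets tibble.
#' @return Tibble with the carried identifier columns, one `credit_<nutrient>`
#'   column per component, and `dash_total`.
#' @export
score_days <- function(profiles, targets = dash_targets()) {
  targets <- validate_targets(targets)
  missing_comp <- setdiff(dash_nutrients(), names(profiles))
  if (length(missing_comp) > 0) {
    abort(paste0("incomplete profiles; missing component(s): ",
                 paste(missing_comp, collapse = ", ")))
  }
  id_cols <- intersect(c("participant_id", "date", "recall_date", "timepoint",
                         "energy_kcal"), names(profiles))
  out <- profiles[, id_cols, drop = FALSE]
  total <- numeric(nrow(profiles))
  for (nu in dash_nutrients()) {
    cr <- score_component(profiles[[nu]], targets[targets$nutrient == nu, ])
    out[[paste0("credit_", nu)]] <- cr
    total <- total + cr
  }
  out$dash_total <- total
  as_tibble(out)
}

#' Mean of daily DASH totals
#'
#' @param scores Numeric vector of daily totals, or a tibble from
#'   [score_days()] (its `dash_total` column is used).
#' @return Arithmetic mean.
#' @export
mean_score <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$dash_total
  if (length(scores) == 0) abort("empty score list")
  if (any(is.na(scores))) abort("scores must not be missing")
  mean(scores)
}
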