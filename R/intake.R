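# Raw-amount CSV columns, in schema order; nutrient keys map to their raw unit
intake_raw_cols <- c(
  total_fat = "total_fat_g", saturated_fat = "saturated_fat_g",
  protein = "protein_g", cholesterol = "cholesterol_mg", fiber = "fiber_g",
  magnesium = "magnesium_mg", calcium = "calcium_mg",
  potassium = "potassium_mg", sodium = "sodium_mg"
)

intake_schema <- function() {
  c("participant_id", "date", "energy_kcal", unname(intake_raw_cols))
}

# Atwater energy conversion factors, kcal per gram
ATWATER_FAT <- 9
ATWATER_PROTEIN <- 4

#' Construct a one-day intake record
#'
#' Convenience constructor for a single participant-day of energy and the nine
#' DASH nutrients in their native units (grams for fats, protein and fiber;
#' milligrams for cholesterol and the minerals).
#'
#' @param participant_id Identifier.
#' @param date Calendar date (`Date` or ISO-8601 string).
#' @param energy_kcal Energy, kcal/day.
#' @param total_fat_g,saturated_fat_g,protein_g,fiber_g Grams/day.
#' @param cholesterol_mg,magnesium_mg,calcium_mg,potassium_mg,sodium_mg
#'   Milligrams/day.
#' @return A one-row tibble in the intake schema.
#' @export
#' @examples
#' daily_intake("p1", "2017-09-04", 2000, 84.2, 13, 90, 344, 18.2,
#'              284.4, 1100, 2800, 3000)
daily_intake <- function(participant_id, date, energy_kcal,
                         total_fat_g = NA_real_, saturated_fat_g = NA_real_,
                         protein_g = NA_real_, cholesterol_mg = NA_real_,
                         fiber_g = NA_real_, magnesium_mg = NA_real_,
                         calcium_mg = NA_real_, potassium_mg = NA_real_,
                         sodium_mg = NA_real_) {
  tibble(
    participant_id = as.character(participant_id), date = as.Date(date),
    energy_kcal = as.numeric(energy_kcal),
    total_fat_g = as.numeric(total_fat_g),
    saturated_fat_g = as.numeric(saturated_fat_g),
    protein_g = as.numeric(protein_g),
    cholesterol_mg = as.numeric(cholesterol_mg),
    fiber_g = as.numeric(fiber_g), magnesium_mg = as.numeric(magnesium_mg),
    calcium_mg = as.numeric(calcium_mg),
    potassium_mg = as.numeric(potassium_mg),
    sodium_mg = as.numeric(sodium_mg)
  )
}

#' Per-row validation of intake records
#'
#' Reports, one row per issue: missing nutrient fields, negative amounts,
#' saturated fat exceeding total fat, and macronutrient-energy implausibility
#' (9 x fat g + 4 x protein g above 125% of reported energy, a warning-level
#' issue that never invalidates a record).
#'
#' @param intake Tibble in the intake schema.
#' @return Tibble with columns `line`, `participant_id`, `field`, `reason`,
#'   `severity` (`"error"` rows make the record incomplete/invalid,
#'   `"warning"` rows do not).
#' @export
validate_intake <- function(intake) {
  issues <- list()
  add <- function(line, pid, field, reason, severity = "error") {
    tibble(line = line, participant_id = pid, field = field,
           reason = reason, severity = severity)
  }
  n <- nrow(intake)
  if (n == 0) {
    return(tibble(line = integer(), participant_id = character(),
                  field = character(), reason = character(),
                  severity = character()))
  }
  num_cols <- c("energy_kcal", unname(intake_raw_cols))
  for (col in num_cols) {
    miss <- which(is.na(intake[[col]]))
    if (length(miss) > 0) {
      issues[[length(issues) + 1L]] <-
        add(miss, intake$participant_id[miss], col, "missing")
    }
    neg <- which(!is.na(intake[[col]]) & intake[[col]] < 0)
    if (length(neg) > 0) {
      issues[[length(issues) + 1L]] <-
        add(neg, intake$participant_id[neg], col, "negative amount")
    }
  }
  sf_gt <- which(!is.na(intake$saturated_fat_g) & !is.na(intake$total_fat_g) &
                 intake$saturated_fat_g > intake$total_fat_g)
  if (length(sf_gt) > 0) {
    issues[[length(issues) + 1L]] <-
      add(sf_gt, intake$participant_id[sf_gt], "saturated_fat_g",
          "saturated fat exceeds total fat")
  }
  macro <- ATWATER_FAT * intake$total_fat_g + ATWATER_PROTEIN * intake$protein_g
  implaus <- which(!is.na(macro) & !is.na(intake$energy_kcal) &
                   macro > intake$energy_kcal * 1.25)
  if (length(implaus) > 0) {
    issues[[length(issues) + 1L]] <-
      add(implaus, intake$participant_id[implaus], "energy_kcal",
          "fat + protein energy exceeds 125% of reported energy",
          severity = "warning")
  }
  out <- dplyr::bind_rows(issues)
  if (nrow(out) > 0) out <- dplyr::arrange(out, .data$line)
  out
}

#' Flag records with all nine nutrients present
#'
#' @param intake Tibble in the intake schema.
#' @return Logical vector: `TRUE` where every nutrient amount is present,
#'   non-negative, and saturated fat does not exceed total fat.
#' @export
intake_complete <- function(intake) {
  vals <- as.matrix(intake[, unname(intake_raw_cols)])
  ok <- rowSums(is.na(vals)) == 0 & rowSums(vals < 0, na.rm = TRUE) == 0
  sf_ok <- is.na(intake$saturated_fat_g) | is.na(intake$total_fat_g) |
    intake$saturated_fat_g <= intake$total_fat_g
  ok & sf_ok
}

read_tracking_csv <- function(path, extra_cols = character()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  want <- c(intake_schema(), extra_cols)
  hdr <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  if (!setequal(hdr, want)) {
    abort(paste0(
      "unexpected CSV header in ", path,
      "\n  missing: ", paste(setdiff(want, hdr), collapse = ", "),
      "\n  extra:   ", paste(setdiff(hdr, want), collapse = ", ")))
  }
  spec <- readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    .default = readr::col_double()
  )
  if ("recall_date" %in% want) spec$cols$recall_date <- readr::col_date()
  df <- readr::read_csv(path, col_types = spec, progress = FALSE)
  df[, want]
}

#' Read a daily diet-tracking CSV
#'
#' Expects the header `participant_id,date,energy_kcal,total_fat_g,
#' saturated_fat_g,protein_g,cholesterol_mg,fiber_g,magnesium_mg,calcium_mg,
#' potassium_mg,sodium_mg` with ISO-8601 dates; empty cells are missing
#' values. A per-row validation report (see [validate_intake()]) is attached
#' as the `"validation"` attribute and surfaced as a message.
#'
#' @param path CSV path.
#' @return Tibble of intake records with a `complete` logical column.
#' @export
read_intake <- function(path) {
  df <- read_tracking_csv(path)
  rep <- validate_intake(df)
  if (nrow(rep) > 0) {
    inform(paste0(path, ": ", nrow(rep), " validation issue(s) on ",
                  length(unique(rep$line)), " row(s)"))
  }
  df$complete <- intake_complete(df)
  attr(df, "validation") <- rep
  df
}

#' Read a 24-hour recall export CSV
#'
#' Same schema as [read_intake()] plus a `recall_date` column; adds the
#' derived `day_class` (`"weekend"` for Saturday/Sunday, else `"weekday"`).
#'
#' @param path CSV path.
#' @return Tibble of recall records with `day_class` and `complete` columns.
#' @export
read_recalls <- function(path) {
  df <- read_tracking_csv(path, extra_cols = "recall_date")
  rep <- validate_intake(df)
  if (nrow(rep) > 0) {
    inform(paste0(path, ": ", nrow(rep), " validation issue(s) on ",
                  length(unique(rep$line)), " row(s)"))
  }
  df$day_class <- classify_recall_day(df$recall_date)
  df$complete <- intake_complete(df)
  attr(df, "validation") <- rep
  df
}

#' Classify a recall date as weekend or weekday
#'
#' @param recall_date `Date` vector (or ISO-8601 strings).
#' @return `"weekend"` for Saturday/Sunday, `"weekday"` for Monday-Friday.
#' @export
#' @examples
#' classify_recall_day(as.Date("2017-09-02"))  # Saturday -> weekend
classify_recall_day <- function(recall_date) {
  d <- tryCatch(as.Date(recall_date),
                error = function(e) abort("unparseable recall_date"))
  if (any(is.na(d) & !is.na(recall_date))) {
    abort("unparseable recall_date")
  }
  # as.POSIXlt wday: 0 = Sunday, 6 = Saturday
  wd <- as.POSIXlt(d)$wday
  ifelse(wd %in% c(0L, 6L), "weekend", "weekday")
}

#' Standardize intakes to their calorie-relative scoring bases
#'
#' Converts raw daily amounts to the bases the DASH standards are expressed
#' in: total fat, saturated fat and protein to percent of energy (Atwater
#' factors of 9 kcal/g for fat and 4 kcal/g for protein); cholesterol, fiber,
#' magnesium, calcium and potassium to amount per 1000 kcal; sodium passed
#' through as the absolute mg/day amount.
#'
#' @param intake Tibble in the intake schema; every row must have positive
#'   energy and all nine nutrients present.
#' @return Tibble with `participant_id`, `date`, `energy_kcal`, and one
#'   standardized column per component (named by [dash_nutrients()]).
#' @export
#' @examples
#' d <- daily_intake("p1", "2017-09-04", 2000, 84.2, 13, 90, 344, 18.2,
#'                   284.4, 1100, 2800, 3000)
#' compute_densities(d)$total_fat  # 37.89% of energy
compute_densities <- function(intake) {
  if (nrow(intake) == 0) {
    out <- tibble(participant_id = character(), date = as.Date(character()),
                  energy_kcal = numeric())
    for (nu in dash_nutrients()) out[[nu]] <- numeric()
    return(out)
  }
  if (any(is.na(intake$energy_kcal) | intake$energy_kcal <= 0)) {
    abort("degenerate day: energy must be present and > 0 for every record")
  }
  complete <- intake_complete(intake)
  if (!all(complete)) {
    vals <- as.matrix(intake[, unname(intake_raw_cols)])
    bad <- unname(intake_raw_cols)[colSums(is.na(vals[!complete, , drop = FALSE])) > 0]
    abort(paste0("incomplete intake record(s); missing field(s): ",
                 paste(bad, collapse = ", ")))
  }
  macro <- ATWATER_FAT * intake$total_fat_g + ATWATER_PROTEIN * intake$protein_g
  if (any(macro > intake$energy_kcal * 1.25)) {
    warn("fat + protein energy exceeds 125% of reported energy for some records")
  }
  e <- intake$energy_kcal
  tibble(
    participant_id = intake$participant_id,
    date = intake$date,
    energy_kcal = e,
    total_fat = intake$total_fat_g * ATWATER_FAT * 100 / e,
    saturated_fat = intake$saturated_fat_g * ATWATER_FAT * 100 / e,
    protein = intake$protein_g * ATWATER_PROTEIN * 100 / e,
    cholesterol = intake$cholesterol_mg * 1000 / e,
    fiber = intake$fiber_g * 1000 / e,
    magnesium = intake$magnesium_mg * 1000 / e,
    calcium = intake$calcium_mg * 1000 / e,
    potassium = intake$potassium_mg * 1000 / e,
    sodium = intake$sodium_mg
  )
}
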