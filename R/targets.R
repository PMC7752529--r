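#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

#' The nine DASH index nutrients
#'
#' Component order is fixed and used throughout the package: total fat,
#' saturated fat and protein are scored as a percent of energy; cholesterol,
#' fiber, magnesium, calcium and potassium as densities per 1000 kcal; sodium
#' as an absolute daily amount.
#'
#' @return Character vector of the nine component keys.
#' @export
dash_nutrients <- function() {
  c("total_fat", "saturated_fat", "protein", "cholesterol",
    "fiber", "magnesium", "calcium", "potassium", "sodium")
}

# display names used in message bodies
nutrient_labels <- c(
  total_fat = "total fat", saturated_fat = "saturated fat",
  protein = "protein", cholesterol = "cholesterol", fiber = "fiber",
  magnesium = "magnesium", calcium = "calcium", potassium = "potassium",
  sodium = "sodium"
)

#' Default DASH nutrient targets
#'
#' Returns the nine-component target set of the nutrient-based DASH adherence
#' index: for each nutrient, the scoring direction (`"min"` = more is better,
#' `"max"` = less is better), the basis the raw amount is standardized to
#' (`percent_of_energy`, `per_1000_kcal`, or `per_day` for sodium), the full
#' target, and the intermediate (half-credit) threshold.
#'
#' Full targets are the published DASH nutrient standards: total fat <27% of
#' energy, saturated fat <6%, protein >18%, cholesterol <71.4 mg/1000 kcal,
#' fiber >14.8 g/1000 kcal, magnesium >238 mg/1000 kcal, calcium >590
#' mg/1000 kcal, potassium >2238 mg/1000 kcal, sodium <2400 mg/day. The
#' intermediate thresholds default to 2/3 of the target for "min" nutrients
#' and 1.5 times the target for "max" nutrients; both can be overridden per
#' nutrient through a targets file (see [read_targets()]).
#'
#' @return A tibble with columns `nutrient`, `direction`, `basis`, `target`,
#'   `intermediate`, one row per component.
#' @export
#' @examples
#' dash_targets()
dash_targets <- function() {
  out <- tibble(
    nutrient  = dash_nutrients(),
    direction = c("max", "max", "min", "max", "min", "min", "min", "min", "max"),
    basis     = c("percent_of_energy", "percent_of_energy", "percent_of_energy",
                  "per_1000_kcal", "per_1000_kcal", "per_1000_kcal",
                  "per_1000_kcal", "per_1000_kcal", "per_day"),
    target    = c(27, 6, 18, 71.4, 14.8, 238, 590, 2238, 2400)
  )
  out$intermediate <- ifelse(out$direction == "min",
                             out$target * 2 / 3, out$target * 1.5)
  out
}

#' Validate a target set
#'
#' Checks that a targets table has exactly the nine DASH components with
#' well-formed directions, bases and thresholds (intermediate below the target
#' for "min" nutrients, above it for "max" nutrients).
#'
#' @param targets A tibble as returned by [dash_targets()].
#' @return The validated targets, invisibly reordered to the canonical
#'   component order.
#' @export
validate_targets <- function(targets) {
  required <- c("nutrient", "direction", "basis", "target", "intermediate")
  missing_cols <- setdiff(required, names(targets))
  if (length(missing_cols) > 0) {
    abort(paste0("targets is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!setequal(targets$nutrient, dash_nutrients()) ||
      nrow(targets) != 9L) {
    abort("targets must contain exactly the 9 DASH components")
  }
  if (!all(targets$direction %in% c("min", "max"))) {
    abort("direction must be 'min' or 'max'")
  }
  if (!all(targets$basis %in%
           c("percent_of_energy", "per_1000_kcal", "per_day"))) {
    abort("basis must be percent_of_energy, per_1000_kcal or per_day")
  }
  if (any(!is.finite(targets$target)) || any(targets$target <= 0)) {
    abort("targets must be positive and finite")
  }
  bad <- (targets$direction == "min" & targets$intermediate >= targets$target) |
         (targets$direction == "max" & targets$intermediate <= targets$target)
  if (any(bad)) {
    abort(paste0("intermediate threshold on the wrong side of the target for: ",
                 paste(targets$nutrient[bad], collapse = ", ")))
  }
  targets <- targets[match(dash_nutrients(), targets$nutrient), required]
  invisible(as_tibble(targets))
}

#' Read a target set from JSON or YAML
#'
#' The file holds a list of nine objects with fields `nutrient`, `direction`,
#' `basis`, `target`, `intermediate`. Missing `intermediate` entries fall back
#' to the default rule (2/3 of target for "min", 1.5 times for "max").
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated targets tibble.
#' @seealso [write_targets()], [dash_targets()]
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) abort(paste0("targets file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml  = {
      lst <- yaml::read_yaml(path)
      dplyr::bind_rows(lapply(lst, as_tibble))
    },
    abort(paste0("unsupported targets format: .", ext))
  )
  raw <- as_tibble(raw)
  if (!"intermediate" %in% names(raw)) raw$intermediate <- NA_real_
  miss <- is.na(raw$intermediate)
  raw$intermediate[miss] <- ifelse(raw$direction[miss] == "min",
                                   raw$target[miss] * 2 / 3,
                                   raw$target[miss] * 1.5)
  validate_targets(raw)
}

#' Write a target set to JSON or YAML
#'
#' JSON is written at full double precision so a default target set
#' round-trips exactly through [read_targets()].
#'
#' @param targets A targets tibble.
#' @param path Destination `.json`, `.yaml` or `.yml` path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  targets <- validate_targets(targets)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(targets, path, digits = I(17),
                                auto_unbox = TRUE, dataframe = "rows",
                                pretty = TRUE),
    yaml = ,
    yml  = yaml::write_yaml(
      lapply(seq_len(nrow(targets)), function(i) as.list(targets[i, ])), path,
      precision = 17L),
    abort(paste0("unsupported targets format: .", ext))
  )
  invisible(path)
}

#' Path to the shipped default targets file
#'
#' @return Path of the default JSON targets file installed with the package.
#' @export
default_targets_path <- function() {
  system.file("extdata", "dash_targets.json", package = "dashtrack",
              mustWork = TRUE)
}
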