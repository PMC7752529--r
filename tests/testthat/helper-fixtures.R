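# Shared fixtures, all built in code.

# standardized profile hitting every default standard
perfect_profile <- function() {
  list(total_fat = 25, saturated_fat = 5, protein = 19, cholesterol = 60,
       fiber = 15, magnesium = 250, calcium = 600, potassium = 2300,
       sodium = 2000)
}

# standardized profile failing every component beyond its intermediate
worst_profile <- function() {
  list(total_fat = 50, saturated_fat = 20, protein = 5, cholesterol = 300,
       fiber = 2, magnesium = 50, calcium = 100, potassium = 400,
       sodium = 5000)
}

# cohort baseline-mean standardized profile used as a worked mid-range case
# (scores 2.0 under the default target set)
midrange_profile <- function() {
  list(total_fat = 37.9, saturated_fat = 12.6, protein = 16.0,
       cholesterol = 172.2, fiber = 9.1, magnesium = 142.2, calcium = 494.4,
       potassium = 1318.0, sodium = 3223.6)
}

# random standardized profile within physiologic-ish ranges
random_profile <- function() {
  list(total_fat = runif(1, 5, 60), saturated_fat = runif(1, 1, 20),
       protein = runif(1, 4, 36), cholesterol = runif(1, 10, 400),
       fiber = runif(1, 0, 30), magnesium = runif(1, 30, 480),
       calcium = runif(1, 50, 1200), potassium = runif(1, 300, 4500),
       sodium = runif(1, 500, 8000))
}

# attach id/date columns so raw intake frames fit the schema
add_ids <- function(d, pid = "px", date = as.Date("2017-09-04")) {
  cbind(tibble::tibble(participant_id = pid, date = date), d)
}

# a complete one-week intake table for one participant
week_intake <- function(pid = "p1", start = as.Date("2017-09-04"),
                        energies = c(1800, 550, NA, 2000, 1900, 650, 2100)) {
  keep <- !is.na(energies)
  dashtrack::daily_intake(
    pid, start + which(keep) - 1L, energies[keep],
    total_fat_g = 70, saturated_fat_g = 20, protein_g = 80,
    cholesterol_mg = 250, fiber_g = 20, magnesium_mg = 300,
    calcium_mg = 900, potassium_mg = 2500, sodium_mg = 3000)
}
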