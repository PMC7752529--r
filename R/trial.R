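effect_row <- function(estimate, lower, upper, p, n,
                       covariates = character()) {
  tibble(estimate = estimate, lower = lower, upper = upper, p = p, n = n,
         covariates = paste(covariates, collapse = "+"))
}

#' Within-group change from baseline to follow-up
#'
#' Paired repeated-measures estimate of the mean change for one arm: the mean
#' of (follow-up - baseline) over participants with both measurements, with a
#' t-based confidence interval and p-value (with two timepoints the
#' repeated-measures ANOVA contrast reduces to the paired t statistic).
#' Participants missing either measurement are dropped (available-case).
#'
#' @param baseline,followup Numeric vectors, same participants in order.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `lower`, `upper`, `p`, `n`.
#' @export
within_group_change <- function(baseline, followup, conf_level = 0.95) {
  if (length(baseline) != length(followup)) {
    abort("baseline and followup must be the same length")
  }
  diffs <- followup - baseline
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2) abort("at least 2 paired observations are required")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    return(effect_row(m, m, m, p = if (m == 0) 1 else 0, n = n))
  }
  tt <- stats::t.test(diffs, conf.level = conf_level)
  effect_row(m, tt$conf.int[1], tt$conf.int[2], tt$p.value, n)
}

#' Baseline-adjusted between-group difference
#'
#' ANCOVA-style linear regression of the 3-month outcome on treatment arm
#' with the baseline value as a covariate. The reported effect is the
#' coefficient on the intervention indicator (intervention minus comparator),
#' with t-based Wald confidence limits on residual degrees of freedom.
#' Rows with missing outcome or covariate are dropped (available-case under
#' a missing-at-random assumption).
#'
#' @param outcome Follow-up measurements.
#' @param arm Character/factor, `"comparator"` / `"intervention"`.
#' @param baseline Baseline values of the same measure (optional: `NULL`
#'   gives the unadjusted arm-mean difference).
#' @param conf_level Confidence level.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `p`, `n`,
#'   `covariates`.
#' @export
adjusted_group_difference <- function(outcome, arm, baseline = NULL,
                                      conf_level = 0.95) {
  arm <- factor(as.character(arm), levels = c("comparator", "intervention"))
  if (any(is.na(levels(arm))) || length(stats::na.omit(unique(arm))) < 2) {
    abort("design error: both arms must be represented")
  }
  df <- data.frame(outcome = outcome, arm = arm)
  covs <- character()
  if (!is.null(baseline)) {
    df$baseline <- baseline
    covs <- "baseline"
  }
  df <- stats::na.omit(df)
  if (length(unique(df$arm)) < 2) {
    abort("design error: both arms must be represented among complete cases")
  }
  fml <- if (is.null(baseline)) outcome ~ arm else outcome ~ arm + baseline
  fit <- stats::lm(fml, data = df)
  co <- summary(fit)$coefficients
  ci <- stats::confint(fit, "armintervention", level = conf_level)
  effect_row(co["armintervention", "Estimate"], ci[1], ci[2],
             co["armintervention", "Pr(>|t|)"], nrow(df), covs)
}

#' Association between DASH-score change and blood-pressure change
#'
#' Least-squares slope of blood-pressure change on DASH-score change and the
#' Pearson correlation, overall and (when `arm` is supplied) within each arm.
#' With improvement coded as a positive DASH change and BP decrease as a
#' negative BP change, a beneficial association gives a negative slope and
#' `r`; `decrease_per_unit` reports the mmHg decrease per one-unit DASH
#' improvement as a positive magnitude (the negated slope).
#'
#' @param delta_dash Change in DASH total (follow-up minus baseline).
#' @param delta_bp Change in blood pressure, mmHg.
#' @param arm Optional arm labels for per-arm fits.
#' @param conf_level Confidence level.
#' @return Tibble, one row per scope (`"overall"` and each arm): `slope`,
#'   `lower`, `upper`, `decrease_per_unit`, `r`, `p`, `n`.
#' @export
#' @examples
#' dd <- c(-1, 0, 1, 2); dbp <- -2.5 * dd
#' dash_bp_association(dd, dbp)  # slope -2.5, r -1
dash_bp_association <- function(delta_dash, delta_bp, arm = NULL,
                                conf_level = 0.95) {
  one_fit <- function(dd, db, scope) {
    keep <- !is.na(dd) & !is.na(db)
    dd <- dd[keep]; db <- db[keep]
    if (length(dd) < 3) abort("at least 3 complete pairs are required")
    if (stats::sd(dd) == 0) {
      abort("undefined slope: no variance in the DASH change")
    }
    fit <- stats::lm(db ~ dd)
    co <- summary(fit)$coefficients
    slope <- co["dd", "Estimate"]
    if (stats::sd(db) == 0) {
      return(tibble(scope = scope, slope = slope, lower = slope,
                    upper = slope, decrease_per_unit = -slope, r = 0,
                    p = 1, n = length(dd)))
    }
    ci <- stats::confint(fit, "dd", level = conf_level)
    r <- stats::cor(dd, db)
    tibble(scope = scope, slope = slope, lower = ci[1], upper = ci[2],
           decrease_per_unit = -slope, r = r, p = co["dd", "Pr(>|t|)"],
           n = length(dd))
  }
  out <- one_fit(delta_dash, delta_bp, "overall")
  if (!is.null(arm)) {
    for (a in sort(unique(as.character(arm)))) {
      sel <- arm == a
      out <- dplyr::bind_rows(out,
                              one_fit(delta_dash[sel], delta_bp[sel], a))
    }
  }
  out
}

#' Per-protocol and sensitivity fits side by side
#'
#' Re-runs an analysis twice: once on protocol-valid records only and once
#' including the records flagged invalid, mirroring a sensitivity analysis
#' that restores excluded measurements.
#'
#' @param outcomes Tibble of participant outcomes.
#' @param valid_flag Name of the logical column marking protocol-valid rows.
#' @param fit_fun Function taking the (filtered) outcomes tibble and
#'   returning an effect tibble.
#' @return List with elements `per_protocol` and `sensitivity`; a fit that
#'   cannot be estimated (e.g. every follow-up excluded) is returned as the
#'   error condition rather than aborting the other fit.
#' @export
sensitivity_with_invalid <- function(outcomes, valid_flag, fit_fun) {
  flag <- outcomes[[valid_flag]]
  if (is.null(flag)) abort(paste0("no such validity flag: ", valid_flag))
  try_fit <- function(data) tryCatch(fit_fun(data), error = function(e) e)
  list(per_protocol = try_fit(outcomes[flag %in% TRUE, ]),
       sensitivity = try_fit(outcomes))
}

#' Full trial analysis of an outcomes table
#'
#' Runs, per measure (DASH total, systolic BP, diastolic BP): within-group
#' changes per arm, and the baseline-adjusted between-group difference; plus
#' the DASH-change vs BP-change association (overall and per arm). DASH
#' measures respect the recall-validity flags when present
#' (`baseline_dash_valid`, `month3_dash_valid`); BP carries no validity
#' filtering.
#'
#' @param outcomes Tibble with `participant_id`, `arm`, `baseline_dash`,
#'   `month3_dash`, `baseline_sbp`, `month3_sbp`, `baseline_dbp`,
#'   `month3_dbp`, optionally validity flag columns.
#' @param per_protocol Use validity flags to blank invalid DASH measures
#'   (default `TRUE`); `FALSE` reproduces the sensitivity analysis.
#' @return Nested list of effect tibbles.
#' @export
analyze_trial <- function(outcomes, per_protocol = TRUE) {
  oc <- outcomes
  if (per_protocol) {
    for (tp in c("baseline", "month3")) {
      fl <- paste0(tp, "_dash_valid")
      if (fl %in% names(oc)) {
        col <- paste0(tp, "_dash")
        oc[[col]][!(oc[[fl]] %in% TRUE)] <- NA_real_
      }
    }
  }
  measures <- c(dash = "dash", sbp = "sbp", dbp = "dbp")
  res <- lapply(measures, function(m) {
    b <- oc[[paste0("baseline_", m)]]
    f <- oc[[paste0("month3_", m)]]
    within <- lapply(c(intervention = "intervention",
                       comparator = "comparator"), function(a) {
      sel <- oc$arm == a
      within_group_change(b[sel], f[sel])
    })
    list(within = within,
         adjusted = adjusted_group_difference(f, oc$arm, b))
  })
  dd <- oc$month3_dash - oc$baseline_dash
  res$association <- list(
    sbp = dash_bp_association(dd, oc$month3_sbp - oc$baseline_sbp, oc$arm),
    dbp = dash_bp_association(dd, oc$month3_dbp - oc$baseline_dbp, oc$arm))
  res
}
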