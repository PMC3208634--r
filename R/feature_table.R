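#' The 45-variable analysis design
#'
#' Data dictionary for the analysis matrix: 6 continuous variables (age, BMI,
#' years since menopause, pregnancies, months of breast feeding, daily
#' calcium intake), derived bins (age at 68 years, BMI at 21 and 30 kg/m2,
#' YSM at 18 years, calcium at 300 mg/day) and 15 yes/no risk-factor pairs in
#' complement coding (each pair sums to one, so selecting either member
#' carries the full information). Binary BMI is a three-level one-hot
#' (<=21, between, >=30). Boundary convention: the upper bin owns its printed
#' boundary (age 68 is ">=68", YSM 18 is ">=18", BMI 30 is ">=30").
#'
#' @return Data frame with columns `name`, `kind` (`"continuous"`/`"binary"`),
#'   `source` (raw record field), and `complement_of` (partner column for
#'   yes/no pairs, `NA` otherwise).
#' @export
variable_spec <- function() {
  cont <- data.frame(
    name = c("age", "bmi", "ysm", "pregnancies", "bf_months", "calcium_mgday"),
    kind = "continuous",
    source = c("age", "bmi", "ysm", "pregnancies", "bf_months", "calcium_mgday"),
    complement_of = NA_character_
  )
  derived <- data.frame(
    name = c("age_lt68", "age_ge68", "bmi_le21", "bmi_21_30", "bmi_ge30",
             "ysm_lt18", "ysm_ge18", "calcium_le300_yes", "calcium_le300_no"),
    kind = "binary",
    source = c("age", "age", "bmi", "bmi", "bmi", "ysm", "ysm",
               "calcium_mgday", "calcium_mgday"),
    complement_of = c("age_ge68", "age_lt68", NA, NA, NA,
                      "ysm_ge18", "ysm_lt18", "calcium_le300_no",
                      "calcium_le300_yes")
  )
  pair_vars <- c("current_smoker", "ex_smoker", "alcohol_ge3", "low_bmd",
                 "prev_fracture", "fam_hip_fracture", "fam_osteoporosis",
                 "hypertension", "dyslipidemia", "gastric_disease",
                 "anxiety_depression", "copd", "osteoarthritis",
                 "kidney_stones", "t2d")
  pairs <- do.call(rbind, lapply(pair_vars, function(v) {
    data.frame(
      name = paste0(v, c("_yes", "_no")),
      kind = "binary",
      source = v,
      complement_of = paste0(v, c("_no", "_yes"))
    )
  }))
  rbind(cont, derived, pairs)
}

#' Encode raw clinical records into the 45-column analysis matrix
#'
#' Builds every column of [variable_spec()] from raw per-patient values:
#' continuous columns pass through, derived bins apply the documented
#' cutpoints, and each yes/no risk factor becomes a complement-coded pair.
#'
#' @param records Data frame of raw values; must carry every `source` field
#'   of [variable_spec()] (as produced by [generate_cohort()]), plus
#'   optionally `patient_id`.
#' @return Data frame of class `cohort_table`: `patient_id` plus the 45
#'   design columns, with the dictionary attached as attribute `"spec"`.
#' @export
encode_features <- function(records) {
  spec <- variable_spec()
  missing_src <- setdiff(unique(spec$source), names(records))
  if (length(missing_src)) {
    stop("schema error: raw records lack source field(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  out <- data.frame(
    patient_id = records$patient_id %||% sprintf("P%04d", seq_len(n))
  )
  for (v in c("age", "bmi", "ysm", "pregnancies", "bf_months", "calcium_mgday")) {
    out[[v]] <- records[[v]]
  }
  out$age_lt68 <- as.integer(records$age < 68)
  out$age_ge68 <- as.integer(records$age >= 68)
  out$bmi_le21 <- as.integer(records$bmi <= 21)
  out$bmi_ge30 <- as.integer(records$bmi >= 30)
  out$bmi_21_30 <- as.integer(records$bmi > 21 & records$bmi < 30)
  out$ysm_lt18 <- as.integer(records$ysm < 18)
  out$ysm_ge18 <- as.integer(records$ysm >= 18)
  out$calcium_le300_yes <- as.integer(records$calcium_mgday <= 300)
  out$calcium_le300_no <- as.integer(records$calcium_mgday > 300)
  raw_pairs <- unique(spec$source[spec$name == paste0(spec$source, "_yes")])
  for (v in raw_pairs) {
    x <- records[[v]]
    if (!all(x %in% c(0, 1, NA))) {
      stop("schema error: raw field '", v, "' must be 0/1", call. = FALSE)
    }
    out[[paste0(v, "_yes")]] <- as.integer(x)
    out[[paste0(v, "_no")]] <- as.integer(1 - x)
  }
  out <- out[, c("patient_id", spec$name)]
  attr(out, "spec") <- spec
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Complete-case filter
#'
#' Drops every record with one or more missing values among the analysis
#' columns and logs which fields were missing for whom. The study design
#' uses no imputation: models that cannot consume missing values dictate a
#' complete-case cohort.
#'
#' @param records Data frame (raw or encoded); `patient_id` is used for the
#'   log when present.
#' @param columns Columns to check (default: all except `patient_id`).
#' @return List with `kept` (the complete-case rows) and `log` (data frame of
#'   `patient_id`, `missing_fields`). Warns when nothing survives.
#' @export
exclude_incomplete <- function(records, columns = setdiff(names(records), "patient_id")) {
  stopifnot(is.data.frame(records))
  sub <- records[, columns, drop = FALSE]
  bad <- !stats::complete.cases(sub)
  ids <- records$patient_id %||% as.character(seq_len(nrow(records)))
  log <- data.frame(
    patient_id = ids[bad],
    missing_fields = vapply(which(bad), function(i) {
      paste(columns[is.na(sub[i, ])], collapse = ";")
    }, character(1))
  )
  kept <- records[!bad, , drop = FALSE]
  if (nrow(kept) == 0L && nrow(records) > 0L) {
    warning("no complete-case records remain after exclusion")
  }
  list(kept = kept, log = log)
}

#' Alcohol consumption in standard units
#'
#' Converts grams of pure alcohol per day into standard units of 8 g each.
#' The analysis dichotomises at 3 or more units/day (elevated fracture
#' risk); intakes above 100 g/day flag the record for exclusion as a
#' possible secondary osteoporosis.
#'
#' @param grams_per_day Non-negative grams of pure alcohol per day.
#' @return Data frame with `units_per_day`, `heavy_flag` (>= 3 units/day),
#'   `exclusion_flag` (> 100 g/day).
#' @export
alcohol_units <- function(grams_per_day) {
  if (any(!is.finite(grams_per_day)) || any(grams_per_day < 0)) {
    stop("alcohol intake must be non-negative grams per day", call. = FALSE)
  }
  units <- grams_per_day / 8
  data.frame(units_per_day = units,
             heavy_flag = units >= 3,
             exclusion_flag = grams_per_day > 100)
}

#' Daily calcium intake from weekly servings
#'
#' Each standardised dairy serving carries approximately 300 mg of calcium;
#' the 7-day food-frequency count converts to mg/day as
#' `servings * 300 / 7`.
#'
#' @param weekly_servings Non-negative serving count over 7 days.
#' @return mg of calcium per day.
#' @export
calcium_intake <- function(weekly_servings) {
  if (any(!is.finite(weekly_servings)) || any(weekly_servings < 0)) {
    stop("weekly servings must be non-negative", call. = FALSE)
  }
  weekly_servings * 300 / 7
}

#' Min-max scale the design matrix for network input
#'
#' Scales each continuous column to \[0, 1\] using extremes taken from the
#' training subset only; values outside the training range (test rows) are
#' clipped. Binary columns pass through. A constant training column scales
#' to 0 with a warning.
#'
#' @param table A `cohort_table` (or data frame with a `"spec"` attribute).
#' @param fit_on Integer/logical index of training rows.
#' @return List with `table` (scaled) and `scaler` (per-column min/max).
#' @export
scale_inputs <- function(table, fit_on) {
  spec <- attr(table, "spec")
  if (is.null(spec)) stop("`table` must carry a variable spec attribute", call. = FALSE)
  if (length(fit_on) == 0L || (is.logical(fit_on) && !any(fit_on))) {
    stop("training subset is empty", call. = FALSE)
  }
  cont <- spec$name[spec$kind == "continuous"]
  scaler <- lapply(cont, function(v) {
    x <- table[[v]][fit_on]
    c(min = min(x), max = max(x))
  })
  names(scaler) <- cont
  for (v in cont) {
    rng <- scaler[[v]]
    if (rng["max"] - rng["min"] < .Machine$double.eps) {
      warning("column '", v, "' is constant on the training subset; scaled to 0")
      table[[v]] <- 0
    } else {
      table[[v]] <- pmin(pmax((table[[v]] - rng["min"]) / (rng["max"] - rng["min"]), 0), 1)
    }
  }
  list(table = table, scaler = scaler)
}
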