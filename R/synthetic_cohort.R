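#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published marginal distributions of a postmenopausal
#' osteoporosis out-patient cohort (n = 372): age mean 68.0 (SD 8.5) years,
#' calcium intake mean 636 (SD 404) mg/day, hypertension prevalence 0.296,
#' low BMD (T-score <= -2.5) 0.651, current smokers 0.153, and so on. Years
#' since menopause is derived as age minus an age at menopause drawn from a
#' truncated normal (mean 50, SD 4, range 35-60), preserving the strong
#' age-YSM correlation. Per-patient fracture risk follows a logistic
#' liability on seven covariates whose default log odds ratios are the
#' published multivariable estimates for the SDI >= 1 endpoint: OR 1.07 per
#' year since menopause, 1.28 previous fragility fracture, 1.54 arterial
#' hypertension, 2.63 COPD, 1.00 per mg/day calcium, 1.06 low BMD, 2.21
#' absence of dyslipidemia.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Master integer seed; all stage randomness is derived from it.
#' @param continuous Named list of distribution specs
#'   (`list(mean=, sd=, min=, max=, family=)`) for `age`, `age_menopause`,
#'   `bmi`, `calcium_mgday`, `pregnancies`, `bf_months`. Families:
#'   `"truncnorm"`, `"pois"` (truncated), `"gamma"` (truncated).
#' @param prevalence Named numeric vector of yes/no variable prevalences
#'   in \[0, 1\].
#' @param liability List with `intercept` (log-odds; `-Inf` allowed for a
#'   zero baseline) and named `coefficients` (log-odds per covariate) over
#'   `ysm`, `prev_fracture`, `hypertension`, `copd`, `calcium_mgday`,
#'   `low_bmd`, `no_dyslipidemia`.
#' @param grade_severity Probabilities of semiquantitative grades 1-3 given a
#'   fracture event (sums to 1).
#' @param severity List controlling how many vertebrae fracture in a case:
#'   `log_mu0` + `scale` x covariate liability set the mean of an
#'   overdispersed (negative binomial, `size`) count of additional fractured
#'   vertebrae beyond the first, capped at 12.
#' @param missing_rate Scalar or named per-variable rate in \[0, 1\] of
#'   values blanked to `NA` in the raw records (default 0), so the
#'   complete-case filter is exercisable.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 372L,
                          seed = 20111104L,
                          continuous = NULL,
                          prevalence = NULL,
                          liability = NULL,
                          grade_severity = c(0.6, 0.3, 0.1),
                          severity = list(log_mu0 = 0.1, size = 0.6, scale = 0.15),
                          missing_rate = 0) {
  default_continuous <- list(
    age           = list(mean = 68.0, sd = 8.5,  min = 40, max = 95,  family = "truncnorm"),
    age_menopause = list(mean = 50.0, sd = 4.0,  min = 35, max = 60,  family = "truncnorm"),
    bmi           = list(mean = 23.5, sd = 3.5,  min = 16, max = 41,  family = "truncnorm"),
    calcium_mgday = list(mean = 636,  sd = 404,  min = 0,  max = 3000, family = "truncnorm"),
    pregnancies   = list(mean = 2,    sd = NA,   min = 0,  max = 5,   family = "pois"),
    bf_months     = list(mean = 6,    sd = NA,   min = 0,  max = 72,  family = "gamma")
  )
  default_prevalence <- c(
    current_smoker = 0.153, ex_smoker = 0.102, alcohol_ge3 = 0.333,
    prev_fracture = 0.089, fam_hip_fracture = 0.172, fam_osteoporosis = 0.25,
    kidney_stones = 0.046, hypertension = 0.296, dyslipidemia = 0.148,
    gastric_disease = 0.226, anxiety_depression = 0.134, copd = 0.038,
    osteoarthritis = 0.215, t2d = 0.038, low_bmd = 0.651
  )
  default_liability <- list(
    intercept = -2.2492,
    coefficients = c(
      ysm = log(1.07), prev_fracture = log(1.28), hypertension = log(1.54),
      copd = log(2.63), calcium_mgday = 0, low_bmd = log(1.06),
      no_dyslipidemia = log(2.21)
    )
  )
  continuous <- utils::modifyList(default_continuous, continuous %||% list())
  if (!is.null(prevalence)) default_prevalence[names(prevalence)] <- prevalence
  prevalence <- default_prevalence
  liability <- utils::modifyList(default_liability, liability %||% list())

  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("configuration error in `n_patients`: must be a count >= 1", call. = FALSE)
  }
  for (v in names(continuous)) {
    spec <- continuous[[v]]
    if (identical(spec$family, "truncnorm") && (!is.finite(spec$sd) || spec$sd <= 0)) {
      stop("configuration error in `continuous$", v, "`: sd must be > 0", call. = FALSE)
    }
    if (spec$min >= spec$max) {
      stop("configuration error in `continuous$", v, "`: min must be < max", call. = FALSE)
    }
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    bad <- names(prevalence)[prevalence < 0 | prevalence > 1]
    stop("configuration error in `prevalence$", bad[1], "`: must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(grade_severity) - 1) > 1e-8 || any(grade_severity < 0)) {
    stop("configuration error in `grade_severity`: probabilities over grades ",
         "1-3 must be non-negative and sum to 1", call. = FALSE)
  }

  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    continuous = continuous, prevalence = prevalence, liability = liability,
    grade_severity = grade_severity, severity = severity,
    missing_rate = missing_rate
  ), class = "cohort_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

draw_continuous <- function(spec, n) {
  switch(spec$family,
    truncnorm = rtruncnorm(n, spec$mean, spec$sd, spec$min, spec$max),
    pois = {
      x <- stats::rpois(n, spec$mean)
      pmin(pmax(x, spec$min), spec$max)
    },
    gamma = {
      x <- stats::rgamma(n, shape = 0.6, scale = spec$mean / 0.6)
      pmin(pmax(round(x), spec$min), spec$max)
    },
    stop("configuration error in distribution family '", spec$family, "'",
         call. = FALSE)
  )
}

# Covariate part of the fracture liability (no intercept), in the order of
# the seven-covariate multivariable model.
liability_eta <- function(records, coefficients) {
  X <- cbind(
    ysm = records$ysm,
    prev_fracture = records$prev_fracture,
    hypertension = records$hypertension,
    copd = records$copd,
    calcium_mgday = records$calcium_mgday,
    low_bmd = records$low_bmd,
    no_dyslipidemia = 1 - records$dyslipidemia
  )
  drop(X %*% coefficients[colnames(X)])
}

#' Generate a seeded synthetic cohort
#'
#' Draws raw clinical records from the configured marginal distributions,
#' then vertebral fracture grades from a two-stage liability model. A
#' patient's case status (any fracture, i.e. SDI >= 1) is Bernoulli with
#' logit equal to the configured intercept plus the seven-covariate
#' liability, so that refitting the same logistic model on a large generated
#' cohort recovers the configured odds ratios. Within cases, fractures are
#' placed on the 13 vertebrae T4-L4: one index fracture plus an
#' overdispersed, liability-linked count of additional fractured vertebrae,
#' each assigned a semiquantitative grade 1-3 from the configured severity
#' distribution. The SDI is the sum of the 13 grades.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `records` (raw
#'   clinical data frame), `sq_grades` (n x 13 integer matrix), `sdi`
#'   (integer vector), and `truth` (the generating parameters).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config object", call. = FALSE)
  }
  n <- config$n_patients

  records <- with_seed(substream_seed(config$seed, "continuous"), {
    age <- draw_continuous(config$continuous$age, n)
    aam <- draw_continuous(config$continuous$age_menopause, n)
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age,
      age_menopause = aam,
      ysm = pmax(age - aam, 1),
      bmi = draw_continuous(config$continuous$bmi, n),
      calcium_mgday = draw_continuous(config$continuous$calcium_mgday, n),
      pregnancies = draw_continuous(config$continuous$pregnancies, n),
      bf_months = draw_continuous(config$continuous$bf_months, n)
    )
  })
  binaries <- with_seed(substream_seed(config$seed, "binary"), {
    as.data.frame(lapply(config$prevalence, function(p) stats::rbinom(n, 1L, p)))
  })
  records <- cbind(records, binaries)

  eta_cov <- liability_eta(records, config$liability$coefficients)
  p_case <- stats::plogis(config$liability$intercept + eta_cov)
  case <- with_seed(substream_seed(config$seed, "case"),
                    stats::rbinom(n, 1L, p_case))

  grades <- matrix(0L, nrow = n, ncol = 13L,
                   dimnames = list(records$patient_id, SDI_VERTEBRAE))
  idx <- which(case == 1L)
  if (length(idx)) {
    sev <- config$severity
    extra <- with_seed(substream_seed(config$seed, "severity"), {
      mu <- exp(sev$log_mu0 + sev$scale * eta_cov[idx])
      pmin(stats::rnbinom(length(idx), size = sev$size, mu = mu), 12L)
    })
    grades[idx, ] <- with_seed(substream_seed(config$seed, "grades"), {
      t(vapply(seq_along(idx), function(j) {
        k <- 1L + extra[j]
        g <- integer(13L)
        at <- sample.int(13L, k)
        g[at] <- sample(1:3, k, replace = TRUE, prob = config$grade_severity)
        g
      }, integer(13L)))
    })
  }
  sdi <- as.integer(rowSums(grades))

  if (any(config$missing_rate > 0)) {
    rate <- config$missing_rate
    vars <- setdiff(names(records), "patient_id")
    if (is.null(names(rate))) rate <- stats::setNames(rep(rate, length(vars)), vars)
    records <- with_seed(substream_seed(config$seed, "missing"), {
      for (v in intersect(names(rate), vars)) {
        hit <- stats::runif(n) < rate[[v]]
        records[[v]][hit] <- NA
      }
      records
    })
  }

  structure(list(
    records = records, sq_grades = grades, sdi = sdi,
    truth = list(liability = config$liability, config = config)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$records), "patients\n")
  cat("  SDI >= 1:", sum(x$sdi >= 1), "  SDI >= 5:", sum(x$sdi >= 5), "\n")
  invisible(x)
}

#' Simulate vertebral heights consistent with a set of grades
#'
#' Inverse of the grading step: for each vertebra a posterior height is drawn
#' around a nominal cranio-caudal gradient (20 mm at T4 to 34 mm at L4,
#' +/- 3\%), and the anterior height is compressed to a target strictly
#' inside the requested grade's band (grade 0 < 15\%, grade 1 in
#' 20.5-24.5\%, grade 2 in 25.5-39.5\%, grade 3 in 40.5-60\%), with the
#' middle height at 60\% of the anterior compression. Regrading the result
#' with [grade_vertebrae()] returns the input grades.
#'
#' @param grades Integer vector of 13 grades in 0:3 (T4..L4 order).
#' @param seed Integer seed.
#' @return Data frame with columns `vertebra`, `h_a`, `h_m`, `h_p` (mm).
#' @export
generate_vertebral_heights <- function(grades, seed = 1L) {
  grades <- as.integer(grades)
  if (length(grades) != 13L || anyNA(grades) || any(!grades %in% 0:3)) {
    stop("`grades` must be 13 semiquantitative grades in {0,1,2,3}",
         call. = FALSE)
  }
  with_seed(seed, {
    nominal <- seq(20, 34, length.out = 13L)
    h_p <- nominal * stats::runif(13L, 0.97, 1.03)
    lo <- c(0.02, 0.205, 0.255, 0.405)[grades + 1L]
    hi <- c(0.15, 0.245, 0.395, 0.600)[grades + 1L]
    comp <- stats::runif(13L, lo, hi)
    data.frame(
      vertebra = SDI_VERTEBRAE,
      h_a = h_p * (1 - comp),
      h_m = h_p * (1 - 0.6 * comp),
      h_p = h_p
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the raw records as CSV (missing values as empty cells) and the
#' generating parameters as a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param csv_path Output CSV path.
#' @param truth_path Optional JSON sidecar path (default: `csv_path` with
#'   `.truth.json` extension).
#' @return Invisibly, the CSV path.
#' @export
write_cohort <- function(cohort, csv_path,
                         truth_path = sub("\\.csv$", ".truth.json", csv_path)) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  out <- cohort$records
  out$sdi <- cohort$sdi
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  truth <- cohort$truth
  truth$config$continuous <- NULL  # nested closures-free, keep scalar params
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(csv_path)
}
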