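test_that("cohort generation is bit-for-bit reproducible for a fixed seed", {
  cfg <- cohort_config(n_patients = 372, seed = 20111104)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a$records), 372L)
  # a different seed changes the draw
  c2 <- generate_cohort(cohort_config(n_patients = 372, seed = 1))
  expect_false(identical(a$records, c2$records))
})

test_that("SDI equals the grade sum and values respect the configured ranges", {
  co <- generate_cohort(cohort_config(n_patients = 800, seed = 3))
  expect_identical(co$sdi, as.integer(rowSums(co$sq_grades)))
  expect_true(all(co$sq_grades %in% 0:3))
  r <- co$records
  expect_true(all(r$age >= 40 & r$age <= 95))
  expect_true(all(r$bmi >= 16 & r$bmi <= 41))
  expect_true(all(r$calcium_mgday >= 0 & r$calcium_mgday <= 3000))
  expect_true(all(r$ysm >= 1))
  expect_true(all(r$pregnancies %in% 0:5))
})

test_that("marginals match the configured prevalences at large n", {
  co <- generate_cohort(cohort_config(n_patients = 10000, seed = 8))
  r <- co$records
  # binomial 3-SE bands around the configured prevalences
  check <- function(col, p) {
    se <- sqrt(p * (1 - p) / nrow(r))
    expect_lt(abs(mean(r[[col]]) - p), 3 * se)
  }
  check("hypertension", 0.296)
  check("low_bmd", 0.651)
  check("current_smoker", 0.153)
  expect_lt(abs(mean(r$age) - 68.0), 3 * 8.5 / sqrt(nrow(r)) + 0.2)
})

test_that("a zero liability produces a fracture-free cohort", {
  cfg <- cohort_config(
    n_patients = 200, seed = 5,
    liability = list(intercept = -Inf,
                     coefficients = c(ysm = 0, prev_fracture = 0,
                                      hypertension = 0, copd = 0,
                                      calcium_mgday = 0, low_bmd = 0,
                                      no_dyslipidemia = 0)))
  co <- generate_cohort(cfg)
  expect_true(all(co$sdi == 0L))
})

test_that("raising a positive-coefficient covariate never lowers the expected SDI", {
  n <- 20000
  base <- generate_cohort(cohort_config(n_patients = n, seed = 77))
  shifted_cfg <- cohort_config(
    n_patients = n, seed = 77,
    continuous = list(age = list(mean = 73.0, sd = 8.5, min = 40, max = 95,
                                 family = "truncnorm")))
  shifted <- generate_cohort(shifted_cfg)  # +5 y of age -> +5 y of YSM
  expect_gt(mean(shifted$sdi), mean(base$sdi) - 1e-9)

  hyper <- generate_cohort(cohort_config(n_patients = n, seed = 77,
                                         prevalence = c(hypertension = 1)))
  none <- generate_cohort(cohort_config(n_patients = n, seed = 77,
                                        prevalence = c(hypertension = 0)))
  expect_gt(mean(hyper$sdi), mean(none$sdi))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(prevalence = c(hypertension = 1.4)), "hypertension")
  expect_error(cohort_config(continuous = list(
    age = list(mean = 68, sd = -1, min = 40, max = 95, family = "truncnorm"))),
    "sd")
  expect_error(cohort_config(grade_severity = c(0.9, 0.3, 0.1)), "grade_severity")
})

test_that("missingness injection blanks roughly the configured fraction", {
  co <- generate_cohort(cohort_config(n_patients = 2000, seed = 9,
                                      missing_rate = 0.05))
  rate <- mean(is.na(co$records$age))
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  # and the default injects nothing
  co0 <- generate_cohort(cohort_config(n_patients = 100, seed = 9))
  expect_false(anyNA(co0$records))
})
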