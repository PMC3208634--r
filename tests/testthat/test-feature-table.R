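test_that("the design dictionary has 45 columns with consistent complement pairs", {
  spec <- variable_spec()
  expect_identical(nrow(spec), 45L)
  expect_identical(sum(spec$kind == "continuous"), 6L)
  # every declared complement points back at its partner
  with_partner <- spec[!is.na(spec$complement_of), ]
  back <- spec$complement_of[match(with_partner$complement_of, spec$name)]
  expect_identical(back, with_partner$name)
})

test_that("encoding applies the documented cutpoints at their boundaries", {
  raw <- data.frame(
    patient_id = c("A", "B", "C"),
    age = c(68, 67.9, 80), bmi = c(21, 25, 30), ysm = c(18, 17.5, 30),
    pregnancies = c(2, 0, 4), bf_months = c(3, 0, 12),
    calcium_mgday = c(300, 301, 100),
    current_smoker = c(0, 1, 0), ex_smoker = c(0, 0, 1),
    alcohol_ge3 = c(0, 1, 0), low_bmd = c(1, 0, 1),
    prev_fracture = c(0, 0, 1), fam_hip_fracture = c(0, 1, 0),
    fam_osteoporosis = c(1, 0, 0), hypertension = c(1, 0, 0),
    dyslipidemia = c(0, 1, 0), gastric_disease = c(0, 0, 1),
    anxiety_depression = c(1, 0, 0), copd = c(0, 0, 1),
    osteoarthritis = c(0, 1, 0), kidney_stones = c(0, 0, 0),
    t2d = c(0, 0, 1))
  enc <- encode_features(raw)
  expect_identical(ncol(enc) - 1L, 45L)  # patient_id + 45 design columns

  # age 68 belongs to the upper bin
  expect_identical(enc$age_lt68, c(0L, 1L, 0L))
  expect_identical(enc$age_ge68, c(1L, 0L, 1L))
  # BMI 21 -> low bin, 30 -> upper bin
  expect_identical(enc$bmi_le21, c(1L, 0L, 0L))
  expect_identical(enc$bmi_21_30, c(0L, 1L, 0L))
  expect_identical(enc$bmi_ge30, c(0L, 0L, 1L))
  # YSM 18 -> upper bin
  expect_identical(enc$ysm_ge18, c(1L, 0L, 1L))
  # calcium 300 counts as <= 300
  expect_identical(enc$calcium_le300_yes, c(1L, 0L, 1L))

  # every yes/no pair sums to one for every record; BMI one-hot sums to one
  spec <- attr(enc, "spec")
  pairs <- spec[!is.na(spec$complement_of) & spec$name < spec$complement_of, ]
  for (i in seq_len(nrow(pairs))) {
    expect_true(all(enc[[pairs$name[i]]] + enc[[pairs$complement_of[i]]] == 1L))
  }
  expect_true(all(enc$bmi_le21 + enc$bmi_21_30 + enc$bmi_ge30 == 1L))

  # encoding already-encoded raw fields is idempotent
  expect_identical(encode_features(raw), encode_features(raw))
  expect_error(encode_features(raw[, -2]), "schema")
})

test_that("complete-case filtering keeps exactly the fully observed records", {
  co <- generate_cohort(cohort_config(n_patients = 430, seed = 21))
  rec <- co$records
  # blank one field in 58 chosen records -> 372 survivors
  drop_idx <- seq(4, by = 7, length.out = 58)
  rec$calcium_mgday[drop_idx[1:30]] <- NA
  rec$bmi[drop_idx[31:58]] <- NA
  res <- exclude_incomplete(rec)
  expect_identical(nrow(res$kept), 372L)
  expect_identical(nrow(res$log), 58L)
  expect_true(all(res$log$missing_fields %in% c("calcium_mgday", "bmi")))

  intact <- exclude_incomplete(co$records)
  expect_identical(intact$kept, co$records)
  expect_identical(nrow(intact$log), 0L)

  all_missing <- co$records
  all_missing$age <- NA
  expect_warning(res2 <- exclude_incomplete(all_missing), "no complete-case")
  expect_identical(nrow(res2$kept), 0L)
})

test_that("alcohol and calcium unit conversions follow the questionnaire rules", {
  a <- alcohol_units(c(24, 0, 104))
  expect_equal(a$units_per_day, c(3, 0, 13))
  expect_identical(a$heavy_flag, c(TRUE, FALSE, TRUE))
  expect_identical(a$exclusion_flag, c(FALSE, FALSE, TRUE))
  expect_error(alcohol_units(-1), "non-negative")

  expect_equal(calcium_intake(7), 300)
  expect_equal(calcium_intake(0), 0)
  expect_equal(calcium_intake(14.84), 636)
  expect_error(calcium_intake(-2), "non-negative")
})

test_that("min-max scaling uses training extremes only and clips test rows", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 31))
  tab <- encode_features(co$records)
  tab$age <- c(40, 90, rep(65, 38))          # training range 40-90 ...
  tab$age[3] <- 95                           # ... with a test row beyond it
  sc <- scale_inputs(tab, fit_on = c(1:2, 4:40))
  expect_equal(sc$table$age[1], 0)
  expect_equal(sc$table$age[2], 1)
  expect_equal(sc$table$age[3], 1)           # clipped
  expect_equal(sc$table$age[4], 0.5)
  # binaries untouched
  expect_identical(sc$table$hypertension_yes, tab$hypertension_yes)
  expect_error(scale_inputs(tab, fit_on = integer(0)), "empty")

  tab$bmi <- 25
  expect_warning(sc2 <- scale_inputs(tab, fit_on = seq_len(nrow(tab))), "constant")
  expect_true(all(sc2$table$bmi == 0))
})
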