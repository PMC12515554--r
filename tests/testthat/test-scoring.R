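test_that("per-variable scorers map the rubric's printed bins", {
  # rows: input -> expected subscore, per variable
  expect_identical(score_bun_trend(c(-10, 20, -15, -25, -26, -40, -50, -51, -60)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L))
  expect_identical(score_urine_sg(c(1.010, 1.025, 1.007, 1.005, 1.002, 1.000, 0.999)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(score_fluid_balance(c(10, -20, 15, 29, 30, 45, 50, 51)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L))
  expect_identical(score_weight_change(c(3, -5, 7, 10.9, 11, 12, 15, 15.1)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L))
  expect_identical(score_urine_output(c(2, 3, 3.1, 3.5, 3.6, 4, 4.1, 5), FALSE),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(score_liver(c(0.5, 0.99, 1, 1.9, 2, 3, 3.5)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L))
})

test_that("categorical scorers use ordinal severity positions", {
  expect_identical(score_fontanelle(c("flat", "full", "bulging", "bulging_tense")),
                   0:3)
  expect_identical(score_eyes(c("normal", "swollen", "puffy_conjunctival_edema",
                                "puffy_unable_to_open")), 0:3)
  expect_identical(score_skin(c("no_edema", "limbs_or_abdomen", "limbs_and_face",
                                "anasarca")), 0:3)
  expect_identical(score_cxr(c("none", "mild", "moderate", "severe")), 0:3)
  expect_error(score_eyes("bloodshot"), "unknown category")
  expect_error(score_fontanelle("sunken"), "unknown category")
})

test_that("unmeasurable and missing inputs pass through as missing", {
  expect_identical(score_fontanelle("closed"), NA_integer_)
  expect_identical(score_urine_output(2.0, TRUE), NA_integer_)
  expect_identical(score_bun_trend(NA_real_), NA_integer_)
  expect_identical(score_skin(NA_character_), NA_integer_)
})

test_that("validation errors name the offense", {
  expect_error(score_urine_sg(1.2), "outside \\[0.990, 1.060\\]")
  expect_error(score_urine_sg(0.5), "outside")
  expect_error(score_liver(-1), "negative")
  expect_error(score_urine_output(-0.1), "negative")
  expect_error(score_bun_trend(Inf), "non-finite")
  expect_error(score_fluid_balance(NaN), "non-finite")
})

test_that("oliguria scores zero with a warning", {
  expect_warning(s <- score_urine_output(0.5, FALSE), "oliguria")
  expect_identical(s, 0L)
  # but not when the variable is unmeasurable anyway
  expect_silent(score_urine_output(0.5, TRUE))
})

test_that("compute_fast handles the all-normal, all-severe and missing cases", {
  expect_equal(compute_fast(normal_encounter())$total, 0L)
  res <- compute_fast(severe_encounter())
  expect_equal(res$total, 30L)
  expect_true(res$valid)
  expect_equal(res$n_missing, 0L)

  obs <- normal_encounter()
  obs$bun_trend_pct <- NA
  obs$fontanelle <- NA
  obs$cxr_grade <- NA
  res3 <- compute_fast(obs)
  expect_equal(res3$n_missing, 3L)
  expect_equal(res3$total, 0L)
  expect_false(res3$valid)

  obs2 <- normal_encounter()
  obs2$fontanelle <- "closed"
  obs2$on_diuretics_or_renal_failure <- TRUE
  res2 <- compute_fast(obs2)
  expect_equal(res2$n_missing, 2L)
  expect_true(res2$valid)
})

test_that("compute_fast total equals the sum of independently computed subscores", {
  set.seed(11)
  for (i in 1:25) {
    obs <- data.frame(
      encounter_id = "x",
      bun_trend_pct = runif(1, -80, 40),
      urine_specific_gravity = runif(1, 0.995, 1.035),
      fluid_balance_ml_kg_day = runif(1, -30, 70),
      weight_change_pct = runif(1, -5, 20),
      urine_output_ml_kg_h = runif(1, 1, 6),
      on_diuretics_or_renal_failure = sample(c(TRUE, FALSE), 1),
      fontanelle = sample(c("flat", "full", "bulging", "bulging_tense", "closed"), 1),
      eyes = sample(c("normal", "swollen", "puffy_conjunctival_edema",
                      "puffy_unable_to_open"), 1),
      liver_cm_below_costal_margin = runif(1, 0, 5),
      skin = sample(c("no_edema", "limbs_or_abdomen", "limbs_and_face",
                      "anasarca"), 1),
      cxr_grade = sample(c("none", "mild", "moderate", "severe"), 1),
      stringsAsFactors = FALSE
    )
    res <- compute_fast(obs)
    manual <- sum(c(
      score_bun_trend(obs$bun_trend_pct),
      score_urine_sg(obs$urine_specific_gravity),
      score_fluid_balance(obs$fluid_balance_ml_kg_day),
      score_weight_change(obs$weight_change_pct),
      score_urine_output(obs$urine_output_ml_kg_h,
                         obs$on_diuretics_or_renal_failure),
      score_fontanelle(obs$fontanelle),
      score_eyes(obs$eyes),
      score_liver(obs$liver_cm_below_costal_margin),
      score_skin(obs$skin),
      score_cxr(obs$cxr_grade)
    ), na.rm = TRUE)
    expect_equal(res$total, manual)
    expect_true(res$total <= 3 * (10 - res$n_missing))
  }
})

test_that("column order of the input never changes the result", {
  obs <- severe_encounter()
  shuffled <- obs[, sample(ncol(obs))]
  expect_equal(compute_fast(obs)$total, compute_fast(shuffled)$total)
})

test_that("field errors propagate with the variable named", {
  obs <- normal_encounter()
  obs$urine_specific_gravity <- 2
  expect_error(compute_fast(obs), "urine_sg")
  obs2 <- normal_encounter()
  obs2$skin <- "wet"
  expect_error(compute_fast(obs2), "skin")
})
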