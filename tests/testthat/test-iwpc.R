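base_cov <- function(...) {
  utils::modifyList(tibble::tibble(
    patient_id = "p1", age_decades = 6, height_cm = 170, weight_kg = 80,
    vkorc1_class = "GG", cyp2c9_class = "*1/*1", race_class = "white",
    enzyme_inducer = "0", amiodarone = 0), tibble::tibble(...))
}

toy_coeffs <- function(rows) {
  dplyr::bind_rows(
    tibble::tibble(term = "intercept", level = ".", coefficient = 2.0),
    rows,
    tibble::tibble(
      term = c("height_cm", "weight_kg", "vkorc1_class", "cyp2c9_class",
               "race_class", "enzyme_inducer", "amiodarone"),
      level = c(".", ".", "AG", "*1/*2", "asian", "1", "1"),
      coefficient = 0))
}

test_that("intercept-only prediction squares the intercept", {
  co <- toy_coeffs(tibble::tibble(term = "age_decades", level = ".",
                                  coefficient = 0))
  cov <- base_cov(height_cm = 1, weight_kg = 1)
  expect_equal(unname(predict_iwpc(cov, co)), 4)  # 2.0^2
  # doubling the sqrt-scale intercept quadruples the dose
  co2 <- co; co2$coefficient[co2$term == "intercept"] <- 4.0
  expect_equal(unname(predict_iwpc(cov, co2)), 16)
})

test_that("toy age coefficient reproduces the hand computation", {
  # sqrt = 2.0 - 0.1 * 7 = 1.3 -> dose 1.69 mg/week
  co <- toy_coeffs(tibble::tibble(term = "age_decades", level = ".",
                                  coefficient = -0.1))
  cov <- base_cov(age_decades = 7, height_cm = 1, weight_kg = 1)
  expect_equal(unname(predict_iwpc(cov, co)), 1.69, tolerance = 1e-12)
})

test_that("shipped IWPC algorithm predicts plausible weekly doses", {
  co <- read_dose_coefficients()
  cov <- base_cov()
  d_ref <- unname(predict_iwpc(cov, co))
  expect_gt(d_ref, 20); expect_lt(d_ref, 70)
  # VKORC1 A/A and CYP2C9 *3/*3 each lower the dose
  expect_lt(unname(predict_iwpc(base_cov(vkorc1_class = "AA"), co)), d_ref)
  expect_lt(unname(predict_iwpc(base_cov(cyp2c9_class = "*3/*3"), co)), d_ref)
  # amiodarone lowers, enzyme inducers raise
  expect_lt(unname(predict_iwpc(base_cov(amiodarone = 1), co)), d_ref)
  expect_gt(unname(predict_iwpc(base_cov(enzyme_inducer = "1"), co)), d_ref)
})

test_that("unknown enzyme-inducer status is treated as 0 with a warning", {
  co <- read_dose_coefficients()
  expect_warning(d_unk <- predict_iwpc(base_cov(enzyme_inducer = "unknown"),
                                       co), "unknown")
  expect_equal(d_unk, predict_iwpc(base_cov(enzyme_inducer = "0"), co))
})

test_that("negative sqrt-dose predictions clamp to zero with a warning", {
  co <- toy_coeffs(tibble::tibble(term = "age_decades", level = ".",
                                  coefficient = -10))
  cov <- base_cov(age_decades = 5, height_cm = 1, weight_kg = 1)
  expect_warning(d <- predict_iwpc(cov, co), "clamped")
  expect_equal(unname(d), 0)
})

test_that("covariate validation rejects unknown classes", {
  expect_error(predict_iwpc(base_cov(vkorc1_class = "GT")), "vkorc1")
  expect_error(predict_iwpc(base_cov(race_class = "martian")), "race")
  expect_error(predict_iwpc(base_cov(weight_kg = -2)), "positive")
  expect_error(predict_iwpc(dplyr::select(base_cov(), -"height_cm")),
               "missing")
})

test_that("residual dose is the exact difference with aligned IDs", {
  expect_equal(residual_dose(35, 30), 5)
  expect_equal(residual_dose(c(a = 40, b = 30), c(a = 40, b = 30)),
               c(a = 0, b = 0))
  expect_error(residual_dose(c(a = 1, b = 2), c(b = 2, a = 1)), "misaligned")
  expect_error(residual_dose(1:3, 1:2), "equal length")
  set.seed(81)
  obs <- runif(50, 10, 80); pred <- runif(50, 10, 80)
  expect_equal(sum(residual_dose(obs, pred)), sum(obs) - sum(pred))
})

test_that("coefficient files round-trip and preserve predictions bit-exactly", {
  co <- read_dose_coefficients()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dose_coefficients(co, path)
  co2 <- read_dose_coefficients(path)
  cov <- simulate_covariates <- base_cov(age_decades = 8,
                                         vkorc1_class = "AG",
                                         cyp2c9_class = "*1/*3",
                                         race_class = "black_or_AA",
                                         amiodarone = 1)
  expect_identical(predict_iwpc(cov, co), predict_iwpc(cov, co2))
})

test_that("iwpc_dose_table keeps residual = observed - predicted exactly", {
  set.seed(82)
  sim <- simulate_reference_panel(tiny_config(seed = 82))
  ch <- simulate_cohort(tiny_config(seed = 82), sim$truth)
  tab <- iwpc_dose_table(ch$covariates, ch$doses$observed_dose)
  expect_equal(tab$residual, tab$observed_dose - tab$predicted_dose)
  expect_equal(tab$predicted_dose, ch$doses$predicted_dose)
})
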