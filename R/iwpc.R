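#' Load IWPC dose-algorithm coefficients
#'
#' The IWPC pharmacogenetic algorithm is a published linear model on the
#' square-root weekly-dose scale. Its coefficients are configuration data, not
#' code: they are read from a TSV of `(term, level, coefficient)` whose header
#' comments record provenance. The package ships the published algorithm as
#' its default file; toy files with the same schema work anywhere a
#' coefficient table is accepted.
#'
#' @param path Coefficient TSV; default is the shipped published algorithm.
#' @return A tibble with columns `term`, `level`, `coefficient`.
#' @export
read_dose_coefficients <- function(path = system.file("extdata",
                                                      "iwpc_coefficients.tsv",
                                                      package = "dosesig")) {
  co <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  req <- c("term", "level", "coefficient")
  if (!identical(names(co), req))
    stop("coefficient file must have columns term, level, coefficient")
  needed <- c("intercept", "age_decades", "height_cm", "weight_kg",
              "vkorc1_class", "cyp2c9_class", "race_class",
              "enzyme_inducer", "amiodarone")
  missing_terms <- setdiff(needed, co$term)
  if (length(missing_terms))
    stop("coefficient file missing terms: ",
         paste(missing_terms, collapse = ", "))
  co
}

#' Write a coefficient table back to TSV
#'
#' @param coefficients Tibble as returned by [read_dose_coefficients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_coefficients <- function(coefficients, path) {
  readr::write_tsv(coefficients, path)
  invisible(path)
}

iwpc_numeric_terms <- c("age_decades", "height_cm", "weight_kg")

#' Predict weekly warfarin dose with the IWPC algorithm
#'
#' Computes `sqrt(weekly dose) = intercept + sum(coefficient x term)` and
#' returns its square, in mg/week. Categorical covariates contribute the
#' coefficient of their level (reference levels — VKORC1 G/G, CYP2C9 *1/*1,
#' white race, no inducer, no amiodarone — contribute 0). Unknown
#' enzyme-inducer status is treated as 0 with a warning, matching an analysis
#' run without inducer information. Negative predicted sqrt-doses (unreachable
#' for sane coefficient files) are clamped to 0 with a warning.
#'
#' @param covariates Data frame with columns `age_decades`, `height_cm`,
#'   `weight_kg`, `vkorc1_class` (GG/AG/AA/unknown), `cyp2c9_class`
#'   (*1/*1 ... *3/*3/unknown), `race_class`
#'   (white/asian/black_or_AA/missing_or_mixed), `enzyme_inducer`
#'   (0/1/unknown), `amiodarone` (0/1); optionally `patient_id`.
#' @param coefficients Coefficient table from [read_dose_coefficients()].
#' @return Numeric vector of predicted weekly doses (mg/week), named by
#'   `patient_id` when present.
#' @examples
#' cov <- tibble::tibble(patient_id = "p1", age_decades = 6, height_cm = 168,
#'                       weight_kg = 75, vkorc1_class = "AG",
#'                       cyp2c9_class = "*1/*1", race_class = "white",
#'                       enzyme_inducer = "0", amiodarone = 0)
#' predict_iwpc(cov)
#' @export
predict_iwpc <- function(covariates, coefficients = read_dose_coefficients()) {
  cov <- validate_covariates(covariates)
  n <- nrow(cov)
  co <- function(term, level = ".") {
    hit <- coefficients$term == term & coefficients$level == level
    if (!any(hit)) 0 else coefficients$coefficient[which(hit)[1]]
  }
  s <- rep(co("intercept"), n)
  for (term in iwpc_numeric_terms) s <- s + co(term) * cov[[term]]
  for (term in c("vkorc1_class", "cyp2c9_class", "race_class")) {
    lv <- cov[[term]]
    s <- s + vapply(lv, function(l) co(term, l), numeric(1))
  }
  inducer <- as.character(cov$enzyme_inducer)
  if (any(inducer == "unknown")) {
    warning("enzyme_inducer 'unknown' treated as 0 (no inducer)")
    inducer[inducer == "unknown"] <- "0"
  }
  s <- s + ifelse(inducer == "1", co("enzyme_inducer", "1"), 0)
  s <- s + ifelse(as.character(cov$amiodarone) == "1", co("amiodarone", "1"), 0)
  if (any(s < 0)) {
    warning("negative predicted sqrt-dose clamped to 0")
    s <- pmax(s, 0)
  }
  dose <- s^2
  if ("patient_id" %in% names(cov)) names(dose) <- cov$patient_id
  dose
}

validate_covariates <- function(covariates) {
  cov <- tibble::as_tibble(covariates)
  need <- c(iwpc_numeric_terms, "vkorc1_class", "cyp2c9_class", "race_class",
            "enzyme_inducer", "amiodarone")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("covariate table missing: ", paste(miss, collapse = ", "))
  chk <- function(col, levels)
    if (!all(as.character(cov[[col]]) %in% levels))
      stop("invalid ", col, " value(s): ",
           paste(setdiff(unique(as.character(cov[[col]])), levels), collapse = ", "))
  chk("vkorc1_class", c("GG", "AG", "AA", "unknown"))
  chk("cyp2c9_class", c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3",
                        "unknown"))
  chk("race_class", c("white", "asian", "black_or_AA", "missing_or_mixed"))
  chk("enzyme_inducer", c("0", "1", "unknown"))
  chk("amiodarone", c("0", "1"))
  if (any(cov$height_cm <= 0) || any(cov$weight_kg <= 0) ||
      any(cov$age_decades <= 0))
    stop("physical covariates must be positive")
  cov
}

#' Residual dose: observed minus IWPC-predicted weekly dose
#'
#' The validation target of the signature analysis: the portion of the
#' therapeutic dose the IWPC algorithm leaves unexplained.
#'
#' @param observed,predicted Equal-length numeric vectors (mg/week). When both
#'   carry names they must agree element-wise (ID alignment check).
#' @return Numeric vector `observed - predicted`.
#' @export
residual_dose <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (!is.null(names(observed)) && !is.null(names(predicted)) &&
      !identical(names(observed), names(predicted)))
    stop("observed and predicted IDs are misaligned")
  observed - predicted
}

#' Build a dose table (observed, predicted, residual) for a cohort
#'
#' @param covariates Covariate table with `patient_id`.
#' @param observed_dose Observed weekly doses aligned with `covariates`.
#' @inheritParams predict_iwpc
#' @return A tibble with `patient_id`, `observed_dose`, `predicted_dose`,
#'   `residual`.
#' @export
iwpc_dose_table <- function(covariates, observed_dose,
                            coefficients = read_dose_coefficients()) {
  pred <- predict_iwpc(covariates, coefficients)
  tibble::tibble(
    patient_id = covariates$patient_id,
    observed_dose = unname(observed_dose),
    predicted_dose = unname(pred),
    residual = unname(observed_dose) - unname(pred)
  )
}
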