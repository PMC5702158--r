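#' Derive a stage-specific random seed from a master seed
#'
#' All randomness in the package flows from one master seed through this
#' splitting rule, so each pipeline stage (and each repeat within a stage)
#' is independently reproducible. The rule is
#' `(seed + 1000003 * stage_code + index) mod (2^31 - 1)`,
#' with stage codes: reference panel 1, cohort 2, missingness 3,
#' cross-validation folds 4, stability repeats 5, shuffled null 6,
#' random-signature null 7, platform subset 8.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (see Details) or an integer code.
#' @param index Repeat/cohort index within the stage (default 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0) {
  codes <- c(
    reference = 1, cohort = 2, missingness = 3, cv_folds = 4,
    stability = 5, null_shuffled = 6, null_random = 7, platform = 8
  )
  code <- if (is.character(stage)) {
    if (!stage %in% names(codes)) stop("unknown stage: ", stage)
    codes[[stage]]
  } else {
    as.integer(stage)
  }
  m <- 2147483647
  as.integer((as.numeric(seed) + 1000003 * code + as.numeric(index)) %% m)
}
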