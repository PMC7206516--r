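#' The modelled neuropsychological battery
#'
#' The package models 11 neuropsychological (NP) tests plus a three-state
#' cognitive status. The tests span five cognitive functions: verbal memory
#' (LMi, LMd, LMr: Logical Memory immediate/delayed recall and recognition),
#' visual memory (VRi, VRd, VRr: Visual Reproductions), new learning (PASi
#' and the hard-pair scores PASi_h, PASd_h of Paired Associate Learning),
#' abstract reasoning (SIM: Similarities) and language/naming (BNT30: 30-item
#' Boston Naming Test). Raw scores are non-negative integers except PASi,
#' which is scored in half points.
#'
#' @return `np_variables()` returns a data.frame with one row per variable:
#'   `name`, `kind` (`np_test`, `status` or `covariate`), `min`, `max`,
#'   `step` (raw-score granularity; `NA` for non-tests).
#' @export
np_variables <- function() {
  tests <- data.frame(
    name = c("LMi", "LMd", "LMr", "VRi", "VRd", "VRr",
             "PASi", "PASi_h", "PASd_h", "SIM", "BNT30"),
    kind = "np_test",
    min = 0,
    max = c(23, 24, 11, 14, 14, 4, 21, 12, 4, 26, 30),
    step = c(1, 1, 1, 1, 1, 1, 0.5, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  other <- data.frame(
    name = c("Status", "sex", "apoe4", "education"),
    kind = c("status", "covariate", "covariate", "covariate"),
    min = NA_real_, max = NA_real_, step = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(tests, other)
}

#' @rdname np_variables
#' @export
np_test_names <- function() {
  v <- np_variables()
  v$name[v$kind == "np_test"]
}

#' @rdname np_variables
#' @export
status_levels <- function() c("HC", "AD", "NAD")

#' Cohort calibration constants
#'
#' Status-conditional raw-score means and standard deviations, status group
#' proportions and covariate prevalences used to calibrate the default
#' synthetic-cohort generator. These reflect the clinical profile of an
#' elderly community cohort: healthy controls (HC) score highest on every
#' test, Alzheimer disease (AD) lowest, non-Alzheimer dementia (NAD) in
#' between.
#'
#' @return a list with `means` and `sds` (11 x 3 matrices, tests x status),
#'   `proportions` (HC/AD/NAD), `covariates` (per-status prevalence of male
#'   sex, ApoE4 carriage and education beyond high school) and
#'   `covariate_missing` (fraction of exams lacking each covariate).
#' @export
cohort_calibration <- function() {
  tests <- np_test_names()
  means <- matrix(c(
    11.2, 4.8, 7.9,   # LMi
    10.2, 3.0, 6.5,   # LMd
    9.4, 7.1, 8.5,    # LMr
    7.1, 3.1, 4.0,    # VRi
    6.1, 1.6, 2.7,    # VRd
    2.6, 1.3, 1.7,    # VRr
    12.8, 8.4, 9.9,   # PASi
    4.4, 1.1, 2.0,    # PASi_h
    2.0, 0.5, 1.0,    # PASd_h
    15.5, 9.8, 11.6,  # SIM
    26.1, 19.4, 22.3  # BNT30
  ), ncol = 3, byrow = TRUE, dimnames = list(tests, status_levels()))
  sds <- matrix(c(
    3.7, 3.8, 3.9,
    3.9, 4.0, 4.1,
    1.4, 2.3, 1.7,
    3.0, 2.3, 2.5,
    3.1, 1.9, 2.4,
    1.1, 1.1, 1.1,
    3.3, 2.9, 2.8,
    3.0, 1.7, 2.0,
    1.3, 0.9, 1.1,
    3.9, 5.0, 4.7,
    3.4, 5.9, 5.4
  ), ncol = 3, byrow = TRUE, dimnames = list(tests, status_levels()))
  list(
    counts = c(HC = 3514, AD = 555, NAD = 443),
    participants = 2091,
    proportions = c(HC = 3514, AD = 555, NAD = 443) / 4512,
    means = means,
    sds = sds,
    covariates = list(
      male = c(HC = 0.433, AD = 0.323, NAD = 0.497),
      apoe4 = c(HC = 0.171, AD = 0.347, NAD = 0.208),
      education_high = c(HC = 0.575, AD = 0.348, NAD = 0.455)
    ),
    covariate_missing = c(apoe4 = 200 / 4512, education = 11 / 4512)
  )
}

#' Reference score-interval map for the 11 NP tests
#'
#' A bundled discretization of the battery into at most ten closed score
#' intervals per test, in the shape produced by `fit_discretization()`:
#' short-range tests (VRr, PASd_h) resolve into singleton intervals per
#' score, longer tests merge sparse tail scores into wider intervals, and
#' PASi carries half-point boundaries. Used as a fixed, data-independent map
#' and as a format example.
#'
#' @return an object of class `np_discretization` (see
#'   [fit_discretization()]).
#' @export
reference_discretization <- function() {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("lo", "hi")
    m
  }
  maps <- list(
    LMi = iv(0, 3, 4, 6, 7, 8, 9, 9, 10, 10, 11, 11, 12, 12, 13, 13, 14, 16, 17, 23),
    LMd = iv(0, 0, 1, 3, 4, 6, 7, 8, 9, 9, 10, 10, 11, 11, 12, 12, 13, 15, 16, 24),
    LMr = iv(0, 1, 2, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 8, 9, 9, 10, 10, 11, 11),
    VRi = iv(0, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 8, 9, 9, 10, 10, 11, 14),
    VRd = iv(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 9, 10, 14),
    VRr = iv(0, 0, 1, 1, 2, 2, 3, 3, 4, 4),
    PASi = iv(0, 7, 7.5, 8.5, 9, 9.5, 10, 11, 11.5, 12.5, 13, 13.5, 14, 14,
              14.5, 15.5, 16, 17.5, 18, 21),
    PASi_h = iv(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 8, 9, 12),
    PASd_h = iv(0, 0, 1, 1, 2, 2, 3, 3, 4, 4),
    SIM = iv(0, 6, 7, 10, 11, 12, 13, 13, 14, 14, 15, 15, 16, 16, 17, 17, 18, 19, 20, 26),
    BNT30 = iv(0, 12, 13, 17, 18, 20, 21, 23, 24, 25, 26, 26, 27, 27, 28, 28, 29, 29, 30, 30)
  )
  vars <- np_variables()
  steps <- stats::setNames(vars$step, vars$name)
  structure(list(
    intervals = maps,
    k = vapply(maps, nrow, integer(1)),
    silhouette = stats::setNames(rep(NA_real_, length(maps)), names(maps)),
    step = steps[names(maps)]
  ), class = "np_discretization")
}
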