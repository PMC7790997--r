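#' Published NHANES adult median comparison table
#'
#' Median plasma concentrations (ng/mL) of selected persistent pollutants
#' for study adults alongside the NHANES 2003-04 whole-weight medians for
#' 30-50-year-olds, as published. Both medians are
#' consumed as given numbers; the survey-weighted NHANES computation is
#' out of scope. The `printed_ratio` column carries the published
#' study/NHANES ratio at one-decimal rounding (one cell was left blank in
#' the original table and is `NA` here).
#'
#' @return A tibble with columns `chemical`, `study_median_ng_ml`,
#'   `nhanes_median_ng_ml`, `printed_ratio`.
#' @export
nhanes_adult_medians <- function() {
  path <- system.file("extdata", "nhanes_adult_medians.csv", package = "exposcreen")
  readr::read_csv(path, col_types = readr::cols(
    chemical = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Published NIST SRM 1958 percent-error table
#'
#' Per-batch percent errors of measured vs certified concentrations in
#' NIST Standard Reference Material 1958 serum for 33 chemicals, as
#' published. `NA` cells are batches where the SRM
#' result was unusable (e.g. a coeluting peak) and are excluded from the
#' accuracy gate's count.
#'
#' @return A tibble with columns `chemical`, `certified`, and
#'   `pe_batch1` ... `pe_batch5` (percent error per batch).
#' @export
srm1958_percent_errors <- function() {
  path <- system.file("extdata", "srm1958_percent_errors.csv", package = "exposcreen")
  readr::read_csv(path, col_types = readr::cols(
    chemical = readr::col_character(),
    .default = readr::col_double()
  ))
}
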