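#' Default synthetic chemical panel
#'
#' A deterministic panel of synthetic chemicals spanning the behaviours a
#' wide GC-MS/MS biomonitoring panel exhibits: abundant persistent
#' pollutants (high detection rates, age-increasing exposure), moderately
#' detected chemicals, rarely detected chemicals (screened out by the
#' detection-rate gate), and chemicals not amenable to the analytical
#' method (zero instrument response, screened out analytically). One
#' chemical has no qualifier transition, so the ratio criterion is
#' exercised as not-applicable.
#'
#' Columns (one row per chemical):
#' \describe{
#'   \item{chemical_id, name, cas, class}{identity; `class` is one of
#'     PCB, PBDE, organochlorine, PAH, other.}
#'   \item{quant_transition, qual_transition}{MRM transitions as
#'     "precursor>product" strings; `qual_transition` may be `NA`.}
#'   \item{expected_rt}{expected retention time, minutes.}
#'   \item{log_kow, mw}{physicochemical descriptors (unitless, g/mol).}
#'   \item{reference_qual_ratio}{qualifier/quantifier area ratio of the
#'     calibration standards.}
#'   \item{gm, gsd}{geometric mean (ng/mL) and geometric SD (unitless) of
#'     the cohort exposure distribution at age 0.}
#'   \item{age_slope}{log-concentration increase per year of age.}
#'   \item{response_slope, response_intercept}{linear instrument response:
#'     area counts per (ng/mL), and counts.}
#'   \item{lod_true}{design limit of detection, ng/mL (the generator's
#'     additive noise floor is `lod_true/3`, so the 3-SD LOD estimate
#'     recovers it).}
#'   \item{spike_nominal}{matrix-spike concentration, ng/mL.}
#'   \item{low_spike_nominal}{low-level spike used for LOD estimation,
#'     ng/mL.}
#'   \item{srm_certified}{certified SRM concentration, ng/mL (`NA` when
#'     the chemical is not SRM-certified).}
#'   \item{donor_base}{background concentration in the donor serum used
#'     for recovery QC, ng/mL.}
#' }
#'
#' @param n_chemicals Optional; keep only the first `n_chemicals` rows
#'   (useful for small, fast simulations). The first rows retain the
#'   behavioural variety where possible.
#' @return A tibble, one row per panel chemical.
#' @export
default_panel <- function(n_chemicals = NULL) {
  mk <- function(id, name, class, rt, kow, mw, gm, gsd, slope_age, lod,
                 resp_slope = 1e5, qual = TRUE, srm = NA_real_) {
    tibble::tibble(
      chemical_id = id, name = name, cas = paste0("0000-00-", id),
      class = class,
      quant_transition = "256>186",
      qual_transition = if (qual) "256>150" else NA_character_,
      expected_rt = rt, log_kow = kow, mw = mw,
      reference_qual_ratio = 0.5,
      gm = gm, gsd = gsd, age_slope = slope_age,
      response_slope = resp_slope, response_intercept = 50,
      lod_true = lod, spike_nominal = 12,
      low_spike_nominal = 2 * lod,
      srm_certified = srm, donor_base = gm / 2
    )
  }

  panel <- dplyr::bind_rows(
    # abundant persistent pollutants: detected in most samples, exposure
    # increases with age (adults carry higher burdens)
    mk("C01", "synPCB-1", "PCB", 22.1, 6.0, 292, 0.10, 2.5, 0.025, 0.020, srm = 0.41),
    mk("C02", "synPCB-2", "PCB", 24.3, 6.4, 326, 0.08, 2.5, 0.025, 0.015, srm = 0.42),
    mk("C03", "synPCB-3", "PCB", 26.0, 6.8, 361, 0.12, 2.6, 0.025, 0.035, srm = 0.46),
    mk("C04", "synPCB-4", "PCB", 27.8, 7.2, 395, 0.06, 2.4, 0.025, 0.018, srm = 0.40),
    mk("C05", "synDDE", "organochlorine", 23.4, 6.5, 318, 0.30, 2.8, 0.030, 0.030, srm = 1.25),
    mk("C06", "synHCB", "organochlorine", 14.2, 5.7, 285, 0.06, 2.2, 0.020, 0.025, srm = 0.44),
    mk("C07", "synNonachlor", "organochlorine", 22.9, 6.1, 444, 0.07, 2.3, 0.025, 0.026, srm = 0.47),
    # PAHs: high detection, no age trend
    mk("C08", "synFluoranthene", "PAH", 17.5, 5.2, 202, 1.60, 2.5, 0.000, 0.015),
    mk("C09", "synFluorene", "PAH", 11.8, 4.2, 166, 4.00, 2.6, 0.000, 0.300),
    # PBDEs
    mk("C10", "synPBDE-1", "PBDE", 28.9, 6.8, 486, 0.13, 2.7, 0.010, 0.055, srm = 0.48),
    mk("C11", "synPBDE-2", "PBDE", 30.6, 7.4, 564, 0.13, 2.7, 0.010, 0.057, srm = 0.44),
    # moderately detected, around 50-60% detection
    mk("C12", "synTrichlorophenol", "other", 8.9, 3.7, 197, 0.28, 2.9, 0.000, 0.150),
    mk("C13", "synIsosafrole", "other", 9.6, 3.3, 162, 0.30, 2.8, 0.000, 0.200),
    mk("C14", "synHexachlorobutadiene", "other", 6.4, 4.8, 261, 0.35, 2.9, 0.000, 0.240),
    # no qualifier transition: ratio criterion not applicable
    mk("C15", "synChlordane", "organochlorine", 21.2, 6.2, 410, 0.05, 2.4, 0.020, 0.030, qual = FALSE),
    # rarely detected: exposure far below the noise floor, screened out
    # by the < 20% detection-rate gate
    mk("C16", "synCyanazine", "other", 16.3, 2.2, 241, 0.002, 2.0, 0.000, 0.200),
    mk("C17", "synHeptachlor", "organochlorine", 18.7, 5.4, 373, 0.003, 2.0, 0.000, 0.120),
    mk("C18", "synMetolachlor", "other", 19.5, 3.1, 284, 0.004, 2.0, 0.000, 0.250),
    # not amenable to the method: no instrument response, fails the
    # analytical (calibration) gate
    mk("C19", "synTCEP", "other", 15.1, 1.4, 285, 0.05, 2.0, 0.000, 0.100, resp_slope = 0),
    mk("C20", "synPhthalate", "other", 12.4, 2.4, 222, 0.08, 2.0, 0.000, 0.100, resp_slope = 0)
  )

  if (!is.null(n_chemicals)) {
    if (n_chemicals < 1 || n_chemicals > nrow(panel)) {
      stop("`n_chemicals` must be between 1 and ", nrow(panel), call. = FALSE)
    }
    panel <- panel[seq_len(n_chemicals), ]
  }
  panel
}

validate_panel <- function(panel) {
  req <- c(
    "chemical_id", "name", "class", "quant_transition", "qual_transition",
    "expected_rt", "reference_qual_ratio", "gm", "gsd", "age_slope",
    "response_slope", "response_intercept", "lod_true", "spike_nominal",
    "low_spike_nominal", "srm_certified", "donor_base"
  )
  missing <- setdiff(req, names(panel))
  if (length(missing) > 0) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(panel$chemical_id)) stop("duplicate chemical_id in panel", call. = FALSE)
  if (any(panel$expected_rt <= 0)) stop("expected_rt must be > 0", call. = FALSE)
  if (any(panel$gsd < 1)) stop("gsd must be >= 1", call. = FALSE)
  if (any(panel$lod_true <= 0)) stop("lod_true must be > 0", call. = FALSE)
  invisible(panel)
}
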