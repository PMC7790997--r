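#' Fit a matrix-matched calibration curve
#'
#' Weighted least squares of mean response on nominal concentration over
#' the detected calibration levels, unweighted or with weights
#' 1/concentration. Undetected levels are excluded from the fit. The
#' curve is acceptable when at least `min_levels` levels were detected
#' and the (weighted) R-squared exceeds `r2_min`; with fewer than two
#' detected levels no line is fitted and the curve is returned
#' unacceptable with no slope (never silently extrapolated).
#'
#' @param nominal Nominal concentrations of the calibration levels, ng/mL.
#' @param response Mean instrument response at each level, counts.
#' @param detected Logical; whether each level was detected (default all).
#' @param weighting `"none"` or `"inverse_concentration"` (weights
#'   1/nominal).
#' @param min_levels,r2_min Acceptance thresholds (defaults 3 levels,
#'   R-squared > 0.8, strict).
#' @return An object of class `calibration_curve`: a list with `slope`,
#'   `intercept`, `r_squared`, `n_detected_levels`, `weighting`,
#'   `acceptable`, and the level table.
#' @export
fit_calibration <- function(nominal, response, detected = TRUE,
                            weighting = c("none", "inverse_concentration"),
                            min_levels = 3, r2_min = 0.8) {
  weighting <- match.arg(weighting)
  detected <- rep_len(detected, length(nominal))
  if (length(response) != length(nominal)) {
    stop("nominal and response must have the same length", call. = FALSE)
  }
  levels <- tibble::tibble(nominal = nominal, response = response,
                           detected = detected)
  d <- levels[levels$detected, ]
  out <- list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
              n_detected_levels = nrow(d), weighting = weighting,
              acceptable = FALSE, levels = levels)
  if (nrow(d) < 2 || length(unique(d$nominal)) < 2) {
    return(structure(out, class = "calibration_curve"))
  }
  w <- if (weighting == "inverse_concentration") 1 / d$nominal else rep(1, nrow(d))
  fit <- lm(response ~ nominal, data = d, weights = w)
  # summary.lm warns on exact fits; R2 itself is well-defined there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out$slope <- unname(coef(fit)[2])
  out$intercept <- unname(coef(fit)[1])
  out$r_squared <- r2
  out$acceptable <- nrow(d) >= min_levels && !is.na(r2) && r2 > r2_min
  structure(out, class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration curve: slope %.4g, intercept %.4g, R2 %.4f, %d detected levels (%s weighting) -> %s\n",
    x$slope, x$intercept, x$r_squared, x$n_detected_levels, x$weighting,
    if (x$acceptable) "acceptable" else "NOT acceptable"
  ))
  invisible(x)
}

#' Choose the calibration weighting mode
#'
#' Fits the detected levels both unweighted and with 1/concentration
#' weights and selects the mode with the smaller sum of squared relative
#' back-calculation errors of the calibration levels; ties (e.g.
#' noiseless levels) go to unweighted.
#'
#' @inheritParams fit_calibration
#' @return `"none"` or `"inverse_concentration"`.
#' @export
choose_weighting <- function(nominal, response, detected = TRUE) {
  err <- vapply(c("none", "inverse_concentration"), function(w) {
    cv <- fit_calibration(nominal, response, detected, weighting = w,
                          min_levels = 2, r2_min = -Inf)
    if (is.na(cv$slope) || cv$slope == 0) return(Inf)
    d <- cv$levels[cv$levels$detected, ]
    bc <- (d$response - cv$intercept) / cv$slope
    sum(((bc - d$nominal) / d$nominal)^2)
  }, numeric(1))
  # tie (within numerical precision, e.g. noiseless levels) -> unweighted
  if (err[1] <= err[2] + 1e-10 * (1 + err[2])) "none" else "inverse_concentration"
}

#' Quantify a response by inverse prediction
#'
#' `(response - intercept) / slope` on an acceptable curve; negative
#' results are floored at 0 and flagged (attribute `"floored"`).
#'
#' @param response Instrument response(s), counts.
#' @param curve A `calibration_curve`.
#' @return Concentration(s), ng/mL.
#' @export
quantify <- function(response, curve) {
  if (!isTRUE(curve$acceptable)) {
    stop("quantitation refused: calibration curve is not acceptable",
         call. = FALSE)
  }
  conc <- (response - curve$intercept) / curve$slope
  floored <- !is.na(conc) & conc < 0
  conc[floored] <- 0
  attr(conc, "floored") <- floored
  conc
}

#' Average duplicate-injection concentrations
#'
#' Arithmetic mean when both injections quantified; when one injection is
#' missing (non-detect) the single quantified value is used and flagged;
#' both missing yields a missing record.
#'
#' @param c1,c2 Concentrations from the two injections (`NA` =
#'   non-detect/missing). Vectorized.
#' @return Tibble with `conc_mean` and `single_injection`.
#' @export
average_duplicates <- function(c1, c2) {
  both <- !is.na(c1) & !is.na(c2)
  one <- xor(is.na(c1), is.na(c2))
  tibble::tibble(
    conc_mean = dplyr::case_when(
      both ~ (c1 + c2) / 2,
      one ~ dplyr::coalesce(c1, c2),
      TRUE ~ NA_real_
    ),
    single_injection = one
  )
}

#' Method-blank subtraction gate
#'
#' Blank subtraction is applied for a chemical/batch only when the
#' average method-blank level exceeds `factor` (default 10) times the
#' lowest calibration standard used AND the blanks' RSD is below
#' `rsd_max` percent (default 50, strict). The offset subtracted is the
#' blank mean. With fewer than two blanks the RSD is undefined and no
#' subtraction is performed (with a warning).
#'
#' @param blank_values Method-blank concentrations for one chemical/batch,
#'   ng/mL (non-detects as 0).
#' @param lowest_cal Lowest detected, accepted calibration level of that
#'   batch's curve, ng/mL.
#' @param factor,rsd_max Gate thresholds.
#' @return List with `subtract` (logical), `offset` (ng/mL, 0 when not
#'   subtracting), `mean_blank`, `rsd`.
#' @export
blank_subtraction_gate <- function(blank_values, lowest_cal,
                                   factor = 10, rsd_max = 50) {
  blank_values <- blank_values[!is.na(blank_values)]
  if (length(blank_values) < 2) {
    warning("fewer than 2 method blanks: RSD undefined, no blank subtraction",
            call. = FALSE)
    return(list(subtract = FALSE, offset = 0,
                mean_blank = if (length(blank_values)) mean(blank_values) else NA_real_,
                rsd = NA_real_))
  }
  m <- mean(blank_values)
  r <- rsd(blank_values)
  subtract <- !is.na(r) && m > factor * lowest_cal && r < rsd_max
  list(subtract = subtract, offset = if (subtract) m else 0,
       mean_blank = m, rsd = r)
}

#' Fit calibration curves for every chemical and batch
#'
#' For each chemical x batch: averages duplicate injections of each
#' calibration level, takes the level's detected flag from the detection
#' calls (either injection), chooses the weighting mode by minimum summed
#' squared relative back-calculation error, and fits the curve.
#'
#' @param peaks,samples,panel Simulation tables.
#' @param detections Output of [detect_peaks()].
#' @param min_levels,r2_min Acceptance thresholds.
#' @return Tibble with one row per chemical x batch: `chemical_id`,
#'   `batch`, `weighting`, `slope`, `intercept`, `r_squared`,
#'   `n_detected_levels`, `acceptable`, `lowest_cal_used`.
#' @export
build_curves <- function(peaks, samples, panel, detections,
                         min_levels = 3, r2_min = 0.8) {
  cal_samples <- samples[samples$sample_type == "calibration", ]
  cal <- peaks |>
    dplyr::inner_join(cal_samples[, c("sample_id", "batch", "cal_level")],
                      by = "sample_id") |>
    dplyr::group_by(.data$chemical_id, .data$batch, .data$cal_level) |>
    dplyr::summarise(response = mean(.data$quant_area), .groups = "drop") |>
    dplyr::left_join(
      detections$calls[detections$calls$sample_type == "calibration",
                       c("sample_id", "chemical_id", "detected")] |>
        dplyr::inner_join(cal_samples[, c("sample_id", "batch", "cal_level")],
                          by = "sample_id"),
      by = c("chemical_id", "batch", "cal_level")
    )
  cal$detected[is.na(cal$detected)] <- FALSE

  cal |>
    dplyr::group_by(.data$chemical_id, .data$batch) |>
    dplyr::group_modify(function(d, key) {
      w <- choose_weighting(d$cal_level, d$response, d$detected)
      cv <- fit_calibration(d$cal_level, d$response, d$detected, weighting = w,
                            min_levels = min_levels, r2_min = r2_min)
      lowest <- if (any(d$detected)) min(d$cal_level[d$detected]) else NA_real_
      tibble::tibble(
        weighting = w, slope = cv$slope, intercept = cv$intercept,
        r_squared = cv$r_squared, n_detected_levels = cv$n_detected_levels,
        acceptable = cv$acceptable, lowest_cal_used = lowest
      )
    }) |>
    dplyr::ungroup()
}

#' Quantify all samples against their batch curves
#'
#' Back-calculates a concentration for each detected injection from its
#' batch's acceptable curve (injections that failed the detection call
#' are non-detects, `NA`), then averages duplicates. Chemicals/batches
#' without an acceptable curve are refused (all `NA`, `curve_ok = FALSE`).
#'
#' @param peaks,samples Simulation tables.
#' @param curves Output of [build_curves()].
#' @param detections Output of [detect_peaks()].
#' @return Tibble with one row per sample x chemical: per-injection
#'   concentrations, `conc_mean`, `single_injection`, `curve_ok`,
#'   `sample_type`, `batch`, `subject_id`.
#' @export
quantify_table <- function(peaks, samples, curves, detections) {
  det <- detections$injections[, c("sample_id", "chemical_id", "injection",
                                   "detected")]
  df <- peaks |>
    dplyr::inner_join(samples[samples$sample_type != "instrument_blank",
                              c("sample_id", "sample_type", "batch", "subject_id")],
                      by = "sample_id") |>
    dplyr::left_join(det, by = c("sample_id", "chemical_id", "injection")) |>
    dplyr::left_join(curves[, c("chemical_id", "batch", "slope", "intercept",
                                "acceptable")],
                     by = c("chemical_id", "batch"))
  df$detected[is.na(df$detected)] <- FALSE
  df$acceptable[is.na(df$acceptable)] <- FALSE
  df$conc <- ifelse(
    df$acceptable & df$detected,
    pmax(0, (df$quant_area - df$intercept) / df$slope),
    NA_real_
  )
  wide <- df |>
    dplyr::select("sample_id", "chemical_id", "sample_type", "batch",
                  "subject_id", "injection", "conc", "acceptable") |>
    tidyr::pivot_wider(names_from = "injection", values_from = "conc",
                       names_prefix = "conc_injection_")
  avg <- average_duplicates(wide$conc_injection_1, wide$conc_injection_2)
  dplyr::bind_cols(wide, avg) |>
    dplyr::rename(curve_ok = "acceptable")
}
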