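#' Peak-shape similarity score
#'
#' Gaussian kernel on the relative deviations of the two shape
#' descriptors from the calibration-standard reference:
#' `exp(-(dw^2 + da^2) / 2)` where `dw` and `da` are the relative
#' deviations of width at half height and asymmetry. The score is 1 at
#' identity, decreases monotonically with either deviation, and tends to
#' 0 as a descriptor diverges.
#'
#' @param width,asymmetry Peak descriptors (width in minutes, asymmetry
#'   unitless).
#' @param ref_width,ref_asymmetry Reference descriptors from the
#'   calibration standards.
#' @return Score(s) in \[0, 1\]. Vectorized.
#' @export
shape_similarity <- function(width, asymmetry, ref_width, ref_asymmetry) {
  if (any(width <= 0, na.rm = TRUE) || any(ref_width <= 0, na.rm = TRUE)) {
    stop("peak widths must be > 0", call. = FALSE)
  }
  dw <- (width - ref_width) / ref_width
  da <- (asymmetry - ref_asymmetry) / ref_asymmetry
  exp(-(dw^2 + da^2) / 2)
}

# Vectorized four-criterion evaluation. Boundary conventions (centralized
# here): the RT window and the qualifier-ratio tolerance are inclusive
# ("within +/-"); the blank comparison is strict ("above").
detection_criteria <- function(rt, quant_area, qual_area,
                               expected_rt, reference_qual_ratio,
                               instrument_blank_area,
                               width, asymmetry, ref_width, ref_asymmetry,
                               rt_window = 0.1, ratio_tol = 0.2,
                               shape_threshold = 0.6) {
  if (any(is.na(expected_rt))) {
    stop("missing expected retention time for a chemical", call. = FALSE)
  }
  if (any(is.na(instrument_blank_area))) {
    stop("missing instrument blank area; no silent default", call. = FALSE)
  }
  crit_rt <- abs(rt - expected_rt) <= rt_window
  crit_blank <- quant_area > instrument_blank_area
  score <- shape_similarity(width, asymmetry, ref_width, ref_asymmetry)
  crit_shape <- score >= shape_threshold
  has_qual <- !is.na(reference_qual_ratio) & !is.na(qual_area)
  ratio_dev <- abs(qual_area / quant_area / reference_qual_ratio - 1)
  crit_ratio <- ifelse(has_qual, ratio_dev <= ratio_tol, NA)
  pf <- function(x) ifelse(is.na(x), "not_applicable", ifelse(x, "pass", "fail"))
  tibble::tibble(
    criterion_rt = pf(crit_rt),
    criterion_blank = pf(crit_blank),
    criterion_shape = pf(crit_shape),
    criterion_ratio = pf(crit_ratio),
    shape_score = score,
    detected = crit_rt & crit_blank & crit_shape & (is.na(crit_ratio) | crit_ratio)
  )
}

#' Four-criterion detection call for one peak
#'
#' A peak is a detect when all applicable criteria pass: retention time
#' within +/- `rt_window` minutes of the calibration standard's retention
#' time (inclusive); quantifier area strictly above the most recent
#' instrument blank's; peak shape similar to the calibration standard
#' ([shape_similarity()] at or above `shape_threshold`); and, when the
#' chemical has a qualifier transition, the measured qualifier/quantifier
#' ratio within +/- `ratio_tol` (relative, inclusive) of the calibration
#' standards' ratio. Chemicals without a qualifier skip the ratio
#' criterion (`not_applicable`).
#'
#' @param peak One-row data frame (or list) with `rt_min`, `quant_area`,
#'   `qual_area`, `width_half_height`, `asymmetry`.
#' @param target One-row data frame (or list) with `expected_rt` and
#'   `reference_qual_ratio` (`NA` ratio means no qualifier).
#' @param instrument_blank_area Quantifier area of the most recent
#'   instrument blank (required; an error if missing).
#' @param reference_shape List with `width` and `asymmetry` of the
#'   calibration-standard peak.
#' @param rt_window,ratio_tol,shape_threshold Thresholds; defaults 0.1
#'   min, 20%, 0.6.
#' @return One-row tibble with `detected` and the four criterion flags
#'   (`pass`/`fail`/`not_applicable`) plus the shape score.
#' @export
call_detection <- function(peak, target, instrument_blank_area, reference_shape,
                           rt_window = 0.1, ratio_tol = 0.2,
                           shape_threshold = 0.6) {
  qual_ref <- target$reference_qual_ratio
  if (!is.null(target$qual_transition) && is.na(target$qual_transition)) {
    qual_ref <- NA_real_
  }
  detection_criteria(
    rt = peak$rt_min, quant_area = peak$quant_area, qual_area = peak$qual_area,
    expected_rt = target$expected_rt, reference_qual_ratio = qual_ref,
    instrument_blank_area = instrument_blank_area,
    width = peak$width_half_height, asymmetry = peak$asymmetry,
    ref_width = reference_shape$width, ref_asymmetry = reference_shape$asymmetry,
    rt_window = rt_window, ratio_tol = ratio_tol,
    shape_threshold = shape_threshold
  )
}

# Resolve, for every sample, the quantifier area of the most recent
# instrument blank: the blank with the largest acquisition index at or
# before the sample's own index within its batch.
most_recent_blank <- function(samples, peaks) {
  blanks <- samples[samples$sample_type == "instrument_blank", ]
  if (nrow(blanks) == 0) stop("no instrument blanks in the run", call. = FALSE)
  blank_areas <- peaks |>
    dplyr::inner_join(blanks[, c("sample_id", "batch", "acquisition_index")],
                      by = "sample_id") |>
    dplyr::group_by(.data$batch, .data$acquisition_index, .data$chemical_id) |>
    dplyr::summarise(blank_area = mean(.data$quant_area), .groups = "drop")

  non_blank <- samples[samples$sample_type != "instrument_blank", ]
  out <- purrr::map_dfr(split(non_blank, non_blank$batch), function(s) {
    b_idx <- sort(blanks$acquisition_index[blanks$batch == s$batch[1]])
    if (length(b_idx) == 0) {
      stop("batch ", s$batch[1], " has no instrument blank", call. = FALSE)
    }
    prev <- vapply(s$acquisition_index, function(i) {
      ok <- b_idx[b_idx <= i]
      if (length(ok) == 0) {
        stop("sample acquired before any instrument blank in batch ",
             s$batch[1], call. = FALSE)
      }
      max(ok)
    }, numeric(1))
    tibble::tibble(sample_id = s$sample_id, batch = s$batch[1],
                   blank_acq = prev)
  })
  out |>
    dplyr::left_join(blank_areas,
                     by = c("batch", "blank_acq" = "acquisition_index"),
                     relationship = "many-to-many")
}

#' Detection calls for a whole peak table
#'
#' Applies [call_detection()] to every injection of every sample x
#' chemical, resolving each sample's most recent instrument blank within
#' its batch, then aggregates to sample level: a sample is detected for a
#' chemical if either injection passes all applicable criteria (the
#' per-injection calls are kept in the output).
#'
#' @param peaks,samples,panel Tables as produced by [simulate_study()]
#'   (or read from `peaks.csv` etc.).
#' @param reference_shape List with `width`, `asymmetry` of the
#'   calibration-standard peak shape.
#' @param rt_window,ratio_tol,shape_threshold Detection thresholds.
#' @return A list: `injections` (one row per injection with the four
#'   criterion flags) and `calls` (one row per sample x chemical with
#'   `detected = any injection detected` and `n_injections_detected`).
#' @export
detect_peaks <- function(peaks, samples, panel,
                         reference_shape = list(width = 0.05, asymmetry = 1.0),
                         rt_window = 0.1, ratio_tol = 0.2,
                         shape_threshold = 0.6) {
  blank_ref <- most_recent_blank(samples, peaks)
  target_cols <- panel[, c("chemical_id", "expected_rt", "qual_transition",
                           "reference_qual_ratio")]
  df <- peaks |>
    dplyr::inner_join(samples[samples$sample_type != "instrument_blank",
                              c("sample_id", "sample_type", "batch")],
                      by = "sample_id") |>
    dplyr::left_join(target_cols, by = "chemical_id") |>
    dplyr::left_join(blank_ref[, c("sample_id", "chemical_id", "blank_area")],
                     by = c("sample_id", "chemical_id"))
  qual_ref <- ifelse(is.na(df$qual_transition), NA_real_, df$reference_qual_ratio)
  crit <- detection_criteria(
    rt = df$rt_min, quant_area = df$quant_area, qual_area = df$qual_area,
    expected_rt = df$expected_rt, reference_qual_ratio = qual_ref,
    instrument_blank_area = df$blank_area,
    width = df$width_half_height, asymmetry = df$asymmetry,
    ref_width = reference_shape$width,
    ref_asymmetry = reference_shape$asymmetry,
    rt_window = rt_window, ratio_tol = ratio_tol,
    shape_threshold = shape_threshold
  )
  injections <- dplyr::bind_cols(
    df[, c("sample_id", "chemical_id", "injection", "sample_type", "batch")],
    crit
  )
  calls <- injections |>
    dplyr::group_by(.data$sample_id, .data$chemical_id, .data$sample_type,
                    .data$batch) |>
    dplyr::summarise(
      detected = any(.data$detected),
      n_injections_detected = sum(.data$detected),
      .groups = "drop"
    )
  list(injections = injections, calls = calls)
}

#' Detection rate of a chemical across study samples
#'
#' Fraction of study samples in which the chemical was called a detect.
#' QC samples must be excluded by the caller (pass only study-sample
#' calls or use `study_sample_ids`).
#'
#' @param calls Sample-level calls for one chemical (tibble with
#'   `sample_id` and `detected`).
#' @param study_sample_ids Optional character vector restricting the
#'   calls to study samples.
#' @return Fraction in \[0, 1\].
#' @export
detection_rate <- function(calls, study_sample_ids = NULL) {
  if (length(unique(calls$chemical_id)) > 1) {
    stop("detection_rate expects calls for a single chemical", call. = FALSE)
  }
  if (!is.null(study_sample_ids)) {
    calls <- calls[calls$sample_id %in% study_sample_ids, ]
  }
  if (nrow(calls) == 0) stop("no study samples to compute a detection rate",
                             call. = FALSE)
  mean(calls$detected)
}
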