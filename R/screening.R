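#' Extraction recovery from donor serum
#'
#' Percent recovery: the difference between the average measured
#' concentrations of spiked and unspiked donor serum divided by the
#' concentration added.
#'
#' @param spiked_concs,unspiked_concs Measured concentrations, ng/mL
#'   (at least one of each; treat non-detects as 0 before calling).
#' @param added Spiked concentration, ng/mL (> 0).
#' @return Recovery in percent.
#' @export
recovery <- function(spiked_concs, unspiked_concs, added) {
  stopifnot_scalar_number(added, "added")
  if (added <= 0) stop("`added` must be > 0", call. = FALSE)
  if (length(spiked_concs) < 1 || length(unspiked_concs) < 1) {
    stop("need at least one spiked and one unspiked measurement", call. = FALSE)
  }
  100 * (mean(spiked_concs) - mean(unspiked_concs)) / added
}

#' Instrumental detection limit from replicate injections
#'
#' IDL = t(conf, n-1) x SD of the back-calculated concentrations of
#' replicate low-level standard injections (one-sided Student-t
#' multiplier at 99% by default).
#'
#' @param replicate_responses Instrument responses of the replicate
#'   injections, counts (about 10; at least 7).
#' @param curve An acceptable `calibration_curve`.
#' @param conf Confidence level for the t multiplier (default 0.99).
#' @return IDL in ng/mL.
#' @export
instrumental_detection_limit <- function(replicate_responses, curve,
                                         conf = 0.99) {
  n <- length(replicate_responses)
  if (n < 7) stop("need at least 7 replicate injections for an IDL",
                  call. = FALSE)
  if (!isTRUE(curve$acceptable)) {
    stop("IDL requires an acceptable calibration curve", call. = FALSE)
  }
  bc <- (replicate_responses - curve$intercept) / curve$slope
  qt(conf, n - 1) * sd(bc)
}

#' Screening gates for one chemical
#'
#' Evaluates the screening gates in fixed order so the exclusion reason
#' is unambiguous: analytical (acceptable calibration), recovery
#' (advisory above 50%, exclusion below), then the detection-rate gate
#' (< 20% of study samples excludes, strict, so exactly 20% advances).
#' Missing metrics are recorded as skipped and the chemical is excluded
#' conservatively at that gate.
#'
#' @param chemical_id Chemical identifier.
#' @param curve_acceptable Logical: did the chemical have an acceptable
#'   calibration?
#' @param recovery_pct Donor-serum recovery, percent.
#' @param rate Detection rate over study samples, fraction.
#' @param recovery_floor,rate_floor Thresholds (defaults 50%, 0.20).
#' @return Tibble of gate rows (`chemical_id`, `gate`, `metric`,
#'   `threshold`, `outcome`, `final_status`); `final_status` is one of
#'   `excluded_screening_analytical`, `excluded_screening_rate`,
#'   `advanced`.
#' @export
screen_chemical <- function(chemical_id, curve_acceptable, recovery_pct, rate,
                            recovery_floor = 50, rate_floor = 0.20) {
  gates <- tibble::tibble(
    chemical_id = character(0), gate = character(0), metric = numeric(0),
    threshold = numeric(0), outcome = character(0)
  )
  add <- function(gate, metric, threshold, outcome) {
    gates <<- dplyr::bind_rows(gates, tibble::tibble(
      chemical_id = chemical_id, gate = gate, metric = metric,
      threshold = threshold, outcome = outcome
    ))
  }
  status <- NULL

  if (is.na(curve_acceptable)) {
    add("analytical", NA_real_, NA_real_, "skipped")
    status <- "excluded_screening_analytical"
  } else if (!curve_acceptable) {
    add("analytical", 0, NA_real_, "fail")
    status <- "excluded_screening_analytical"
  } else {
    add("analytical", 1, NA_real_, "pass")
  }

  if (is.null(status)) {
    if (is.na(recovery_pct)) {
      add("recovery", NA_real_, recovery_floor, "skipped")
      status <- "excluded_screening_analytical"
    } else if (recovery_pct < recovery_floor) {
      add("recovery", recovery_pct, recovery_floor, "fail")
      status <- "excluded_screening_analytical"
    } else {
      add("recovery", recovery_pct, recovery_floor, "pass")
    }
  }

  if (is.null(status)) {
    if (is.na(rate)) {
      add("detection_rate", NA_real_, rate_floor, "skipped")
      status <- "excluded_screening_rate"
    } else if (rate < rate_floor) {
      add("detection_rate", rate, rate_floor, "fail")
      status <- "excluded_screening_rate"
    } else {
      add("detection_rate", rate, rate_floor, "pass")
      status <- "advanced"
    }
  }

  gates$final_status <- status
  gates
}

#' Screen the whole panel
#'
#' Computes, per chemical: whether the calibration was acceptable in a
#' majority of batches, donor-serum recovery, and the detection rate
#' over study samples; then applies [screen_chemical()].
#'
#' @param detections Output of [detect_peaks()].
#' @param curves Output of [build_curves()].
#' @param concs Output of [quantify_table()].
#' @param panel Panel tibble.
#' @param recovery_floor,rate_floor Gate thresholds.
#' @return A list: `ledger` (all gate rows), `status` (one row per
#'   chemical with `final_status`).
#' @export
screen_panel <- function(detections, curves, concs, panel,
                         recovery_floor = 50, rate_floor = 0.20) {
  curve_ok <- curves |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(curve_acceptable = mean(.data$acceptable) > 0.5)

  study_calls <- detections$calls[detections$calls$sample_type == "study", ]
  rates <- study_calls |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(rate = mean(.data$detected))

  donor <- concs[concs$sample_type %in% c("donor_spiked", "donor_unspiked"), ]
  recov <- donor |>
    dplyr::mutate(value = dplyr::coalesce(.data$conc_mean, 0)) |>
    dplyr::left_join(panel[, c("chemical_id", "spike_nominal")],
                     by = "chemical_id") |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(
      recovery_pct = if (any(.data$sample_type == "donor_spiked") &&
                         any(.data$sample_type == "donor_unspiked")) {
        recovery(.data$value[.data$sample_type == "donor_spiked"],
                 .data$value[.data$sample_type == "donor_unspiked"],
                 added = .data$spike_nominal[1])
      } else NA_real_,
      .groups = "drop"
    )

  per_chem <- panel["chemical_id"] |>
    dplyr::left_join(curve_ok, by = "chemical_id") |>
    dplyr::left_join(recov, by = "chemical_id") |>
    dplyr::left_join(rates, by = "chemical_id")

  ledger <- purrr::pmap_dfr(per_chem, function(chemical_id, curve_acceptable,
                                               recovery_pct, rate) {
    screen_chemical(chemical_id, curve_acceptable, recovery_pct, rate,
                    recovery_floor = recovery_floor, rate_floor = rate_floor)
  })
  status <- ledger |>
    dplyr::distinct(.data$chemical_id, .data$final_status)
  list(ledger = ledger, status = status)
}

#' Assemble the targeted panel
#'
#' Union of the chemicals that advanced through screening and a list of
#' additions of toxicological interest that bypass the screening gates
#' (flagged). Duplicated additions are counted once.
#'
#' @param status Screening status tibble (`chemical_id`, `final_status`).
#' @param additions Character vector of chemical_ids to add.
#' @param master_ids All chemical_ids in the master panel definition;
#'   additions outside it are an error.
#' @return Tibble `chemical_id`, `bypassed_screening`.
#' @export
assemble_targeted_panel <- function(status, additions = character(0),
                                    master_ids = status$chemical_id) {
  bad <- setdiff(additions, master_ids)
  if (length(bad) > 0) {
    stop("additions not in the master panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  advanced <- status$chemical_id[status$final_status == "advanced"]
  extra <- setdiff(additions, advanced)
  tibble::tibble(
    chemical_id = c(advanced, extra),
    bypassed_screening = c(rep(FALSE, length(advanced)),
                           rep(TRUE, length(extra)))
  )
}
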