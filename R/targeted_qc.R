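#' Matrix-spike relative standard deviation gate
#'
#' Inter-sample variability gate: RSD of the matrix-spike concentrations
#' pooled over all batches; the chemical fails when RSD is strictly
#' greater than `max_rsd` percent (exactly 60% passes).
#'
#' @param values Matrix-spike concentrations pooled over batches, ng/mL.
#' @param max_rsd Threshold in percent (default 60).
#' @return List with `rsd` (percent) and `pass` (logical; `NA` = gate
#'   skipped when fewer than 3 values, with a warning).
#' @export
spike_rsd_gate <- function(values, max_rsd = 60) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    warning("fewer than 3 matrix-spike values: RSD gate skipped", call. = FALSE)
    return(list(rsd = NA_real_, pass = NA))
  }
  r <- rsd(values)
  list(rsd = r, pass = !is.na(r) && r <= max_rsd)
}

#' Inter-batch Kruskal-Wallis gate
#'
#' Non-parametric test for batch differences in matrix-spike values
#' (rank-based, tie-corrected H with a chi-square p on k-1 degrees of
#' freedom via [stats::kruskal.test()]). The chemical fails when
#' p < `alpha` (default 0.01). Requires at least two batches with two or
#' more values each; otherwise the gate is skipped (chemical retained,
#' with a warning). All-tied values are the degenerate case H = 0, p = 1.
#'
#' With small groups the chi-square reference distribution is
#' conservative in the far tail (at five batches of six the realized
#' type-I error at p < 0.01 is well under 1%), so a Monte-Carlo
#' permutation p-value is available via `method = "permutation"`: the
#' observed tie-corrected H is compared against `n_perm` random
#' relabelings, `p = (1 + #\{H* >= H\}) / (n_perm + 1)`, which restores
#' nominal calibration.
#'
#' @param values Matrix-spike concentrations, ng/mL.
#' @param batches Batch labels, same length as `values`.
#' @param alpha Probability cut-off (default 0.01).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Permutations for the Monte-Carlo p (default 1999; uses
#'   the current RNG stream).
#' @return List with `H`, `p`, `pass`.
#' @export
kruskal_wallis_gate <- function(values, batches, alpha = 0.01,
                                method = c("chisq", "permutation"),
                                n_perm = 1999) {
  method <- match.arg(method)
  keep <- !is.na(values)
  values <- values[keep]
  batches <- factor(batches[keep])
  sizes <- table(batches)
  if (length(sizes) < 2 || sum(sizes >= 2) < 2) {
    warning("insufficient batches for the Kruskal-Wallis gate: skipped",
            call. = FALSE)
    return(list(H = NA_real_, p = NA_real_, pass = NA))
  }
  # degenerate case: all values tied (within numerical precision, so that
  # quantitation round-off cannot masquerade as a batch effect)
  rng <- diff(range(values))
  if (rng <= 1e-10 * max(abs(values), 1e-300)) {
    return(list(H = 0, p = 1, pass = TRUE))
  }
  kt <- stats::kruskal.test(values, batches)
  H <- unname(kt$statistic)
  if (method == "chisq") {
    p <- kt$p.value
  } else {
    r <- rank(values)
    g <- as.integer(batches)
    n <- length(r)
    n_g <- tabulate(g)
    ties <- table(r)
    tie_c <- 1 - sum(ties^3 - ties) / (n^3 - n)
    h_of <- function(rr) {
      s <- rowsum(rr, g)[, 1]
      (12 / (n * (n + 1)) * sum(s^2 / n_g) - 3 * (n + 1)) / tie_c
    }
    h_star <- vapply(seq_len(n_perm), function(i) h_of(r[sample.int(n)]),
                     numeric(1))
    p <- (1 + sum(h_star >= H - 1e-12)) / (n_perm + 1)
  }
  list(H = H, p = p, pass = p >= alpha)
}

#' Standard-reference-material accuracy gate
#'
#' The chemical fails when the absolute percent error against the
#' certified concentration exceeds `pe_max` percent in more than
#' `max_bad_batches` batches (default: |PE| > 50% in two or more
#' batches). Batches with unusable SRM results (`NA`, e.g. a coeluting
#' peak) are excluded from the count. Chemicals without SRM data skip
#' the gate.
#'
#' @param percent_errors Per-batch percent errors,
#'   `100 * (measured - certified) / certified`; `NA` = unusable batch.
#' @param pe_max Percent-error threshold (default 50, strict).
#' @param max_bad_batches Largest tolerated number of failing batches
#'   (default 1).
#' @return List with `n_bad` and `pass` (`NA` = skipped, no SRM data).
#' @export
srm_accuracy_gate <- function(percent_errors, pe_max = 50, max_bad_batches = 1) {
  pe <- percent_errors[!is.na(percent_errors)]
  if (length(pe) == 0) return(list(n_bad = NA_integer_, pass = NA))
  n_bad <- sum(abs(pe) > pe_max)
  list(n_bad = n_bad, pass = n_bad <= max_bad_batches)
}

#' Estimate a limit of detection from low-level spikes
#'
#' LOD = `multiplier` x SD of the measured concentrations of low-level
#' spiked standards (about n = 10; at least 7). The default multiplier
#' is 3 (a 3-SD detection limit).
#'
#' @param low_spike_concs Measured low-spike concentrations, ng/mL.
#' @param multiplier SD multiplier (default 3).
#' @return List with `lod` (ng/mL), `n_replicates`, `method`.
#' @export
estimate_lod <- function(low_spike_concs, multiplier = 3) {
  x <- low_spike_concs[!is.na(low_spike_concs)]
  if (length(x) < 7) {
    stop("need at least 7 low-level spike replicates to estimate an LOD",
         call. = FALSE)
  }
  list(lod = multiplier * sd(x), n_replicates = length(x),
       method = "low_spike_sd")
}

#' Censor sub-LOD values and substitute LOD/sqrt(2)
#'
#' Values strictly below the LOD are censored and replaced by
#' `lod / divisor` for statistics (default divisor `sqrt(2)`, a
#' substitution with low bias when censoring is under 50%); a value
#' exactly at the LOD is not censored. Missing concentrations
#' (non-detects with no quantifiable injection) are censored. Negative
#' concentrations are an error (blank-subtraction flooring should
#' prevent them).
#'
#' @param conc Concentration(s), ng/mL; `NA` = non-detect.
#' @param lod Limit of detection, ng/mL.
#' @param divisor Substitution divisor (default `sqrt(2)`).
#' @return Tibble with `censored` and `value_for_stats`. Vectorized.
#' @export
censor_and_substitute <- function(conc, lod, divisor = sqrt(2)) {
  if (any(conc < 0, na.rm = TRUE)) {
    stop("negative concentrations cannot be censored; floor them first",
         call. = FALSE)
  }
  censored <- is.na(conc) | conc < lod
  tibble::tibble(
    censored = censored,
    value_for_stats = ifelse(censored, lod / divisor, conc)
  )
}

#' Apply the targeted QC gates and censoring to a quantified study
#'
#' For each chemical in the targeted panel: identifies batches where the
#' chemical was unmeasurable (all matrix spikes non-detect, the stored
#' volatile-loss signature) and drops them from gates and statistics;
#' applies the method-blank subtraction rule per batch; runs the
#' matrix-spike RSD gate, the inter-batch Kruskal-Wallis gate, and the
#' SRM accuracy gate; estimates the LOD from the low-level spikes; and
#' censors/substitutes the study-sample concentrations.
#'
#' @param concs Output of [quantify_table()].
#' @param curves Output of [build_curves()] (for the lowest calibration
#'   level used in blank subtraction).
#' @param panel Panel tibble (for `spike_nominal`, `srm_certified`).
#' @param targeted_ids Chemical ids in the targeted panel.
#' @param spike_rsd_max,kw_alpha,srm_pe_max,srm_max_bad_batches,lod_multiplier,substitution_divisor,blank_factor,blank_rsd_max
#'   Gate thresholds (paper defaults).
#' @return A list: `gates` (per-chemical gate metrics and `reported`
#'   status), `lods`, `records` (per sample x chemical concentration
#'   records with `censored` and `value_for_stats`),
#'   `dropped_batches` (chemical x batch dropped as unmeasurable).
#' @export
apply_targeted_qc <- function(concs, curves, panel, targeted_ids,
                              spike_rsd_max = 60, kw_alpha = 0.01,
                              srm_pe_max = 50, srm_max_bad_batches = 1,
                              lod_multiplier = 3,
                              substitution_divisor = sqrt(2),
                              blank_factor = 10, blank_rsd_max = 50) {
  concs <- concs[concs$chemical_id %in% targeted_ids, ]

  spikes <- concs[concs$sample_type == "matrix_spike", ]
  dropped <- spikes |>
    dplyr::group_by(.data$chemical_id, .data$batch) |>
    dplyr::summarise(unmeasurable = all(is.na(.data$conc_mean)), .groups = "drop") |>
    dplyr::filter(.data$unmeasurable)

  is_dropped <- function(chem, batch) {
    paste(chem, batch) %in% paste(dropped$chemical_id, dropped$batch)
  }

  curve_ok <- curves |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(curve_ok = mean(.data$acceptable) > 0.5)

  lods <- purrr::map_dfr(targeted_ids, function(chem) {
    ls <- concs[concs$sample_type == "low_spike" & concs$chemical_id == chem, ]
    ls <- ls[!is_dropped(chem, ls$batch), ]
    vals <- ls$conc_mean[!is.na(ls$conc_mean)]
    if (length(vals) < 7) {
      tibble::tibble(chemical_id = chem, lod = NA_real_,
                     n_replicates = length(vals))
    } else {
      est <- estimate_lod(vals, multiplier = lod_multiplier)
      tibble::tibble(chemical_id = chem, lod = est$lod,
                     n_replicates = est$n_replicates)
    }
  })

  gates <- purrr::map_dfr(targeted_ids, function(chem) {
    sp <- spikes[spikes$chemical_id == chem, ]
    sp <- sp[!is_dropped(chem, sp$batch), ]
    sp_vals <- sp$conc_mean[!is.na(sp$conc_mean)]
    g_rsd <- suppressWarnings(spike_rsd_gate(sp_vals, max_rsd = spike_rsd_max))
    g_kw <- suppressWarnings(
      kruskal_wallis_gate(sp$conc_mean, sp$batch, alpha = kw_alpha)
    )
    cert <- panel$srm_certified[panel$chemical_id == chem]
    if (!is.na(cert)) {
      srm <- concs[concs$sample_type == "srm" & concs$chemical_id == chem, ]
      pe <- srm |>
        dplyr::filter(!is_dropped(chem, .data$batch)) |>
        dplyr::group_by(.data$batch) |>
        dplyr::summarise(
          measured = mean(.data$conc_mean, na.rm = TRUE), .groups = "drop"
        ) |>
        dplyr::mutate(pe = 100 * (.data$measured - cert) / cert)
      g_srm <- srm_accuracy_gate(pe$pe, pe_max = srm_pe_max,
                                 max_bad_batches = srm_max_bad_batches)
    } else {
      g_srm <- list(n_bad = NA_integer_, pass = NA)
    }
    chem_curve_ok <- isTRUE(curve_ok$curve_ok[curve_ok$chemical_id == chem])
    has_lod <- !is.na(lods$lod[match(chem, lods$chemical_id)])
    # skipped gates (NA) retain the chemical; any failing gate excludes it,
    # and a chemical cannot be reported without an estimable LOD
    reported <- chem_curve_ok && has_lod && !isFALSE(g_rsd$pass) &&
      !isFALSE(g_kw$pass) && !isFALSE(g_srm$pass)
    tibble::tibble(
      chemical_id = chem, curve_ok = chem_curve_ok, has_lod = has_lod,
      spike_rsd = g_rsd$rsd, spike_rsd_pass = g_rsd$pass,
      kw_H = g_kw$H, kw_p = g_kw$p, kw_pass = g_kw$pass,
      srm_n_bad = g_srm$n_bad, srm_pass = g_srm$pass,
      reported = reported
    )
  })

  # blank subtraction per chemical x batch, on the concentration scale
  blanks <- concs[concs$sample_type == "method_blank", ]
  blank_offsets <- blanks |>
    dplyr::left_join(curves[, c("chemical_id", "batch", "lowest_cal_used")],
                     by = c("chemical_id", "batch")) |>
    dplyr::group_by(.data$chemical_id, .data$batch) |>
    dplyr::summarise(
      offset = {
        vals <- dplyr::coalesce(.data$conc_mean, 0)
        low <- .data$lowest_cal_used[1]
        if (is.na(low) || length(vals) < 2) 0 else {
          suppressWarnings(
            blank_subtraction_gate(vals, low, factor = blank_factor,
                                   rsd_max = blank_rsd_max)$offset
          )
        }
      },
      .groups = "drop"
    )

  study <- concs[concs$sample_type == "study", ] |>
    dplyr::left_join(blank_offsets, by = c("chemical_id", "batch")) |>
    dplyr::left_join(lods, by = "chemical_id") |>
    dplyr::mutate(
      offset = dplyr::coalesce(.data$offset, 0),
      blank_subtracted = .data$offset > 0,
      conc_mean = pmax(0, .data$conc_mean - .data$offset),
      batch_dropped = is_dropped(.data$chemical_id, .data$batch)
    )
  cen <- censor_and_substitute(study$conc_mean, study$lod,
                               divisor = substitution_divisor)
  records <- dplyr::bind_cols(study, cen)

  list(gates = gates, lods = lods, records = records, dropped_batches = dropped)
}
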