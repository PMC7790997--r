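#' Pipeline run configuration
#'
#' Collects every analytical threshold with the published defaults:
#' retention-time window 0.1 min, qualifier-ratio tolerance 20%,
#' screening detection-rate floor 20%, recovery floor 50%, calibration
#' R-squared > 0.8 with at least 3 detected levels, blank subtraction at
#' 10x the lowest calibration level with blank RSD < 50%, matrix-spike
#' RSD <= 60%, Kruskal-Wallis cut-off p < 0.01, SRM percent error 50% in
#' at most 1 batch, LOD = 3 SD of low spikes with LOD/sqrt(2)
#' substitution, median reporting above 50% detects, test eligibility at
#' 30% detects, initial alpha 0.05. Every threshold is overridable.
#'
#' @param rt_window,ratio_tol,shape_threshold Detection thresholds.
#' @param rate_floor,recovery_floor Screening gates.
#' @param cal_r2,cal_min_levels Calibration acceptance.
#' @param blank_factor,blank_rsd_max Blank-subtraction gate.
#' @param spike_rsd_max,kw_alpha,srm_pe_max,srm_max_bad_batches Targeted
#'   QC gates.
#' @param lod_multiplier,substitution_divisor LOD estimation and
#'   censoring substitution.
#' @param median_floor,test_floor,alpha0 Reporting-layer rules.
#' @param reference_shape Calibration-standard peak-shape reference.
#' @return A list of class `run_config`.
#' @export
run_config <- function(rt_window = 0.1, ratio_tol = 0.2, shape_threshold = 0.6,
                       rate_floor = 0.20, recovery_floor = 50,
                       cal_r2 = 0.8, cal_min_levels = 3,
                       blank_factor = 10, blank_rsd_max = 50,
                       spike_rsd_max = 60, kw_alpha = 0.01,
                       srm_pe_max = 50, srm_max_bad_batches = 1,
                       lod_multiplier = 3, substitution_divisor = sqrt(2),
                       median_floor = 0.5, test_floor = 0.3, alpha0 = 0.05,
                       reference_shape = list(width = 0.05, asymmetry = 1.0)) {
  cfg <- as.list(environment())
  frac <- c("rate_floor", "median_floor", "test_floor", "ratio_tol",
            "shape_threshold", "alpha0", "kw_alpha")
  for (nm in frac) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  if (rt_window <= 0) stop("rt_window must be > 0", call. = FALSE)
  if (substitution_divisor <= 0) stop("substitution_divisor must be > 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run the full two-step pipeline on a simulated study
#'
#' Executes detect -> calibrate -> screen -> targeted QC -> censor ->
#' cohort statistics and assembles a machine-readable run report with
#' the gate counts of the analytical flow (screened, excluded
#' analytically, excluded by detection rate, advanced, additions,
#' excluded by targeted QC, reported). Deterministic given the
#' simulation and configuration.
#'
#' @param sim An `exposcreen_sim` from [simulate_study()].
#' @param config A [run_config()].
#' @param additions Chemical ids added to the targeted panel bypassing
#'   the screening gates.
#' @return A list of class `exposcreen_run`: `detections`, `curves`,
#'   `concs`, `screening` (ledger + status), `targeted_panel`, `qc`,
#'   `records`, `summary_table`, `comparisons`, `correlations` (mother
#'   and father), `report`.
#' @export
run_pipeline <- function(sim, config = run_config(), additions = character(0)) {
  panel <- sim$panel
  detections <- detect_peaks(
    sim$peaks, sim$samples, panel,
    reference_shape = config$reference_shape,
    rt_window = config$rt_window, ratio_tol = config$ratio_tol,
    shape_threshold = config$shape_threshold
  )
  curves <- build_curves(sim$peaks, sim$samples, panel, detections,
                         min_levels = config$cal_min_levels,
                         r2_min = config$cal_r2)
  concs <- quantify_table(sim$peaks, sim$samples, curves, detections)

  screening <- screen_panel(detections, curves, concs, panel,
                            recovery_floor = config$recovery_floor,
                            rate_floor = config$rate_floor)
  targeted_panel <- assemble_targeted_panel(screening$status, additions,
                                            master_ids = panel$chemical_id)

  qc <- apply_targeted_qc(
    concs, curves, panel, targeted_panel$chemical_id,
    spike_rsd_max = config$spike_rsd_max, kw_alpha = config$kw_alpha,
    srm_pe_max = config$srm_pe_max,
    srm_max_bad_batches = config$srm_max_bad_batches,
    lod_multiplier = config$lod_multiplier,
    substitution_divisor = config$substitution_divisor,
    blank_factor = config$blank_factor, blank_rsd_max = config$blank_rsd_max
  )
  reported_ids <- qc$gates$chemical_id[qc$gates$reported]

  records <- qc$records |>
    dplyr::inner_join(sim$subjects[, c("subject_id", "role", "family_id", "age")],
                      by = "subject_id")

  summary_table <- build_summary_table(qc$records, sim$subjects, qc$lods,
                                       reported_ids,
                                       median_floor = config$median_floor)

  # group comparisons: adults vs children, probands vs controls,
  # mothers vs fathers, on chemicals meeting the pooled 30%-detects floor
  usable <- records[records$chemical_id %in% reported_ids &
                      !records$batch_dropped, ]
  usable$grp_age <- ifelse(usable$role %in% c("mother", "father"),
                           "adults", "children")
  eligible <- usable |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(rate = mean(!.data$censored)) |>
    dplyr::filter(.data$rate >= config$test_floor)
  n_eligible <- nrow(eligible)
  adj <- if (n_eligible > 0) bonferroni_alpha(config$alpha0, n_eligible) else
    list(alpha = NA_real_, alpha_rounded = NA_real_)

  comparison_sets <- list(
    adults_vs_children = function(d) list(a = d[d$grp_age == "adults", ],
                                          b = d[d$grp_age == "children", ]),
    probands_vs_controls = function(d) list(a = d[d$role == "proband", ],
                                            b = d[d$role == "control", ]),
    mothers_vs_fathers = function(d) list(a = d[d$role == "mother", ],
                                          b = d[d$role == "father", ])
  )
  comparisons <- purrr::map_dfr(names(comparison_sets), function(cmp) {
    purrr::map_dfr(eligible$chemical_id, function(chem) {
      d <- usable[usable$chemical_id == chem, ]
      ab <- comparison_sets[[cmp]](d)
      if (nrow(ab$a) == 0 || nrow(ab$b) == 0) return(NULL)
      res <- compare_groups(ab$a$value_for_stats, ab$b$value_for_stats,
                            ab$a$censored, ab$b$censored,
                            adjusted_alpha = adj$alpha,
                            test_floor = config$test_floor)
      res$comparison <- cmp
      res$chemical_id <- chem
      res[, c("comparison", "chemical_id", "n_a", "n_b",
              "pooled_detection_rate", "eligible", "W", "p_raw",
              "adjusted_alpha", "significant")]
    })
  })

  correlations <- list(
    mother = family_correlation(records[records$chemical_id %in% reported_ids &
                                          !records$batch_dropped, ],
                                parent_role = "mother"),
    father = family_correlation(records[records$chemical_id %in% reported_ids &
                                          !records$batch_dropped, ],
                                parent_role = "father")
  )

  status <- screening$status
  report <- list(
    n_screened = nrow(panel),
    excluded_screening_analytical =
      sum(status$final_status == "excluded_screening_analytical"),
    excluded_screening_rate =
      sum(status$final_status == "excluded_screening_rate"),
    advanced = sum(status$final_status == "advanced"),
    additions = sum(targeted_panel$bypassed_screening),
    targeted_panel_size = nrow(targeted_panel),
    excluded_targeted_qc = sum(!qc$gates$reported),
    reported = length(reported_ids),
    n_eligible_for_tests = n_eligible,
    adjusted_alpha = adj$alpha,
    adjusted_alpha_rounded = adj$alpha_rounded,
    seed = if (!is.null(sim$config)) sim$config$seed else NA_integer_,
    thresholds = unclass(config)[vapply(config, is.numeric, logical(1))]
  )

  structure(
    list(detections = detections, curves = curves, concs = concs,
         screening = screening, targeted_panel = targeted_panel, qc = qc,
         records = records, summary_table = summary_table,
         comparisons = comparisons, correlations = correlations,
         report = report),
    class = "exposcreen_run"
  )
}

#' @export
print.exposcreen_run <- function(x, ...) {
  r <- x$report
  cat("two-step biomonitoring run\n")
  cat(sprintf("  screened: %d chemicals\n", r$n_screened))
  cat(sprintf("  excluded (analytical): %d, excluded (rate): %d, advanced: %d\n",
              r$excluded_screening_analytical, r$excluded_screening_rate,
              r$advanced))
  cat(sprintf("  targeted panel: %d (incl. %d additions)\n",
              r$targeted_panel_size, r$additions))
  cat(sprintf("  excluded by targeted QC: %d, reported: %d\n",
              r$excluded_targeted_qc, r$reported))
  if (!is.na(r$adjusted_alpha)) {
    cat(sprintf("  %d chemicals eligible for tests, adjusted alpha %.4g (%.3f)\n",
                r$n_eligible_for_tests, r$adjusted_alpha,
                r$adjusted_alpha_rounded))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the stage tables as CSV (detections, curves, concentrations,
#' screening ledger, targeted panel, QC gates, LODs, censored records,
#' summary table, comparisons, correlations) plus `report.json`.
#'
#' @param run An `exposcreen_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) readr::write_csv(df, file.path(dir, f))
  wr(run$detections$calls, "detections.csv")
  wr(run$curves, "curves.csv")
  wr(run$screening$ledger, "ledger.csv")
  wr(run$targeted_panel, "panel_targeted.csv")
  wr(run$qc$gates, "qc_gates.csv")
  wr(run$qc$lods, "lods.csv")
  wr(run$qc$records, "concentrations_censored.csv")
  wr(run$summary_table, "summary_table.csv")
  wr(run$comparisons, "comparisons.csv")
  wr(run$correlations$mother, "correlations_mother.csv")
  wr(run$correlations$father, "correlations_father.csv")
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
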