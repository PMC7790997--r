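#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic biomonitoring study: cohort
#' composition (role counts and family-pair counts), exposure
#' distributions (per-chemical geometric mean/SD, age slope, within-family
#' rank correlation), the linear instrument-response model (slope,
#' intercept, multiplicative batch effects, injection CV, additive
#' baseline noise floor), and the per-batch quality-control sample layout
#' (calibration levels, instrument/method blanks, matrix spikes,
#' standard-reference-material aliquots, low-level spikes, donor serum
#' pairs).
#'
#' Defaults reproduce the emulated study design: a 177-subject
#' family-structured cohort (72 probands, 29 unrelated controls, 76
#' parents; 37 mother/father, 33 father/proband and 32 mother/proband
#' pairs), five batches with ten-plus QC samples each, duplicate
#' injections, and six matrix-matched calibration levels spanning four
#' orders of magnitude.
#'
#' @param seed Integer seed; the full simulation is byte-identical under a
#'   fixed seed.
#' @param n_probands,n_controls,n_parents Role counts.
#' @param n_mother_father_pairs,n_father_proband_pairs,n_mother_proband_pairs
#'   Family-pair counts the cohort must realize exactly.
#' @param male_fraction Named fractions for probands and controls
#'   (parents' sex is fixed by the mother/father role).
#' @param age_range Named list of `c(min, max)` ages (years) per role;
#'   ages are uniform on the range.
#' @param panel Chemical panel tibble, see [default_panel()].
#' @param family_correlation Target Spearman correlation between family
#'   members' log exposures, in \[0, 1\].
#' @param batch_effect_sd Log-scale SD of the multiplicative per-batch,
#'   per-chemical instrument sensitivity effect.
#' @param response_cv Multiplicative injection-to-injection CV of the
#'   signal.
#' @param noise_floor Additive baseline noise, in concentration units
#'   (ng/mL): per-chemical vector, a scalar recycled to all chemicals, or
#'   `NULL` for the default `lod_true / 3` (so a 3-SD detection limit
#'   estimate recovers `lod_true`).
#' @param rt_jitter_sd SD (minutes) of retention-time jitter.
#' @param qual_ratio_cv CV of the qualifier/quantifier area ratio.
#' @param shape_reference,shape_cv Reference peak-shape descriptors
#'   (width at half height in minutes, unitless asymmetry) and their CV.
#' @param n_batches Number of analytical batches.
#' @param n_blanks_per_batch,n_spikes_per_batch,n_srm_per_batch,n_low_spikes_per_batch,n_instrument_blanks_per_batch
#'   QC samples per batch.
#' @param n_donor_unspiked,n_donor_spiked Donor serum recovery samples
#'   (placed in batch 1).
#' @param calibration_levels Nominal calibration concentrations, ng/mL.
#' @param contamination Optional named vector (chemical_id -> ng/mL) of a
#'   procedural contamination added to method blanks and study samples,
#'   to exercise the blank-subtraction gate.
#' @param batch_loss Character vector of chemical_ids lost from stored
#'   samples in the final batch (volatile-loss scenario); calibration
#'   standards, prepared fresh, are unaffected.
#' @param interferents Optional named vector (chemical_id -> minutes) of
#'   a retention-time offset applied to study-sample peaks of that
#'   chemical, emulating a misidentified interfering peak.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_probands = 72L, n_controls = 29L, n_parents = 76L,
                             n_mother_father_pairs = 37L,
                             n_father_proband_pairs = 33L,
                             n_mother_proband_pairs = 32L,
                             male_fraction = c(proband = 0.83, control = 0.62),
                             age_range = list(proband = c(3, 14),
                                              control = c(7.4, 17),
                                              parent = c(32, 50.6)),
                             panel = default_panel(),
                             family_correlation = 0.6,
                             batch_effect_sd = 0.1,
                             response_cv = 0.05,
                             noise_floor = NULL,
                             rt_jitter_sd = 0.02,
                             qual_ratio_cv = 0.03,
                             shape_reference = list(width = 0.05, asymmetry = 1.0),
                             shape_cv = 0.05,
                             n_batches = 5L,
                             n_blanks_per_batch = 5L,
                             n_spikes_per_batch = 6L,
                             n_srm_per_batch = 3L,
                             n_low_spikes_per_batch = 2L,
                             n_instrument_blanks_per_batch = 2L,
                             n_donor_unspiked = 2L,
                             n_donor_spiked = 6L,
                             calibration_levels = c(0.005, 0.02, 0.1, 0.5, 2, 10),
                             contamination = NULL,
                             batch_loss = character(0),
                             interferents = NULL) {
  validate_panel(panel)
  counts <- c(n_probands = n_probands, n_controls = n_controls,
              n_parents = n_parents,
              n_mother_father_pairs = n_mother_father_pairs,
              n_father_proband_pairs = n_father_proband_pairs,
              n_mother_proband_pairs = n_mother_proband_pairs,
              n_batches = n_batches)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (family_correlation < 0 || family_correlation > 1) {
    stop("family_correlation must be in [0, 1]", call. = FALSE)
  }
  if (n_batches < 1) stop("need at least one batch", call. = FALSE)
  if (n_instrument_blanks_per_batch < 1) {
    stop("each batch needs at least one instrument blank (the detection ",
         "call compares peak areas to the most recent instrument blank)",
         call. = FALSE)
  }
  if (any(calibration_levels <= 0)) stop("calibration levels must be > 0", call. = FALSE)

  nf <- noise_floor %||% (panel$lod_true / 3)
  if (length(nf) == 1L) nf <- rep(nf, nrow(panel))
  if (length(nf) != nrow(panel)) {
    stop("noise_floor must be scalar or one value per panel chemical", call. = FALSE)
  }
  if (any(nf < 0)) stop("noise_floor must be >= 0", call. = FALSE)

  cfg <- list(
    seed = as.integer(seed),
    n_probands = n_probands, n_controls = n_controls, n_parents = n_parents,
    n_mother_father_pairs = n_mother_father_pairs,
    n_father_proband_pairs = n_father_proband_pairs,
    n_mother_proband_pairs = n_mother_proband_pairs,
    male_fraction = male_fraction, age_range = age_range,
    panel = panel,
    family_correlation = family_correlation,
    batch_effect_sd = batch_effect_sd, response_cv = response_cv,
    noise_floor = nf,
    rt_jitter_sd = rt_jitter_sd, qual_ratio_cv = qual_ratio_cv,
    shape_reference = shape_reference, shape_cv = shape_cv,
    n_batches = as.integer(n_batches),
    n_blanks_per_batch = n_blanks_per_batch,
    n_spikes_per_batch = n_spikes_per_batch,
    n_srm_per_batch = n_srm_per_batch,
    n_low_spikes_per_batch = n_low_spikes_per_batch,
    n_instrument_blanks_per_batch = n_instrument_blanks_per_batch,
    n_donor_unspiked = n_donor_unspiked, n_donor_spiked = n_donor_spiked,
    calibration_levels = calibration_levels,
    contamination = contamination,
    batch_loss = batch_loss,
    interferents = interferents
  )
  # fail early on infeasible family structure
  plan_families(cfg)
  structure(cfg, class = "synthetic_config")
}

# Solve the family structure: a = number of full mother/father/proband
# triads, chosen as the smallest count that fits all three pair counts
# inside n_parents; remaining parents are unpaired singles.
plan_families <- function(config) {
  mf <- config$n_mother_father_pairs
  fp <- config$n_father_proband_pairs
  mp <- config$n_mother_proband_pairs
  a_min <- max(0L, as.integer(ceiling((2 * mf + fp + mp - config$n_parents) / 2)))
  a_max <- min(mf, fp, mp)
  if (a_min > a_max) {
    stop("infeasible family structure: pair counts cannot be realized ",
         "with ", config$n_parents, " parents", call. = FALSE)
  }
  a <- a_min
  singles <- config$n_parents - (2 * mf + fp + mp - 2 * a)
  fam_probands <- fp + mp - a
  if (fam_probands > config$n_probands) {
    stop("infeasible family structure: more parent/proband pairs than probands",
         call. = FALSE)
  }
  list(
    triads = a, mf_only = mf - a, fp_only = fp - a, mp_only = mp - a,
    single_parents = singles, fam_probands = fam_probands,
    solo_probands = config$n_probands - fam_probands
  )
}

#' Generate the synthetic study cohort
#'
#' Builds a subject table realizing the configured role counts and
#' family-pair counts exactly: full mother/father/proband triads first,
#' then the remaining mother/father, father/proband, and mother/proband
#' pairs, then unpaired parents and probands whose relatives were not
#' sampled. Controls are unrelated and carry no family id. Sex is drawn
#' per role (mothers female, fathers male by construction) and ages are
#' uniform on the role's range.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `subject_id`, `role`
#'   (proband/control/mother/father), `family_id` (`NA` for controls),
#'   `age` (years), `sex` ("M"/"F").
#' @export
generate_cohort <- function(config) {
  plan <- plan_families(config)
  set.seed(config$seed + 1L)

  roles <- character(0)
  fams <- character(0)
  fam_counter <- 0L
  add_family <- function(members) {
    fam_counter <<- fam_counter + 1L
    id <- sprintf("F%03d", fam_counter)
    roles <<- c(roles, members)
    fams <<- c(fams, rep(id, length(members)))
  }
  for (i in seq_len(plan$triads)) add_family(c("mother", "father", "proband"))
  for (i in seq_len(plan$mf_only)) add_family(c("mother", "father"))
  for (i in seq_len(plan$fp_only)) add_family(c("father", "proband"))
  for (i in seq_len(plan$mp_only)) add_family(c("mother", "proband"))
  if (plan$single_parents > 0) {
    single_roles <- rep(c("mother", "father"), length.out = plan$single_parents)
    for (r in single_roles) add_family(r)
  }
  for (i in seq_len(plan$solo_probands)) add_family("proband")
  roles <- c(roles, rep("control", config$n_controls))
  fams <- c(fams, rep(NA_character_, config$n_controls))

  n <- length(roles)
  if (n == 0L) {
    return(tibble::tibble(subject_id = character(0), role = character(0),
                          family_id = character(0), age = numeric(0),
                          sex = character(0)))
  }

  age_role <- ifelse(roles %in% c("mother", "father"), "parent", roles)
  lo <- vapply(age_role, function(r) config$age_range[[r]][1], numeric(1))
  hi <- vapply(age_role, function(r) config$age_range[[r]][2], numeric(1))
  age <- runif(n, lo, hi)

  sex <- character(n)
  sex[roles == "mother"] <- "F"
  sex[roles == "father"] <- "M"
  for (r in c("proband", "control")) {
    idx <- which(roles == r)
    if (length(idx) > 0) {
      sex[idx] <- ifelse(rbinom(length(idx), 1, config$male_fraction[[r]]) == 1, "M", "F")
    }
  }

  tibble::tibble(
    subject_id = sprintf("SUB%03d", seq_len(n)),
    role = roles, family_id = fams, age = age, sex = sex
  )
}

#' Generate latent true exposures
#'
#' For each chemical, log concentrations are Gaussian with mean
#' `log(gm) + age_slope * age` and SD `log(gsd)`. Family members share a
#' Gaussian random effect whose variance fraction is set so that two
#' members of the same family reach the target Spearman correlation: for
#' a bivariate normal, `rho_pearson = 2 sin(pi * rho_spearman / 6)`, and
#' the shared-component fraction equals that Pearson correlation.
#' Subjects without a family id get an independent effect of the same
#' size, so every subject has the same marginal distribution.
#'
#' @param subjects Cohort tibble from [generate_cohort()].
#' @param config A [synthetic_config()].
#' @return A tibble `subject_id`, `chemical_id`, `concentration` (ng/mL,
#'   latent truth; strictly positive).
#' @export
generate_true_exposures <- function(subjects, config) {
  set.seed(config$seed + 2L)
  rho_p <- 2 * sin(pi * config$family_correlation / 6)
  fam_key <- ifelse(is.na(subjects$family_id), subjects$subject_id, subjects$family_id)
  fams <- unique(fam_key)
  fam_idx <- match(fam_key, fams)

  purrr::map_dfr(seq_len(nrow(config$panel)), function(i) {
    chem <- config$panel[i, ]
    sigma <- log(chem$gsd)
    b <- rnorm(length(fams), 0, sigma * sqrt(rho_p))
    e <- rnorm(nrow(subjects), 0, sigma * sqrt(1 - rho_p))
    mu <- log(chem$gm) + chem$age_slope * subjects$age
    tibble::tibble(
      subject_id = subjects$subject_id,
      chemical_id = chem$chemical_id,
      concentration = exp(mu + b[fam_idx] + e)
    )
  })
}

# Per-batch acquisition layout. The first acquisition is an instrument
# blank so every later sample has a "most recent" blank to compare to.
layout_batch <- function(config, batch, study_ids) {
  b <- batch
  mk <- function(type, k, prefix) {
    if (k == 0) return(NULL)
    tibble::tibble(
      sample_id = sprintf("B%d_%s%02d", b, prefix, seq_len(k)),
      sample_type = type, subject_id = NA_character_, cal_level = NA_real_
    )
  }
  cal <- tibble::tibble(
    sample_id = sprintf("B%d_CAL%02d", b, seq_along(config$calibration_levels)),
    sample_type = "calibration", subject_id = NA_character_,
    cal_level = config$calibration_levels
  )
  study <- tibble::tibble(
    sample_id = paste0("S_", study_ids), sample_type = "study",
    subject_id = study_ids, cal_level = NA_real_
  )
  ib <- mk("instrument_blank", config$n_instrument_blanks_per_batch, "IB")
  n_study <- nrow(study)
  first_half <- study[seq_len(ceiling(n_study / 2)), ]
  second_half <- study[setdiff(seq_len(n_study), seq_len(ceiling(n_study / 2))), ]
  parts <- list(
    ib[1, ], cal, first_half,
    mk("method_blank", config$n_blanks_per_batch, "MB"),
    mk("matrix_spike", config$n_spikes_per_batch, "MS"),
    if (nrow(ib) > 1) ib[-1, ],
    second_half,
    mk("srm", config$n_srm_per_batch, "SRM"),
    mk("low_spike", config$n_low_spikes_per_batch, "LS")
  )
  if (b == 1L) {
    parts <- c(parts, list(
      mk("donor_unspiked", config$n_donor_unspiked, "DU"),
      mk("donor_spiked", config$n_donor_spiked, "DS")
    ))
  }
  out <- dplyr::bind_rows(parts)
  out$batch <- b
  out$acquisition_index <- seq_len(nrow(out))
  out
}

#' Simulate instrument peak observations
#'
#' Emits duplicate-injection integrated peaks for every study and QC
#' sample in every batch. The response model is
#' `area = slope * conc * batch_effect * (1 + eps) + intercept + eta`,
#' with `eps ~ N(0, response_cv)` per injection, a multiplicative
#' per-chemical, per-batch sensitivity effect `exp(N(0, batch_effect_sd))`,
#' and additive baseline noise `eta ~ N(0, slope * noise_floor)`.
#' Qualifier area is the quantifier times the chemical's true ratio with
#' small noise; retention time gets Gaussian jitter around the expected
#' value. Instrument blanks report a deterministic baseline reference
#' area of `intercept + 3 * slope * noise_floor` (an upper envelope of
#' the integrated baseline). Calibration standards are prepared fresh,
#' so the volatile-loss scenario (`batch_loss`) zeroes stored sample
#' types only.
#'
#' @param exposures Tibble from [generate_true_exposures()].
#' @param subjects Cohort tibble.
#' @param config A [synthetic_config()].
#' @return A list with `samples` (sample metadata: sample_id, batch,
#'   sample_type, subject_id, cal_level, acquisition_index) and `peaks`
#'   (sample_id, chemical_id, injection, rt_min, quant_area, qual_area,
#'   width_half_height, asymmetry).
#' @export
simulate_instrument <- function(exposures, subjects, config) {
  set.seed(config$seed + 3L)
  panel <- config$panel

  # even random assignment of study subjects to batches
  n_sub <- nrow(subjects)
  batch_of <- if (n_sub > 0) {
    sample(rep(seq_len(config$n_batches), length.out = n_sub))
  } else integer(0)

  samples <- purrr::map_dfr(seq_len(config$n_batches), function(b) {
    layout_batch(config, b, subjects$subject_id[batch_of == b])
  })

  # true concentration per sample x chemical
  grid <- tidyr::expand_grid(
    samples[, c("sample_id", "sample_type", "subject_id", "batch", "cal_level")],
    chemical_id = panel$chemical_id
  )
  pi_ <- match(grid$chemical_id, panel$chemical_id)
  exp_key <- paste(grid$subject_id, grid$chemical_id)
  exp_map <- setNames(exposures$concentration,
                      paste(exposures$subject_id, exposures$chemical_id))
  contam <- rep(0, nrow(grid))
  if (!is.null(config$contamination)) {
    hit <- grid$chemical_id %in% names(config$contamination) &
      grid$sample_type %in% c("study", "method_blank")
    contam[hit] <- config$contamination[grid$chemical_id[hit]]
  }
  conc <- dplyr::case_when(
    grid$sample_type == "study" ~ unname(exp_map[exp_key]),
    grid$sample_type == "calibration" ~ grid$cal_level,
    grid$sample_type == "method_blank" ~ 0,
    grid$sample_type == "matrix_spike" ~ panel$spike_nominal[pi_],
    grid$sample_type == "srm" ~ dplyr::coalesce(panel$srm_certified[pi_], 0),
    grid$sample_type == "low_spike" ~ panel$low_spike_nominal[pi_],
    grid$sample_type == "donor_unspiked" ~ panel$donor_base[pi_],
    grid$sample_type == "donor_spiked" ~ panel$donor_base[pi_] + panel$spike_nominal[pi_],
    grid$sample_type == "instrument_blank" ~ 0
  )
  conc <- conc + contam
  # volatile loss: stored samples in the final batch lose the chemical
  if (length(config$batch_loss) > 0) {
    lost <- grid$chemical_id %in% config$batch_loss &
      grid$batch == config$n_batches &
      grid$sample_type != "calibration"
    conc[lost] <- 0
  }
  grid$true_conc <- conc

  batch_mult <- matrix(
    exp(rnorm(nrow(panel) * config$n_batches, 0, config$batch_effect_sd)),
    nrow = nrow(panel)
  )

  peaks <- purrr::map_dfr(1:2, function(inj) {
    n <- nrow(grid)
    slope <- panel$response_slope[pi_]
    intercept <- panel$response_intercept[pi_]
    nf <- config$noise_floor[pi_]
    mult <- batch_mult[cbind(pi_, grid$batch)]
    eps <- rnorm(n, 0, config$response_cv)
    eta <- rnorm(n, 0, slope * nf)
    area <- pmax(0, slope * grid$true_conc * mult * (1 + eps) + intercept + eta)
    is_ib <- grid$sample_type == "instrument_blank"
    area[is_ib] <- intercept[is_ib] + 3 * slope[is_ib] * nf[is_ib]
    ratio_noise <- 1 + rnorm(n, 0, config$qual_ratio_cv)
    qual <- ifelse(is.na(panel$qual_transition[pi_]), NA_real_,
                   pmax(0, area * panel$reference_qual_ratio[pi_] * ratio_noise))
    rt <- panel$expected_rt[pi_] + rnorm(n, 0, config$rt_jitter_sd)
    if (!is.null(config$interferents)) {
      hit <- grid$chemical_id %in% names(config$interferents) &
        grid$sample_type == "study"
      rt[hit] <- rt[hit] + config$interferents[grid$chemical_id[hit]]
    }
    tibble::tibble(
      sample_id = grid$sample_id,
      chemical_id = grid$chemical_id,
      injection = inj,
      rt_min = rt,
      quant_area = area,
      qual_area = qual,
      width_half_height = config$shape_reference$width *
        (1 + rnorm(n, 0, config$shape_cv)),
      asymmetry = config$shape_reference$asymmetry *
        (1 + rnorm(n, 0, config$shape_cv))
    )
  })
  peaks <- dplyr::arrange(peaks, .data$sample_id, .data$chemical_id, .data$injection)

  list(samples = samples, peaks = peaks)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_true_exposures()] and [simulate_instrument()].
#'
#' @param config A [synthetic_config()].
#' @return A list of class `exposcreen_sim` with elements `config`,
#'   `panel`, `subjects`, `exposures`, `samples`, `peaks`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  subjects <- generate_cohort(config)
  exposures <- generate_true_exposures(subjects, config)
  instr <- simulate_instrument(exposures, subjects, config)
  structure(
    list(config = config, panel = config$panel, subjects = subjects,
         exposures = exposures, samples = instr$samples, peaks = instr$peaks),
    class = "exposcreen_sim"
  )
}

#' Write a simulated study to plain-text files
#'
#' Writes `subjects.csv`, `panel.csv`, `samples.csv`, `peaks.csv`,
#' `truth.csv` (the latent exposures, for tests only) and `config.txt`
#' (scalar settings echoed as key-value lines).
#'
#' @param sim An `exposcreen_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(sim$panel, file.path(dir, "panel.csv"))
  readr::write_csv(sim$samples, file.path(dir, "samples.csv"))
  readr::write_csv(sim$peaks, file.path(dir, "peaks.csv"))
  readr::write_csv(sim$exposures, file.path(dir, "truth.csv"))
  cfg <- sim$config
  scalars <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) <= 10, logical(1))]
  lines <- vapply(names(scalars), function(nm) {
    paste0(nm, " = ", paste(scalars[[nm]], collapse = ", "))
  }, character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a simulated study back from disk
#'
#' @param dir Directory written by [write_simulation()].
#' @param config Optional `synthetic_config` to attach (thresholds and
#'   reference shapes are not round-tripped through `config.txt`).
#' @return An `exposcreen_sim` list (without `config` unless supplied).
#' @export
read_simulation <- function(dir, config = NULL) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  structure(
    list(config = config, panel = rd("panel.csv"), subjects = rd("subjects.csv"),
         exposures = rd("truth.csv"), samples = rd("samples.csv"),
         peaks = rd("peaks.csv")),
    class = "exposcreen_sim"
  )
}
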