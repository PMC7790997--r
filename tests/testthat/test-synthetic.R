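test_that("default cohort realizes the study's role and family-pair counts", {
  cfg <- synthetic_config(seed = 1)
  sub <- generate_cohort(cfg)

  expect_equal(nrow(sub), 177)
  expect_equal(sum(sub$role == "proband"), 72)
  expect_equal(sum(sub$role == "control"), 29)
  expect_equal(sum(sub$role %in% c("mother", "father")), 76)

  pairs <- function(r1, r2) {
    f1 <- sub$family_id[sub$role == r1]
    f2 <- sub$family_id[sub$role == r2]
    length(intersect(f1[!is.na(f1)], f2[!is.na(f2)]))
  }
  expect_equal(pairs("mother", "father"), 37)
  expect_equal(pairs("father", "proband"), 33)
  expect_equal(pairs("mother", "proband"), 32)

  # at most one of each role per family
  per_fam <- table(sub$family_id[!is.na(sub$family_id)], sub$role[!is.na(sub$family_id)])
  expect_true(all(per_fam <= 1))
  # controls are unrelated
  expect_true(all(is.na(sub$family_id[sub$role == "control"])))
  # ages within role ranges
  kids <- sub$role %in% c("proband", "control")
  expect_true(all(sub$age[!kids] >= 32 & sub$age[!kids] <= 50.6))
})

test_that("cohort edge cases: empty, forced structure, infeasible", {
  empty <- synthetic_config(seed = 1, n_probands = 0, n_controls = 0,
                            n_parents = 0, n_mother_father_pairs = 0,
                            n_father_proband_pairs = 0,
                            n_mother_proband_pairs = 0)
  expect_equal(nrow(generate_cohort(empty)), 0)

  forced <- synthetic_config(seed = 1, n_probands = 2, n_controls = 0,
                             n_parents = 2, n_mother_father_pairs = 0,
                             n_father_proband_pairs = 0,
                             n_mother_proband_pairs = 2)
  sub <- generate_cohort(forced)
  expect_equal(nrow(sub), 4)
  expect_equal(length(unique(sub$family_id)), 2)
  per_fam <- table(sub$family_id, sub$role)
  expect_true(all(per_fam[, "mother"] == 1) && all(per_fam[, "proband"] == 1))

  # more mother/proband pairs than probands
  expect_error(
    synthetic_config(seed = 1, n_probands = 1, n_parents = 4,
                     n_mother_father_pairs = 0, n_father_proband_pairs = 0,
                     n_mother_proband_pairs = 2),
    "infeasible"
  )
})

test_that("exposures are exactly the geometric mean in the degenerate case", {
  pan <- default_panel(2)
  pan$gsd <- 1
  pan$age_slope <- 0
  cfg <- small_config(panel = pan)
  sub <- generate_cohort(cfg)
  exp_ <- generate_true_exposures(sub, cfg)
  for (i in 1:2) {
    vals <- exp_$concentration[exp_$chemical_id == pan$chemical_id[i]]
    expect_equal(vals, rep(pan$gm[i], nrow(sub)))
  }
})

test_that("zero family correlation yields near-zero parent-child rank correlation", {
  # 500 mother/proband families, independence within families
  pan <- default_panel(1)
  cfg <- synthetic_config(seed = 12, panel = pan,
                          n_probands = 500, n_controls = 0, n_parents = 500,
                          n_mother_father_pairs = 0,
                          n_father_proband_pairs = 0,
                          n_mother_proband_pairs = 500,
                          family_correlation = 0)
  sub <- generate_cohort(cfg)
  exp_ <- generate_true_exposures(sub, cfg)
  df <- merge(exp_, sub[, c("subject_id", "role", "family_id")])
  kid <- df[df$role == "proband", c("family_id", "concentration")]
  mom <- df[df$role == "mother", c("family_id", "concentration")]
  m <- merge(kid, mom, by = "family_id")
  rho <- cor(m$concentration.x, m$concentration.y, method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("a positive age slope makes adult exposures exceed children's", {
  pan <- default_panel(1)
  pan$age_slope <- 0.025
  cfg <- synthetic_config(seed = 3, panel = pan)
  # large synthetic population: 5000 children at age 8, 5000 adults at 41
  sub <- tibble::tibble(
    subject_id = sprintf("X%05d", 1:10000),
    role = rep(c("proband", "mother"), each = 5000),
    family_id = NA_character_,
    age = rep(c(8, 41), each = 5000),
    sex = "F"
  )
  exp_ <- generate_true_exposures(sub, cfg)
  med <- tapply(exp_$concentration, sub$role[match(exp_$subject_id, sub$subject_id)], median)
  expect_gt(med[["mother"]], med[["proband"]])
})

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_study(small_config(seed = 21))
  s2 <- simulate_study(small_config(seed = 21))
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$exposures, s2$exposures)
  expect_identical(s1$peaks, s2$peaks)
  s3 <- simulate_study(small_config(seed = 22))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("batch structure matches the configuration", {
  cfg <- small_config(seed = 9)
  sim <- simulate_study(cfg)
  s <- sim$samples
  expect_equal(sort(unique(s$batch)), 1:2)
  # study samples spread as evenly as possible
  study_sizes <- table(s$batch[s$sample_type == "study"])
  expect_lte(diff(range(study_sizes)), 1)
  expect_equal(sum(study_sizes), 30)
  # QC counts exact per batch
  for (b in 1:2) {
    sb <- s[s$batch == b, ]
    expect_equal(sum(sb$sample_type == "method_blank"), cfg$n_blanks_per_batch)
    expect_equal(sum(sb$sample_type == "matrix_spike"), cfg$n_spikes_per_batch)
    expect_equal(sum(sb$sample_type == "srm"), cfg$n_srm_per_batch)
    expect_equal(sum(sb$sample_type == "calibration"),
                 length(cfg$calibration_levels))
    expect_equal(sum(sb$sample_type == "low_spike"), cfg$n_low_spikes_per_batch)
  }
  # duplicate injections for every sample x chemical
  inj <- table(paste(sim$peaks$sample_id, sim$peaks$chemical_id))
  expect_true(all(inj == 2))
})

test_that("noiseless areas are exactly slope * concentration", {
  pan <- default_panel(3)
  pan$response_intercept <- 0
  cfg <- noiseless_config(panel = pan, batch_effect_sd = 0)
  sim <- simulate_study(cfg)
  cal <- sim$samples[sim$samples$sample_type == "calibration", ]
  pk <- merge(sim$peaks, cal[, c("sample_id", "cal_level")])
  slope <- pan$response_slope[match(pk$chemical_id, pan$chemical_id)]
  expect_equal(pk$quant_area, slope * pk$cal_level, tolerance = 1e-12)
  # method blanks are intercept-only baselines (zero here)
  mb <- sim$samples$sample_id[sim$samples$sample_type == "method_blank"]
  expect_true(all(sim$peaks$quant_area[sim$peaks$sample_id %in% mb] == 0))
})

test_that("calibration round-trips through its own curve in the noiseless limit", {
  sim <- simulate_study(noiseless_config())
  run <- run_pipeline(sim)
  cal_samples <- sim$samples[sim$samples$sample_type == "calibration", ]
  df <- merge(run$concs[run$concs$sample_type == "calibration", ],
              cal_samples[, c("sample_id", "cal_level")])
  df <- df[!is.na(df$conc_mean), ]
  expect_gt(nrow(df), 0)
  expect_true(all(abs(df$conc_mean - df$cal_level) / df$cal_level < 1e-6))
})

test_that("simulation round-trips through CSV files", {
  sim <- simulate_study(small_config(seed = 13, panel = default_panel(3)))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("subjects.csv", "panel.csv", "samples.csv", "peaks.csv",
           "truth.csv", "config.txt")
  ))))
  back <- read_simulation(dir, config = sim$config)
  expect_equal(as.data.frame(back$peaks), as.data.frame(sim$peaks),
               tolerance = 1e-12)
  expect_equal(back$subjects$subject_id, sim$subjects$subject_id)
})

test_that("volatile-loss scenario zeroes stored samples in the last batch only", {
  pan <- default_panel(3)
  cfg <- noiseless_config(panel = pan, batch_loss = "C02")
  sim <- simulate_study(cfg)
  lost_batch <- cfg$n_batches
  spikes <- sim$samples[sim$samples$sample_type == "matrix_spike", ]
  pk <- merge(sim$peaks[sim$peaks$chemical_id == "C02", ],
              spikes[, c("sample_id", "batch")])
  # spikes in the lost batch are baseline-only; earlier batches carry signal
  expect_true(all(pk$quant_area[pk$batch == lost_batch] ==
                    pan$response_intercept[2]))
  expect_true(all(pk$quant_area[pk$batch < lost_batch] >
                    pan$response_intercept[2]))
  # calibration standards (prepared fresh) keep their signal in that batch
  cal <- sim$samples[sim$samples$sample_type == "calibration" &
                       sim$samples$batch == lost_batch, ]
  pc <- merge(sim$peaks[sim$peaks$chemical_id == "C02", ],
              cal[, c("sample_id", "cal_level")])
  expect_true(all(pc$quant_area > pan$response_intercept[2]))
})

test_that("interferent injector shifts study-sample retention times out of window", {
  cfg <- noiseless_config(panel = default_panel(2),
                          interferents = c(C01 = 0.3))
  sim <- simulate_study(cfg)
  study_ids <- sim$samples$sample_id[sim$samples$sample_type == "study"]
  pk <- sim$peaks[sim$peaks$chemical_id == "C01" &
                    sim$peaks$sample_id %in% study_ids, ]
  expect_true(all(abs(pk$rt_min - default_panel(2)$expected_rt[1]) > 0.1))
  run <- run_pipeline(sim)
  calls <- run$detections$calls
  c01 <- calls[calls$chemical_id == "C01" & calls$sample_type == "study", ]
  expect_true(all(!c01$detected))
})
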