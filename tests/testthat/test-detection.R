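test_that("detection call requires all four criteria", {
  # all criteria comfortably satisfied
  ok <- call_detection(reference_peak(rt = 10.05, quant = 1000, qual = 525),
                       reference_target(), instrument_blank_area = 100,
                       reference_shape = ref_shape)
  expect_true(ok$detected)
  expect_equal(ok$criterion_rt, "pass")

  # retention time 0.15 min off: only the RT criterion fails
  rt_off <- call_detection(reference_peak(rt = 10.15), reference_target(),
                           instrument_blank_area = 100,
                           reference_shape = ref_shape)
  expect_false(rt_off$detected)
  expect_equal(rt_off$criterion_rt, "fail")
  expect_equal(rt_off$criterion_blank, "pass")

  # qualifier ratio 25% off
  ratio_off <- call_detection(reference_peak(qual = 1000 * 0.5 * 1.25),
                              reference_target(), instrument_blank_area = 100,
                              reference_shape = ref_shape)
  expect_false(ratio_off$detected)
  expect_equal(ratio_off$criterion_ratio, "fail")
})

test_that("boundary conventions: inclusive windows, strict blank comparison", {
  # RT exactly 0.1 min off passes, on both sides (two-sided window)
  for (rt in c(10.1, 9.9)) {
    r <- call_detection(reference_peak(rt = rt), reference_target(),
                        instrument_blank_area = 100, reference_shape = ref_shape)
    expect_true(r$detected)
  }
  up <- call_detection(reference_peak(rt = 10.1), reference_target(),
                       instrument_blank_area = 100, reference_shape = ref_shape)
  dn <- call_detection(reference_peak(rt = 9.9), reference_target(),
                       instrument_blank_area = 100, reference_shape = ref_shape)
  expect_identical(up$detected, dn$detected)

  # ratio exactly 20% off passes
  r20 <- call_detection(reference_peak(qual = 1000 * 0.5 * 1.2),
                        reference_target(), instrument_blank_area = 100,
                        reference_shape = ref_shape)
  expect_true(r20$detected)
  expect_equal(r20$criterion_ratio, "pass")

  # area exactly equal to the blank fails ("above" is strict)
  eq <- call_detection(reference_peak(quant = 100, qual = 50),
                       reference_target(), instrument_blank_area = 100,
                       reference_shape = ref_shape)
  expect_false(eq$detected)
  expect_equal(eq$criterion_blank, "fail")
})

test_that("chemicals without a qualifier skip the ratio criterion", {
  r <- call_detection(reference_peak(qual = NA_real_),
                      reference_target(qual = FALSE),
                      instrument_blank_area = 100, reference_shape = ref_shape)
  expect_true(r$detected)
  expect_equal(r$criterion_ratio, "not_applicable")
})

test_that("missing expected RT or instrument blank is an error", {
  expect_error(
    call_detection(reference_peak(), reference_target(rt = NA_real_),
                   instrument_blank_area = 100, reference_shape = ref_shape),
    "retention time"
  )
  expect_error(
    call_detection(reference_peak(), reference_target(),
                   instrument_blank_area = NA_real_,
                   reference_shape = ref_shape),
    "blank"
  )
})

test_that("shape similarity: identity, closed form, limits, invalid widths", {
  expect_equal(shape_similarity(0.05, 1, 0.05, 1), 1.0)
  # width double the reference: 100% relative deviation -> exp(-1/2)
  expect_equal(shape_similarity(0.10, 1, 0.05, 1), exp(-0.5))
  # divergent width drives the score to zero
  expect_lt(shape_similarity(5, 1, 0.05, 1), 1e-10)
  expect_error(shape_similarity(-0.01, 1, 0.05, 1), "width")
})

test_that("increasing quantifier area never turns a detect into a non-detect", {
  set.seed(401)
  for (i in 1:50) {
    blank <- runif(1, 50, 500)
    rt <- 10 + runif(1, -0.15, 0.15)
    width <- 0.05 * exp(runif(1, -0.5, 0.5))
    areas <- sort(runif(5, 10, 5000))
    ratio_true <- 0.5 * (1 + runif(1, -0.3, 0.3))
    det <- vapply(areas, function(a) {
      call_detection(
        reference_peak(rt = rt, quant = a, qual = a * ratio_true, width = width),
        reference_target(), instrument_blank_area = blank,
        reference_shape = ref_shape
      )$detected
    }, logical(1))
    # once detected, larger areas stay detected
    expect_true(all(diff(det) >= 0))
  }
})

test_that("detection call agrees with an independent one-expression oracle", {
  set.seed(402)
  for (i in 1:100) {
    p <- reference_peak(
      rt = 10 + runif(1, -0.2, 0.2),
      quant = runif(1, 10, 2000),
      qual = runif(1, 10, 1500),
      width = runif(1, 0.02, 0.15),
      asym = runif(1, 0.5, 2)
    )
    blank <- runif(1, 50, 800)
    got <- call_detection(p, reference_target(), instrument_blank_area = blank,
                          reference_shape = ref_shape)$detected
    want <- (abs(p$rt_min - 10) <= 0.1) &
      (p$quant_area > blank) &
      (exp(-(((p$width_half_height - 0.05) / 0.05)^2 +
               ((p$asymmetry - 1) / 1)^2) / 2) >= 0.6) &
      (abs(p$qual_area / p$quant_area / 0.5 - 1) <= 0.2)
    expect_identical(got, want)
  }
})

test_that("detection rate is detects over study samples", {
  calls <- tibble::tibble(
    chemical_id = "C01",
    sample_id = sprintf("S%02d", 1:69),
    detected = c(rep(TRUE, 25), rep(FALSE, 44))
  )
  r <- detection_rate(calls)
  expect_equal(r, 25 / 69)
  expect_equal(round(100 * r), 36)
  expect_equal(detection_rate(dplyr::mutate(calls, detected = FALSE)), 0)
  expect_equal(detection_rate(dplyr::mutate(calls, detected = TRUE)), 1)
  expect_error(detection_rate(calls[0, ]), "no study samples")
  expect_error(detection_rate(dplyr::mutate(calls, chemical_id = sample_id)),
               "single chemical")
})

test_that("the most recent preceding instrument blank is used", {
  samples <- tibble::tibble(
    sample_id = c("IB1", "A", "IB2", "B"),
    batch = 1L,
    sample_type = c("instrument_blank", "study", "instrument_blank", "study"),
    subject_id = NA_character_, cal_level = NA_real_,
    acquisition_index = 1:4
  )
  mkpeak <- function(id, area) tibble::tibble(
    sample_id = id, chemical_id = "C01", injection = 1L, rt_min = 10,
    quant_area = area, qual_area = area * 0.5,
    width_half_height = 0.05, asymmetry = 1
  )
  peaks <- dplyr::bind_rows(
    mkpeak("IB1", 100), mkpeak("A", 150), mkpeak("IB2", 200), mkpeak("B", 150)
  )
  panel <- tibble::tibble(
    chemical_id = "C01", expected_rt = 10, qual_transition = "a>b",
    reference_qual_ratio = 0.5
  )
  det <- detect_peaks(peaks, samples, panel, reference_shape = ref_shape)
  calls <- det$calls
  # A (area 150) is above IB1 (100): detected; B compares to IB2 (200): not
  expect_true(calls$detected[calls$sample_id == "S_A" | calls$sample_id == "A"][1])
  expect_false(calls$detected[calls$sample_id == "B"])
})
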