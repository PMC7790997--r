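mk_records <- function(values, censored, lod = 0.03) {
  tibble::tibble(
    conc_mean = ifelse(censored, NA_real_, values),
    censored = censored,
    value_for_stats = ifelse(censored, lod / sqrt(2), values)
  )
}

test_that("group summaries follow the detection-rate-conditional rules", {
  # high detection: both median and maximum reported
  set.seed(61)
  hi <- mk_records(rlnorm(100, log(0.27), 0.5), c(TRUE, rep(FALSE, 99)))
  s1 <- summarize_group(hi, "children")
  expect_equal(s1$detection_rate, 0.99)
  expect_false(is.na(s1$median))
  expect_false(is.na(s1$maximum))

  # 28% detects: median suppressed, maximum still reported
  lo <- mk_records(rlnorm(100, log(0.05), 0.5),
                   c(rep(FALSE, 28), rep(TRUE, 72)))
  s2 <- summarize_group(lo, "children")
  expect_equal(s2$detection_rate, 0.28)
  expect_true(is.na(s2$median))
  expect_equal(s2$median_label, "<LOD")
  expect_false(is.na(s2$maximum))

  # zero detects: both suppressed
  none <- mk_records(rep(0.01, 20), rep(TRUE, 20))
  s3 <- summarize_group(none, "adults")
  expect_equal(s3$median_label, "<LOD")
  expect_equal(s3$maximum_label, "<LOD")

  # exactly 50% detects reports no median (strict "> 50%")
  half <- mk_records(rlnorm(20, 0, 0.3), rep(c(TRUE, FALSE), 10))
  expect_true(is.na(summarize_group(half, "all")$median))

  expect_error(summarize_group(hi[0, ], "all"), "empty")
})

test_that("summaries are invariant to sample order", {
  set.seed(62)
  rec <- mk_records(rlnorm(50, 0, 1), rbinom(50, 1, 0.3) == 1)
  s1 <- summarize_group(rec, "all")
  s2 <- summarize_group(rec[sample.int(50), ], "all")
  expect_equal(s1, s2)
})

test_that("Bonferroni construction matches the published arithmetic", {
  a23 <- bonferroni_alpha(0.05, 23)
  expect_equal(a23$alpha, 0.05 / 23)
  expect_equal(a23$alpha_rounded, 0.002)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)
  expect_equal(bonferroni_alpha(0.05, 50)$alpha, 0.001)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("rank-sum test: identical samples, tiny-sample exact case", {
  same <- rank_sum_test(rep(1, 5), rep(1, 5))
  expect_equal(same$p, 1)

  # 3 vs 3 fully separated: the most extreme of choose(6,3)=20 splits,
  # two-sided p = 2/20
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact_enumeration")
})

test_that("exact p-values agree with wilcox.test on tie-free data", {
  set.seed(63)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    got <- rank_sum_test(x, y)$p
    want <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("exact p-values with ties match an independent enumeration oracle", {
  # oracle: enumerate index subsets via combinations of positions written
  # independently of the implementation (recursive index walk)
  oracle_p <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x); n <- length(r)
    idx <- utils::combn(n, n1)
    w_obs <- sum(r[seq_len(n1)])
    w_all <- apply(idx, 2, function(j) sum(r[j]))
    min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
  }
  set.seed(64)
  for (i in 1:15) {
    # heavy ties from censoring-style substitution
    x <- sample(c(0.02, 0.02, 0.02, round(rlnorm(5, -2, 1), 2)), 6)
    y <- sample(c(0.02, 0.02, round(rlnorm(6, -2, 1), 2)), 7)
    expect_equal(rank_sum_test(x, y)$p, oracle_p(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample p uses the tie-corrected normal approximation", {
  set.seed(65)
  x <- rlnorm(40); y <- rlnorm(45) * 1.5
  got <- rank_sum_test(x, y)
  expect_equal(got$method, "normal_ties")
  want <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p, want, tolerance = 1e-9)
})

test_that("group comparison enforces the 30% pooled-detects floor", {
  set.seed(66)
  a <- rlnorm(20); b <- rlnorm(20)
  low <- compare_groups(a, b, censored_a = rep(TRUE, 20),
                        censored_b = c(rep(TRUE, 12), rep(FALSE, 8)),
                        adjusted_alpha = 0.002)
  expect_false(low$eligible)
  expect_true(is.na(low$p_raw))

  ok <- compare_groups(a, b, censored_a = rep(FALSE, 20),
                       censored_b = rep(FALSE, 20), adjusted_alpha = 0.002)
  expect_true(ok$eligible)
  expect_false(is.na(ok$p_raw))

  # raising the floor never adds chemicals to the test set
  rates <- runif(50)
  eligible_30 <- rates >= 0.30
  eligible_50 <- rates >= 0.50
  expect_true(all(which(eligible_50) %in% which(eligible_30)))
})

test_that("a 2x shift at n=100 per group is significant at the adjusted cut-off", {
  # power check: adults vs children with a doubled median
  set.seed(67)
  hits <- mean(replicate(50, {
    a <- rlnorm(100, log(0.2), 0.8)
    b <- rlnorm(100, log(0.1), 0.8)
    rank_sum_test(a, b)$p < 0.002
  }))
  expect_gte(hits, 0.95)
})

test_that("family correlation matrix: identity, nulls, sparse cells", {
  fam <- sprintf("F%03d", 1:40)
  vals <- rlnorm(40, 0, 1)
  rec <- dplyr::bind_rows(
    tibble::tibble(subject_id = paste0("K", 1:40), chemical_id = "C01",
                   value_for_stats = vals, role = "proband", family_id = fam),
    tibble::tibble(subject_id = paste0("M", 1:40), chemical_id = "C01",
                   value_for_stats = vals, role = "mother", family_id = fam)
  )
  fc <- family_correlation(rec, "mother")
  expect_equal(fc$rho[fc$child_chemical == "C01"], 1)
  expect_equal(fc$n, 40)

  # independent child/parent values: small average |rho| over 500 pairs
  set.seed(68)
  fam2 <- sprintf("F%03d", 1:500)
  rec2 <- dplyr::bind_rows(
    tibble::tibble(subject_id = paste0("K", 1:500), chemical_id = "C01",
                   value_for_stats = rlnorm(500), role = "proband",
                   family_id = fam2),
    tibble::tibble(subject_id = paste0("M", 1:500), chemical_id = "C01",
                   value_for_stats = rlnorm(500), role = "mother",
                   family_id = fam2)
  )
  expect_lt(abs(family_correlation(rec2, "mother")$rho), 0.15)

  # fewer than the minimum pairs: missing, not zero
  fc3 <- family_correlation(rec[c(1:3, 41:43), ], "mother")
  expect_true(is.na(fc3$rho))
  expect_equal(fc3$n, 3)
})

test_that("reference ratios reproduce every printed comparison cell", {
  tab <- nhanes_adult_medians()
  got <- reference_ratio(tab$study_median_ng_ml, tab$nhanes_median_ng_ml)
  printed <- tab$printed_ratio
  expect_equal(got[!is.na(printed)], printed[!is.na(printed)])
  # spot values
  expect_equal(reference_ratio(0.0468, 0.0081), 5.8)
  expect_equal(reference_ratio(0.564, 1.24), 0.5)
  expect_equal(reference_ratio(1, 1), 1.0)
  expect_true(is.na(reference_ratio(0.5, NA)))
  expect_true(is.na(reference_ratio(0.5, 0)))
})
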