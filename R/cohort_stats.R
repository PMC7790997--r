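#' Summarize one chemical for one reporting group
#'
#' Detection-rate-conditional summary: the detection rate is the
#' fraction of samples above the LOD (not censored); the median is taken
#' over `value_for_stats` (substituted values included) and reported only
#' when the detection rate is strictly above `median_floor` (default
#' 50%), otherwise `<LOD`; the maximum is over uncensored values and is
#' `<LOD` when there are none.
#'
#' @param records Concentration records for one chemical and one group:
#'   tibble with `censored`, `value_for_stats`, `conc_mean`.
#' @param group Group label (children/adults/probands/controls/all).
#' @param median_floor Detection-rate floor for reporting a median
#'   (fraction, default 0.5, strict).
#' @return One-row tibble: `group`, `n`, `detection_rate` (fraction),
#'   `median` (ng/mL, `NA` when below the floor), `maximum` (ng/mL, `NA`
#'   when no detects), and display labels `median_label`,
#'   `maximum_label`.
#' @export
summarize_group <- function(records, group, median_floor = 0.5) {
  if (nrow(records) == 0) stop("empty group", call. = FALSE)
  rate <- mean(!records$censored)
  med <- if (rate > median_floor) median(records$value_for_stats) else NA_real_
  detects <- records$conc_mean[!records$censored]
  mx <- if (length(detects) > 0) max(detects) else NA_real_
  lab <- function(x) if (is.na(x)) "<LOD" else format(report_signif(x))
  tibble::tibble(
    group = group, n = nrow(records), detection_rate = rate,
    median = med, maximum = mx,
    median_label = lab(med), maximum_label = lab(mx)
  )
}

#' Bonferroni-adjusted significance cut-off
#'
#' Initial cut-off `alpha0` divided by the number of chemicals eligible
#' for testing, reported both at full precision and at the conventional
#' 3-decimal rounding.
#'
#' @param alpha0 Initial p-value cut-off (default 0.05).
#' @param n_eligible Number of eligible chemicals (>= 1).
#' @return List with `alpha` (full precision) and `alpha_rounded`
#'   (3 decimals).
#' @export
bonferroni_alpha <- function(alpha0 = 0.05, n_eligible) {
  stopifnot_scalar_number(n_eligible, "n_eligible", min = 1)
  a <- alpha0 / n_eligible
  list(alpha = a, alpha_rounded = round_half_up(a, 3))
}

#' Two-sided Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Rank-sum test on midranks. When both groups have at most
#' `exact_max_n` observations the p-value is computed by exact
#' enumeration of all assignments of the pooled (mid)ranks to the two
#' groups, `p = min(1, 2 min(P(W <= w), P(W >= w)))`; otherwise a
#' tie-corrected normal approximation with continuity correction is
#' used. Substituted censored values tie at LOD/sqrt(2) and are handled
#' by the midranks.
#'
#' @param x,y Numeric samples.
#' @param exact_max_n Largest per-group size for exact enumeration
#'   (default 8).
#' @return List with `W` (rank sum of `x`), `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max_n = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    sums <- utils::combn(n, n1, FUN = function(idx) sum(r[idx]))
    eps <- 1e-9
    p_le <- mean(sums <= w + eps)
    p_ge <- mean(sums >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(W = w, p = p, method = "exact_enumeration"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(W = w, p = 1, method = "normal_ties"))
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(W = w, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal_ties")
}

#' Compare a chemical between two groups
#'
#' Two-sided Wilcoxon rank-sum test on `value_for_stats` (substituted
#' values included), run only when the chemical is eligible: pooled
#' detection rate at or above `test_floor` (default 30%). Significance
#' is judged against the supplied Bonferroni-adjusted cut-off.
#'
#' @param values_a,values_b `value_for_stats` for the two groups.
#' @param censored_a,censored_b Censoring flags for the two groups.
#' @param adjusted_alpha Significance cut-off (from [bonferroni_alpha()]).
#' @param test_floor Pooled detection-rate eligibility floor (fraction).
#' @return One-row tibble: group sizes, pooled detection rate,
#'   `eligible`, `W`, `p_raw`, `adjusted_alpha`, `significant`.
#' @export
compare_groups <- function(values_a, values_b, censored_a, censored_b,
                           adjusted_alpha = 0.05, test_floor = 0.3) {
  pooled_rate <- mean(!c(censored_a, censored_b))
  eligible <- pooled_rate >= test_floor
  if (!eligible) {
    return(tibble::tibble(
      n_a = length(values_a), n_b = length(values_b),
      pooled_detection_rate = pooled_rate, eligible = FALSE,
      W = NA_real_, p_raw = NA_real_, adjusted_alpha = adjusted_alpha,
      significant = NA
    ))
  }
  ts <- rank_sum_test(values_a, values_b)
  tibble::tibble(
    n_a = length(values_a), n_b = length(values_b),
    pooled_detection_rate = pooled_rate, eligible = TRUE,
    W = ts$W, p_raw = ts$p, adjusted_alpha = adjusted_alpha,
    significant = ts$p < adjusted_alpha
  )
}

#' Parent-child Spearman correlation matrix
#'
#' Spearman correlations between children's and one parent role's
#' chemical concentrations (`value_for_stats`), paired by family id,
#' over a full child-chemical x parent-chemical grid. Cells with fewer
#' than `min_pairs` complete pairs are missing, not zero. Diagonal cells
#' are same-chemical pairs.
#'
#' @param records Concentration records joined to subjects: tibble with
#'   `subject_id`, `chemical_id`, `value_for_stats`, `role`, `family_id`.
#' @param parent_role `"mother"` or `"father"`.
#' @param child_roles Roles counted as children (default proband).
#' @param min_pairs Minimum complete pairs per cell (default 5).
#' @return Long tibble: `child_chemical`, `parent_chemical`, `rho`, `n`.
#' @export
family_correlation <- function(records, parent_role = c("mother", "father"),
                               child_roles = "proband", min_pairs = 5) {
  parent_role <- match.arg(parent_role)
  kids <- records[records$role %in% child_roles & !is.na(records$family_id), ]
  pars <- records[records$role == parent_role & !is.na(records$family_id), ]
  chems <- sort(unique(records$chemical_id))
  grid <- tidyr::expand_grid(child_chemical = chems, parent_chemical = chems)
  purrr::pmap_dfr(grid, function(child_chemical, parent_chemical) {
    k <- kids[kids$chemical_id == child_chemical,
              c("family_id", "value_for_stats")]
    p <- pars[pars$chemical_id == parent_chemical,
              c("family_id", "value_for_stats")]
    m <- dplyr::inner_join(k, p, by = "family_id", suffix = c("_child", "_parent"))
    m <- m[complete.cases(m), ]
    constant <- length(unique(m$value_for_stats_child)) < 2 ||
      length(unique(m$value_for_stats_parent)) < 2
    if (nrow(m) < min_pairs || constant) {
      # too few pairs, or a constant vector (e.g. fully censored chemical):
      # correlation undefined, cell is missing
      return(tibble::tibble(child_chemical = child_chemical,
                            parent_chemical = parent_chemical,
                            rho = NA_real_, n = nrow(m)))
    }
    tibble::tibble(
      child_chemical = child_chemical, parent_chemical = parent_chemical,
      rho = cor(m$value_for_stats_child, m$value_for_stats_parent,
                method = "spearman"),
      n = nrow(m)
    )
  })
}

#' Ratio of a study median to a reference median
#'
#' `study / reference`, rounded to one decimal place half away from
#' zero, as in published reference-comparison tables. Missing or
#' nonpositive reference medians yield a missing ratio.
#'
#' @param study_median,reference_median Medians, ng/mL. Vectorized.
#' @return Ratio(s) rounded to one decimal.
#' @export
reference_ratio <- function(study_median, reference_median) {
  out <- ifelse(
    is.na(reference_median) | reference_median <= 0 | is.na(study_median),
    NA_real_,
    round_half_up(study_median / reference_median, 1)
  )
  out
}

#' Build the reported summary table
#'
#' One row per targeted-and-reported chemical per reporting group
#' (children = probands + controls, adults = mothers + fathers, plus the
#' pooled total), with LOD, detection rate, median and maximum under the
#' detection-rate-conditional reporting rules of [summarize_group()].
#' Records from dropped (unmeasurable) batches are excluded.
#'
#' @param records Censored concentration records (from
#'   [apply_targeted_qc()]), joined internally to `subjects`.
#' @param subjects Cohort tibble.
#' @param lods Per-chemical LODs.
#' @param reported_ids Chemicals that passed the targeted QC gates.
#' @param median_floor Median-reporting floor (fraction).
#' @return Tibble in the reported-concentrations schema.
#' @export
build_summary_table <- function(records, subjects, lods, reported_ids,
                                median_floor = 0.5) {
  df <- records |>
    dplyr::filter(.data$chemical_id %in% reported_ids, !.data$batch_dropped) |>
    dplyr::inner_join(subjects[, c("subject_id", "role")], by = "subject_id") |>
    dplyr::mutate(grp = ifelse(.data$role %in% c("mother", "father"),
                               "adults", "children"))
  purrr::map_dfr(sort(unique(df$chemical_id)), function(chem) {
    d <- df[df$chemical_id == chem, ]
    rows <- dplyr::bind_rows(
      summarize_group(d, "all", median_floor),
      summarize_group(d[d$grp == "children", ], "children", median_floor),
      summarize_group(d[d$grp == "adults", ], "adults", median_floor)
    )
    rows$chemical_id <- chem
    rows$lod <- lods$lod[match(chem, lods$chemical_id)]
    rows[, c("chemical_id", "lod", "group", "n", "detection_rate",
             "median", "maximum", "median_label", "maximum_label")]
  })
}
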