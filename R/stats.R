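#' Shapiro-gated branch choice for paired comparisons
#'
#' Tests the paired differences for normality with the Shapiro-Wilk
#' test; the comparison branch is parametric (paired t-test) when the
#' normality hypothesis is not rejected at `alpha`, otherwise
#' nonparametric (Wilcoxon signed-rank).
#'
#' @param diffs Numeric vector of paired differences (n >= 3).
#' @param alpha Gate significance level.
#' @return A list with `branch` (`"parametric"`/`"nonparametric"`)
#'   and `shapiro_p`.
#' @export
normality_gate <- function(diffs, alpha = 0.05) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3L) {
    abort("normality gate needs at least 3 paired differences.",
          class = "gazeog_insufficient_data")
  }
  if (sd(diffs) == 0) {
    # Shapiro-Wilk is undefined for constant input; constant
    # differences are maximally non-normal
    return(list(branch = "nonparametric", shapiro_p = 0))
  }
  # shapiro.test caps n at 5000; subsample deterministically above it
  x <- if (n > 5000L) diffs[round(seq(1L, n, length.out = 5000L))] else diffs
  p <- shapiro.test(x)$p.value
  list(branch = if (p >= alpha) "parametric" else "nonparametric",
       shapiro_p = p)
}

# paired Cohen's d: mean difference over SD of differences
cohens_d_paired <- function(diffs) {
  s <- sd(diffs)
  if (s == 0) return(0)
  mean(diffs) / s
}

#' Shapiro-gated paired comparison with Bonferroni correction
#'
#' Compares two paired sample vectors: the Shapiro-Wilk gate on the
#' differences selects a two-sided paired t-test or Wilcoxon
#' signed-rank test; the p-value is Bonferroni-adjusted for
#' `n_comparisons` family members; paired Cohen's d is
#' `mean(diff) / sd(diff)`. Wilcoxon zero differences are discarded
#' (classic convention) and the exact distribution is used for
#' n <= 25, the normal approximation above.
#'
#' @param a,b Equal-length numeric vectors.
#' @param alpha Gate significance level.
#' @param n_comparisons Bonferroni family size.
#' @return A `paired_comparison` object with fields `test_name`,
#'   `statistic`, `p_value`, `p_adjusted`, `cohens_d`, `shapiro_p`,
#'   `n`, `degenerate`.
#' @export
paired_compare <- function(a, b, alpha = 0.05, n_comparisons = 1) {
  a <- as.double(unclass(a))
  b <- as.double(unclass(b))
  if (length(a) != length(b)) {
    abort("paired vectors must have equal length.", class = "gazeog_alignment_error")
  }
  d <- a - b
  n <- length(d)
  if (all(d == 0)) {
    res <- list(test_name = "degenerate", statistic = NA_real_,
                p_value = 1, p_adjusted = 1, cohens_d = 0,
                shapiro_p = NA_real_, n = n, degenerate = TRUE)
    return(structure(res, class = "paired_comparison"))
  }
  gate <- normality_gate(d, alpha)
  if (gate$branch == "parametric") {
    tt <- t.test(a, b, paired = TRUE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
    test_name <- "paired t-test"
  } else {
    nz <- d[d != 0]
    wt <- suppressWarnings(
      wilcox.test(nz, exact = length(nz) <= 25, correct = TRUE)
    )
    stat <- unname(wt$statistic)
    p <- wt$p.value
    test_name <- "wilcoxon signed-rank"
  }
  res <- list(
    test_name = test_name, statistic = stat, p_value = p,
    p_adjusted = min(1, p * n_comparisons),
    cohens_d = cohens_d_paired(d),
    shapiro_p = gate$shapiro_p, n = n, degenerate = FALSE
  )
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> %s: statistic=%.4g, p=%.3g (adjusted %.3g), d=%.3f, n=%d\n",
    x$test_name, x$statistic, x$p_value, x$p_adjusted, x$cohens_d, x$n
  ))
  invisible(x)
}

#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test_name, statistic = x$statistic, p_value = x$p_value,
    p_adjusted = x$p_adjusted, cohens_d = x$cohens_d,
    shapiro_p = x$shapiro_p, n = x$n
  )
}

#' TOST equivalence test with a standardized SESOI
#'
#' Two one-sided t-tests of the paired mean difference against
#' symmetric equivalence bounds. The smallest effect size of interest
#' is given as a Cohen's d (`sesoi_d`, default 0.1 — a trivially
#' small effect) and converted to raw units via the SD of the paired
#' differences: `bound = sesoi_d * sd(a - b)`. Equivalence is
#' declared when the 90% confidence interval of the mean difference
#' (for `conf = 0.95`, i.e. `2 * conf - 1`) lies entirely within
#' `[-bound, bound]`; this is identical to both one-sided tests
#' rejecting at `1 - conf`.
#'
#' @param a,b Equal-length paired numeric vectors (n >= 3).
#' @param sesoi_d Smallest effect size of interest, as a Cohen's d.
#' @param conf One-sided test confidence level (0.95 gives the
#'   conventional 90% TOST interval).
#' @return A `tost_result` with fields `sesoi_d`, `sd_diff`,
#'   `mean_diff`, `bound`, `ci_low`, `ci_high`, `ci_level`,
#'   `p_lower`, `p_upper`, `p_tost`, `equivalent`, `degenerate`, `n`.
#' @export
tost_equivalence <- function(a, b, sesoi_d = 0.1, conf = 0.95) {
  a <- as.double(unclass(a))
  b <- as.double(unclass(b))
  if (length(a) != length(b)) {
    abort("paired vectors must have equal length.", class = "gazeog_alignment_error")
  }
  d <- a - b
  n <- length(d)
  if (n < 3L) {
    abort("TOST needs at least 3 pairs.", class = "gazeog_insufficient_data")
  }
  sd_diff <- sd(d)
  mean_diff <- mean(d)
  bound <- sesoi_d * sd_diff
  ci_level <- 2 * conf - 1
  if (sd_diff == 0) {
    eq <- mean_diff == 0 && bound >= 0
    res <- list(sesoi_d = sesoi_d, sd_diff = 0, mean_diff = mean_diff,
                bound = bound, ci_low = mean_diff, ci_high = mean_diff,
                ci_level = ci_level,
                p_lower = if (eq) 0 else 1, p_upper = if (eq) 0 else 1,
                p_tost = if (eq) 0 else 1,
                equivalent = eq, degenerate = TRUE, n = n)
    return(structure(res, class = "tost_result"))
  }
  se <- sd_diff / sqrt(n)
  df <- n - 1
  tcrit <- qt(conf, df)
  ci_low <- mean_diff - tcrit * se
  ci_high <- mean_diff + tcrit * se
  # H0 lower: mean <= -bound (reject when mean significantly above)
  t_lower <- (mean_diff + bound) / se
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  # H0 upper: mean >= +bound
  t_upper <- (mean_diff - bound) / se
  p_upper <- pt(t_upper, df, lower.tail = TRUE)
  res <- list(
    sesoi_d = sesoi_d, sd_diff = sd_diff, mean_diff = mean_diff,
    bound = bound, ci_low = ci_low, ci_high = ci_high,
    ci_level = ci_level, p_lower = p_lower, p_upper = p_upper,
    p_tost = max(p_lower, p_upper),
    equivalent = (ci_low >= -bound) && (ci_high <= bound),
    degenerate = FALSE, n = n
  )
  structure(res, class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    "<tost_result> mean diff %.4g, %d%% CI [%.4g, %.4g], bounds +/-%.4g -> %s\n",
    x$mean_diff, round(100 * x$ci_level), x$ci_low, x$ci_high, x$bound,
    if (x$equivalent) "equivalent" else "not equivalent"
  ))
  invisible(x)
}

#' @export
tidy.tost_result <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff, bound = x$bound,
    ci_low = x$ci_low, ci_high = x$ci_high, ci_level = x$ci_level,
    p_tost = x$p_tost, equivalent = x$equivalent, n = x$n
  )
}

#' Bootstrap-CI TOST variant
#'
#' Fully nonparametric alternative to [tost_equivalence()]: the
#' confidence interval of the mean difference is taken from the
#' percentile bootstrap instead of the t distribution. The bound
#' conversion (`sesoi_d * sd(diff)`) is unchanged.
#'
#' @inheritParams tost_equivalence
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for a local RNG stream.
#' @return A `tost_result` (with `method = "bootstrap"` attribute).
#' @export
tost_equivalence_boot <- function(a, b, sesoi_d = 0.1, conf = 0.95,
                                  n_boot = 2000, seed = NULL) {
  a <- as.double(unclass(a))
  b <- as.double(unclass(b))
  d <- a - b
  n <- length(d)
  if (n < 3L) {
    abort("TOST needs at least 3 pairs.", class = "gazeog_insufficient_data")
  }
  run <- function() {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(d[idx], nrow = n))
  }
  boot_means <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  ci_level <- 2 * conf - 1
  ci <- unname(quantile(boot_means, c((1 - ci_level) / 2, (1 + ci_level) / 2)))
  bound <- sesoi_d * sd(d)
  res <- list(
    sesoi_d = sesoi_d, sd_diff = sd(d), mean_diff = mean(d),
    bound = bound, ci_low = ci[1], ci_high = ci[2], ci_level = ci_level,
    p_lower = NA_real_, p_upper = NA_real_, p_tost = NA_real_,
    equivalent = (ci[1] >= -bound) && (ci[2] <= bound),
    degenerate = FALSE, n = n
  )
  structure(res, class = "tost_result", method = "bootstrap")
}

#' Post hoc power of a two-tailed paired t-test
#'
#' Power computed from the noncentral t distribution with
#' noncentrality `d * sqrt(n)` and `n - 1` degrees of freedom. At
#' `d = 0` the power equals `alpha` by construction.
#'
#' @param d Paired Cohen's d (may be a vector).
#' @param n Number of pairs (>= 2).
#' @param alpha Two-tailed significance level.
#' @return Power in \[0, 1\] (vectorized over `d`).
#' @examples
#' posthoc_power_paired(1.85, n = 11) # > 0.99
#' @export
posthoc_power_paired <- function(d, n, alpha = 0.05) {
  if (n < 2) abort("power needs n >= 2.", class = "gazeog_invalid_parameter")
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "gazeog_invalid_parameter")
  }
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Table of paired comparisons and equivalence tests per participant
#'
#' The group comparison battery for eyes-open trials: for every
#' participant, the EOG and eye-tracker grand averages (pooled across
#' both lighting conditions) are resampled to the analysis rate,
#' z-scored, and compared per axis with the Shapiro-gated paired test
#' and the TOST equivalence test. A group-level `"All"` row tests the
#' mean of the per-participant signals. The Bonferroni family
#' defaults to the number of rows per axis (participants + group).
#'
#' @param cohort A preprocessed cohort tibble.
#' @param fs_analysis Common comparison rate in Hz.
#' @param sesoi_d Smallest effect size of interest (Cohen's d).
#' @param conf TOST one-sided confidence level.
#' @param alpha Shapiro gate level.
#' @param n_comparisons Bonferroni family size; `NULL` means
#'   participants + 1 (the per-axis family).
#' @return A tibble with one row per participant x axis plus `"All"`
#'   rows: test statistic, p, adjusted p, equivalence bound, CI and
#'   verdict.
#' @export
modality_equivalence_table <- function(cohort, fs_analysis = 30,
                                       sesoi_d = 0.1, conf = 0.95,
                                       alpha = 0.05, n_comparisons = NULL) {
  open <- dplyr::filter(cohort, .data$eye_state == "open")
  if (nrow(open) == 0L) {
    abort("no eyes-open trials in cohort.", class = "gazeog_empty_input")
  }
  pairs <- open |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(c(horizontal = "h", vertical = "v"), function(suffix) {
        eog <- standardize(participant_grand_average(
          d, paste0("eog_", suffix), fs_analysis))
        et <- standardize(participant_grand_average(
          d, paste0("et_", suffix), fs_analysis))
        tibble::tibble(eog = list(as.double(unclass(eog))),
                       et = list(as.double(unclass(et))))
      }, .id = "axis")
    }) |>
    dplyr::ungroup()

  group_rows <- pairs |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      eog = list(Reduce(`+`, .data$eog) / dplyr::n()),
      et = list(Reduce(`+`, .data$et) / dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(participant = "All")
  pairs <- dplyr::bind_rows(pairs, group_rows)

  fam <- n_comparisons %||% (dplyr::n_distinct(pairs$participant))
  purrr::pmap_dfr(
    pairs,
    function(participant, axis, eog, et) {
      cmp <- paired_compare(eog, et, alpha = alpha, n_comparisons = fam)
      tst <- tost_equivalence(eog, et, sesoi_d = sesoi_d, conf = conf)
      tibble::tibble(
        participant = participant, axis = axis,
        test = cmp$test_name, statistic = cmp$statistic,
        p_value = cmp$p_value, p_adjusted = cmp$p_adjusted,
        cohens_d = cmp$cohens_d,
        bound = tst$bound, ci_low = tst$ci_low, ci_high = tst$ci_high,
        equivalent = tst$equivalent, n = cmp$n
      )
    }
  ) |>
    dplyr::arrange(.data$axis, .data$participant != "All", .data$participant)
}
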