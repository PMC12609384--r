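#' Mean absolute error between two signals
#'
#' @param a,b Equal-length [gaze_signal()]s or numeric vectors.
#' @return Mean of absolute pointwise differences (>= 0).
#' @export
mae <- function(a, b) {
  x <- as.double(unclass(a))
  y <- as.double(unclass(b))
  if (length(x) != length(y)) {
    abort("signals must have equal length.", class = "gazeog_alignment_error")
  }
  mean(abs(x - y))
}

#' Shuffled-trajectory surrogate control for eyes-closed trials
#'
#' The chance-level control: for every eyes-closed trial and axis,
#' the z-scored EOG signal (resampled to the analysis rate) is scored
#' by its MAE against the z-scored instructed trajectory (the
#' "paired" condition) and against `n_shuffles` trajectories whose
#' visit sequence has been randomly permuted (the "shuffled"
#' condition; the initial center phase is never shuffled). Shuffling
#' permutes only the fixation order, so the multiset of instructed
#' positions — and hence the z-scored value multiset — is preserved:
#' any MAE difference is attributable to temporal arrangement alone.
#' Per axis, the per-trial mean over the shuffles enters a
#' Shapiro-gated paired test against the paired MAEs.
#'
#' @param cohort A preprocessed cohort tibble containing eyes-closed
#'   trials (signals z-scored; see [preprocess_cohort()]).
#' @param pattern The [marker_pattern()] that generated the trials
#'   (default: taken from the cohort's attached trajectory).
#' @param n_shuffles Number of random permutations (default 100).
#' @param seed Integer seed for the shuffle stream.
#' @param alpha Shapiro gate level for the comparison test.
#' @param fs_analysis Analysis rate in Hz (default 30).
#' @return A `surrogate_result`: list with `table` (one row per axis:
#'   `mean_paired`, `sd_paired`, `mean_shuffled`, `sd_shuffled`,
#'   `shapiro_p`, `test`, `statistic`, `p_value`, `cohens_d`,
#'   `n_trials`), `trial_mae` (per trial x axis: `paired_mae`,
#'   `shuffled_mae_mean`), `shuffled_mae` (the full per-trial x
#'   per-shuffle collection, long format), and `n_shuffles`.
#' @export
surrogate_mae_test <- function(cohort, pattern = NULL, n_shuffles = 100,
                               seed = 1L, alpha = 0.05, fs_analysis = 30) {
  closed <- dplyr::filter(cohort, .data$eye_state == "closed")
  if (nrow(closed) == 0L) {
    abort("no eyes-closed trials in cohort.", class = "gazeog_empty_input")
  }
  if (is.null(pattern)) {
    traj_attr <- attr(cohort, "trajectory")
    if (is.null(traj_attr)) {
      abort("no `pattern` given and the cohort carries no trajectory.",
            class = "gazeog_invalid_input")
    }
    pattern <- traj_attr$pattern
  }

  std_axis <- function(traj, axis) {
    as.double(unclass(standardize(trajectory_signal(traj, axis))))
  }
  true_traj <- build_trajectory(pattern, fs_analysis)
  target <- list(horizontal = std_axis(true_traj, "horizontal"),
                 vertical = std_axis(true_traj, "vertical"))

  shuffled_targets <- purrr::map(seq_len(n_shuffles), function(k) {
    p <- shuffle_visit_sequence(pattern, seed = child_seed(seed, 0L, k))
    tr <- build_trajectory(p, fs_analysis)
    list(horizontal = std_axis(tr, "horizontal"),
         vertical = std_axis(tr, "vertical"))
  })

  trial_signal <- function(sig) {
    as.double(unclass(standardize(resample_to(sig, fs_analysis))))
  }

  per_trial <- purrr::map_dfr(seq_len(nrow(closed)), function(i) {
    purrr::map_dfr(
      c(horizontal = "eog_h", vertical = "eog_v"),
      function(column) {
        axis <- if (column == "eog_h") "horizontal" else "vertical"
        x <- trial_signal(closed[[column]][[i]])
        sh <- vapply(shuffled_targets, function(tg) mae(x, tg[[axis]]),
                     numeric(1))
        tibble::tibble(
          trial_row = i,
          participant = closed$participant[i],
          paired_mae = mae(x, target[[axis]]),
          shuffled_mae_mean = mean(sh),
          shuffled_mae = list(sh)
        )
      },
      .id = "axis"
    )
  })

  table <- per_trial |>
    dplyr::group_by(.data$axis) |>
    dplyr::group_modify(function(d, key) {
      cmp <- paired_compare(d$paired_mae, d$shuffled_mae_mean, alpha = alpha)
      tibble::tibble(
        mean_paired = mean(d$paired_mae),
        sd_paired = sd(d$paired_mae),
        mean_shuffled = mean(d$shuffled_mae_mean),
        sd_shuffled = sd(d$shuffled_mae_mean),
        shapiro_p = cmp$shapiro_p,
        test = cmp$test_name,
        statistic = cmp$statistic,
        p_value = cmp$p_value,
        cohens_d = cmp$cohens_d,
        n_trials = nrow(d)
      )
    }) |>
    dplyr::ungroup()

  long <- per_trial |>
    dplyr::select("axis", "trial_row", "participant", "shuffled_mae") |>
    tidyr::unnest_longer("shuffled_mae", values_to = "mae",
                         indices_to = "shuffle")

  structure(
    list(
      table = table,
      trial_mae = dplyr::select(per_trial, "axis", "trial_row",
                                "participant", "paired_mae",
                                "shuffled_mae_mean"),
      shuffled_mae = long,
      n_shuffles = n_shuffles
    ),
    class = "surrogate_result"
  )
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> %d trials x %d shuffles\n",
              dplyr::n_distinct(x$trial_mae$trial_row), x$n_shuffles))
  print(x$table)
  invisible(x)
}

#' @export
tidy.surrogate_result <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$trial_mae, -"shuffled_mae_mean") |>
      dplyr::rename(paired = "paired_mae") |>
      dplyr::left_join(
        dplyr::select(x$trial_mae, "axis", "trial_row",
                      shuffled = "shuffled_mae_mean"),
        by = c("axis", "trial_row")
      ),
    c("paired", "shuffled"),
    names_to = "condition", values_to = "mae"
  )
}

#' @export
glance.surrogate_result <- function(x, ...) x$table

#' Box plot of paired vs shuffled MAEs
#'
#' @param object A [surrogate_mae_test()] result.
#' @param ... Unused.
#' @export
autoplot.surrogate_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$condition, y = .data$mae,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = 1, show.legend = FALSE) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = NULL, y = "MAE (z-units)") +
    ggplot2::theme_minimal()
}
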