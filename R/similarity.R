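#' Grand average of time-aligned signals
#'
#' Pointwise mean across a list of equal-length, equal-rate signals
#' (e.g. the trials of one participant in one condition).
#'
#' @param signals A list of [gaze_signal()]s with identical length,
#'   rate and axis.
#' @return A [gaze_signal()], the pointwise mean.
#' @export
grand_average <- function(signals) {
  signals <- purrr::compact(signals)
  if (length(signals) == 0L) {
    abort("no signals to average.", class = "gazeog_alignment_error")
  }
  n <- length(signals[[1]])
  fs <- fs_hz(signals[[1]])
  ok <- purrr::every(signals, function(s) {
    length(s) == n && abs(fs_hz(s) - fs) < 1e-9 &&
      signal_axis(s) == signal_axis(signals[[1]])
  })
  if (!ok) {
    abort("signals differ in length, rate or axis.", class = "gazeog_alignment_error")
  }
  m <- Reduce(`+`, lapply(signals, function(s) as.double(unclass(s)))) /
    length(signals)
  signal_like(signals[[1]], m)
}

#' Cosine similarity between two signals
#'
#' Inner product over the product of Euclidean norms; 1 for identical
#' direction, -1 for opposite, 0 for orthogonal. Symmetric and
#' invariant to positive rescaling.
#'
#' @param a,b Equal-length [gaze_signal()]s (or numeric vectors).
#' @return A scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  x <- as.double(unclass(a))
  y <- as.double(unclass(b))
  if (length(x) != length(y)) {
    abort("signals must have equal length.", class = "gazeog_alignment_error")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    abort("cosine similarity of a zero vector is undefined.",
          class = "gazeog_degenerate_signal")
  }
  sum(x * y) / (nx * ny)
}

#' Normalized full cross-correlation with peak lag
#'
#' Computes the full cross-correlation of two equal-rate signals over
#' all `2N - 1` displacements (inputs are z-scored internally), then
#' min-max rescales the coefficients to \[0, 1\] and maps the lag axis
#' affinely so that displacement `-(N-1)` is 0 and `+(N-1)` is 1 — a
#' peak at normalized lag 0.5 therefore means the signals are
#' temporally aligned. The sign convention of `peak_lag_s` is
#' positive when the first argument leads (precedes) the second.
#'
#' @param a,b [gaze_signal()]s with equal sampling rate (equal length
#'   for the 0.5-at-zero-lag normalization to hold exactly).
#' @return A `crosscorr_result` with fields `norm_lags`,
#'   `norm_coeffs`, `lags_s`, `coeffs` (raw correlation sums),
#'   `peak_norm_lag`, `peak_lag_s`, `peak_coeff` (raw Pearson-style
#'   peak correlation, for diagnostics), `fs_hz`, `n`.
#' @export
normalized_xcorr <- function(a, b) {
  stopifnot(inherits(a, "gaze_signal"), inherits(b, "gaze_signal"))
  if (abs(fs_hz(a) - fs_hz(b)) > 1e-9) {
    abort("signals must share a sampling rate.", class = "gazeog_alignment_error")
  }
  fs <- fs_hz(a)
  x <- scale(as.double(unclass(a)))[, 1]
  y <- scale(as.double(unclass(b)))[, 1]
  n <- length(x)
  m <- length(y)
  # r[k] = sum_i x[i] * y[i + k]; k in [-(m-1), n-1]
  r <- rev(stats::convolve(x, y, conj = TRUE, type = "open"))
  lags <- seq.int(-(m - 1L), n - 1L)
  rng <- range(r)
  norm_coeffs <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else rep(0.5, length(r))
  norm_lags <- (lags - lags[1]) / (lags[length(lags)] - lags[1])
  ipk <- which.max(r)
  structure(
    list(
      norm_lags = norm_lags,
      norm_coeffs = norm_coeffs,
      lags_s = lags / fs,
      coeffs = r,
      peak_norm_lag = norm_lags[ipk],
      peak_lag_s = lags[ipk] / fs,
      peak_coeff = r[ipk] / sqrt(sum(x^2) * sum(y^2)),
      fs_hz = fs, n = n
    ),
    class = "crosscorr_result"
  )
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf(
    "<crosscorr_result> n=%d @ %g Hz; peak at normalized lag %.4f (%.1f ms, %s leads)\n",
    x$n, x$fs_hz, x$peak_norm_lag, abs(x$peak_lag_s) * 1000,
    if (x$peak_lag_s >= 0) "first" else "second"
  ))
  invisible(x)
}

#' @export
tidy.crosscorr_result <- function(x, ...) {
  tibble::tibble(norm_lag = x$norm_lags, norm_coeff = x$norm_coeffs,
                 lag_s = x$lags_s)
}

#' @export
glance.crosscorr_result <- function(x, ...) {
  tibble::tibble(peak_norm_lag = x$peak_norm_lag,
                 peak_lag_s = x$peak_lag_s,
                 peak_coeff = x$peak_coeff, n = x$n)
}

#' Plot a normalized cross-correlation curve
#'
#' @param object A `crosscorr_result`.
#' @param ... Unused.
#' @export
autoplot.crosscorr_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$norm_lag, y = .data$norm_coeff)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "normalized lag", y = "normalized correlation") +
    ggplot2::theme_minimal()
}

# participant-level grand averages for one modality/axis at a common
# analysis rate; trials is a cohort tibble already filtered
participant_grand_average <- function(trials, column, fs_analysis = 30) {
  sigs <- purrr::compact(trials[[column]])
  if (length(sigs) == 0L) return(NULL)
  resample_to(grand_average(sigs), fs_analysis)
}

#' Cosine similarity of EOG vs eye tracker per participant
#'
#' For every participant and lighting condition with eyes-open
#' trials: grand-average the EOG and eye-tracker signals over that
#' condition's trials, resample both to the analysis rate, and report
#' the cosine similarity per axis. Participants lacking a lighting
#' condition are simply absent from that condition's rows.
#'
#' @param cohort A preprocessed cohort tibble ([preprocess_cohort()]).
#' @param fs_analysis Common comparison rate in Hz (default 30, the
#'   eye tracker's video frame rate).
#' @return A tibble with columns `participant`, `lighting`, `axis`,
#'   `n_trials`, `cosine`.
#' @export
modality_similarity_table <- function(cohort, fs_analysis = 30) {
  open <- dplyr::filter(cohort, .data$eye_state == "open")
  if (nrow(open) == 0L) {
    abort("no eyes-open trials in cohort.", class = "gazeog_empty_input")
  }
  open |>
    dplyr::group_by(.data$participant, .data$lighting) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(c(horizontal = "h", vertical = "v"), function(suffix) {
        eog <- participant_grand_average(d, paste0("eog_", suffix), fs_analysis)
        et <- participant_grand_average(d, paste0("et_", suffix), fs_analysis)
        tibble::tibble(n_trials = nrow(d),
                       cosine = cosine_similarity(eog, et))
      }, .id = "axis")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant, .data$axis, .data$lighting)
}

#' Cross-correlation lag between EOG and eye tracker
#'
#' The machinery behind the group lag analysis: per participant and
#' axis, pool the eyes-open trials across both lighting conditions,
#' grand-average each modality, resample to the analysis rate, and
#' compute the normalized cross-correlation of EOG against the eye
#' tracker. The group-level curve is the mean of the per-participant
#' normalized curves. A positive `peak_lag_s` means EOG precedes the
#' eye tracker.
#'
#' @param cohort A preprocessed cohort tibble.
#' @param fs_analysis Common comparison rate in Hz.
#' @return A tibble with one row per participant x axis (plus a
#'   `"All"` group row per axis): `participant`, `axis`,
#'   `peak_norm_lag`, `peak_lag_s`, `peak_coeff`. The per-participant
#'   and group curves are attached as attribute `curves` (a tibble
#'   with `participant`, `axis`, `norm_lag`, `norm_coeff`).
#' @export
modality_lag_table <- function(cohort, fs_analysis = 30) {
  open <- dplyr::filter(cohort, .data$eye_state == "open")
  if (nrow(open) == 0L) {
    abort("no eyes-open trials in cohort.", class = "gazeog_empty_input")
  }
  per <- open |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(c(horizontal = "h", vertical = "v"), function(suffix) {
        eog <- participant_grand_average(d, paste0("eog_", suffix), fs_analysis)
        et <- participant_grand_average(d, paste0("et_", suffix), fs_analysis)
        xc <- normalized_xcorr(eog, et)
        tibble::tibble(
          peak_norm_lag = xc$peak_norm_lag,
          peak_lag_s = xc$peak_lag_s,
          peak_coeff = xc$peak_coeff,
          curve = list(tibble::tibble(norm_lag = xc$norm_lags,
                                      norm_coeff = xc$norm_coeffs))
        )
      }, .id = "axis")
    }) |>
    dplyr::ungroup()

  curves <- per |>
    dplyr::select("participant", "axis", "curve") |>
    tidyr::unnest("curve")
  group_curves <- curves |>
    dplyr::group_by(.data$axis, .data$norm_lag) |>
    dplyr::summarise(norm_coeff = mean(.data$norm_coeff), .groups = "drop") |>
    dplyr::mutate(participant = "All")
  group_rows <- group_curves |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      peak_norm_lag = .data$norm_lag[which.max(.data$norm_coeff)],
      peak_lag_s = NA_real_, peak_coeff = NA_real_, .groups = "drop"
    ) |>
    dplyr::mutate(participant = "All")

  tab <- dplyr::bind_rows(
    dplyr::select(per, "participant", "axis", "peak_norm_lag",
                  "peak_lag_s", "peak_coeff"),
    dplyr::select(group_rows, "participant", "axis", "peak_norm_lag",
                  "peak_lag_s", "peak_coeff")
  )
  attr(tab, "curves") <- dplyr::bind_rows(
    dplyr::mutate(curves, participant = .data$participant),
    group_curves
  ) |> dplyr::select("participant", "axis", "norm_lag", "norm_coeff")
  tab
}

#' Plot per-participant and group cross-correlation curves
#'
#' @param lag_table A [modality_lag_table()] result.
#' @return A ggplot object: thin lines per participant, a heavy line
#'   for the group mean.
#' @export
plot_lag_curves <- function(lag_table) {
  curves <- attr(lag_table, "curves")
  stopifnot(!is.null(curves))
  ggplot2::ggplot(
    dplyr::filter(curves, .data$participant != "All"),
    ggplot2::aes(x = .data$norm_lag, y = .data$norm_coeff,
                 group = .data$participant)
  ) +
    ggplot2::geom_line(alpha = 0.35, colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_line(
      data = dplyr::filter(curves, .data$participant == "All"),
      colour = "navy", linewidth = 0.9
    ) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "normalized lag", y = "normalized correlation") +
    ggplot2::theme_minimal()
}
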