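#' Remove the best-fit straight line from a signal
#'
#' Least-squares linear detrend; the fitted intercept-plus-slope line
#' is subtracted so the output has (numerically) zero mean and zero
#' linear trend. Idempotent.
#'
#' @param sig A [gaze_signal()] with at least 2 samples.
#' @return A detrended [gaze_signal()].
#' @export
linear_detrend <- function(sig) {
  stopifnot(inherits(sig, "gaze_signal"))
  n <- length(sig)
  if (n < 2L) {
    abort("linear_detrend needs at least 2 samples.", class = "gazeog_invalid_input")
  }
  t <- seq_len(n)
  x <- as.double(unclass(sig))
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc * tc)
  signal_like(sig, x - mean(x) - slope * tc)
}

#' Sliding median filter
#'
#' Each output sample is the median of a centered window; edges are
#' handled by edge-value padding so length and rate are preserved.
#' The window length in ms is converted to samples by
#' `round(ms * fs / 1000)` and forced odd (+1).
#'
#' @param sig A [gaze_signal()].
#' @param window_ms Window length in milliseconds.
#' @return The filtered [gaze_signal()].
#' @export
median_filter <- function(sig, window_ms) {
  stopifnot(inherits(sig, "gaze_signal"))
  k <- window_samples(window_ms, fs_hz(sig))
  if (k <= 1L) return(sig)
  x <- as.double(unclass(sig))
  n <- length(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  y <- runmed(xp, k, endrule = "keep")
  signal_like(sig, y[(half + 1L):(half + n)])
}

# sliding sums of x and x^2 over a centered window of k (odd) samples,
# with edge-value padding; returns list(s1, s2, k)
sliding_sums <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  c1 <- cumsum(xp)
  c2 <- cumsum(xp^2)
  idx_hi <- (k):(k + n - 1L)
  idx_lo <- 0:(n - 1L)
  s1 <- c1[idx_hi] - c(0, c1)[idx_lo + 1L]
  s2 <- c2[idx_hi] - c(0, c2)[idx_lo + 1L]
  list(s1 = s1, s2 = s2, k = k)
}

#' Continuous Haar wavelet coefficients
#'
#' Correlates the signal with a Haar wavelet of total width
#' `2 * scale` samples (negative half then positive half), normalized
#' by `scale^(-1/2)`:
#' `c[n] = (sum(x[n..n+scale-1]) - sum(x[n-scale..n-1])) / sqrt(scale)`.
#' A rising edge therefore produces a positive coefficient peak and a
#' falling edge a negative one, so a positive blink transient shows
#' the signature positive-then-negative peak pair. Borders are
#' zero-padded; output length equals input length.
#'
#' @param sig A [gaze_signal()] (or numeric vector).
#' @param scale Wavelet half-width in samples (>= 1). The default of
#'   20 samples matches the blink detector's operating point at the
#'   default 512 Hz EOG rate; at other rates rescale proportionally.
#' @return Numeric vector of coefficients, same length as the input.
#' @export
haar_cwt <- function(sig, scale = 20) {
  x <- as.double(unclass(sig))
  scale <- as.integer(scale)
  if (scale < 1L) abort("`scale` must be >= 1.", class = "gazeog_invalid_parameter")
  n <- length(x)
  if (n <= 2L * scale) {
    abort("signal too short for this wavelet scale.", class = "gazeog_invalid_input")
  }
  xp <- c(numeric(scale), x, numeric(scale)) # zero-padded borders
  cs <- c(0, cumsum(xp))
  # position i in x sits at index i + scale in xp
  i <- seq_len(n) + scale
  right <- cs[i + scale] - cs[i]       # sum x[n .. n+scale-1]
  left <- cs[i] - cs[i - scale]        # sum x[n-scale .. n-1]
  (right - left) / sqrt(scale)
}

# strict-left / non-strict-right local extrema indices
local_maxima <- function(c) {
  n <- length(c)
  if (n < 3L) return(integer(0))
  which(c[2:(n - 1)] > c[1:(n - 2)] & c[2:(n - 1)] >= c[3:n]) + 1L
}

#' Detect blink events in a vertical EOG channel
#'
#' Implements the wavelet blink detector: compute [haar_cwt()]
#' coefficients, find local maxima exceeding `mean + sd` and local
#' minima below `mean - sd` of the whole-trial coefficient sequence,
#' and pair each positive peak with the nearest following negative
#' peak no more than `max_gap_s` later (blinks are typically shorter
#' than 0.5 s). Events are returned non-overlapping in time order.
#' The one-standard-deviation threshold presumes coefficient
#' statistics dominated by saccades and blinks, as in a real trial;
#' on a featureless noise-only signal it is permissive by design.
#'
#' @param vertical A vertical-axis [gaze_signal()].
#' @param scale Wavelet half-width in samples (see [haar_cwt()]).
#' @param max_gap_s Maximum peak-pair separation in seconds.
#' @return A tibble with one row per blink: `pos_peak_index`,
#'   `neg_peak_index`, and the interpolation span `onset_index`
#'   (the positive peak) and `offset_index` (one inter-peak interval
#'   past the negative peak, clipped at the signal end, so the
#'   trailing lobe of a biphasic artifact is covered).
#' @export
detect_blinks <- function(vertical, scale = 20, max_gap_s = 0.5) {
  stopifnot(inherits(vertical, "gaze_signal"))
  if (signal_axis(vertical) != "vertical") {
    abort("blink detection expects the vertical channel.",
          class = "gazeog_invalid_input")
  }
  co <- haar_cwt(vertical, scale)
  mu <- mean(co)
  sigma <- sd(co)
  pos <- local_maxima(co)
  pos <- pos[co[pos] > mu + sigma]
  neg <- local_maxima(-co)
  neg <- neg[co[neg] < mu - sigma]

  fs <- fs_hz(vertical)
  n_sig <- length(vertical)
  max_gap <- max_gap_s * fs
  events <- list()
  used_neg <- rep(FALSE, length(neg))
  last_end <- -Inf
  for (p in pos) {
    if (p <= last_end) next
    j <- which(!used_neg & neg > p & (neg - p) <= max_gap)
    if (length(j) == 0L) next
    j <- j[1]
    used_neg[j] <- TRUE
    # the peak pair marks the artifact's leading edge and its central
    # transition; a biphasic transient extends about one inter-peak
    # interval past the negative peak, so the interpolation span is
    # extended symmetrically (this also swallows the trailing
    # recovery edge, whose positive coefficient peak would otherwise
    # seed a spurious pairing)
    offset <- min(n_sig, neg[j] + (neg[j] - p))
    events[[length(events) + 1L]] <- c(p, neg[j], offset)
    last_end <- offset
  }
  if (length(events) == 0L) {
    return(tibble::tibble(
      pos_peak_index = integer(0), neg_peak_index = integer(0),
      onset_index = integer(0), offset_index = integer(0)
    ))
  }
  m <- do.call(rbind, events)
  tibble::tibble(
    pos_peak_index = as.integer(m[, 1]),
    neg_peak_index = as.integer(m[, 2]),
    onset_index = as.integer(m[, 1]),
    offset_index = as.integer(m[, 3])
  )
}

#' Interpolate across blink events
#'
#' For each event, samples in `[onset - pad, offset + pad]` are
#' replaced by linear interpolation between the samples immediately
#' outside the padded span (or a boundary-value hold when the span is
#' clipped at the signal ends). Overlapping padded spans are merged.
#' No sample outside a padded span is modified.
#'
#' @param sig A [gaze_signal()].
#' @param events A tibble from [detect_blinks()].
#' @param pad Extra samples interpolated on each side (default 5).
#' @param anchor `"sample"` anchors the interpolation on the single
#'   sample just outside the span; `"mean"` anchors on the mean of the
#'   `pad` samples just outside (useful when the boundary samples are
#'   themselves noisy).
#' @return The corrected [gaze_signal()].
#' @export
remove_blinks <- function(sig, events, pad = 5, anchor = c("sample", "mean")) {
  stopifnot(inherits(sig, "gaze_signal"))
  anchor <- match.arg(anchor)
  if (is.null(events) || nrow(events) == 0L) return(sig)
  if (pad < 0) abort("`pad` must be >= 0.", class = "gazeog_invalid_parameter")
  pad <- as.integer(pad)
  x <- as.double(unclass(sig))
  n <- length(x)

  spans <- events |>
    dplyr::transmute(
      start = pmax(1L, .data$onset_index - pad),
      end = pmin(n, .data$offset_index + pad)
    ) |>
    dplyr::arrange(.data$start)
  # merge overlapping/adjacent spans
  merged <- list()
  cur <- c(spans$start[1], spans$end[1])
  if (nrow(spans) > 1L) {
    for (i in 2:nrow(spans)) {
      if (spans$start[i] <= cur[2] + 1L) {
        cur[2] <- max(cur[2], spans$end[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(spans$start[i], spans$end[i])
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur

  for (sp in merged) {
    a <- sp[1] - 1L
    b <- sp[2] + 1L
    anchor_val <- function(i, dir) {
      if (anchor == "sample") return(x[i])
      idx <- if (dir < 0) seq.int(max(1L, i - pad + 1L), i) else
        seq.int(i, min(n, i + pad - 1L))
      mean(x[idx])
    }
    if (a < 1L && b > n) {
      next # event spans the whole signal; nothing to anchor on
    } else if (a < 1L) {
      x[sp[1]:sp[2]] <- anchor_val(b, +1) # boundary-value hold
    } else if (b > n) {
      x[sp[1]:sp[2]] <- anchor_val(a, -1)
    } else {
      va <- anchor_val(a, -1)
      vb <- anchor_val(b, +1)
      idx <- sp[1]:sp[2]
      x[idx] <- va + (vb - va) * (idx - a) / (b - a)
    }
  }
  signal_like(sig, x)
}

#' Hampel outlier filter
#'
#' Sliding-window outlier replacement: a sample deviating more than
#' `n_sigma` times the windowed dispersion from the windowed median is
#' replaced by that median. The dispersion is the standard deviation
#' of the window around its median with the center sample excluded —
#' excluding the center keeps an isolated outlier from masking its
#' own detection. `dispersion = "mad"` uses the scaled median absolute
#' deviation instead.
#'
#' @param sig A [gaze_signal()].
#' @param window_ms Window length in milliseconds (>= 3 samples after
#'   conversion).
#' @param n_sigma Rejection threshold in dispersion units.
#' @param dispersion `"sd"` (default) or `"mad"`.
#' @return The filtered [gaze_signal()].
#' @export
hampel_filter <- function(sig, window_ms = 100, n_sigma = 3,
                          dispersion = c("sd", "mad")) {
  stopifnot(inherits(sig, "gaze_signal"))
  dispersion <- match.arg(dispersion)
  k <- window_samples(window_ms, fs_hz(sig), minimum = 3L)
  x <- as.double(unclass(sig))
  n <- length(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  med <- runmed(xp, k, endrule = "keep")[(half + 1L):(half + n)]

  if (dispersion == "sd") {
    ss <- sliding_sums(x, k)
    # SD of the k-1 non-center window samples around the window median
    s1 <- ss$s1 - x
    s2 <- ss$s2 - x^2
    m <- k - 1L
    var_loo <- (s2 - 2 * med * s1 + m * med^2) / (m - 1L)
    disp <- sqrt(pmax(var_loo, 0))
  } else {
    xp2 <- c(rep(x[1], half), x, rep(x[n], half))
    disp <- vapply(seq_len(n), function(i) {
      w <- xp2[i:(i + k - 1L)][-(half + 1L)]
      1.4826 * median(abs(w - med[i]))
    }, numeric(1))
  }
  out <- x
  bad <- abs(x - med) > n_sigma * disp
  out[bad] <- med[bad]
  res <- signal_like(sig, out)
  attr(res, "n_replaced") <- sum(bad)
  res
}

#' Sliding-window standard deviation
#'
#' Per-sample sample SD of a centered window, edge-value padded. A
#' standalone feature extractor (the short default window tracks
#' local signal volatility, e.g. for saccade-burst inspection); it is
#' not part of the main conditioning chain.
#'
#' @param sig A [gaze_signal()].
#' @param window_ms Window length in milliseconds (>= 2 samples).
#' @return A [gaze_signal()] of windowed SDs.
#' @export
sliding_sd <- function(sig, window_ms = 31) {
  stopifnot(inherits(sig, "gaze_signal"))
  k <- window_samples(window_ms, fs_hz(sig), minimum = 3L)
  x <- as.double(unclass(sig))
  ss <- sliding_sums(x, k)
  v <- (ss$s2 - ss$s1^2 / k) / (k - 1L)
  signal_like(sig, sqrt(pmax(v, 0)))
}

#' Transform a signal to z-scores
#'
#' Subtracts the mean and divides by the sample SD.
#'
#' @param sig A [gaze_signal()].
#' @return A [gaze_signal()] with `units = "zscore"`.
#' @export
standardize <- function(sig) {
  stopifnot(inherits(sig, "gaze_signal"))
  x <- as.double(unclass(sig))
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot z-score a constant (zero-variance) signal.",
          class = "gazeog_degenerate_signal")
  }
  signal_like(sig, (x - mean(x)) / s, units = "zscore")
}

#' Resample a signal by linear interpolation
#'
#' Interpolates onto a uniform grid of `round(duration * fs_target)`
#' samples starting at time 0, covering the same time range as the
#' input (values beyond the last source sample hold the boundary
#' value).
#'
#' @param sig A [gaze_signal()].
#' @param fs_target Target sampling rate in Hz (> 0).
#' @return The resampled [gaze_signal()].
#' @export
resample_to <- function(sig, fs_target) {
  stopifnot(inherits(sig, "gaze_signal"))
  if (!is.numeric(fs_target) || fs_target <= 0) {
    abort("`fs_target` must be > 0.", class = "gazeog_invalid_parameter")
  }
  fs <- fs_hz(sig)
  if (abs(fs - fs_target) < 1e-12) return(sig)
  n_out <- as.integer(round(duration(sig) * fs_target))
  t_out <- (seq_len(n_out) - 1) / fs_target
  y <- approx(x = signal_time(sig), y = as.double(unclass(sig)),
              xout = t_out, rule = 2)$y
  signal_like(sig, y, fs_hz = fs_target)
}

#' Preprocessing parameter set
#'
#' Defaults follow the study protocol: EOG linear detrend, 200 ms
#' median filter, wavelet blink removal (scale-20 Haar, 0.5 s peak
#' gap, 5-sample interpolation pad) on the vertical channel only;
#' eye tracker Hampel filter (100 ms, 3 sigma) then 100 ms median
#' filter; both chains end with z-scoring. The wavelet scale is
#' denominated in samples at the 512 Hz reference EOG rate and is
#' rescaled proportionally for signals at other rates.
#'
#' @param eog_median_ms EOG median-filter window (ms).
#' @param blink_scale Haar half-width in samples at `blink_scale_fs_hz`.
#' @param blink_scale_fs_hz Reference rate for `blink_scale`.
#' @param blink_max_gap_s Maximum blink peak-pair separation (s).
#' @param blink_pad Interpolation pad (samples).
#' @param et_hampel_ms Eye-tracker Hampel window (ms).
#' @param et_hampel_sigma Hampel threshold (dispersion units).
#' @param et_median_ms Eye-tracker median-filter window (ms).
#' @return A named list of parameters.
#' @export
preprocess_params <- function(eog_median_ms = 200,
                              blink_scale = 20,
                              blink_scale_fs_hz = 512,
                              blink_max_gap_s = 0.5,
                              blink_pad = 5,
                              et_hampel_ms = 100,
                              et_hampel_sigma = 3,
                              et_median_ms = 100) {
  list(
    eog_median_ms = eog_median_ms,
    blink_scale = blink_scale,
    blink_scale_fs_hz = blink_scale_fs_hz,
    blink_max_gap_s = blink_max_gap_s,
    blink_pad = blink_pad,
    et_hampel_ms = et_hampel_ms,
    et_hampel_sigma = et_hampel_sigma,
    et_median_ms = et_median_ms
  )
}

# wavelet scale in samples for a signal at rate fs
scale_at_rate <- function(params, fs) {
  max(1L, as.integer(round(params$blink_scale * fs / params$blink_scale_fs_hz)))
}

#' EOG conditioning chain for one channel
#'
#' Linear detrend, 200 ms median filter, then (vertical channel only)
#' wavelet blink detection and interpolation, then z-scoring.
#'
#' @param sig An EOG [gaze_signal()].
#' @param params A [preprocess_params()] list.
#' @param remove_blink_stage Set `FALSE` to skip blink removal (for
#'   detector-specificity checks).
#' @return The conditioned, z-scored [gaze_signal()].
#' @export
preprocess_eog_signal <- function(sig, params = preprocess_params(),
                                  remove_blink_stage = TRUE) {
  out <- linear_detrend(sig)
  out <- median_filter(out, params$eog_median_ms)
  if (remove_blink_stage && signal_axis(sig) == "vertical") {
    ev <- detect_blinks(out, scale = scale_at_rate(params, fs_hz(out)),
                        max_gap_s = params$blink_max_gap_s)
    out <- remove_blinks(out, ev, pad = params$blink_pad)
  }
  standardize(out)
}

#' Eye-tracker conditioning chain for one channel
#'
#' Hampel filter (100 ms, 3 sigma), 100 ms median filter, z-scoring.
#'
#' @param sig An eye-tracker [gaze_signal()].
#' @param params A [preprocess_params()] list.
#' @return The conditioned, z-scored [gaze_signal()].
#' @export
preprocess_et_signal <- function(sig, params = preprocess_params()) {
  out <- hampel_filter(sig, params$et_hampel_ms, params$et_hampel_sigma)
  out <- median_filter(out, params$et_median_ms)
  standardize(out)
}

#' Preprocess every trial of a cohort
#'
#' Applies the EOG chain to `eog_h`/`eog_v` and the eye-tracker chain
#' to `et_h`/`et_v` (where present) of a [simulate_cohort()] tibble.
#' Eyes-closed trials, which carry no eye-tracker channels, keep their
#' `NULL` entries. The ordered list of applied operators is attached
#' as attribute `provenance`.
#'
#' @param cohort A cohort tibble.
#' @param params A [preprocess_params()] list.
#' @return The cohort tibble with conditioned, z-scored signals.
#' @export
preprocess_cohort <- function(cohort, params = preprocess_params()) {
  out <- cohort
  out$eog_h <- purrr::map(cohort$eog_h, preprocess_eog_signal, params = params)
  out$eog_v <- purrr::map(cohort$eog_v, preprocess_eog_signal, params = params)
  out$et_h <- purrr::map(cohort$et_h, function(s) {
    if (is.null(s)) NULL else preprocess_et_signal(s, params)
  })
  out$et_v <- purrr::map(cohort$et_v, function(s) {
    if (is.null(s)) NULL else preprocess_et_signal(s, params)
  })
  attr(out, "provenance") <- list(
    eog = c("linear_detrend",
            sprintf("median_filter(%g ms)", params$eog_median_ms),
            sprintf("remove_blinks(scale=%d@%gHz, gap=%gs, pad=%d; vertical only)",
                    params$blink_scale, params$blink_scale_fs_hz,
                    params$blink_max_gap_s, params$blink_pad),
            "standardize"),
    et = c(sprintf("hampel_filter(%g ms, %g sigma)", params$et_hampel_ms,
                   params$et_hampel_sigma),
           sprintf("median_filter(%g ms)", params$et_median_ms),
           "standardize"),
    params = params
  )
  attr(out, "trajectory") <- attr(cohort, "trajectory")
  attr(out, "spec") <- attr(cohort, "spec")
  out
}
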