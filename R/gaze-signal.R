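#' Uniformly sampled gaze channel
#'
#' A `gaze_signal` is a numeric vector with sampling-rate and channel
#' metadata attached. It is the unit every filter in the preprocessing
#' chain consumes and returns. Sample `i` is taken at time
#' `(i - 1) / fs_hz` seconds.
#'
#' @param samples Numeric vector, the uniformly sampled signal.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param modality `"eog"` or `"et"` (camera-based eye tracker).
#' @param axis `"horizontal"` or `"vertical"`.
#' @param units `"raw"` or `"zscore"`.
#'
#' @return A `gaze_signal` object.
#' @examples
#' s <- gaze_signal(sin(seq(0, 2 * pi, length.out = 100)), fs_hz = 50)
#' duration(s)
#' @export
gaze_signal <- function(samples, fs_hz,
                        modality = c("eog", "et"),
                        axis = c("horizontal", "vertical"),
                        units = c("raw", "zscore")) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty numeric vector.", class = "gazeog_invalid_input")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    abort("`fs_hz` must be a single positive number.", class = "gazeog_invalid_parameter")
  }
  structure(
    as.double(samples),
    fs_hz = as.double(fs_hz),
    modality = match.arg(modality),
    axis = match.arg(axis),
    units = match.arg(units),
    class = "gaze_signal"
  )
}

#' @export
print.gaze_signal <- function(x, ...) {
  cat(sprintf(
    "<gaze_signal> %s/%s, %d samples @ %g Hz (%.3f s), units=%s\n",
    attr(x, "modality"), attr(x, "axis"), length(x),
    attr(x, "fs_hz"), duration(x), attr(x, "units")
  ))
  invisible(x)
}

# rebuild a signal with new samples, keeping (or overriding) metadata
signal_like <- function(template, samples, fs_hz = NULL, units = NULL) {
  gaze_signal(
    samples,
    fs_hz = fs_hz %||% attr(template, "fs_hz"),
    modality = attr(template, "modality"),
    axis = attr(template, "axis"),
    units = units %||% attr(template, "units")
  )
}

#' @rdname gaze_signal
#' @param x,sig A `gaze_signal`.
#' @export
fs_hz <- function(sig) attr(sig, "fs_hz")

#' @rdname gaze_signal
#' @export
duration <- function(sig) length(sig) / attr(sig, "fs_hz")

#' @rdname gaze_signal
#' @export
signal_axis <- function(sig) attr(sig, "axis")

#' @rdname gaze_signal
#' @export
signal_modality <- function(sig) attr(sig, "modality")

#' Time stamps of a signal's samples
#'
#' @param sig A [gaze_signal()].
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
signal_time <- function(sig) (seq_along(sig) - 1) / attr(sig, "fs_hz")

#' @export
as_tibble.gaze_signal <- function(x, ...) {
  tibble::tibble(
    time_s = signal_time(x),
    value = as.double(unclass(x)),
    modality = attr(x, "modality"),
    axis = attr(x, "axis")
  )
}

#' Plot a gaze signal
#'
#' @param object A [gaze_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_signal <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = sprintf("%s %s (%s)", attr(object, "modality"),
                  attr(object, "axis"), attr(object, "units"))
    ) +
    ggplot2::theme_minimal()
}

# convert a window length in ms to an odd number of samples (>= minimum)
window_samples <- function(window_ms, fs, minimum = 1L) {
  w <- as.integer(round(window_ms * fs / 1000))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, as.integer(minimum))
}
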