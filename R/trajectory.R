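#' Calibration marker pattern
#'
#' Geometry and visit order of the tactile calibration pattern. The
#' participant rests the gaze at the pattern center for an initial
#' phase, then fixates the markers in `visit_sequence` order, each
#' fixation lasting `fixation_duration_s`. Coordinates live in a
#' normalized gaze plane: x positive rightward, y positive upward,
#' origin at the pattern center; the analysis z-scores all signals so
#' only the relative geometry and the ordering matter.
#'
#' @param markers Two-column matrix (or data frame) of marker x/y
#'   coordinates.
#' @param visit_sequence Integer vector of row indices into `markers`,
#'   one entry per fixation.
#' @param fixation_duration_s Seconds per fixation (> 0).
#' @param initial_phase_s Seconds of initial center fixation (>= 0).
#' @param center Length-2 numeric, the pattern center.
#'
#' @return A `marker_pattern` object.
#' @seealso [default_pattern()], [build_trajectory()],
#'   [shuffle_visit_sequence()]
#' @export
marker_pattern <- function(markers, visit_sequence,
                           fixation_duration_s = 2,
                           initial_phase_s = 2,
                           center = c(0, 0)) {
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  if (ncol(markers) != 2L) {
    abort("`markers` must have two columns (x, y).", class = "gazeog_invalid_parameter")
  }
  visit_sequence <- as.integer(visit_sequence)
  if (any(visit_sequence < 1L) || any(visit_sequence > nrow(markers))) {
    abort("`visit_sequence` contains indices outside the marker set.",
          class = "gazeog_invalid_parameter")
  }
  if (!is.numeric(fixation_duration_s) || fixation_duration_s <= 0) {
    abort("`fixation_duration_s` must be > 0.", class = "gazeog_invalid_parameter")
  }
  if (!is.numeric(initial_phase_s) || initial_phase_s < 0) {
    abort("`initial_phase_s` must be >= 0.", class = "gazeog_invalid_parameter")
  }
  structure(
    list(
      markers = unname(markers),
      visit_sequence = visit_sequence,
      fixation_duration_s = as.double(fixation_duration_s),
      initial_phase_s = as.double(initial_phase_s),
      center = as.double(center)
    ),
    class = "marker_pattern"
  )
}

#' @export
print.marker_pattern <- function(x, ...) {
  cat(sprintf(
    "<marker_pattern> %d markers, %d fixations x %g s + %g s initial (total %g s)\n",
    nrow(x$markers), length(x$visit_sequence), x$fixation_duration_s,
    x$initial_phase_s, pattern_duration(x)
  ))
  invisible(x)
}

#' Total instructed duration of a pattern
#'
#' @param pattern A [marker_pattern()].
#' @return Seconds: initial phase plus one fixation period per visit.
#' @export
pattern_duration <- function(pattern) {
  pattern$initial_phase_s +
    length(pattern$visit_sequence) * pattern$fixation_duration_s
}

#' Default 10-marker calibration pattern
#'
#' Ten markers on the normalized \[-1, 1\] x \[-1, 1\] plane: the eight
#' points of the outer 3 x 3 grid, the center, and one interior point.
#' The visit sequence has 11 entries; the upper-left marker is visited
#' twice (first and last) and every other marker once. With 2 s
#' fixations and a 2 s initial center phase the instructed trial lasts
#' 24 s.
#'
#' @return A [marker_pattern()].
#' @examples
#' p <- default_pattern()
#' pattern_duration(p) # 24
#' @export
default_pattern <- function() {
  markers <- rbind(
    c(-1,  1),  # 1 upper-left (visited twice)
    c( 0,  1),  # 2 upper-center
    c( 1,  1),  # 3 upper-right
    c( 1,  0),  # 4 mid-right
    c( 1, -1),  # 5 lower-right
    c( 0, -1),  # 6 lower-center
    c(-1, -1),  # 7 lower-left
    c(-1,  0),  # 8 mid-left
    c( 0,  0),  # 9 center
    c( 0.5, 0.5) # 10 interior
  )
  marker_pattern(
    markers = markers,
    visit_sequence = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 1L),
    fixation_duration_s = 2,
    initial_phase_s = 2,
    center = c(0, 0)
  )
}

#' Build the instructed gaze trajectory
#'
#' Turns a marker pattern into a piecewise-constant 2-D time series:
#' `initial_phase_s` seconds at the center followed by one constant
#' segment per visited marker. Transitions are instantaneous; saccade
#' dynamics belong to the simulator, not the instruction. Segments use
#' half-open sample intervals `[start_index, end_index)` so no sample
#' belongs to two segments.
#'
#' @param pattern A [marker_pattern()].
#' @param fs_hz Sampling rate in Hz (> 0).
#'
#' @return An `instructed_trajectory`: a list with `fs_hz`, numeric
#'   vectors `x` and `y` of length `round(total_duration * fs_hz)`, and
#'   a tibble `segments` with columns `segment`, `phase`
#'   (`"initial"`/`"fixation"`), `marker_index` (`NA` for the initial
#'   phase), `start_index`, `end_index` (half-open, 1-based).
#' @examples
#' tr <- build_trajectory(default_pattern(), 30)
#' length(tr$x) # 720
#' @export
build_trajectory <- function(pattern, fs_hz) {
  stopifnot(inherits(pattern, "marker_pattern"))
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    abort("`fs_hz` must be a single positive number.", class = "gazeog_invalid_parameter")
  }
  n_fix <- length(pattern$visit_sequence)
  # segment time edges; sample index edges by rounding each time edge
  t_edges <- c(0, pattern$initial_phase_s +
                 seq_len(n_fix) * pattern$fixation_duration_s)
  if (pattern$initial_phase_s > 0) {
    t_edges <- c(0, pattern$initial_phase_s, t_edges[-1])
  }
  i_edges <- as.integer(round(t_edges * fs_hz)) # 0-based half-open edges
  n_total <- as.integer(round(pattern_duration(pattern) * fs_hz))
  i_edges[length(i_edges)] <- n_total

  has_init <- pattern$initial_phase_s > 0
  seg_marker <- c(if (has_init) NA_integer_, pattern$visit_sequence)
  seg_phase <- c(if (has_init) "initial",
                 rep("fixation", n_fix))
  coords <- rbind(
    if (has_init) matrix(pattern$center, nrow = 1),
    pattern$markers[pattern$visit_sequence, , drop = FALSE]
  )

  lens <- diff(i_edges)
  x <- rep(coords[, 1], times = lens)
  y <- rep(coords[, 2], times = lens)

  segments <- tibble::tibble(
    segment = seq_along(lens),
    phase = seg_phase,
    marker_index = seg_marker,
    start_index = head(i_edges, -1) + 1L,
    end_index = tail(i_edges, -1) + 1L # half-open: [start, end)
  )

  structure(
    list(fs_hz = as.double(fs_hz), x = x, y = y, segments = segments,
         pattern = pattern),
    class = "instructed_trajectory"
  )
}

#' @export
print.instructed_trajectory <- function(x, ...) {
  cat(sprintf(
    "<instructed_trajectory> %d samples @ %g Hz, %d segments\n",
    length(x$x), x$fs_hz, nrow(x$segments)
  ))
  invisible(x)
}

#' @export
as_tibble.instructed_trajectory <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$x) - 1) / x$fs_hz,
    target_x = x$x,
    target_y = x$y
  )
}

#' One axis of a trajectory as a gaze signal
#'
#' @param traj An [build_trajectory()] result.
#' @param axis `"horizontal"` (x) or `"vertical"` (y).
#' @param modality Metadata tag for the returned signal.
#' @return A [gaze_signal()].
#' @export
trajectory_signal <- function(traj, axis = c("horizontal", "vertical"),
                              modality = "eog") {
  axis <- match.arg(axis)
  gaze_signal(if (axis == "horizontal") traj$x else traj$y,
              fs_hz = traj$fs_hz, modality = modality, axis = axis)
}

#' Plot an instructed trajectory
#'
#' @param object An `instructed_trajectory`.
#' @param ... Unused.
#' @export
autoplot.instructed_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("target_x", "target_y"),
                        names_to = "axis", values_to = "target")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$target)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "instructed gaze (normalized)") +
    ggplot2::theme_minimal()
}

#' Shuffle the visit sequence of a pattern
#'
#' Returns a pattern identical to the input except that the visit
#' sequence is a uniformly random permutation of the original. The
#' initial center phase and all durations are unchanged. This is the
#' surrogate-null building block: the shuffled trajectory has the same
#' multiset of fixated positions as the true one, so any accuracy
#' difference is attributable to temporal arrangement alone.
#'
#' @param pattern A [marker_pattern()].
#' @param seed Optional integer; when given, the shuffle is drawn from
#'   a local RNG stream seeded with it (the global RNG is untouched).
#' @return A [marker_pattern()] with permuted `visit_sequence`.
#' @export
shuffle_visit_sequence <- function(pattern, seed = NULL) {
  stopifnot(inherits(pattern, "marker_pattern"))
  perm <- if (is.null(seed)) {
    sample(pattern$visit_sequence)
  } else {
    withr::with_seed(as.integer(seed), sample(pattern$visit_sequence))
  }
  out <- pattern
  out$visit_sequence <- perm
  out
}

#' Export a trajectory as delimited text
#'
#' Writes columns `time_s`, `target_x`, `target_y`.
#'
#' @param traj An `instructed_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}
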