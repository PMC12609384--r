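#' Default run configuration
#'
#' Nested list of every pipeline parameter with its protocol default:
#' 200 ms EOG median window, 100 ms eye-tracker Hampel (3 sigma) and
#' median windows, scale-20 Haar blink detector with 0.5 s peak gap
#' and 5-sample interpolation pad, alpha 0.05, SESOI d = 0.1, 90%
#' TOST interval, 100 surrogate shuffles. Serialized as YAML by
#' [write_run_config()].
#'
#' @param ... Named overrides, e.g. `cohort = list(n_participants = 2)`;
#'   merged recursively into the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    pattern = NULL, # NULL means default_pattern()
    cohort = list(
      n_participants = 11L,
      trials_per_cell = 10L,
      incomplete = list(P11 = "off"),
      fs_eog_hz = 512,
      fs_et_hz = 200
    ),
    noise = as.list(unclass(noise_model())),
    preprocess = preprocess_params(),
    analysis = list(fs_analysis_hz = 30),
    stats = list(alpha = 0.05, sesoi_d = 0.1, conf = 0.95,
                 n_comparisons = NULL),
    surrogate = list(n_shuffles = 100L, seed = 1L)
  )
  dots <- list(...)
  merge_rec <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) && nm != "incomplete") {
        base[[nm]] <- merge_rec(base[[nm]], upd[[nm]])
      } else {
        base[nm] <- upd[nm]
      }
    }
    base
  }
  structure(merge_rec(cfg, dots), class = "run_config")
}

config_pattern <- function(config) {
  p <- config$pattern
  if (is.null(p)) return(default_pattern())
  marker_pattern(
    markers = matrix(unlist(p$markers), ncol = 2, byrow = TRUE),
    visit_sequence = unlist(p$visit_sequence),
    fixation_duration_s = p$fixation_duration_s %||% 2,
    initial_phase_s = p$initial_phase_s %||% 2,
    center = unlist(p$center %||% c(0, 0))
  )
}

config_spec <- function(config) {
  cohort_spec(
    n_participants = config$cohort$n_participants,
    trials_per_cell = config$cohort$trials_per_cell,
    incomplete = config$cohort$incomplete %||% list(),
    fs_eog_hz = config$cohort$fs_eog_hz,
    fs_et_hz = config$cohort$fs_et_hz,
    pattern = config_pattern(config),
    model = do.call(noise_model, config$noise),
    seed = config$seed
  )
}

# short deterministic hash of a config, for provenance headers
# (polynomial rolling hash; stays inside the exact-integer range of
# doubles so it is platform independent)
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Read / write a run configuration
#'
#' YAML round trip for [run_config()] objects.
#'
#' @param path File path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "gazeog_missing_input")
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

trial_file_name <- function(participant, block, trial) {
  sprintf("%s_b%d_t%02d.csv", participant, block, trial)
}

#' Write a cohort to delimited-text files
#'
#' One CSV per trial (columns `time_eog_s`, `eog_h`, `eog_v`,
#' `time_et_s`, `et_h`, `et_v`; the eye-tracker columns are empty for
#' eyes-closed trials and the two time bases are padded to a common
#' row count) plus a `manifest.csv` listing participant, block,
#' lighting, eye state, per-trial seed and file path. Each file
#' carries a provenance header (`#` comment lines: package version,
#' config hash, seed).
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if missing).
#' @param config Optional `run_config` used for the provenance hash.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- if (is.null(config)) "none" else config_hash(config)
  header <- function(seed) c(
    sprintf("# gazeog %s", as.character(utils::packageVersion("gazeog"))),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %d", seed)
  )
  files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    eog_h <- cohort$eog_h[[i]]
    eog_v <- cohort$eog_v[[i]]
    et_h <- cohort$et_h[[i]]
    n_eog <- length(eog_h)
    n_et <- if (is.null(et_h)) 0L else length(et_h)
    n_row <- max(n_eog, n_et)
    pad <- function(x, n) c(x, rep(NA_real_, n - length(x)))
    df <- tibble::tibble(
      time_eog_s = pad(signal_time(eog_h), n_row),
      eog_h = pad(as.double(unclass(eog_h)), n_row),
      eog_v = pad(as.double(unclass(eog_v)), n_row),
      time_et_s = if (n_et > 0) pad(signal_time(et_h), n_row) else rep(NA_real_, n_row),
      et_h = if (n_et > 0) pad(as.double(unclass(et_h)), n_row) else rep(NA_real_, n_row),
      et_v = if (n_et > 0) pad(as.double(unclass(cohort$et_v[[i]])), n_row) else rep(NA_real_, n_row)
    )
    fn <- trial_file_name(cohort$participant[i], cohort$block[i],
                          cohort$trial[i])
    path <- file.path(dir, fn)
    writeLines(header(cohort$seed[i]), path)
    suppressMessages(readr::write_csv(df, path, append = TRUE,
                                      col_names = TRUE))
    files[i] <- fn
  }
  first_et <- purrr::detect(cohort$et_h, Negate(is.null))
  manifest <- dplyr::mutate(
    dplyr::select(tibble::as_tibble(cohort), "participant", "block",
                  "lighting", "eye_state", "trial", "seed"),
    file = files,
    fs_eog_hz = fs_hz(cohort$eog_h[[1]]),
    fs_et_hz = if (is.null(first_et)) NA_real_ else fs_hz(first_et)
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and trial files.
#' @param pattern A [marker_pattern()] to rebuild the instructed
#'   trajectory attribute (default [default_pattern()]).
#' @return A cohort tibble.
#' @export
read_cohort <- function(dir, pattern = default_pattern()) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path),
          class = "gazeog_missing_input")
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  rows <- purrr::pmap(manifest, function(participant, block, lighting,
                                         eye_state, trial, seed, file,
                                         fs_eog_hz, fs_et_hz, ...) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      abort(sprintf("trial file missing for %s block %d trial %d: %s",
                    participant, block, trial, path),
            class = "gazeog_missing_input")
    }
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    eog_rows <- !is.na(df$eog_h)
    mk <- function(v, fs, modality, axis) {
      gaze_signal(v, fs, modality = modality, axis = axis)
    }
    has_et <- any(!is.na(df$et_h))
    if (eye_state == "open" && !has_et) {
      abort(sprintf(
        "eyes-open trial without eye-tracker columns: %s block %d trial %d",
        participant, block, trial), class = "gazeog_missing_input")
    }
    list(
      eog_h = mk(df$eog_h[eog_rows], fs_eog_hz, "eog", "horizontal"),
      eog_v = mk(df$eog_v[eog_rows], fs_eog_hz, "eog", "vertical"),
      et_h = if (has_et) mk(df$et_h[!is.na(df$et_h)], fs_et_hz, "et", "horizontal") else NULL,
      et_v = if (has_et) mk(df$et_v[!is.na(df$et_v)], fs_et_hz, "et", "vertical") else NULL
    )
  })
  out <- dplyr::mutate(
    manifest,
    eog_h = purrr::map(rows, "eog_h"),
    eog_v = purrr::map(rows, "eog_v"),
    et_h = purrr::map(rows, "et_h"),
    et_v = purrr::map(rows, "et_v")
  )
  attr(out, "trajectory") <- build_trajectory(pattern, manifest$fs_eog_hz[1])
  class(out) <- c("gazeog_cohort", class(out))
  out
}
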