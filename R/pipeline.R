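#' End-to-end pipeline stages
#'
#' Five pure stage functions tying the modules together; each is a
#' function of (config, directories) only, with all randomness flowing
#' from the seeds in the config, so reruns with the same config are
#' byte-identical. Reports are delimited text with a `#` provenance
#' header (package version, config hash, master seed).
#'
#' * `run_simulate()` generates the synthetic cohort and writes one
#'   delimited-text file per trial plus a manifest.
#' * `run_preprocess()` reads a simulated cohort directory, applies the
#'   conditioning chains and writes the processed trials alongside a
#'   `provenance.txt` sidecar listing the applied operators.
#' * `run_analyze()` writes the similarity, equivalence and lag tables.
#' * `run_surrogate()` writes the shuffled-trajectory MAE report.
#' * `run_report()` runs all stages in order under one output root.
#'
#' @param config A [run_config()].
#' @param dir Stage directory (input and/or output, see details).
#' @param in_dir,out_dir Input / output directories for stages that
#'   read an upstream stage.
#' @return Each stage invisibly returns its main product (a cohort
#'   tibble or a named list of tibbles).
#' @name pipeline
NULL

report_header <- function(config) {
  c(sprintf("# gazeog %s", as.character(utils::packageVersion("gazeog"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %d", config$seed))
}

write_report <- function(df, path, config) {
  writeLines(report_header(config), path)
  suppressMessages(readr::write_csv(df, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname pipeline
#' @export
run_simulate <- function(config = run_config(), dir) {
  cohort <- simulate_cohort(config_spec(config))
  write_cohort(cohort, dir, config)
  invisible(cohort)
}

#' @rdname pipeline
#' @export
run_preprocess <- function(config = run_config(), in_dir, out_dir) {
  cohort <- read_cohort(in_dir, config_pattern(config))
  params <- do.call(preprocess_params, config$preprocess)
  processed <- preprocess_cohort(cohort, params)
  write_cohort(processed, out_dir, config)
  prov <- attr(processed, "provenance")
  writeLines(
    c(report_header(config), "# applied operators:",
      paste0("eog: ", prov$eog), paste0("et:  ", prov$et)),
    file.path(out_dir, "provenance.txt")
  )
  invisible(processed)
}

#' @rdname pipeline
#' @export
run_analyze <- function(config = run_config(), in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  processed <- read_cohort(in_dir, config_pattern(config))
  fs <- config$analysis$fs_analysis_hz
  sim <- modality_similarity_table(processed, fs_analysis = fs)
  eqv <- modality_equivalence_table(
    processed, fs_analysis = fs,
    sesoi_d = config$stats$sesoi_d, conf = config$stats$conf,
    alpha = config$stats$alpha,
    n_comparisons = config$stats$n_comparisons
  )
  lag <- modality_lag_table(processed, fs_analysis = fs)
  write_report(sim, file.path(out_dir, "similarity.csv"), config)
  write_report(eqv, file.path(out_dir, "equivalence.csv"), config)
  write_report(tibble::as_tibble(lag), file.path(out_dir, "lags.csv"), config)
  invisible(list(similarity = sim, equivalence = eqv, lags = lag))
}

#' @rdname pipeline
#' @export
run_surrogate <- function(config = run_config(), in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  processed <- read_cohort(in_dir, config_pattern(config))
  res <- surrogate_mae_test(
    processed, pattern = config_pattern(config),
    n_shuffles = config$surrogate$n_shuffles,
    seed = config$surrogate$seed,
    alpha = config$stats$alpha,
    fs_analysis = config$analysis$fs_analysis_hz
  )
  write_report(res$table, file.path(out_dir, "surrogate.csv"), config)
  write_report(res$trial_mae, file.path(out_dir, "surrogate_trials.csv"),
               config)
  invisible(res)
}

#' @rdname pipeline
#' @export
run_report <- function(config = run_config(), dir) {
  raw_dir <- file.path(dir, "raw")
  proc_dir <- file.path(dir, "processed")
  analysis_dir <- file.path(dir, "analysis")
  run_simulate(config, raw_dir)
  run_preprocess(config, raw_dir, proc_dir)
  tables <- run_analyze(config, proc_dir, analysis_dir)
  surr <- run_surrogate(config, proc_dir, analysis_dir)
  invisible(c(tables, list(surrogate = surr)))
}
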