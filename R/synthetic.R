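#' Noise and artifact model for synthetic trials
#'
#' Parameters of the trial simulator. Defaults emulate the signal
#' features the preprocessing chain is designed to remove: saccadic
#' first-order step responses, slow electrode drift (random walk),
#' additive white noise, biphasic blink transients on the vertical EOG
#' channel, sparse spike outliers on the eye-tracker channels, and a
#' fixed temporal lag of the eye tracker relative to EOG (about 50 ms
#' horizontally and 200 ms vertically).
#'
#' @param gain_h,gain_v Scale from trajectory units to signal units.
#' @param saccade_tau_s First-order step-response time constant (s).
#' @param drift_sd Random-walk step SD per sample (raw units).
#' @param white_sd Additive white-noise SD (raw units).
#' @param blink_rate_hz Poisson rate of blinks (vertical EOG only).
#' @param blink_amp Blink transient amplitude (raw units).
#' @param blink_dur_s Total blink transient width (s).
#' @param lag_h_s,lag_v_s Eye-tracker lag relative to EOG (s).
#' @param spike_rate_hz Poisson rate of eye-tracker outlier spikes.
#' @param spike_amp Spike amplitude (raw units, random sign).
#' @param closed_noise_factor Multiplier on `drift_sd` and `white_sd`
#'   for eyes-closed trials.
#' @return A `noise_model` list.
#' @export
noise_model <- function(gain_h = 1, gain_v = 1,
                        saccade_tau_s = 0.02,
                        drift_sd = 1e-3,
                        white_sd = 0.05,
                        blink_rate_hz = 0.2,
                        blink_amp = 3,
                        blink_dur_s = 0.4,
                        lag_h_s = 0.05,
                        lag_v_s = 0.2,
                        spike_rate_hz = 0.1,
                        spike_amp = 5,
                        closed_noise_factor = 1.5) {
  m <- list(
    gain_h = gain_h, gain_v = gain_v, saccade_tau_s = saccade_tau_s,
    drift_sd = drift_sd, white_sd = white_sd,
    blink_rate_hz = blink_rate_hz, blink_amp = blink_amp,
    blink_dur_s = blink_dur_s, lag_h_s = lag_h_s, lag_v_s = lag_v_s,
    spike_rate_hz = spike_rate_hz, spike_amp = spike_amp,
    closed_noise_factor = closed_noise_factor
  )
  nonneg <- c("saccade_tau_s", "drift_sd", "white_sd", "blink_rate_hz",
              "blink_dur_s", "spike_rate_hz", "closed_noise_factor")
  for (f in nonneg) {
    if (!is.numeric(m[[f]]) || m[[f]] < 0) {
      abort(sprintf("`%s` must be >= 0.", f), class = "gazeog_invalid_parameter")
    }
  }
  structure(m, class = "noise_model")
}

# first-order low-pass step response; tau = 0 is the identity
smooth_first_order <- function(x, fs, tau_s) {
  if (tau_s <= 0) return(x)
  alpha <- 1 - exp(-1 / (fs * tau_s))
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

# biphasic blink transient: positive half-cosine lobe then negative
# lobe, integrating to ~0 (one sine period over the blink width)
blink_shape <- function(n_samples) {
  sin(2 * pi * (seq_len(n_samples) - 0.5) / n_samples)
}

# delay a series by a whole number of samples, holding the first value
delay_samples <- function(x, k) {
  k <- as.integer(round(k))
  if (k <= 0) return(x)
  c(rep(x[1], k), head(x, -k))
}

#' Simulate one EOG trial
#'
#' Horizontal channel: `gain_h` times the first-order-smoothed
#' instructed x trajectory, plus random-walk drift and white noise.
#' Vertical channel: same construction on y, plus biphasic blink
#' transients (positive lobe then negative lobe) at Poisson times.
#' Injected blink onset times are recorded on the vertical channel as
#' attribute `blink_onsets_s` for ground-truth bookkeeping; the clean
#' (noise-free, smoothed, gain-scaled) projections are attached as
#' attribute `ground_truth` on each channel.
#'
#' @param traj An [build_trajectory()] result.
#' @param model A [noise_model()].
#' @param seed Optional integer seed for a local RNG stream.
#' @param noise_factor Multiplier on drift and white noise SDs (used
#'   for eyes-closed trials).
#' @param clean Optional precomputed list `(h, v)` of clean projected
#'   channels (gain times smoothed trajectory); used by
#'   [simulate_cohort()] to avoid re-smoothing the shared trajectory
#'   for every trial.
#' @return List with `gaze_signal` elements `h` and `v`.
#' @export
simulate_eog_trial <- function(traj, model = noise_model(), seed = NULL,
                               noise_factor = 1, clean = NULL) {
  stopifnot(inherits(traj, "instructed_trajectory"))
  run <- function() {
    fs <- traj$fs_hz
    n <- length(traj$x)
    clean_h <- clean$h %||%
      (model$gain_h * smooth_first_order(traj$x, fs, model$saccade_tau_s))
    clean_v <- clean$v %||%
      (model$gain_v * smooth_first_order(traj$y, fs, model$saccade_tau_s))
    drift_sd <- model$drift_sd * noise_factor
    white_sd <- model$white_sd * noise_factor
    mk_noise <- function() {
      d <- if (drift_sd > 0) cumsum(rnorm(n, 0, drift_sd)) else numeric(n)
      w <- if (white_sd > 0) rnorm(n, 0, white_sd) else numeric(n)
      d + w
    }
    h <- clean_h + mk_noise()
    v <- clean_v + mk_noise()

    blink_onsets <- numeric(0)
    if (model$blink_rate_hz > 0 && model$blink_amp != 0) {
      dur <- duration_samples <- max(2L, as.integer(round(model$blink_dur_s * fs)))
      n_blinks <- rpois(1, model$blink_rate_hz * n / fs)
      if (n_blinks > 0) {
        onsets <- sort(runif(n_blinks, 0, (n - duration_samples) / fs))
        shape <- model$blink_amp * blink_shape(duration_samples)
        for (t0 in onsets) {
          i0 <- as.integer(round(t0 * fs)) + 1L
          idx <- i0:(i0 + duration_samples - 1L)
          v[idx] <- v[idx] + shape
        }
        blink_onsets <- onsets
      }
    }

    sh <- gaze_signal(h, fs, modality = "eog", axis = "horizontal")
    sv <- gaze_signal(v, fs, modality = "eog", axis = "vertical")
    attr(sh, "ground_truth") <- clean_h
    attr(sv, "ground_truth") <- clean_v
    attr(sv, "blink_onsets_s") <- blink_onsets
    attr(sv, "blink_dur_s") <- model$blink_dur_s
    list(h = sh, v = sv)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Simulate one eye-tracker trial
#'
#' Per channel: the instructed trajectory delayed by the modality lag
#' (`lag_h_s` / `lag_v_s`), first-order smoothed, plus white noise and
#' sparse single-sample spikes of amplitude `spike_amp` (random sign)
#' at Poisson times, sampled at `fs_et_hz`. Injected spike indices are
#' recorded as attribute `spike_index`; clean projections as attribute
#' `ground_truth`.
#'
#' @param traj An [build_trajectory()] result (any rate; it is
#'   resampled to `fs_et_hz` internally).
#' @param model A [noise_model()].
#' @param fs_et_hz Eye-tracker sampling rate in Hz.
#' @param seed Optional integer seed for a local RNG stream.
#' @param clean Optional precomputed list `(h, v)` of clean delayed,
#'   smoothed channels at `fs_et_hz` (see [simulate_eog_trial()]).
#' @return List with `gaze_signal` elements `h` and `v`.
#' @export
simulate_et_trial <- function(traj, model = noise_model(), fs_et_hz = 200,
                              seed = NULL, clean = NULL) {
  stopifnot(inherits(traj, "instructed_trajectory"))
  run <- function() {
    traj_et <- if (abs(traj$fs_hz - fs_et_hz) > 1e-9) {
      build_trajectory(traj$pattern, fs_et_hz)
    } else {
      traj
    }
    fs <- fs_et_hz
    n <- length(traj_et$x)
    one_channel <- function(base, lag_s, axis) {
      clean_ch <- clean[[if (axis == "horizontal") "h" else "v"]] %||%
        smooth_first_order(delay_samples(base, lag_s * fs), fs,
                           model$saccade_tau_s)
      x <- clean_ch
      if (model$white_sd > 0) x <- x + rnorm(n, 0, model$white_sd)
      spike_idx <- integer(0)
      if (model$spike_rate_hz > 0 && model$spike_amp != 0) {
        n_spikes <- rpois(1, model$spike_rate_hz * n / fs)
        if (n_spikes > 0) {
          spike_idx <- sort(sample.int(n, min(n_spikes, n)))
          x[spike_idx] <- x[spike_idx] +
            model$spike_amp * sample(c(-1, 1), length(spike_idx), replace = TRUE)
        }
      }
      s <- gaze_signal(x, fs, modality = "et", axis = axis)
      attr(s, "ground_truth") <- clean_ch
      attr(s, "spike_index") <- spike_idx
      s
    }
    list(
      h = one_channel(traj_et$x, model$lag_h_s, "horizontal"),
      v = one_channel(traj_et$y, model$lag_v_s, "vertical")
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Cohort specification
#'
#' Describes the study-structured cohort the simulator generates: a
#' 2 x 2 within-subjects design with factors lighting (on/off) and eye
#' state (open/closed). Each participant performs two blocks per
#' lighting condition (one eyes-open, one eyes-closed, order
#' counterbalanced by participant parity), each block holding
#' `trials_per_cell` trials. By default 11 participants are generated
#' and one of them completes only the lights-off condition, so the
#' eyes-open grand-average pool spans 210 trials.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Trials per (lighting x eye-state) cell.
#' @param incomplete Named list mapping participant id (e.g. `"P11"`)
#'   to the character vector of lighting conditions completed. The
#'   default (`NULL`) marks the last participant of an 11-strong
#'   cohort as having completed only the lights-off condition, and
#'   means no incompletes for other cohort sizes.
#' @param fs_eog_hz EOG sampling rate (Hz).
#' @param fs_et_hz Eye-tracker sampling rate (Hz).
#' @param pattern A [marker_pattern()].
#' @param model A [noise_model()] (applied to every participant unless
#'   overridden).
#' @param participant_models Optional named list of [noise_model()]
#'   overrides per participant id.
#' @param seed Master seed; every trial derives its own child seed
#'   from it, so trials are reproducible independently of generation
#'   order.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 11,
                        trials_per_cell = 10,
                        incomplete = NULL,
                        fs_eog_hz = 512,
                        fs_et_hz = 200,
                        pattern = default_pattern(),
                        model = noise_model(),
                        participant_models = list(),
                        seed = 1L) {
  ids <- sprintf("P%02d", seq_len(n_participants))
  if (is.null(incomplete)) {
    incomplete <- if (n_participants == 11L) {
      setNames(list("off"), ids[n_participants])
    } else {
      list()
    }
  }
  if (length(incomplete) > 0) {
    bad <- setdiff(names(incomplete), ids)
    if (length(bad) > 0) {
      abort(sprintf("incomplete participant(s) not in roster: %s",
                    paste(bad, collapse = ", ")),
            class = "gazeog_invalid_spec")
    }
    if (!all(unlist(incomplete) %in% c("on", "off"))) {
      abort("incomplete entries must be subsets of c('on', 'off').",
            class = "gazeog_invalid_spec")
    }
  }
  bad_m <- setdiff(names(participant_models), ids)
  if (length(bad_m) > 0) {
    abort(sprintf("participant_models id(s) not in roster: %s",
                  paste(bad_m, collapse = ", ")),
          class = "gazeog_invalid_spec")
  }
  structure(
    list(
      participants = ids,
      trials_per_cell = as.integer(trials_per_cell),
      incomplete = incomplete,
      fs_eog_hz = fs_eog_hz, fs_et_hz = fs_et_hz,
      pattern = pattern, model = model,
      participant_models = participant_models,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# deterministic child seed per (participant index, trial counter),
# kept below 2^31
child_seed <- function(master, p_index, trial_index) {
  as.integer((as.double(master) * 7919 + p_index * 104729 +
                trial_index * 131) %% 2147483647)
}

#' Simulate a full cohort
#'
#' Generates every trial of the design described by a [cohort_spec()].
#' Lighting-condition order is counterbalanced by participant parity,
#' and within each lighting condition the eyes-open and eyes-closed
#' blocks alternate order the same way. Eyes-closed trials carry no
#' eye-tracker channels (the camera-based tracker cannot see the
#' occluded eye) and use drift/white noise inflated by
#' `closed_noise_factor`. The result is bit-reproducible for a given
#' spec because every trial draws from its own child seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` tibble with one row per trial: `participant`,
#'   `block`, `lighting`, `eye_state`, `trial`, `seed`, and
#'   list-columns `eog_h`, `eog_v`, `et_h`, `et_v` of
#'   [gaze_signal()]s (`et_*` are `NULL` for eyes-closed trials).
#'   The instructed trajectory at EOG rate is attached as attribute
#'   `trajectory`, the spec as attribute `spec`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_participants = 2,
#'                                    trials_per_cell = 1,
#'                                    incomplete = list(),
#'                                    fs_eog_hz = 64))
#' nrow(coh) # 8
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  traj <- build_trajectory(spec$pattern, spec$fs_eog_hz)

  plan <- purrr::imap_dfr(spec$participants, function(pid, p_index) {
    lightings <- spec$incomplete[[pid]] %||% c("on", "off")
    light_order <- if (p_index %% 2L == 0L) c("off", "on") else c("on", "off")
    lightings <- light_order[light_order %in% lightings]
    if (length(lightings) == 0L) return(tibble::tibble())
    eye_order <- if (p_index %% 2L == 0L) c("closed", "open") else c("open", "closed")
    blocks <- tidyr::expand_grid(lighting = lightings, eye_state = eye_order)
    blocks$block <- seq_len(nrow(blocks))
    tidyr::expand_grid(blocks, trial = seq_len(spec$trials_per_cell)) |>
      dplyr::mutate(participant = pid, p_index = p_index)
  })
  plan <- plan |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(trial_counter = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(seed = child_seed(spec$seed, .data$p_index, .data$trial_counter))

  # the clean (noise-free) channels are shared by all of a
  # participant's trials; precompute them once per participant
  traj_et <- build_trajectory(spec$pattern, spec$fs_et_hz)
  clean_for <- function(model) {
    list(
      eog = list(
        h = model$gain_h * smooth_first_order(traj$x, spec$fs_eog_hz,
                                              model$saccade_tau_s),
        v = model$gain_v * smooth_first_order(traj$y, spec$fs_eog_hz,
                                              model$saccade_tau_s)
      ),
      et = list(
        h = smooth_first_order(
          delay_samples(traj_et$x, model$lag_h_s * spec$fs_et_hz),
          spec$fs_et_hz, model$saccade_tau_s),
        v = smooth_first_order(
          delay_samples(traj_et$y, model$lag_v_s * spec$fs_et_hz),
          spec$fs_et_hz, model$saccade_tau_s)
      )
    )
  }
  default_clean <- clean_for(spec$model)
  clean_by_pid <- lapply(setNames(nm = spec$participants), function(pid) {
    m <- spec$participant_models[[pid]]
    if (is.null(m)) default_clean else clean_for(m)
  })

  sims <- purrr::pmap(
    list(plan$participant, plan$eye_state, plan$seed),
    function(pid, eye_state, seed) {
      model <- spec$participant_models[[pid]] %||% spec$model
      nf <- if (eye_state == "closed") model$closed_noise_factor else 1
      cl <- clean_by_pid[[pid]]
      eog <- simulate_eog_trial(traj, model, seed = seed, noise_factor = nf,
                                clean = cl$eog)
      if (eye_state == "open") {
        et <- simulate_et_trial(traj_et, model, fs_et_hz = spec$fs_et_hz,
                                seed = seed + 1L, clean = cl$et)
      } else {
        et <- list(h = NULL, v = NULL)
      }
      list(eog_h = eog$h, eog_v = eog$v, et_h = et$h, et_v = et$v)
    }
  )

  out <- tibble::tibble(
    participant = plan$participant,
    block = plan$block,
    lighting = plan$lighting,
    eye_state = plan$eye_state,
    trial = plan$trial,
    seed = plan$seed,
    eog_h = purrr::map(sims, "eog_h"),
    eog_v = purrr::map(sims, "eog_v"),
    et_h = purrr::map(sims, "et_h"),
    et_v = purrr::map(sims, "et_v")
  )
  attr(out, "trajectory") <- traj
  attr(out, "spec") <- spec
  class(out) <- c("gazeog_cohort", class(out))
  out
}

#' Instructed trajectory attached to a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return The `instructed_trajectory` the cohort was generated from.
#' @export
cohort_trajectory <- function(cohort) attr(cohort, "trajectory")
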