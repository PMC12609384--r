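test_that("linear detrend recovers a sinusoid from sinusoid + line", {
  fs <- 100
  n <- 401 # odd: the grid is symmetric about its middle sample
  t <- (seq_len(n) - 1) / fs
  # a cosine spanning full periods of the (n - 1) sample intervals is
  # exactly symmetric about the record midpoint, so its least-squares
  # line is exactly zero and detrending must return it unchanged
  sine <- cos(2 * pi * 2 * t) # 2 Hz, 8 periods over t in [0, 4]
  sine <- sine - mean(sine)
  line <- 0.7 + 0.3 * t
  sig <- gaze_signal(sine + line, fs, axis = "horizontal")
  out <- linear_detrend(sig)
  expect_lt(max(abs(as.double(unclass(out)) - sine)), 1e-9)
  # idempotent
  out2 <- linear_detrend(out)
  expect_equal(as.double(unclass(out2)), as.double(unclass(out)),
               tolerance = 1e-12)
})

test_that("median filter matches the brute-force sliding median", {
  for (seed in 1:3) {
    sig <- rand_sig(150, fs = 100, seed = seed)
    for (window_ms in c(50, 90, 31)) {
      out <- median_filter(sig, window_ms)
      # the window actually used: round(ms*fs/1000), forced odd
      kk <- as.integer(round(window_ms * 100 / 1000))
      if (kk %% 2L == 0L) kk <- kk + 1L
      expect_identical(as.double(unclass(out)),
                       brute_median_filter(as.double(unclass(sig)), kk))
    }
  }
})

test_that("median filter preserves constants and suppresses lone spikes", {
  sig <- gaze_signal(rep(2, 50), 100, axis = "horizontal")
  expect_equal(as.double(unclass(median_filter(sig, 50))), rep(2, 50))
  x <- rep(0, 50); x[25] <- 10
  out <- median_filter(gaze_signal(x, 100, axis = "horizontal"), 50)
  expect_equal(as.double(unclass(out)), rep(0, 50))
})

test_that("Haar coefficients match the brute-force inner product", {
  for (seed in 4:6) {
    sig <- rand_sig(200, fs = 100, seed = seed)
    for (scale in c(3, 10, 20)) {
      expect_lt(max(abs(haar_cwt(sig, scale) -
                          brute_haar(as.double(unclass(sig)), scale))),
                1e-9)
    }
  }
})

test_that("a rising unit step gives a positive Haar extremum at the step", {
  n <- 200; k <- 100
  x <- c(rep(0, k - 1), rep(1, n - k + 1)) # step up at index k
  co <- haar_cwt(gaze_signal(x, 100, axis = "vertical"), 10)
  expect_equal(which.max(co), k)
  expect_gt(co[k], 0)
  # analytic peak value: scale samples of 1 on the right, 0 left
  expect_equal(co[k], 10 / sqrt(10), tolerance = 1e-12)
  # falling step: negative extremum
  co2 <- haar_cwt(gaze_signal(1 - x, 100, axis = "vertical"), 10)
  expect_equal(which.min(co2), k)
  expect_lt(co2[k], 0)
})

test_that("sliding SD matches the brute-force windowed SD", {
  for (seed in 7:9) {
    sig <- rand_sig(120, fs = 1000, seed = seed)
    out <- sliding_sd(sig, 15) # 15 samples at 1 kHz
    expect_lt(max(abs(as.double(unclass(out)) -
                        brute_sliding_sd(as.double(unclass(sig)), 15L))),
              1e-9)
  }
})

test_that("sliding SD of unit-variance white noise concentrates near 1", {
  sig <- rand_sig(20000, fs = 1000, seed = 10)
  vals <- as.double(unclass(sliding_sd(sig, 31)))
  # E[SD] for n=31 Gaussian samples is ~0.992; allow a 3-SE band
  se <- sd(vals) / sqrt(length(vals) / 31) # effective independent windows
  expect_lt(abs(mean(vals) - 1), 0.01 + 3 * se)
})

test_that("one injected biphasic blink yields exactly one event", {
  tr <- build_trajectory(default_pattern(), 512)
  m <- noise_model(drift_sd = 1e-4, white_sd = 0.02, blink_rate_hz = 0,
                   spike_rate_hz = 0)
  eog <- simulate_eog_trial(tr, m, seed = 21)
  v <- as.double(unclass(eog$v))
  dur <- round(0.4 * 512)
  shape <- 3 * sin(2 * pi * (seq_len(dur) - 0.5) / dur)
  i0 <- round(5 * 512) + 1L
  v[i0:(i0 + dur - 1L)] <- v[i0:(i0 + dur - 1L)] + shape
  sig <- median_filter(linear_detrend(
    gaze_signal(v, 512, modality = "eog", axis = "vertical")), 200)
  ev <- detect_blinks(sig, scale = 20)
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$pos_peak_index, i0 - 26L) # within half a wavelet width
  expect_lte(ev$pos_peak_index, i0 + dur)
})

test_that("two blinks one second apart yield two separate events", {
  tr <- build_trajectory(default_pattern(), 512)
  m <- noise_model(drift_sd = 1e-4, white_sd = 0.02, blink_rate_hz = 0,
                   spike_rate_hz = 0)
  eog <- simulate_eog_trial(tr, m, seed = 22)
  v <- as.double(unclass(eog$v))
  dur <- round(0.4 * 512)
  shape <- 3 * sin(2 * pi * (seq_len(dur) - 0.5) / dur)
  starts <- round(c(5, 6) * 512) + 1L
  for (i0 in starts) v[i0:(i0 + dur - 1L)] <- v[i0:(i0 + dur - 1L)] + shape
  sig <- median_filter(linear_detrend(
    gaze_signal(v, 512, modality = "eog", axis = "vertical")), 200)
  ev <- detect_blinks(sig, scale = 20)
  expect_equal(nrow(ev), 2L)
  # neither event spans both injected windows
  expect_lt(ev$offset_index[1], starts[2])
  expect_gt(ev$onset_index[2], starts[1] + dur)
})

test_that("a blink-free trial yields no events", {
  tr <- build_trajectory(default_pattern(), 512)
  m <- noise_model(blink_rate_hz = 0)
  for (seed in 23:25) {
    eog <- simulate_eog_trial(tr, m, seed = seed)
    sig <- median_filter(linear_detrend(eog$v), 200)
    expect_equal(nrow(detect_blinks(sig, scale = 20)), 0L)
  }
})

test_that("detect_blinks insists on the vertical channel", {
  sig <- rand_sig(2000, fs = 512, axis = "horizontal", seed = 1)
  expect_error(detect_blinks(sig), class = "gazeog_invalid_input")
})

test_that("blink removal reduces RMSE to the clean signal and touches
           nothing outside the padded spans", {
  tr <- build_trajectory(default_pattern(), 512)
  eog <- simulate_eog_trial(tr, noise_model(), seed = 5)
  clean <- median_filter(linear_detrend(
    gaze_signal(attr(eog$v, "ground_truth"), 512, modality = "eog",
                axis = "vertical")), 200)
  v <- median_filter(linear_detrend(eog$v), 200)
  ev <- detect_blinks(v, scale = 20)
  expect_gt(nrow(ev), 0L)
  fixed <- remove_blinks(v, ev, pad = 5)
  rmse <- function(a, b) sqrt(mean((as.double(unclass(a)) -
                                      as.double(unclass(b)))^2))
  expect_lt(rmse(fixed, clean), rmse(v, clean))
  # untouched outside padded spans
  in_span <- rep(FALSE, length(v))
  for (i in seq_len(nrow(ev))) {
    a <- max(1L, ev$onset_index[i] - 5L)
    b <- min(length(v), ev$offset_index[i] + 5L)
    in_span[a:b] <- TRUE
  }
  expect_identical(as.double(unclass(fixed))[!in_span],
                   as.double(unclass(v))[!in_span])
})

test_that("remove_blinks with no events is the identity", {
  sig <- rand_sig(100, fs = 100, axis = "vertical", seed = 2)
  empty <- tibble::tibble(pos_peak_index = integer(0),
                          neg_peak_index = integer(0),
                          onset_index = integer(0),
                          offset_index = integer(0))
  expect_identical(unclass(remove_blinks(sig, empty)), unclass(sig))
})

test_that("Hampel filter replaces a lone spike (worked example)", {
  # spike of 100 in zeros; 7-sample window at 70 Hz / 100 ms
  x <- rep(0, 40); x[20] <- 100
  sig <- gaze_signal(x, 70, modality = "et", axis = "horizontal")
  out <- hampel_filter(sig, 100, 3)
  expect_equal(as.double(unclass(out))[20], 0)
  expect_equal(attr(out, "n_replaced"), 1L)
  expect_equal(as.double(unclass(out)), rep(0, 40))
})

test_that("Hampel filter alters spikes but rarely clean samples", {
  tr <- build_trajectory(default_pattern(), 512)
  spikes <- 0L; altered <- 0L; clean_alt <- 0L; n_clean <- 0L
  for (seed in 1:5) {
    et <- simulate_et_trial(tr, noise_model(), fs_et_hz = 200, seed = seed)
    for (ch in list(et$h, et$v)) {
      idx <- attr(ch, "spike_index")
      out <- hampel_filter(ch, 100, 3)
      changed <- which(as.double(unclass(out)) != as.double(unclass(ch)))
      spikes <- spikes + length(idx)
      altered <- altered + sum(idx %in% changed)
      clean_alt <- clean_alt + length(setdiff(changed, idx))
      n_clean <- n_clean + length(ch) - length(idx)
    }
  }
  expect_gt(spikes, 0L)
  expect_gte(altered / spikes, 0.95)
  expect_lte(clean_alt / n_clean, 0.01)
})

test_that("MAD dispersion is accepted and also catches the worked example", {
  x <- rep(0, 40); x[20] <- 100
  sig <- gaze_signal(x, 70, modality = "et", axis = "horizontal")
  out <- hampel_filter(sig, 100, 3, dispersion = "mad")
  expect_equal(as.double(unclass(out))[20], 0)
})

test_that("standardize yields zero mean, unit SD, and rejects constants", {
  sig <- rand_sig(500, seed = 3)
  z <- standardize(sig)
  expect_equal(mean(as.double(unclass(z))), 0, tolerance = 1e-12)
  expect_equal(sd(as.double(unclass(z))), 1, tolerance = 1e-12)
  flat <- gaze_signal(rep(1, 10), 30, axis = "horizontal")
  expect_error(standardize(flat), class = "gazeog_degenerate_signal")
})

test_that("resampling maps a 24 s signal to 720 samples at 30 Hz", {
  sig <- gaze_signal(sin(seq_len(12288) / 300), 512, axis = "horizontal")
  out <- resample_to(sig, 30)
  expect_length(out, 720L)
  expect_equal(fs_hz(out), 30)
  # values interpolate the source
  expect_equal(as.double(unclass(out))[1], as.double(unclass(sig))[1])
})

test_that("noiseless end-to-end EOG reproduces the instructed trajectory", {
  tr <- build_trajectory(default_pattern(), 512)
  m <- noise_model(drift_sd = 0, white_sd = 0, blink_rate_hz = 0,
                   spike_rate_hz = 0)
  eog <- simulate_eog_trial(tr, m, seed = 1)
  out <- resample_to(preprocess_eog_signal(eog$h), 30)
  # the chain detrends, so compare against the identically detrended
  # standardized trajectory (the instructed path has a nonzero net
  # slope; detrending tilts both sides equally)
  ref <- standardize(resample_to(
    linear_detrend(trajectory_signal(tr, "horizontal")), 30))
  expect_gt(cosine_similarity(out, ref), 0.99)
})

test_that("shared-seed trials with and without blinks agree after the chain", {
  tr <- build_trajectory(default_pattern(), 512)
  a <- simulate_eog_trial(tr, noise_model(), seed = 2)
  b <- simulate_eog_trial(tr, noise_model(blink_rate_hz = 0), seed = 2)
  va <- preprocess_eog_signal(a$v)
  vb <- preprocess_eog_signal(b$v)
  d <- as.double(unclass(va)) - as.double(unclass(vb))
  # interpolated spans replace genuine signal, so agreement is judged
  # outside them; overall the channels stay far closer than the blink
  # amplitude (several z-units)
  ev <- detect_blinks(median_filter(linear_detrend(a$v), 200), scale = 20)
  in_span <- rep(FALSE, length(d))
  for (i in seq_len(nrow(ev))) {
    lo <- max(1L, ev$onset_index[i] - 5L)
    hi <- min(length(d), ev$offset_index[i] + 5L)
    in_span[lo:hi] <- TRUE
  }
  expect_lt(sqrt(mean(d[!in_span]^2)), 0.1)
  expect_lt(sqrt(mean(d^2)), 0.6)
  # and removal is essential: without it the channels disagree more
  va_raw <- preprocess_eog_signal(a$v, remove_blink_stage = FALSE)
  d_raw <- as.double(unclass(va_raw)) - as.double(unclass(vb))
  expect_lt(sqrt(mean(d^2)), sqrt(mean(d_raw^2)))
})

test_that("preprocess_cohort conditions every channel and records provenance", {
  spec <- cohort_spec(n_participants = 2, trials_per_cell = 1,
                      incomplete = list(), fs_eog_hz = 64, fs_et_hz = 64)
  coh <- preprocess_cohort(simulate_cohort(spec))
  open <- coh[coh$eye_state == "open", ]
  for (s in c(open$eog_h, open$eog_v, open$et_h, open$et_v)) {
    expect_equal(sd(as.double(unclass(s))), 1, tolerance = 1e-9)
  }
  closed <- coh[coh$eye_state == "closed", ]
  expect_true(all(vapply(closed$et_h, is.null, logical(1))))
  prov <- attr(coh, "provenance")
  expect_true(any(grepl("linear_detrend", prov$eog)))
  expect_true(any(grepl("hampel", prov$et)))
})
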