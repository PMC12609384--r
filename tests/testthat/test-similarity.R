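test_that("grand average equals the pointwise mean and shrinks noise", {
  sigs <- lapply(1:4, function(k) rand_sig(50, seed = k))
  ga <- grand_average(sigs)
  ref <- rowMeans(vapply(sigs, function(s) as.double(unclass(s)),
                         numeric(50)))
  expect_equal(as.double(unclass(ga)), ref, tolerance = 1e-12)

  # 10 noisy copies of a trajectory: residual SD ~ sigma / sqrt(10)
  base <- trajectory_signal(build_trajectory(default_pattern(), 30),
                            "horizontal")
  sigma <- 0.5
  copies <- lapply(1:10, function(k) {
    withr::with_seed(k, gaze_signal(as.double(unclass(base)) +
                                      rnorm(720, 0, sigma),
                                    30, axis = "horizontal"))
  })
  resid <- as.double(unclass(grand_average(copies))) -
    as.double(unclass(base))
  target <- sigma / sqrt(10)
  se <- target / sqrt(2 * 720) # SE of an SD estimate from 720 draws
  expect_lt(abs(sd(resid) - target), 3 * se + 0.01)
})

test_that("grand average rejects misaligned inputs", {
  a <- rand_sig(50, fs = 100, seed = 1)
  b <- rand_sig(60, fs = 100, seed = 2)
  expect_error(grand_average(list(a, b)), class = "gazeog_alignment_error")
  expect_error(grand_average(list()), class = "gazeog_alignment_error")
})

test_that("cosine similarity has the textbook geometry", {
  a <- rand_sig(100, seed = 1)
  expect_equal(cosine_similarity(a, a), 1, tolerance = 1e-12)
  neg <- gaze_signal(-as.double(unclass(a)), 100, axis = "horizontal")
  expect_equal(cosine_similarity(a, neg), -1, tolerance = 1e-12)
  # invariant to positive rescaling
  scaled <- gaze_signal(3.7 * as.double(unclass(a)), 100,
                        axis = "horizontal")
  expect_equal(cosine_similarity(a, scaled), 1, tolerance = 1e-12)
  # orthogonal by construction
  x <- gaze_signal(c(1, 0, 1, 0), 10, axis = "horizontal")
  y <- gaze_signal(c(0, 1, 0, 1), 10, axis = "horizontal")
  expect_equal(cosine_similarity(x, y), 0)
  z <- gaze_signal(rep(0, 4), 10, axis = "horizontal")
  expect_error(cosine_similarity(x, z), class = "gazeog_degenerate_signal")
})

test_that("self cross-correlation peaks at normalized lag 0.5", {
  tr <- build_trajectory(default_pattern(), 30)
  s <- trajectory_signal(tr, "horizontal")
  xc <- normalized_xcorr(s, s)
  expect_equal(xc$peak_norm_lag, 0.5)
  expect_equal(xc$peak_lag_s, 0)
  expect_equal(xc$peak_coeff, 1, tolerance = 1e-9)
  expect_true(all(xc$norm_coeffs >= 0 & xc$norm_coeffs <= 1))
  expect_equal(range(xc$norm_lags), c(0, 1))
})

test_that("a constructed delay displaces the peak by exactly k samples", {
  fs <- 100
  # white noise has a delta autocorrelation, so the full
  # cross-correlation peaks exactly at the constructed displacement
  withr::with_seed(8, base <- rnorm(300))
  for (k in c(3L, 17L)) {
    a <- gaze_signal(base, fs, axis = "horizontal")
    b <- gaze_signal(c(rep(base[1], k), head(base, -k)), fs,
                     axis = "horizontal")
    xc <- normalized_xcorr(a, b)
    # a leads the delayed copy by k samples: positive lag k/fs
    expect_equal(xc$peak_lag_s, k / fs)
    expect_equal(xc$peak_norm_lag, 0.5 + k / (2 * (length(base) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("cross-correlation matches the brute-force oracle", {
  for (seed in 1:3) {
    n <- sample(100:200, 1)
    a <- rand_sig(n, seed = seed)
    b <- rand_sig(n, seed = seed + 50)
    xc <- normalized_xcorr(a, b)
    oracle <- brute_xcorr(a, b)
    expect_lt(max(abs(xc$coeffs - oracle$r)), 1e-9)
    expect_identical(oracle$lags[which.max(oracle$r)],
                     as.integer(round(xc$peak_lag_s * 100)))
  }
})

test_that("cross-correlation validates rates and exposes tidy views", {
  a <- rand_sig(50, fs = 100, seed = 1)
  b <- rand_sig(50, fs = 30, seed = 2)
  expect_error(normalized_xcorr(a, b), class = "gazeog_alignment_error")
  xc <- normalized_xcorr(a, rand_sig(50, fs = 100, seed = 3))
  td <- tidy(xc)
  expect_equal(nrow(td), 99L)
  expect_named(td, c("norm_lag", "norm_coeff", "lag_s"))
  gl <- glance(xc)
  expect_equal(gl$n, 50L)
})

small_cohort <- function(model, seed = 1, trials = 1, participants = 2) {
  simulate_cohort(cohort_spec(
    n_participants = participants, trials_per_cell = trials,
    incomplete = list(), fs_eog_hz = 64, fs_et_hz = 64,
    model = model, seed = seed
  ))
}

test_that("a noiseless cohort yields near-perfect modality similarity", {
  m <- noise_model(drift_sd = 0, white_sd = 0, blink_rate_hz = 0,
                   spike_rate_hz = 0, lag_h_s = 0, lag_v_s = 0)
  raw <- small_cohort(m)
  coh <- preprocess_cohort(raw)
  tab <- modality_similarity_table(coh)
  # the study chains detrend EOG but not the tracker, and the
  # instructed path has a nonzero net slope, so cross-modality
  # cosines saturate just below 1 even without noise
  expect_true(all(tab$cosine > 0.97))
  expect_setequal(unique(tab$axis), c("horizontal", "vertical"))
  # under identical conditioning the agreement is essentially exact
  i <- which(raw$eye_state == "open")[1]
  eog <- resample_to(preprocess_eog_signal(raw$eog_h[[i]]), 30)
  et <- resample_to(preprocess_eog_signal(raw$et_h[[i]]), 30)
  expect_gt(cosine_similarity(eog, et), 0.999)
})

test_that("a noise-swapped tracker makes its participant the low outlier", {
  coh <- preprocess_cohort(small_cohort(noise_model(), participants = 3,
                                        trials = 2))
  bad <- coh$participant == "P02" & coh$eye_state == "open"
  coh$et_h[bad] <- lapply(coh$et_h[bad], function(s) {
    withr::with_seed(99, signal <- rnorm(length(s)))
    standardize(gaze_signal(signal, fs_hz(s), modality = "et",
                            axis = "horizontal"))
  })
  tab <- modality_similarity_table(coh)
  horiz <- tab[tab$axis == "horizontal", ]
  by_p <- tapply(horiz$cosine, horiz$participant, mean)
  expect_equal(names(which.min(by_p)), "P02")
  expect_lt(max(by_p[["P02"]]), min(by_p[c("P01", "P03")]) - 0.2)
})

test_that("similarity and lag tables reject cohorts without open trials", {
  m <- noise_model()
  coh <- small_cohort(m)
  closed_only <- coh[coh$eye_state == "closed", ]
  expect_error(modality_similarity_table(closed_only),
               class = "gazeog_empty_input")
  expect_error(modality_lag_table(closed_only),
               class = "gazeog_empty_input")
})

test_that("the lag table recovers the simulated tracker delay", {
  m <- noise_model(blink_rate_hz = 0.1)
  coh <- preprocess_cohort(small_cohort(m, trials = 2))
  tab <- modality_lag_table(coh, fs_analysis = 30)
  per <- tab[tab$participant != "All", ]
  # EOG leads the tracker: positive lag, larger on the vertical axis
  horiz <- per$peak_lag_s[per$axis == "horizontal"]
  vert <- per$peak_lag_s[per$axis == "vertical"]
  expect_true(all(horiz >= 0))
  expect_true(all(vert >= 0.1 & vert <= 0.3)) # simulated 0.2 s
  expect_true(all(abs(horiz - 0.05) <= 0.067)) # within 2 analysis samples
  # group rows and curves are present
  expect_equal(sum(tab$participant == "All"), 2L)
  curves <- attr(tab, "curves")
  expect_true(all(c("participant", "axis", "norm_lag", "norm_coeff") %in%
                    names(curves)))
  expect_true("All" %in% curves$participant)
})
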