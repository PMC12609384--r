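# Brute-force reference implementations used as oracles. Each mirrors
# the documented convention of the fast implementation (edge-value
# padding for sliding windows, zero padding for the wavelet) but is
# written as a direct per-sample loop.

rand_sig <- function(n, fs = 100, axis = "horizontal", seed = 1,
                     modality = "eog") {
  withr::with_seed(seed, gaze_signal(rnorm(n), fs, modality = modality,
                                     axis = axis))
}

brute_median_filter <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) median(xp[i:(i + k - 1L)]), numeric(1))
}

brute_sliding_sd <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) sd(xp[i:(i + k - 1L)]), numeric(1))
}

brute_haar <- function(x, scale) {
  n <- length(x)
  xp <- c(numeric(scale), x, numeric(scale))
  vapply(seq_len(n), function(i) {
    j <- i + scale # position of x[i] in xp
    (sum(xp[j:(j + scale - 1L)]) - sum(xp[(j - scale):(j - 1L)])) /
      sqrt(scale)
  }, numeric(1))
}

# full cross-correlation of z-scored inputs over all displacements;
# returns list(lags, r)
brute_xcorr <- function(x, y) {
  x <- as.numeric(scale(as.double(unclass(x))))
  y <- as.numeric(scale(as.double(unclass(y))))
  n <- length(x)
  m <- length(y)
  lags <- seq.int(-(m - 1L), n - 1L)
  r <- vapply(lags, function(k) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= m
    sum(x[i[ok]] * y[j[ok]])
  }, numeric(1))
  list(lags = lags, r = r)
}

brute_mae <- function(x, y) {
  d <- abs(as.double(unclass(x)) - as.double(unclass(y)))
  mean(d)
}
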