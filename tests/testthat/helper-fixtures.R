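# Shared fixtures. Small, fast trials for unit tests (lower sampling rate,
# short static prefix); the acceptance suite uses the full defaults.

fast_params <- function(...) {
  gait_params(fs = 60, static_duration = 1.5,
              noise_sigma_acc = 0, noise_sigma_gyr = 0, ...)
}

fast_trial <- function(seed = 1, ...) {
  simulate_trial(fast_params(seed = seed, ...), trial_id = paste0("fx", seed))
}

fast_corpus <- function(n, seed = 1, ...) {
  make_corpus(n, seed = seed, fs = 60, static_duration = 1.5,
              noise_sigma_acc = 0, noise_sigma_gyr = 0, ...)
}

# independent exhaustive search for the best information-gain split:
# brute force over every feature and every midpoint threshold
oracle_best_gain <- function(X, y, min_leaf = 1) {
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (f in names(X)) {
    xs <- sort(unique(X[[f]]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      nl <- sum(X[[f]] <= thr)
      if (nl < min_leaf || (length(y) - nl) < min_leaf) next
      g <- information_gain(X[[f]], y, thr)
      if (g > best$gain + 1e-12) {
        best <- list(gain = g, feature = f, threshold = thr)
      }
    }
  }
  best
}

# random small classification table
random_table <- function(n, p, k) {
  X <- as.data.frame(matrix(sample(1:5, n * p, replace = TRUE) +
                              stats::rnorm(n * p, sd = 0.01), n, p))
  names(X) <- paste0("f", seq_len(p))
  y <- factor(sample(letters[seq_len(k)], n, replace = TRUE))
  list(X = X, y = y)
}
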