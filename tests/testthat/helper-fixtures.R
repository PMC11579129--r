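# Shared fixtures: everything is generated in code at test time.

# sinusoid sampled at fs over an exact duration
sine_wave <- function(freq_hz, fs = 2000, duration_s = 1, phase = 0, amp = 1) {
  t <- (seq_len(round(fs * duration_s)) - 1) / fs
  amp * sin(2 * pi * freq_hz * t + phase)
}

# white-noise recording
noise_recording <- function(n_ch = 4, n_samp = 2000, fs = 2000, sd = 1,
                            seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_ch * n_samp, sd = sd), n_ch, n_samp), fs_hz = fs)
}

# minimal trial_set built by hand: trials x channels x samples
manual_trial_set <- function(epochs, labels, fs = 2000) {
  structure(list(epochs = epochs,
                 label = factor(labels, levels = c("rest", "active")),
                 onset_s = seq_len(dim(epochs)[1]),
                 duration_s = rep(dim(epochs)[3] / fs, dim(epochs)[1]),
                 fs_hz = fs,
                 channel_id = sprintf("E%03d", seq_len(dim(epochs)[2])),
                 good_mask = rep(TRUE, dim(epochs)[2])),
            class = "trial_set")
}

# fast low-cost simulation config for unit tests
quick_sim_config <- function(seed = 1, duration_s = 1, ...) {
  sim_config(duration_s = duration_s, source_spacing_mm = 2,
             n_subpoints = 4, seed = seed, ...)
}

# brute-force IED bin oracle: exhaustive enumeration over all good pairs
brute_force_bins <- function(layout, good_mask = NULL, round_to = 0.1,
                             min_pairs = 1) {
  n <- nrow(layout)
  if (is.null(good_mask)) good_mask <- rep(TRUE, n)
  keep <- which(good_mask)
  counts <- list()
  for (i in keep) for (j in keep) {
    if (j <= i) next
    d <- sqrt((layout$x[i] - layout$x[j])^2 + (layout$y[i] - layout$y[j])^2)
    lab <- sprintf("%.9g", round(round(d / round_to) * round_to, 9))
    counts[[lab]] <- (if (is.null(counts[[lab]])) 0L else counts[[lab]]) + 1L
  }
  d <- as.numeric(names(counts))
  n_pairs <- unlist(counts, use.names = FALSE)
  ord <- order(d)
  out <- data.frame(distance_mm = d[ord], n_pairs = n_pairs[ord])
  out[out$n_pairs >= min_pairs, , drop = FALSE]
}

# exhaustive two-sided rank-sum p-value by enumerating all assignments
enumerate_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- colSums(matrix(rk[combos], nrow = n))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
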