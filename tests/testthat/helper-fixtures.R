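# Shared fixtures, all generated in code.

# A conditioned window cut from the middle of a clean synthetic recording
# (the leading samples are dropped so the filter warm-up never leaks in).
conditioned_window <- function(hr = 75, seed = 1, N = 256, fs = 32,
                               noise_sd = 2, drift_sd = 0.5) {
  dur <- (2 * N) / fs + 8
  rec <- synth_recording(synth_config(fs = fs, duration_s = dur, hr = hr,
                                      noise_sd = noise_sd, drift_sd = drift_sd,
                                      seed = seed))
  y <- condition_signal(rec$ppg, conditioning_config(fs = fs))
  start <- length(y) - N + 1
  y[start:(length(y))]
}

# Literal transcription of the shifted-index (1-based matrix) definition of
# the binary local-maxima scalogram: cell (k, i) is 0 iff
# x[i-1] > x[i-k-1] and x[i-1] > x[i+k-1], for i = k+2 ... N-k+1, else 1.
# Used as an independent oracle for compute_binary_lms().
literal_binary_lms <- function(x, lambda_max) {
  N <- length(x)
  bits <- matrix(1L, nrow = lambda_max, ncol = N)
  for (k in seq_len(lambda_max)) {
    for (i in (k + 2):(N - k + 1)) {
      if (x[i - 1] > x[i - k - 1] && x[i - 1] > x[i + k - 1]) {
        # cell i refers to sample i - 1; package columns are samples
        bits[k, i - 1] <- 0L
      }
    }
  }
  bits
}

# Zero-mean periodic signal whose every crest is two equal samples,
# exercising the flat-peak midpoint rule; period 16 samples.
flat_peak_signal <- function(n_cycles = 16) {
  cyc <- c(0, 1, 2, 3, 4, 5, 5, 4, 3, 2, 1, 0, -1, -2, -1, 0)
  rep(cyc, n_cycles)
}
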