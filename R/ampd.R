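#' Parameters for the binary multiscale peak detector
#'
#' @param lambda_max Maximum usable scale; scalogram rows beyond it are never
#'   computed, saving memory, and a window whose minimising scale hits the
#'   truncation boundary is declared too noisy. The default of 17 was chosen
#'   empirically for 32 Hz wrist PPG.
#' @param flat_peak_rule Apply the half-sample midpoint rule rescuing crests
#'   realised as two equal samples (default `TRUE`).
#' @return An object of class `"ampd_params"`.
#' @export
ampd_params <- function(lambda_max = 17, flat_peak_rule = TRUE) {
  stopifnot(lambda_max >= 1)
  structure(list(lambda_max = as.integer(lambda_max),
                 flat_peak_rule = isTRUE(flat_peak_rule)),
            class = "ampd_params")
}

#' Binary local-maxima scalogram
#'
#' Computes the 1-bit local-maxima scalogram (LMS): cell `(k, c)` is 0 when
#' sample `c` is a strict local maximum at neighbour distance `k`, i.e.
#' `x[c] > x[c-k]` and `x[c] > x[c+k]`, for `c` in `[k+1, N-k]`; every other
#' cell (including the `2k` boundary columns where one comparison index
#' falls outside the window) is 1. Only rows `k = 1..lambda_max` are stored.
#'
#' Indexing note: the defining formulas are usually written with a 1-based
#' matrix column `i` examining sample `i-1`, valid for
#' `i = k+2, ..., N-k+1`; here columns are the samples themselves
#' (`c = i - 1`), which makes column `c` of the scalogram refer directly to
#' `x[c]`. Tests check this mapping against a literal transcription of the
#' shifted-index form.
#'
#' @param x Numeric window of length N (conditioned, zero-mean).
#' @param params [ampd_params()].
#' @return Integer 0/1 matrix, `lambda_max` rows by `N` columns.
#' @export
compute_binary_lms <- function(x, params = ampd_params()) {
  N <- length(x)
  L <- params$lambda_max
  if (N < 2 * (L + 2)) stop("window too short for lambda_max rows")
  bits <- matrix(1L, nrow = L, ncol = N)
  for (k in seq_len(L)) {
    c_idx <- (k + 1):(N - k)
    hit <- x[c_idx] > x[c_idx - k] & x[c_idx] > x[c_idx + k]
    bits[k, c_idx[hit]] <- 0L
  }
  bits
}

#' Row sums of the scalogram and the minimising scale
#'
#' `gamma[k]` counts the 1-cells in row `k`; the scale `lambda` is the
#' smallest `k` attaining the minimum of `gamma` (most zero cells, i.e. the
#' scale at which local maxima are most consistently expressed). Rows beyond
#' `lambda` carry no information about the peaks and are discarded
#' downstream.
#'
#' @param lms Binary LMS matrix from [compute_binary_lms()].
#' @return List with `gamma` (integer vector, one per row) and `lambda`
#'   (smallest minimising row index).
#' @export
compute_gamma <- function(lms) {
  gamma <- as.integer(rowSums(lms))
  list(gamma = gamma, lambda = which.min(gamma))
}

#' Noise-quality gate
#'
#' A window is usable only when the minimising scale is certified to lie
#' strictly below the truncation bound: with only `lambda_max` scalogram
#' rows stored, a minimum sitting exactly on the last row cannot be
#' distinguished from a true minimiser beyond it, so such windows are
#' declared too noisy and no estimate is produced.
#'
#' @param gamma_info Result of [compute_gamma()].
#' @param params [ampd_params()].
#' @return `TRUE` when the window passes (interior minimum), `FALSE` when it
#'   is rejected as too noisy.
#' @export
quality_gate <- function(gamma_info, params = ampd_params()) {
  gamma_info$lambda < params$lambda_max
}

#' Column sums of the truncated scalogram
#'
#' @param lms Binary LMS matrix.
#' @param lambda Number of rows to sum (the minimising scale).
#' @return Integer vector `s` of length N; `s[c] == 0` marks sample `c` as a
#'   peak expressed at every scale up to `lambda`.
#' @export
column_sums <- function(lms, lambda) {
  stopifnot(lambda >= 1, lambda <= nrow(lms))
  if (lambda == 1L) as.integer(lms[1L, ]) else
    as.integer(colSums(lms[seq_len(lambda), , drop = FALSE]))
}

#' Half-sample positions of flat peaks
#'
#' A weak, coarsely quantised pulse crest can be realised as two consecutive
#' equal samples; no strict-inequality maximum exists there and the column
#' sums never reach 0. Such crests leave the signature
#' `s[c-2] > 1, s[c-1] == 1, s[c] == 1, s[c+1] > 1` (the two crest samples
#' fail only the scale-1 comparison against each other), and a peak is
#' emitted at the midpoint `c - 0.5` between them.
#'
#' @param s Integer column-sum vector from [column_sums()].
#' @return Numeric vector of half-sample peak positions (possibly empty).
#' @export
flat_peak_positions <- function(s) {
  N <- length(s)
  if (N < 4) return(numeric(0))
  c_idx <- 3:(N - 1)
  hit <- s[c_idx - 2] > 1 & s[c_idx - 1] == 1 & s[c_idx] == 1 & s[c_idx + 1] > 1
  c_idx[hit] - 0.5
}

#' Detect pulse peaks in a conditioned window
#'
#' Runs the full binary multiscale detector: scalogram, minimising scale,
#' noise gate, column sums, integer peaks where the column sum is zero, and
#' (optionally) flat-peak midpoints merged in. The input must already be
#' band-pass conditioned: the detector relies on the signal being zero-mean
#' and detrended.
#'
#' @param x Conditioned window (length at least `2 * (lambda_max + 2)`).
#' @param params [ampd_params()].
#' @return An object of class `"peak_detection"`: list with `peaks` (sorted
#'   positions in sample units, half-sample values possible), `lambda`,
#'   `gamma`, `s` (column sums), and `valid` (noise-gate verdict; when
#'   `FALSE` the peak list is empty).
#' @export
detect_peaks <- function(x, params = ampd_params()) {
  lms <- compute_binary_lms(x, params)
  gi <- compute_gamma(lms)
  valid <- quality_gate(gi, params)
  s <- column_sums(lms, gi$lambda)
  if (!valid) {
    peaks <- numeric(0)
  } else {
    peaks <- as.numeric(which(s == 0L))
    if (params$flat_peak_rule) {
      fp <- flat_peak_positions(s)
      # a midpoint within 1 sample of an integer peak is the same crest
      if (length(fp) && length(peaks))
        fp <- fp[vapply(fp, function(p) min(abs(peaks - p)) > 1, NA)]
      peaks <- sort(c(peaks, fp))
    }
  }
  structure(list(peaks = peaks, lambda = gi$lambda, gamma = gi$gamma,
                 s = s, valid = valid),
            class = "peak_detection")
}

#' Original real-valued multiscale peak detector (reference oracle)
#'
#' Literal implementation of the classic automatic multiscale peak detection
#' algorithm: the full local-maxima scalogram with `L = ceiling(N/2) - 1`
#' rows, cells holding `r + 1` with `r ~ Uniform(0, 1)` except 0 at strict
#' local maxima; the minimising scale over all rows; peaks where the
#' column-wise standard deviation of the retained rows is exactly zero.
#' Kept for cross-checking the memory-reduced binary detector (the 0-cells
#' of both scalograms are defined by the identical comparison, so peak sets
#' agree whenever both select the same scale).
#'
#' @param x Numeric window.
#' @param seed Seed for the uniform cell noise (the original algorithm is
#'   stochastic in its fill values, though not in its 0-cells).
#' @return Same structure as [detect_peaks()] (class `"peak_detection"`),
#'   with `lambda` the untruncated minimiser and `valid = TRUE` always.
#' @export
detect_peaks_original_ampd <- function(x, seed = 1L) {
  N <- length(x)
  L <- as.integer(ceiling(N / 2) - 1)
  if (L < 1) stop("window too short")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- matrix(stats::runif(L * N) + 1, nrow = L, ncol = N)
  for (k in seq_len(L)) {
    c_idx <- (k + 1):(N - k)
    hit <- x[c_idx] > x[c_idx - k] & x[c_idx] > x[c_idx + k]
    m[k, c_idx[hit]] <- 0
  }
  gamma <- rowSums(m)
  lambda <- which.min(gamma)
  mr <- m[seq_len(lambda), , drop = FALSE]
  if (lambda == 1L) {
    peaks <- which(mr[1L, ] == 0)
  } else {
    sigma <- apply(mr, 2, stats::sd)
    peaks <- which(sigma == 0)
  }
  structure(list(peaks = as.numeric(peaks), lambda = lambda, gamma = gamma,
                 s = NULL, valid = TRUE),
            class = "peak_detection")
}
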