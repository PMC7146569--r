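#' Motion-detection parameters
#'
#' @param H Movement threshold on the normalised indicator `d` (default
#'   0.0025, tuned for a ±2 g accelerometer).
#' @param Ts_ms Minimum duration, in milliseconds, for a movement indication
#'   to be kept (default 500 ms): runs of above-threshold samples shorter
#'   than this are treated as spikes and dropped. Set
#'   `spike_rule = "remove_long"` for the alternative reading in which runs
#'   *longer* than `Ts_ms` are dropped instead.
#' @param full_range Accelerometer full range in g (default 2, i.e. ±2 g);
#'   used to derive the normaliser `G`.
#' @param G Normalisation constant for the movement indicator. The default
#'   (`NULL`) uses the largest possible sample-to-sample difference norm,
#'   `2 * full_range * sqrt(3)` (a rail-to-rail jump on all three axes), so
#'   the indicator is guaranteed to lie in `[0, 1]` and the bound is tight.
#' @param spike_rule `"remove_short"` (default; matches the published
#'   behaviour of eliminating short-term spikes) or `"remove_long"`.
#' @return An object of class `"motion_params"`.
#' @export
motion_params <- function(H = 0.0025, Ts_ms = 500, full_range = 2,
                          G = NULL, spike_rule = c("remove_short", "remove_long")) {
  spike_rule <- match.arg(spike_rule)
  if (is.null(G)) G <- 2 * full_range * sqrt(3)
  if (G <= 0) stop("normaliser G must be positive")
  stopifnot(H > 0, H < 1, Ts_ms >= 0)
  structure(list(H = H, Ts_ms = Ts_ms, full_range = full_range, G = G,
                 spike_rule = spike_rule),
            class = "motion_params")
}

#' Movement indicator from 3-axis accelerometry
#'
#' First-differences each axis and takes the Euclidean norm, normalised to
#' `[0, 1]` by `G`:
#' \deqn{d_i = \frac{1}{G}\sqrt{\Delta g_{x,i}^2 + \Delta g_{y,i}^2 +
#'       \Delta g_{z,i}^2},}
#' with `d[1] = 0` by convention. Differencing removes gravity and slow
#' orientation changes, so `d` responds to jerky wrist motion — exactly the
#' kind that corrupts the optical pulse signal.
#'
#' @param acc Data frame or list with numeric components `ax`, `ay`, `az`
#'   (acceleration in g, aligned to the PPG timebase).
#' @param params [motion_params()].
#' @return Numeric vector `d`, same length as the input axes.
#' @export
movement_indicator <- function(acc, params = motion_params()) {
  ax <- acc$ax; ay <- acc$ay; az <- acc$az
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  if (length(ax) < 2) stop("need at least two accelerometer samples")
  d <- c(0, sqrt(diff(ax)^2 + diff(ay)^2 + diff(az)^2) / params$G)
  d
}

#' Threshold the movement indicator and remove spikes
#'
#' Produces the binary movement flag `V` (`d > H`), then applies run-length
#' filtering: with the default `spike_rule = "remove_short"`, flagged runs
#' strictly shorter than `Ts_ms` are cleared (a debounce — an isolated
#' accelerometer blip does not invalidate beats), while `"remove_long"`
#' clears runs strictly longer than `Ts_ms` instead.
#'
#' @param d Movement indicator from [movement_indicator()].
#' @param params [motion_params()].
#' @param fs Sampling rate, Hz.
#' @return An object of class `"motion_mask"`: list with `d`, `V` (integer
#'   0/1 vector) and the parameters used.
#' @export
threshold_and_despike <- function(d, params = motion_params(), fs = 32) {
  V <- as.integer(d > params$H)
  min_run <- params$Ts_ms / 1000 * fs
  r <- rle(V)
  if (params$spike_rule == "remove_short") {
    drop <- r$values == 1L & r$lengths < min_run
  } else {
    drop <- r$values == 1L & r$lengths > min_run
  }
  r$values[drop] <- 0L
  structure(list(d = d, V = inverse.rle(r), params = params, fs = fs),
            class = "motion_mask")
}

#' Compute the motion mask for an accelerometer trace
#'
#' Convenience wrapper: [movement_indicator()] followed by
#' [threshold_and_despike()].
#'
#' @inheritParams movement_indicator
#' @param fs Sampling rate, Hz.
#' @return A `"motion_mask"` object.
#' @export
motion_mask <- function(acc, params = motion_params(), fs = 32) {
  threshold_and_despike(movement_indicator(acc, params), params, fs)
}

#' Keep only inter-peak periods unaffected by movement
#'
#' For each pair of consecutive detected peaks, the period between them is
#' retained only when no sample in the closed interval from the first peak
#' (rounded up) to the second peak (rounded down) carries a movement flag.
#' Periods overlapping flagged motion are discarded from the pulse-period
#' pool; the heart-rate estimate is then formed from what remains.
#'
#' @param peaks Sorted peak positions in sample units (half-sample values
#'   allowed), e.g. from [detect_peaks()].
#' @param mask A `"motion_mask"` (or any list with an integer `V` aligned to
#'   the same window), or `NULL` for no motion data (all periods kept).
#' @return Numeric vector of retained inter-peak periods, in samples, with
#'   attribute `"kept"` flagging which consecutive-pair periods survived.
#' @export
exclude_periods <- function(peaks, mask = NULL) {
  if (length(peaks) < 2) {
    out <- numeric(0); attr(out, "kept") <- logical(0); return(out)
  }
  periods <- diff(peaks)
  if (is.null(mask)) {
    kept <- rep(TRUE, length(periods))
  } else {
    V <- mask$V
    kept <- vapply(seq_along(periods), function(j) {
      lo <- max(1L, ceiling(peaks[j]))
      hi <- min(length(V), floor(peaks[j + 1]))
      lo > hi || all(V[lo:hi] == 0L)
    }, NA)
  }
  out <- periods[kept]
  attr(out, "kept") <- kept
  out
}
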