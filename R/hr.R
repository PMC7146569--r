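#' Heart-rate estimation parameters
#'
#' @param fs Sampling rate, Hz (default 32).
#' @param N Analysis window length in samples; one of 128, 256, 512, 1024
#'   (4--32 s at 32 Hz). Longer windows average more beats (lower error) at
#'   the price of responsiveness.
#' @param bpm_min Lowest heart rate the system is required to measure
#'   (default 40 bpm); together with `N` it fixes the minimum number of
#'   peaks a window must contain for a trustworthy estimate.
#' @param bpm_max Plausibility ceiling; estimates above it are marked
#'   invalid (default 220 bpm, guarding against doubled-peak pathologies).
#' @param shift_s Output cadence: the window advances by this many seconds
#'   between estimates (default 2 s).
#' @param require_peaks_after_exclusion Count only movement-free peaks
#'   towards the minimum-peak requirement (default `TRUE`); `FALSE` counts
#'   all detected peaks.
#' @param ampd [ampd_params()] forwarded to the peak detector.
#' @return An object of class `"hr_params"`.
#' @export
hr_params <- function(fs = 32, N = 1024, bpm_min = 40, bpm_max = 220,
                      shift_s = 2, require_peaks_after_exclusion = TRUE,
                      ampd = ampd_params()) {
  stopifnot(fs > 0, N >= 2, bpm_min >= 0, bpm_max > bpm_min, shift_s > 0)
  structure(list(fs = fs, N = as.integer(N), bpm_min = bpm_min,
                 bpm_max = bpm_max, shift_s = shift_s,
                 require_peaks_after_exclusion =
                   isTRUE(require_peaks_after_exclusion),
                 ampd = ampd),
            class = "hr_params")
}

#' Minimum peak count for a valid window
#'
#' A window of `N` samples must contain at least
#' `P = floor(N * bpm_min / (60 * fs))` detected peaks — the number of beats
#' the slowest measurable heart rate would produce in the window. Fewer
#' peaks means either the signal is unusable or the rate is below the
#' system's measuring range; either way no estimate is issued.
#'
#' @param params [hr_params()] (or anything with `N`, `bpm_min`, `fs`).
#' @return Integer minimum peak count P.
#' @examples
#' min_peaks_required(hr_params(N = 1024, bpm_min = 40, fs = 32)) # 21
#' @export
min_peaks_required <- function(params = hr_params()) {
  as.integer(floor(params$N * params$bpm_min / (60 * params$fs)))
}

#' Heart rate from one window's peaks and motion mask
#'
#' The estimate is the inverse of the median inter-peak period over the
#' movement-free periods: `bpm = 60 * fs / median(periods)`. The window is
#' valid only when (a) the peak detector's noise gate passed, (b) enough
#' peaks remain (see [min_peaks_required()]; by default peaks inside
#' movement-flagged samples do not count), (c) at least one movement-free
#' period remains, and (d) the resulting rate lies in
#' `[bpm_min, min(bpm_max, 60 * fs / 2)]`.
#'
#' @param det A `"peak_detection"` result for the window.
#' @param mask A `"motion_mask"` aligned to the same window, or `NULL`.
#' @param params [hr_params()].
#' @param t Timestamp (s) to attach, conventionally the window's trailing
#'   edge.
#' @return An object of class `"hr_estimate"`: list with `t`, `bpm` (`NA`
#'   when invalid), `valid`, `n_peaks`, `n_valid_periods`, `lambda`, and
#'   `reason` (one of `"ok"`, `"gate"`, `"sparse"`, `"motion"`,
#'   `"implausible"`).
#' @export
estimate_hr <- function(det, mask = NULL, params = hr_params(), t = NA_real_) {
  P <- min_peaks_required(params)
  mk <- function(bpm, valid, np, nvp, reason)
    structure(list(t = t, bpm = bpm, valid = valid, n_peaks = np,
                   n_valid_periods = nvp, lambda = det$lambda,
                   reason = reason),
              class = "hr_estimate")
  if (!det$valid)
    return(mk(NA_real_, FALSE, 0L, 0L, "gate"))
  peaks <- det$peaks
  free_peaks <- peaks
  if (!is.null(mask) && length(peaks)) {
    idx <- pmin(pmax(round(peaks), 1L), length(mask$V))
    free_peaks <- peaks[mask$V[idx] == 0L]
  }
  n_count <- if (params$require_peaks_after_exclusion)
    length(free_peaks) else length(peaks)
  periods <- exclude_periods(peaks, mask)
  nvp <- length(periods)
  if (n_count < P || length(peaks) < 2)
    return(mk(NA_real_, FALSE, length(peaks), nvp, "sparse"))
  if (nvp < 1)
    return(mk(NA_real_, FALSE, length(peaks), 0L, "motion"))
  bpm <- 60 * params$fs / stats::median(periods)
  lo <- params$bpm_min; hi <- min(params$bpm_max, 60 * params$fs / 2)
  if (bpm < lo || bpm > hi)
    return(mk(NA_real_, FALSE, length(peaks), nvp, "implausible"))
  mk(bpm, TRUE, length(peaks), nvp, "ok")
}

#' Sliding-window heart-rate trace
#'
#' Conditions the full PPG stream once (the conditioning chain is stateful
#' and streaming), then slides a window of `N` samples forward by
#' `shift_s` seconds, running peak detection, motion-period exclusion and
#' the median-period estimate in each window. Peaks falling inside the
#' filter warm-up transient at the start of the stream are dropped.
#'
#' @param ppg Raw PPG sample vector (counts).
#' @param acc Optional accelerometer data (list/data.frame with `ax`, `ay`,
#'   `az` in g, same length and rate as `ppg`); `NULL` disables motion
#'   exclusion.
#' @param params [hr_params()].
#' @param conditioning [conditioning_config()]; its `fs` should match
#'   `params$fs`.
#' @param motion [motion_params()].
#' @return A data frame with one row per window: `t` (window trailing edge,
#'   s), `bpm`, `valid`, `n_peaks`, `n_valid_periods`, `lambda`, `reason`.
#'   Zero rows when the stream is shorter than one window.
#' @export
sliding_hr <- function(ppg, acc = NULL, params = hr_params(),
                       conditioning = conditioning_config(fs = params$fs),
                       motion = motion_params()) {
  fs <- params$fs
  N <- params$N
  if (length(ppg) < N) {
    warning("stream shorter than one analysis window: no estimates")
    return(data.frame(t = numeric(0), bpm = numeric(0), valid = logical(0),
                      n_peaks = integer(0), n_valid_periods = integer(0),
                      lambda = integer(0), reason = character(0)))
  }
  y <- condition_signal(ppg, conditioning)
  warmup <- attr(y, "warmup")
  mask_full <- NULL
  if (!is.null(acc)) mask_full <- motion_mask(acc, motion, fs = fs)
  shift <- max(1L, round(params$shift_s * fs))
  starts <- seq(1L, length(y) - N + 1L, by = shift)
  rows <- lapply(starts, function(s0) {
    win <- y[s0:(s0 + N - 1L)]
    det <- detect_peaks(win, params$ampd)
    # drop peaks inside the global warm-up transient
    if (s0 <= warmup && length(det$peaks)) {
      det$peaks <- det$peaks[det$peaks + s0 - 1 > warmup]
    }
    mk <- NULL
    if (!is.null(mask_full)) {
      mk <- list(V = mask_full$V[s0:(s0 + N - 1L)])
    }
    est <- estimate_hr(det, mk, params, t = (s0 + N - 1L) / fs)
    data.frame(t = est$t, bpm = est$bpm, valid = est$valid,
               n_peaks = est$n_peaks, n_valid_periods = est$n_valid_periods,
               lambda = est$lambda, reason = est$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Substitute the last valid estimate for invalid windows
#'
#' Implements the hold-last-valid output mode: wherever a window is invalid,
#' the most recent valid bpm is carried forward. Windows before the first
#' valid estimate remain `NA`.
#'
#' @param est Data frame from [sliding_hr()].
#' @return The same data frame with an added `bpm_held` column.
#' @export
hold_last_valid <- function(est) {
  bpm <- est$bpm
  last <- NA_real_
  held <- vapply(seq_along(bpm), function(i) {
    if (isTRUE(est$valid[i])) last <<- bpm[i]
    last
  }, 0)
  est$bpm_held <- held
  est
}
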