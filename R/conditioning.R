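#' Biquad coefficient set
#'
#' Constructs a second-order recursive filter section (biquad) from its five
#' transfer-function coefficients, in direct form I:
#' \deqn{y_i = \frac{1}{a_0}\,(b_0 x_i + b_1 x_{i-1} + b_2 x_{i-2}
#'       - a_1 y_{i-1} - a_2 y_{i-2}).}
#' `a0` is kept as an explicit normaliser; internally the section is scaled so
#' that the stored `a0` is 1.
#'
#' @param b0,b1,b2 Feedforward (numerator) coefficients.
#' @param a0,a1,a2 Feedback (denominator) coefficients; `a0` must be non-zero.
#' @param check_stable If `TRUE` (default), error when the poles are not
#'   strictly inside the unit circle.
#' @return An object of class `"biquad"`: a named numeric vector
#'   `(b0, b1, b2, a0, a1, a2)` with `a0 = 1`.
#' @examples
#' biquad(1, 0, 0, 1, 0, 0) # identity pass-through
#' @export
biquad <- function(b0, b1, b2, a0 = 1, a1 = 0, a2 = 0, check_stable = TRUE) {
  co <- c(b0 = b0, b1 = b1, b2 = b2, a0 = a0, a1 = a1, a2 = a2)
  if (!all(is.finite(co))) stop("biquad coefficients must be finite")
  if (a0 == 0) stop("a0 must be non-zero")
  co[1:3] <- co[1:3] / a0
  co[4:6] <- co[4:6] / a0
  if (check_stable) {
    p <- polyroot(c(co[["a2"]], co[["a1"]], 1))  # z^2 + a1 z + a2
    if (any(Mod(p) >= 1 - 1e-12))
      stop("unstable biquad: poles not strictly inside the unit circle")
  }
  structure(co, class = "biquad")
}

#' Limiter bounds for the nonlinear conditioning stage
#'
#' The limiter clamps the *stored* output of the first conditioning biquad to
#' `[lower, upper]`. Because the clamped value (not the linear candidate) is
#' fed back into the recursion, a large input transient cannot charge the
#' filter state, and the chain recovers quickly afterwards. Bounds should sit
#' at roughly 100--150% of the negative/positive amplitude of the useful
#' pulse signal; the defaults of -150/+150 counts suit a wrist PPG with
#' pulse amplitude around 30--50 counts after band-pass filtering.
#'
#' @param lower,upper Clamp bounds in filter-output units; need
#'   `lower < 0 < upper`.
#' @return An object of class `"limiter_bounds"`.
#' @export
limiter_bounds <- function(lower = -150, upper = 150) {
  if (!is.finite(lower) || !is.finite(upper)) stop("bounds must be finite")
  if (!(lower < 0 && upper > 0))
    stop("need lower < 0 < upper: the conditioned signal is zero-mean")
  structure(list(lower = lower, upper = upper), class = "limiter_bounds")
}

#' Run a biquad section over a sample sequence
#'
#' Direct-form-I recursion, optionally with an internal output limiter. With
#' `bounds` supplied, each output is computed in two steps: the linear
#' candidate from the recursion, then a clamp to `[lower, upper]`; the
#' *clamped* value is stored as the previous output for subsequent samples.
#' This is what distinguishes the limited section from post-hoc clipping and
#' is what gives fast recovery after large baseline transients.
#'
#' @param x Numeric sample sequence (finite values).
#' @param coef A [biquad()] coefficient set.
#' @param bounds Optional [limiter_bounds()]; `NULL` for a plain linear
#'   section.
#' @param state Optional 4-vector `(x1, x2, y1, y2)` of the two previous
#'   inputs/outputs, for streaming use; zeros at stream start.
#' @return Numeric vector of outputs, same length as `x`, with the final
#'   recursion state attached as attribute `"state"`.
#' @export
biquad_filter <- function(x, coef, bounds = NULL, state = c(0, 0, 0, 0)) {
  stopifnot(inherits(coef, "biquad"), length(state) == 4)
  if (!all(is.finite(x))) stop("non-finite input sample: corrupt stream")
  b0 <- coef[["b0"]]; b1 <- coef[["b1"]]; b2 <- coef[["b2"]]
  a1 <- coef[["a1"]]; a2 <- coef[["a2"]]
  lo <- -Inf; hi <- Inf
  if (!is.null(bounds)) {
    stopifnot(inherits(bounds, "limiter_bounds"))
    lo <- bounds$lower; hi <- bounds$upper
  }
  x1 <- state[1]; x2 <- state[2]; y1 <- state[3]; y2 <- state[4]
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    yc <- b0 * x[i] + b1 * x1 + b2 * x2 - a1 * y1 - a2 * y2
    if (yc > hi) yc <- hi else if (yc < lo) yc <- lo
    y[i] <- yc
    x2 <- x1; x1 <- x[i]
    y2 <- y1; y1 <- yc
  }
  attr(y, "state") <- c(x1, x2, y1, y2)
  y
}

# Split a (b, a) polynomial pair of even order 2m into m stable biquads by
# conjugate-pair pole/zero grouping. Poles are paired with their nearest
# zeros; the overall gain is spread evenly across sections.
tf_to_biquads <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  z <- polyroot(rev(b / b[1]))
  p <- polyroot(rev(a))
  m <- length(p) / 2L
  if (m != round(m)) stop("odd filter order: cannot split into biquads")
  pair_conj <- function(r) {
    used <- rep(FALSE, length(r)); out <- list()
    ord <- order(-Im(r), Mod(r))
    for (j in ord) {
      if (used[j]) next
      used[j] <- TRUE
      mate <- which(!used & abs(r - Conj(r[j])) ==
                      min(abs(r[!used] - Conj(r[j]))))[1]
      used[mate] <- TRUE
      out[[length(out) + 1L]] <- c(r[j], r[mate])
    }
    out
  }
  pp <- pair_conj(p)
  # order pole pairs by distance to the unit circle (closest first), then
  # assign each the zero pair nearest its mean angle
  pp <- pp[order(vapply(pp, function(q) min(1 - Mod(q)), 0))]
  zleft <- z
  gain <- b[1]
  secs <- vector("list", m)
  for (s in seq_len(m)) {
    q <- pp[[s]]
    d <- abs(zleft - q[1])
    z1 <- zleft[which.min(d)]; zleft <- zleft[-which.min(d)]
    d <- abs(zleft - Conj(z1))
    z2 <- zleft[which.min(d)]; zleft <- zleft[-which.min(d)]
    bs <- Re(c(1, -(z1 + z2), z1 * z2))
    as <- Re(c(1, -(q[1] + q[2]), q[1] * q[2]))
    g <- abs(gain)^(1 / m) * sign(gain)^(s == 1)
    secs[[s]] <- biquad(g * bs[1], g * bs[2], g * bs[3], as[1], as[2], as[3])
  }
  secs
}

#' Design a Butterworth band-pass as one or two biquad sections
#'
#' Designs a digital Butterworth band-pass (bilinear transform) with -3 dB
#' points at `low` and `high` Hz and returns it as second-order sections
#' ready for [biquad_filter()]. `order = 2` yields a single biquad (a
#' first-order low-pass/high-pass prototype pair), `order = 4` two cascaded
#' biquads.
#'
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz; `0 < low < high < fs/2`.
#' @param order Overall filter order, 2 or 4.
#' @return A list of [biquad()] sections (length 1 or 2).
#' @examples
#' design_bandpass(32, 0.5, 2.5, order = 2)
#' @export
design_bandpass <- function(fs, low, high, order = 2) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("infeasible band: need 0 < low < high < fs/2")
  if (!order %in% c(2L, 4L)) stop("order must be 2 or 4")
  bf <- signal::butter(order / 2L, c(low, high) / (fs / 2), type = "pass")
  if (order == 2L) {
    list(biquad(bf$b[1], bf$b[2], bf$b[3], bf$a[1], bf$a[2], bf$a[3]))
  } else {
    tf_to_biquads(bf$b, bf$a)
  }
}

#' Frequency response of a biquad cascade
#'
#' @param sections List of [biquad()] sections.
#' @param f Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Complex response values, one per frequency.
#' @export
cascade_response <- function(sections, f, fs) {
  w <- 2 * pi * f / fs
  z1 <- exp(-1i * w)
  h <- rep(1 + 0i, length(f))
  for (co in sections) {
    h <- h * (co[["b0"]] + co[["b1"]] * z1 + co[["b2"]] * z1^2) /
      (1 + co[["a1"]] * z1 + co[["a2"]] * z1^2)
  }
  h
}

#' Conditioning configuration for the two-stage input chain
#'
#' The raw PPG is conditioned by a band-pass biquad with an internal output
#' limiter (stage 1), followed by a fourth-order band-pass built from two
#' plain biquads (stage 2). Both stages share the 0.5--2.5 Hz pass-band,
#' which covers 30--150 bpm and removes the baseline (about 11,100 counts at
#' the wrist) and high-frequency noise, leaving a zero-mean pulse waveform.
#'
#' @param fs Sampling rate, Hz (default 32).
#' @param passband Length-2 numeric, band edges in Hz (default `c(0.5, 2.5)`).
#' @param bounds [limiter_bounds()] for stage 1; `NULL` disables the limiter
#'   (useful for comparing recovery behaviour).
#' @param auto_calibrate If `TRUE`, [condition_signal()] replaces `bounds`
#'   with ±1.25 × a robust pulse-amplitude estimate taken from the stage-1
#'   output over the calibration window (the first `calib_s` seconds),
#'   matching the guidance that the bounds sit at 100--150% of the useful
#'   signal amplitude.
#' @param calib_s Calibration window length, seconds, when auto-calibrating.
#' @return An object of class `"conditioning_config"` holding the designed
#'   stage-1 section (+ bounds) and the two stage-2 sections.
#' @export
conditioning_config <- function(fs = 32, passband = c(0.5, 2.5),
                                bounds = limiter_bounds(),
                                auto_calibrate = FALSE, calib_s = 8) {
  stopifnot(length(passband) == 2, passband[1] < passband[2])
  stage1 <- design_bandpass(fs, passband[1], passband[2], order = 2)[[1]]
  stage2 <- design_bandpass(fs, passband[1], passband[2], order = 4)
  structure(list(fs = fs, passband = passband, stage1 = stage1,
                 stage2 = stage2, bounds = bounds,
                 auto_calibrate = isTRUE(auto_calibrate), calib_s = calib_s),
            class = "conditioning_config")
}

# Robust peak-to-trough amplitude estimate over a calm window: median of
# per-second (max - min) excursions, halved to a one-sided amplitude.
robust_amplitude <- function(y, fs) {
  nsec <- floor(length(y) / fs)
  if (nsec < 1) return(stats::median(abs(y)))
  ex <- vapply(seq_len(nsec), function(s) {
    seg <- y[((s - 1) * fs + 1):(s * fs)]
    max(seg) - min(seg)
  }, 0)
  stats::median(ex) / 2
}

#' Condition a raw PPG sample sequence
#'
#' Applies the full two-stage chain: limited band-pass biquad, then the
#' fourth-order band-pass cascade. The output is zero-mean in steady state
#' and has the same length as the input. The first
#' `ceiling(2 * fs / passband[1])` samples are the filter warm-up transient
#' and are reported in the `"warmup"` attribute; downstream peak detection
#' ignores peaks inside it.
#'
#' @param x Raw PPG samples (counts).
#' @param cfg A [conditioning_config()].
#' @return Conditioned numeric sequence with attributes `"warmup"` (sample
#'   count) and `"bounds"` (the limiter bounds actually used).
#' @export
condition_signal <- function(x, cfg = conditioning_config()) {
  stopifnot(inherits(cfg, "conditioning_config"))
  if (length(x) < 3) stop("sequence too short to filter")
  bounds <- cfg$bounds
  if (cfg$auto_calibrate) {
    ncal <- min(length(x), round(cfg$calib_s * cfg$fs))
    y0 <- biquad_filter(x[seq_len(ncal)], cfg$stage1)
    amp <- robust_amplitude(y0, cfg$fs)
    if (amp > 0) bounds <- limiter_bounds(-1.25 * amp, 1.25 * amp)
  }
  y <- biquad_filter(x, cfg$stage1, bounds = bounds)
  for (co in cfg$stage2) y <- biquad_filter(y, co)
  attributes(y) <- NULL
  attr(y, "warmup") <- min(length(y), ceiling(2 * cfg$fs / cfg$passband[1]))
  attr(y, "bounds") <- bounds
  y
}
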