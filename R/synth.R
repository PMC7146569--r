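#' Configuration for the synthetic PPG + accelerometer generator
#'
#' The generator emulates the signal classes a wrist-worn reflective PPG
#' front-end produces: a weak quasi-periodic pulse train (amplitude a few
#' tens of counts) riding on a large DC baseline (about 11,100 counts on a
#' 14-bit converter), slow baseline wander, white sensor noise, and
#' occasional large motion-artifact transients time-locked to accelerometer
#' bursts.
#'
#' @param fs Sampling rate, Hz (default 32).
#' @param duration_s Recording length, seconds.
#' @param hr Heart-rate trajectory in bpm: a single number (constant rate)
#'   or a function of time in seconds returning bpm; values must stay in
#'   \[40, 180\].
#' @param baseline Mean signal level, counts (default 11100).
#' @param pulse_amplitude Peak pulse height above baseline, counts
#'   (default 40; wrist amplitudes are typically 30--50).
#' @param noise_sd White-noise standard deviation, counts.
#' @param drift_sd Random-walk baseline wander, counts per sample.
#' @param jitter_frac Gaussian beat-to-beat jitter as a fraction of the
#'   current period (default 0.02), avoiding pathological exact
#'   periodicity.
#' @param artifacts Data frame with columns `start_s`, `duration_s`,
#'   `ppg_counts`, `accel_g`: each row adds an oscillatory transient of the
#'   given magnitude to the PPG and a synchronized burst to the
#'   accelerometer. `NULL` for none.
#' @param accel_noise_sd Per-axis accelerometer noise, g (default 0.001,
#'   well under the movement threshold after differencing).
#' @param seed Integer seed; the recording is deterministic per seed.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(fs = 32, duration_s = 60, hr = 75,
                         baseline = 11100, pulse_amplitude = 40,
                         noise_sd = 2, drift_sd = 0.5, jitter_frac = 0.02,
                         artifacts = NULL,
                         accel_noise_sd = 0.001, seed = 1L) {
  hr_fun <- if (is.function(hr)) hr else function(t) rep(hr, length(t))
  probe <- hr_fun(seq(0, duration_s, length.out = 101))
  if (any(probe < 40 | probe > 180))
    stop("hr trajectory must stay within [40, 180] bpm")
  if (!is.null(artifacts)) {
    stopifnot(all(c("start_s", "duration_s", "ppg_counts", "accel_g") %in%
                    names(artifacts)))
    if (any(artifacts$start_s + artifacts$duration_s > duration_s))
      stop("artifact burst extends beyond the recording")
  }
  structure(list(fs = fs, duration_s = duration_s, hr_fun = hr_fun,
                 baseline = baseline, pulse_amplitude = pulse_amplitude,
                 noise_sd = noise_sd, drift_sd = drift_sd,
                 jitter_frac = jitter_frac,
                 artifacts = artifacts, accel_noise_sd = accel_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Asymmetric unimodal pulse template on a time grid (s), peaking at 0 with
# unit height: log-normal bump with ~0.15 s rise and ~0.35 s decay at a 1 s
# period, scaled linearly with the period.
pulse_template <- function(tau, period) {
  sc <- period / 1.0
  rise <- 0.15 * sc
  sdlog <- 0.55
  tt <- tau + rise           # shift so the mode sits at tau = 0
  g <- numeric(length(tau))
  pos <- tt > 0
  mu <- log(rise) + sdlog^2  # lognormal density mode at exp(mu - sdlog^2)
  g[pos] <- stats::dlnorm(tt[pos], meanlog = mu, sdlog = sdlog)
  g / stats::dlnorm(exp(mu - sdlog^2), meanlog = mu, sdlog = sdlog)
}

#' Generate a synthetic wrist PPG + accelerometer recording
#'
#' Beat times are laid down by integrating the heart-rate trajectory (each
#' inter-beat interval is `60 / hr` at the current time, plus optional
#' jitter); each beat contributes an asymmetric fast-rise/slow-decay pulse
#' of `pulse_amplitude` counts. Baseline, random-walk drift, white noise
#' and any artifact bursts are added, and the result is rounded and clipped
#' to the 14-bit range \[0, 16383\]. The accelerometer rests near (0, 0, 1) g
#' with small noise; artifact bursts add a synchronized oscillation.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `"tdhr_recording"` (see [recording()]) with
#'   `truth` attached: `truth$hr` (data frame `t`, `bpm` on a 2 s grid) and
#'   `truth$peaks` (beat crest times, s).
#' @export
synth_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  tgrid <- (seq_len(n) - 1) / fs

  # beat crest times by integrating the rate trajectory
  beats <- numeric(0)
  tb <- 0.3  # first crest shortly after stream start
  while (tb < cfg$duration_s) {
    beats <- c(beats, tb)
    period <- 60 / cfg$hr_fun(tb)
    if (cfg$jitter_frac > 0)
      period <- period * (1 + stats::rnorm(1, 0, cfg$jitter_frac))
    tb <- tb + max(period, 60 / 200)
  }

  ppg <- numeric(n)
  for (tb in beats) {
    period <- 60 / cfg$hr_fun(tb)
    i0 <- max(1L, floor((tb - 0.3 * period) * fs) + 1L)
    i1 <- min(n, ceiling((tb + 1.2 * period) * fs) + 1L)
    if (i0 > n || i1 < 1) next
    idx <- i0:i1
    ppg[idx] <- ppg[idx] +
      cfg$pulse_amplitude * pulse_template(tgrid[idx] - tb, period)
  }
  drift <- if (cfg$drift_sd > 0) cumsum(stats::rnorm(n, 0, cfg$drift_sd)) else 0
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else 0
  ppg <- ppg + cfg$baseline + drift + noise

  ax <- stats::rnorm(n, 0, cfg$accel_noise_sd)
  ay <- stats::rnorm(n, 0, cfg$accel_noise_sd)
  az <- 1 + stats::rnorm(n, 0, cfg$accel_noise_sd)

  if (!is.null(cfg$artifacts)) {
    for (r in seq_len(nrow(cfg$artifacts))) {
      a <- cfg$artifacts[r, ]
      idx <- which(tgrid >= a$start_s & tgrid < a$start_s + a$duration_s)
      if (!length(idx)) next
      ph <- 2 * pi * 5 * tgrid[idx]  # 5 Hz shake
      # tapered-cosine (Tukey) envelope, 10% ramp at each end
      u <- (tgrid[idx] - a$start_s) / a$duration_s
      env <- rep(1, length(u))
      rl <- u < 0.1; env[rl] <- sin(pi * u[rl] / 0.2)^2
      rr <- u > 0.9; env[rr] <- sin(pi * (1 - u[rr]) / 0.2)^2
      ppg[idx] <- ppg[idx] + a$ppg_counts * env * sin(ph)
      ax[idx] <- ax[idx] + a$accel_g * env * sin(ph)
      ay[idx] <- ay[idx] + a$accel_g * env * cos(ph)
      az[idx] <- az[idx] + 0.5 * a$accel_g * env * sin(2 * ph)
    }
  }
  ppg <- pmin(pmax(round(ppg), 0), 16383)

  hr_grid <- seq(2, cfg$duration_s, by = 2)
  truth <- list(hr = data.frame(t = hr_grid, bpm = cfg$hr_fun(hr_grid)),
                peaks = beats)
  recording(ppg = ppg, fs = fs,
            acc = data.frame(ax = ax, ay = ay, az = az),
            full_range = 2, truth = truth,
            meta = list(source = "synthetic", seed = cfg$seed))
}
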