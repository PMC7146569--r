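test_that("biquad recursion matches identity, DC rejection and an independent oracle", {
  # identity pass-through
  idn <- biquad(1, 0, 0, 1, 0, 0)
  expect_equal(as.numeric(biquad_filter(7.5, idn)), 7.5)

  # band-pass biquad kills DC after the transient
  bp <- design_bandpass(32, 0.5, 2.5, order = 2)[[1]]
  y <- biquad_filter(rep(1, 2000), bp)
  expect_lt(max(abs(tail(y, 100))), 1e-3)

  # arbitrary sequence against signal::filter as independent recursion oracle
  set.seed(4)
  x <- rnorm(32)
  mine <- as.numeric(biquad_filter(x, bp))
  oracle <- as.numeric(signal::filter(
    c(bp[["b0"]], bp[["b1"]], bp[["b2"]]),
    c(1, bp[["a1"]], bp[["a2"]]), x))
  expect_equal(mine, oracle, tolerance = 1e-12)

  # a0 acts as a normaliser: scaling all coefficients changes nothing
  bq2 <- biquad(2 * bp[["b0"]], 2 * bp[["b1"]], 2 * bp[["b2"]],
                2, 2 * bp[["a1"]], 2 * bp[["a2"]])
  expect_equal(as.numeric(biquad_filter(x, bq2)), mine)

  expect_error(biquad_filter(c(1, NaN), bp), "corrupt")
  expect_error(biquad(1, 0, 0, 0, 0, 0), "a0")
  expect_error(biquad(1, 0, 0, 1, 0, 1.5), "unstable")
})

test_that("limiter clamps the candidate and the clamped value feeds the recursion", {
  b <- limiter_bounds(-150, 150)
  # pass-through section makes the candidate equal to the input
  idn <- biquad(1, 0, 0, 1, 0, 0)
  expect_equal(as.numeric(biquad_filter(c(200, 100), idn, bounds = b)),
               c(150, 100))

  # the stored output must be the clamped value: with y_{i} feedback the
  # next sample sees 150, not the 500 candidate
  fb <- biquad(1, 0, 0, 1, -0.5, 0, check_stable = TRUE) # y_i = x_i + 0.5 y_{i-1}
  y <- biquad_filter(c(500, 0, 0), fb, bounds = b)
  expect_equal(as.numeric(y), c(150, 75, 37.5))

  # within bounds: limited and unlimited chains identical
  set.seed(9)
  x <- rnorm(500, sd = 5)
  bp <- design_bandpass(32, 0.5, 2.5, order = 2)[[1]]
  expect_equal(as.numeric(biquad_filter(x, bp, bounds = b)),
               as.numeric(biquad_filter(x, bp)))

  expect_error(limiter_bounds(10, 150))
  expect_error(limiter_bounds(-150, -10))
})

test_that("band-pass design meets the band and rejects infeasible requests", {
  s2 <- design_bandpass(32, 0.5, 2.5, order = 2)
  h_centre <- abs(cascade_response(s2, sqrt(0.5 * 2.5), 32))
  h_max <- max(abs(cascade_response(s2, seq(0.1, 5, by = 0.02), 32)))
  expect_gt(20 * log10(h_centre / h_max), -3)

  s4 <- design_bandpass(32, 0.5, 2.5, order = 4)
  expect_length(s4, 2)
  h_lo <- abs(cascade_response(s4, 0.05, 32))
  h_pass <- max(abs(cascade_response(s4, seq(0.5, 2.5, by = 0.02), 32)))
  expect_lt(20 * log10(h_lo / h_pass), -20)

  # cascading the split sections reproduces the full fourth-order response
  bf <- signal::butter(2, c(0.5, 2.5) / 16, type = "pass")
  f <- seq(0.1, 10, by = 0.1)
  h_sos <- cascade_response(s4, f, 32)
  w <- 2 * pi * f / 32
  z1 <- exp(-1i * w)
  h_tf <- (outer(z1, 0:4, "^") %*% bf$b) / (outer(z1, 0:4, "^") %*% bf$a)
  expect_equal(abs(h_sos), abs(as.vector(h_tf)), tolerance = 1e-8)

  expect_error(design_bandpass(32, 2.5, 0.5, 2), "infeasible")
  expect_error(design_bandpass(32, 0.5, 20, 2), "infeasible")
})

test_that("full conditioning chain passes the pulse band and rejects DC", {
  fs <- 32
  t <- (0:4095) / fs
  x <- 11100 + 40 * sin(2 * pi * 1.5 * t)
  y <- condition_signal(x, conditioning_config(fs = fs))
  ss <- y[2049:4096] # steady state
  expect_lt(abs(mean(ss)), 0.5)
  # output stays sinusoidal at 1.5 Hz with near-unit passband gain
  sp <- Mod(fft(ss))[1:1024]
  f_peak <- (which.max(sp[-1])) * fs / length(ss)
  expect_equal(f_peak, 1.5, tolerance = 0.05)
  amp <- (max(ss) - min(ss)) / 2
  gain <- abs(cascade_response(c(list(conditioning_config()$stage1),
                                 conditioning_config()$stage2), 1.5, fs))
  expect_equal(amp, 40 * gain, tolerance = 0.05)

  # constant wrist baseline: steady-state output ~ 0
  y0 <- condition_signal(rep(11100, 2000), conditioning_config(fs = fs))
  expect_lt(max(abs(tail(y0, 200))), 1e-2)
})

test_that("limiter bounds the transient of the full chain on a motion spike", {
  rec <- synth_recording(synth_config(duration_s = 30, hr = 75, seed = 3,
                                      noise_sd = 0, drift_sd = 0))
  ppg <- rec$ppg
  i0 <- 15 * 32
  ppg[i0:(i0 + 16)] <- ppg[i0:(i0 + 16)] + 3000 # ~0.5 s artifact transient
  y_lim <- condition_signal(ppg, conditioning_config())
  y_no <- condition_signal(ppg, conditioning_config(bounds = NULL))
  win <- i0:(i0 + 4 * 32)
  expect_lt(max(abs(y_lim[win])), max(abs(y_no[win])))
})

test_that("auto-calibrated bounds land at 100-150% of the pulse amplitude", {
  rec <- synth_recording(synth_config(duration_s = 40, hr = 75, seed = 8,
                                      noise_sd = 1, drift_sd = 0))
  cfg <- conditioning_config(auto_calibrate = TRUE, calib_s = 10)
  y <- condition_signal(rec$ppg, cfg)
  b <- attr(y, "bounds")
  # stage-1 output amplitude of a 40-count pulse is a few tens of counts;
  # bounds should bracket it with the 1.25 safety factor
  stage1 <- biquad_filter(rec$ppg, conditioning_config()$stage1,
                          bounds = NULL)
  amp <- (max(stage1[641:1280]) - min(stage1[641:1280])) / 2
  expect_gt(b$upper, 0.6 * amp)
  expect_lt(b$upper, 2.5 * amp)
  expect_equal(b$lower, -b$upper)
})
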