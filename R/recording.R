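#' PPG + accelerometer recording container
#'
#' Bundles a uniformly sampled PPG channel with an optional synchronized
#' 3-axis accelerometer trace and optional ground-truth heart-rate series.
#' Accelerometer samples acquired at a different rate are resampled onto
#' the PPG timebase by nearest-sample hold.
#'
#' @param ppg Numeric PPG sample vector (counts).
#' @param fs PPG sampling rate, Hz.
#' @param acc Optional data frame with columns `ax`, `ay`, `az` (g).
#' @param acc_fs Accelerometer rate, Hz; defaults to `fs`.
#' @param full_range Accelerometer full range in g (±`full_range`).
#' @param truth Optional list with `hr` (data frame `t`, `bpm`) and/or
#'   `peaks` (beat times, s).
#' @param meta Optional named list of metadata (subject id, source, ...).
#' @return An object of class `"tdhr_recording"`.
#' @export
recording <- function(ppg, fs = 32, acc = NULL, acc_fs = fs, full_range = 2,
                      truth = NULL, meta = list()) {
  ppg <- as.numeric(ppg)
  if (!all(is.finite(ppg))) stop("non-finite PPG samples")
  if (!is.null(acc)) {
    if (!all(c("ax", "ay", "az") %in% names(acc)))
      stop("accelerometer data must have columns ax, ay, az")
    if (acc_fs != fs) {
      tp <- (seq_along(ppg) - 1) / fs
      ta <- (seq_len(nrow(acc)) - 1) / acc_fs
      j <- pmin(nrow(acc), pmax(1L, round(tp * acc_fs) + 1L))
      acc <- acc[j, c("ax", "ay", "az")]
      rownames(acc) <- NULL
    }
    if (nrow(acc) != length(ppg))
      stop("PPG and accelerometer lengths are inconsistent")
  }
  structure(list(ppg = ppg, fs = fs, acc = acc, full_range = full_range,
                 truth = truth, meta = meta),
            class = "tdhr_recording")
}

#' @export
print.tdhr_recording <- function(x, ...) {
  cat(sprintf("PPG recording: %d samples at %g Hz (%.1f s)%s%s\n",
              length(x$ppg), x$fs, length(x$ppg) / x$fs,
              if (!is.null(x$acc)) ", with 3-axis accelerometer" else "",
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Read a recording from columnar CSV
#'
#' Expects a header row and columns `t` (s) and `ppg` (counts); optional
#' columns `ax`, `ay`, `az` (g) carry the accelerometer. The sampling rate
#' is inferred from the median timestamp increment. A companion
#' `<path>_truth.csv` (columns `t`, `bpm`), if present, is attached as
#' ground truth.
#'
#' @param path CSV file path.
#' @param full_range Accelerometer full range in g.
#' @return A `"tdhr_recording"`.
#' @export
read_recording <- function(path, full_range = 2) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("t", "ppg") %in% names(df)))
    stop("missing channel: recording CSV needs columns t and ppg")
  fs <- 1 / stats::median(diff(df$t))
  acc <- NULL
  if (all(c("ax", "ay", "az") %in% names(df)))
    acc <- df[, c("ax", "ay", "az")]
  truth <- NULL
  tp <- sub("\\.csv$", "_truth.csv", path)
  if (file.exists(tp)) {
    tr <- utils::read.csv(tp)
    if (all(c("t", "bpm") %in% names(tr))) truth <- list(hr = tr)
  }
  recording(df$ppg, fs = round(fs, 6), acc = acc, full_range = full_range,
            truth = truth, meta = list(source = path))
}

#' Write a recording to columnar CSV
#'
#' Writes `t`, `ppg` and, when present, `ax`, `ay`, `az` columns; ground
#' truth, when present, goes to `<path>_truth.csv` with columns `t`, `bpm`.
#'
#' @param rec A `"tdhr_recording"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tdhr_recording"))
  df <- data.frame(t = (seq_along(rec$ppg) - 1) / rec$fs, ppg = rec$ppg)
  if (!is.null(rec$acc)) df <- cbind(df, rec$acc)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(rec$truth) && !is.null(rec$truth$hr))
    utils::write.csv(rec$truth$hr, sub("\\.csv$", "_truth.csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Read pipeline settings from a YAML configuration file
#'
#' Recognised keys (all optional, shown with defaults): `fs` (32),
#' `passband` (\[0.5, 2.5\] Hz), `limiter` (-150/150 or `auto`), `N` (1024),
#' `shift_s` (2), `bpm_min` (40), `lambda_max` (17), `H` (0.0025), `Ts_ms`
#' (500), `full_range` (2).
#'
#' @param path YAML file.
#' @return A list with components `hr` ([hr_params()]), `conditioning`
#'   ([conditioning_config()]) and `motion` ([motion_params()]).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare key `N` as boolean FALSE; map it back
  names(y)[names(y) == "FALSE"] <- "N"
  g <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  fs <- g("fs", 32)
  pb <- as.numeric(g("passband", c(0.5, 2.5)))
  lim <- g("limiter", c(-150, 150))
  auto <- identical(lim, "auto")
  bounds <- if (auto) limiter_bounds() else limiter_bounds(lim[[1]], lim[[2]])
  list(
    hr = hr_params(fs = fs, N = g("N", 1024), bpm_min = g("bpm_min", 40),
                   shift_s = g("shift_s", 2),
                   ampd = ampd_params(lambda_max = g("lambda_max", 17))),
    conditioning = conditioning_config(fs = fs, passband = pb, bounds = bounds,
                                       auto_calibrate = auto),
    motion = motion_params(H = g("H", 0.0025), Ts_ms = g("Ts_ms", 500),
                           full_range = g("full_range", 2))
  )
}
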