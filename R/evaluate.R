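#' Mean absolute error of a heart-rate trace against a reference
#'
#' Scores an estimate trace against a reference bpm series (e.g. ECG-derived
#' ground truth on a 2 s grid). Estimates are matched to references by
#' nearest timestamp within ±1 s; unmatched windows are dropped from W.
#'
#' Two reporting modes mirror common practice for wearable HR evaluation:
#' `"hold-last"` substitutes the most recent valid estimate for invalid
#' windows and averages over every matched window (windows before the first
#' valid estimate are excluded, there being nothing to hold); `"valid-only"`
#' averages only over windows the algorithm itself declared valid and
#' additionally reports the fraction of windows that were valid.
#'
#' @param est Data frame from [sliding_hr()] (columns `t`, `bpm`, `valid`),
#'   or any data frame with those columns.
#' @param ref Data frame with columns `t` (s) and `bpm` (reference rate).
#' @param mode `"hold-last"` or `"valid-only"`.
#' @param match_tol_s Maximum timestamp mismatch for pairing (default 1 s).
#' @return An object of class `"hr_evaluation"`: list with `mae` (bpm),
#'   `valid_fraction`, `W` (number of scored windows) and
#'   `per_window_errors`.
#' @export
hr_mae <- function(est, ref, mode = c("hold-last", "valid-only"),
                   match_tol_s = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(est), is.data.frame(ref),
            all(c("t", "bpm", "valid") %in% names(est)),
            all(c("t", "bpm") %in% names(ref)))
  if (nrow(ref) == 0 || nrow(est) == 0) stop("empty estimate or reference trace")
  j <- vapply(est$t, function(tt) which.min(abs(ref$t - tt)), 0L)
  ok <- abs(ref$t[j] - est$t) <= match_tol_s
  est <- est[ok, , drop = FALSE]
  refv <- ref$bpm[j[ok]]
  if (!nrow(est)) stop("no estimate window matches the reference grid")
  valid_fraction <- mean(est$valid)
  if (mode == "hold-last") {
    held <- hold_last_valid(est)$bpm_held
    keep <- !is.na(held)
    err <- abs(held[keep] - refv[keep])
  } else {
    keep <- est$valid
    err <- abs(est$bpm[keep] - refv[keep])
  }
  structure(list(mae = if (length(err)) mean(err) else NA_real_,
                 valid_fraction = valid_fraction,
                 W = sum(keep), per_window_errors = err, mode = mode),
            class = "hr_evaluation")
}

#' @export
print.hr_evaluation <- function(x, ...) {
  cat(sprintf("HR evaluation (%s mode): MAE = %.2f bpm over %d windows; valid fraction = %.1f%%\n",
              x$mode, x$mae, x$W, 100 * x$valid_fraction))
  invisible(x)
}
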