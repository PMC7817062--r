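new_oscillation_stats <- function(kind, values, extra = list()) {
  n <- length(values)
  mu <- if (n > 0) mean(values) else NA_real_
  s <- if (n > 1) sd(values) else NA_real_
  out <- list(kind = kind, values = values, n = n, mean = mu, sd = s,
              cv = if (n > 1 && isTRUE(mu > 0)) s / mu else NA_real_,
              oscillatory = n >= 1)
  out[names(extra)] <- extra
  structure(out, class = "oscillation_stats")
}

#' @export
print.oscillation_stats <- function(x, ...) {
  if (!x$oscillatory) {
    cat(sprintf("Non-oscillatory (%s detector found no complete cycles)\n",
                x$kind))
  } else {
    cat(sprintf("%s statistics over %d cycles: mean = %.4g, sd = %.4g, cv = %.4g\n",
                x$kind, x$n, x$mean, x$sd, x$cv))
  }
  invisible(x)
}

# Linear-interpolated times at which series x crosses `level` going up
# (direction = 1) or down (direction = -1).
crossing_times <- function(time, x, level, direction) {
  d <- x - level
  if (direction > 0) idx <- which(d[-1] > 0 & d[-length(d)] <= 0)
  else idx <- which(d[-1] < 0 & d[-length(d)] >= 0)
  if (length(idx) == 0) return(numeric(0))
  t1 <- time[idx]; t2 <- time[idx + 1]
  d1 <- d[idx]; d2 <- d[idx + 1]
  t1 + (0 - d1) / (d2 - d1) * (t2 - t1)
}

#' Threshold-crossing period detection
#'
#' Detects the times at which `X` crosses the up threshold (rising) and the
#' down threshold (falling), removes repeated same-direction crossings so
#' the retained events alternate, and computes periods as differences of
#' consecutive retained up-crossing times. Only excursions that visit both
#' branches of the switch count, so small-amplitude wiggles around one
#' threshold are not scored as cycles. Fewer than two retained up-crossings
#' is a non-oscillatory verdict, not an error.
#'
#' @param traj a `"switch_trajectory"` (or any data.frame with `time` and
#'   `X` columns).
#' @param up,down crossing thresholds, conventionally the saddle-node
#'   vertical coordinates from [event_thresholds()].
#' @return An `"oscillation_stats"` object (kind `"period"`) with fields
#'   `values` (the periods), `n`, `mean`, `sd`, `cv`, `oscillatory`, and
#'   `up_times` (the retained up-crossing times).
#' @export
detect_period <- function(traj, up, down) {
  stopifnot(up > down)
  tu <- crossing_times(traj$time, traj$X, up, +1)
  td <- crossing_times(traj$time, traj$X, down, -1)
  ev <- rbind(data.frame(t = tu, dir = rep(1L, length(tu))),
              data.frame(t = td, dir = rep(-1L, length(td))))
  ev <- ev[order(ev$t), , drop = FALSE]
  keep <- c(TRUE, diff(ev$dir) != 0)  # first of any same-direction run
  ev <- ev[keep, , drop = FALSE]
  up_times <- ev$t[ev$dir == 1L]
  periods <- diff(up_times)
  new_oscillation_stats("period", periods, extra = list(up_times = up_times))
}

# Dominant period of a (roughly periodic) series by discrete Fourier peak.
dominant_period <- function(time, x) {
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12) return(NA_real_)
  n <- length(x)
  sp <- Mod(fft(x))[2:floor(n / 2)]
  k <- which.max(sp)
  dt <- mean(diff(time))
  n * dt / k
}

#' Amplitude detection by smoothing and extrema pairing
#'
#' Smooths the series with a zero-phase low-pass Butterworth filter (cutoff
#' at five times the dominant frequency, estimated from the Fourier peak),
#' locates local maxima and minima, and measures each amplitude as a
#' maximum minus the following minimum.
#'
#' @inheritParams detect_period
#' @return An `"oscillation_stats"` object (kind `"amplitude"`); a constant
#'   or extremum-free signal yields a non-oscillatory verdict.
#' @export
detect_amplitude <- function(traj) {
  time <- traj$time; x <- traj$X
  P <- dominant_period(time, x)
  if (!is.finite(P) || P <= 0)
    return(new_oscillation_stats("amplitude", numeric(0)))
  dt <- mean(diff(time))
  w <- min(0.95, 2 * dt * (5 / P))  # cutoff 5 * dominant frequency (Nyquist units)
  sm <- if (w > 0 && w < 1) {
    bf <- signal::butter(2, w)
    as.numeric(signal::filtfilt(bf, x))
  } else x
  dx <- diff(sm)
  s <- sign(dx)
  turns <- which(s[-1] * s[-length(s)] < 0) + 1L
  if (length(turns) < 2)
    return(new_oscillation_stats("amplitude", numeric(0)))
  is_max <- dx[turns - 1] > 0
  amps <- numeric(0)
  for (i in seq_along(turns)) {
    if (is_max[i] && i < length(turns) && !is_max[i + 1])
      amps <- c(amps, sm[turns[i]] - sm[turns[i + 1]])
  }
  new_oscillation_stats("amplitude", amps)
}

#' Coefficient of variation of a sample
#'
#' @param samples numeric vector, at least two values.
#' @param boot_se if `TRUE`, attach a bootstrap standard error of the CV
#'   (`boot` resamples).
#' @param boot number of bootstrap resamples.
#' @return list with `mean`, `sd` (n-1 denominator), `cv`, and optionally
#'   `cv_se`. A non-positive mean leaves `cv` as `NA` (flagged undefined).
#' @examples
#' cv_statistics(c(1, 3))  # mean 2, sd sqrt(2), cv ~0.707
#' @export
cv_statistics <- function(samples, boot_se = FALSE, boot = 500L) {
  if (length(samples) < 2) stop("cv_statistics needs at least 2 samples")
  mu <- mean(samples); s <- sd(samples)
  cv <- if (mu > 0) s / mu else NA_real_
  out <- list(mean = mu, sd = s, cv = cv)
  if (boot_se) {
    n <- length(samples)
    cvs <- vapply(seq_len(boot), function(i) {
      xi <- samples[sample.int(n, n, replace = TRUE)]
      mi <- mean(xi)
      if (mi > 0) sd(xi) / mi else NA_real_
    }, numeric(1))
    out$cv_se <- sd(cvs, na.rm = TRUE)
  }
  out
}
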