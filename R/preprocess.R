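#' Zero-phase Butterworth bandpass filter
#'
#' Fourth-order (by default) Butterworth bandpass applied forward and
#' backward so no temporal shift is introduced relative to the injection
#' events; the effective attenuation order is therefore doubled. Edge
#' transients are suppressed by odd-reflection padding of three times the
#' effective filter length before filtering.
#'
#' @param x numeric vector, or matrix with one signal per row; or a
#'   [fusi_roits()] / [fusi_image()] object (filtered in place).
#' @param low_hz,high_hz passband edges; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param fs sampling rate (taken from the object when `x` is one).
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered object of the same shape/class as `x`.
#' @examples
#' t <- seq(0, 3599)
#' x <- sin(2 * pi * 0.05 * t)          # mid-band component survives
#' y <- bandpass(x, 0.01, 0.1, fs = 1)
#' max(abs(y)) # close to 1
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.1, fs = NULL, order = 4) {
  if (inherits(x, "fusi_roits")) {
    x$signals <- bandpass(x$signals, low_hz, high_hz, fs = x$fs, order = order)
    return(x)
  }
  if (inherits(x, "fusi_image")) {
    d <- dim(x$data)
    m <- matrix(x$data, d[1] * d[2], d[3])
    m <- bandpass(m, low_hz, high_hz, fs = x$fs, order = order)
    x$data <- array(m, d)
    return(x)
  }
  fs <- fs %||% 1
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stopf("passband must satisfy 0 < low (%g) < high (%g) < fs/2 (%g)",
          low_hz, high_hz, fs / 2)
  bt <- signal::butter(order, c(low_hz, high_hz) * 2 / fs, type = "pass")
  pad <- 3L * (length(bt$b) - 1L)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n <= pad + 1L)
    stopf("series too short for zero-phase filtering: need more than %d samples, got %d",
          pad + 1L, n)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, filtfilt_reflect, b = bt$b, a = bt$a, pad = pad))
    dimnames(out) <- dimnames(x)
    out
  } else {
    filtfilt_reflect(x, b = bt$b, a = bt$a, pad = pad)
  }
}

## Forward-backward IIR filtering with odd reflection padding (the series is
## mirrored and point-reflected about each endpoint, as in standard
## zero-phase filtering practice).
filtfilt_reflect <- function(x, b, a, pad) {
  n <- length(x)
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(pad + 1L):(pad + n)]
}

#' Censor motion-corrupted frames
#'
#' Flags frames whose global-mean intensity deviates from a centered rolling
#' median by more than `zmax` robust standard deviations (median absolute
#' deviation of the residuals, scaled to the normal). Data values are never
#' altered: censoring only updates the validity mask, and frames already
#' invalid stay invalid.
#'
#' @param series a [fusi_image()].
#' @param zmax robust-SD threshold (> 0), default 5.
#' @param window rolling-median window in frames (odd; default 121, i.e.
#'   about 2 min at 1 Hz).
#' @return The input with its `valid` mask updated; the indices of newly
#'   flagged frames are attached as attribute `"censored"`.
#' @export
censor_frames <- function(series, zmax = 5, window = 121) {
  stopifnot(inherits(series, "fusi_image"))
  if (zmax <= 0) stopf("zmax must be positive")
  nt <- dim(series$data)[3]
  window <- min(window, if (nt %% 2 == 1) nt else nt - 1)
  if (window %% 2 == 0) window <- window - 1
  g <- colMeans(matrix(series$data, ncol = nt))
  ref <- runmed(g, k = max(window, 3), endrule = "median")
  resid <- g - ref
  s <- mad(resid)
  if (s == 0) s <- sd(resid)
  flagged <- if (s == 0) rep(FALSE, nt) else abs(resid) > zmax * s
  new_flags <- which(flagged & series$valid)
  series$valid <- series$valid & !flagged
  attr(series, "censored") <- new_flags
  series
}

#' Extract ROI-mean time series from an image stack
#'
#' Per-frame unweighted mean over each ROI's pixels. Invalid frames
#' propagate to the output mask; an empty ROI is an error naming the label.
#'
#' @param series a [fusi_image()].
#' @param roi_map named list mapping ROI label -> linear pixel indices.
#' @return A [fusi_roits()] with one row per ROI in `roi_map` order.
#' @export
extract_roi <- function(series, roi_map) {
  stopifnot(inherits(series, "fusi_image"))
  d <- dim(series$data)
  check_roi_layout(roi_map, d[1], d[2])
  m <- matrix(series$data, d[1] * d[2], d[3])
  sig <- t(vapply(roi_map, function(idx) {
    if (length(idx) == 1) m[idx, ] else colMeans(m[idx, , drop = FALSE])
  }, numeric(d[3])))
  fusi_roits(sig, series$time_s, fs = series$fs, valid = series$valid,
             labels = names(roi_map))
}

#' Select a drug-anchored time interval
#'
#' Returns the contiguous sub-series with
#' `center - width/2 <= t <= center + width/2` (closed interval, consistent
#' with the inclusive time grid: a 9-min interval at 1 Hz has 541 frames).
#' Invalid frames are retained with their mask so that downstream
#' correlations can exclude them pairwise.
#'
#' @param series a [fusi_image()] or [fusi_roits()].
#' @param center_min,width_min interval center and width in minutes relative
#'   to the ketamine injection.
#' @return Object of the same class restricted to the interval.
#' @export
select_interval <- function(series, center_min, width_min) {
  t_min <- series$time_s / 60
  lo <- center_min - width_min / 2
  hi <- center_min + width_min / 2
  if (lo < min(t_min) - 1e-9 || hi > max(t_min) + 1e-9)
    stopf("requested interval [%g, %g] min outside recording span [%g, %g] min",
          lo, hi, min(t_min), max(t_min))
  keep <- which(t_min >= lo - 1e-9 & t_min <= hi + 1e-9)
  if (inherits(series, "fusi_image")) {
    fusi_image(series$data[, , keep, drop = FALSE], series$time_s[keep],
               fs = series$fs, pixel_mm = series$pixel_mm,
               valid = series$valid[keep])
  } else if (inherits(series, "fusi_roits")) {
    fusi_roits(series$signals[, keep, drop = FALSE], series$time_s[keep],
               fs = series$fs, valid = series$valid[keep],
               labels = series$labels)
  } else {
    stopf("select_interval expects a fusi_image or fusi_roits")
  }
}
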