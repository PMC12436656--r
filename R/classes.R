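#' Construct an image time-series container
#'
#' Holds a 2-D pixel-grid cerebral-blood-volume (power Doppler) stack with its
#' acquisition geometry, a per-frame validity mask and a time axis anchored to
#' the ketamine injection (t = 0 s).
#'
#' @param data numeric array `rows x cols x T` of CBV values (arbitrary units).
#' @param time_s numeric vector of length `T`, seconds relative to injection,
#'   strictly increasing with constant step `1/fs`.
#' @param fs sampling rate in frames per second.
#' @param pixel_mm in-plane pixel size in mm.
#' @param valid logical vector of length `T`; `FALSE` marks motion-corrupted
#'   frames that must be excluded from correlation computations.
#' @return An object of class `fusi_image`.
#' @export
fusi_image <- function(data, time_s, fs = 1, pixel_mm = 0.1,
                       valid = rep(TRUE, length(time_s))) {
  if (!is.array(data) || length(dim(data)) != 3)
    stopf("data must be a rows x cols x T array")
  nt <- dim(data)[3]
  if (length(time_s) != nt)
    stopf("time_s has length %d but data has %d frames", length(time_s), nt)
  if (length(valid) != nt) stopf("valid mask must have one entry per frame")
  dt <- diff(time_s)
  if (nt > 1 && (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6))
    stopf("time_s must be strictly increasing with step 1/fs")
  structure(list(data = data, time_s = time_s, fs = fs,
                 pixel_mm = pixel_mm, valid = as.logical(valid)),
            class = "fusi_image")
}

#' @export
print.fusi_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fusi_image: %d x %d pixels, %d frames at %g Hz (%.1f to %.1f min)\n",
              d[1], d[2], d[3], x$fs, min(x$time_s) / 60, max(x$time_s) / 60))
  cat(sprintf("  pixel size %g mm; %d invalid frame(s)\n",
              x$pixel_mm, sum(!x$valid)))
  invisible(x)
}

#' Construct an ROI time-series container
#'
#' Labeled ROI-mean signals sharing one time axis and validity mask. Labels
#' follow the canonical order of [fusi_roi_labels()] for the standard 22-ROI
#' segmentation, but any consistent label set is accepted.
#'
#' @param signals numeric matrix, one ROI per row, one frame per column.
#' @param time_s,fs,valid as in [fusi_image()].
#' @param labels character vector of row labels; defaults to
#'   `rownames(signals)`.
#' @return An object of class `fusi_roits`.
#' @export
fusi_roits <- function(signals, time_s, fs = 1,
                       valid = rep(TRUE, length(time_s)),
                       labels = rownames(signals)) {
  signals <- as.matrix(signals)
  if (is.null(labels)) stopf("ROI signals must be labeled")
  if (length(labels) != nrow(signals))
    stopf("one label per signal row required")
  if (ncol(signals) != length(time_s))
    stopf("signals have %d columns but time_s has length %d",
          ncol(signals), length(time_s))
  if (length(valid) != length(time_s))
    stopf("valid mask must have one entry per frame")
  if (any(!is.finite(signals[, valid])))
    stopf("signals must be finite on valid frames")
  rownames(signals) <- labels
  structure(list(signals = signals, labels = labels, time_s = time_s,
                 fs = fs, valid = as.logical(valid)),
            class = "fusi_roits")
}

#' @export
print.fusi_roits <- function(x, ...) {
  cat(sprintf("fusi_roits: %d ROI signals, %d frames at %g Hz (%.1f to %.1f min)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              min(x$time_s) / 60, max(x$time_s) / 60))
  cat("  labels:", paste(head(x$labels, 6), collapse = ", "),
      if (length(x$labels) > 6) "...", "\n")
  invisible(x)
}
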