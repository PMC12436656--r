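#' Kendall's coefficient of concordance
#'
#' Concordance of `k` time series over `n` time points,
#' \deqn{W = \frac{12}{k^2 (n^3 - n)} \sum_{i=1}^n \Big(\sum_{j=1}^k R_{ij} - k \bar R\Big)^2,}
#' where \eqn{R_{ij}} is the rank of time point `i` within series `j` and
#' \eqn{\bar R = (n+1)/2} the mean rank. W is 0 for maximally discordant and
#' 1 for identical rank orders; ties are midranked and the statistic is used
#' in its uncorrected form (no tie-correction term), since exact ties have
#' measure zero for continuous CBV data. Being rank-based, W is invariant to
#' any strictly monotone transform of each series.
#'
#' @param signals numeric matrix, one series per row (`k x n`, `k >= 2`,
#'   `n >= 3`). A constant series is an error: its ranks carry no
#'   concordance information.
#' @return Scalar in `[0, 1]` (clipped only against numerical round-off).
#' @examples
#' x <- sort(rnorm(50))
#' kcc(rbind(x, x, x))          # identical series -> 1
#' kcc(rbind(x, rev(x)))        # reversed ranks  -> 0
#' @export
kcc <- function(signals) {
  signals <- as.matrix(signals)
  k <- nrow(signals); n <- ncol(signals)
  if (k < 2) stopf("need at least 2 series, got %d", k)
  if (n < 3) stopf("need at least 3 time points, got %d", n)
  if (any(!is.finite(signals))) stopf("signals must be finite")
  v <- apply(signals, 1, function(s) max(s) - min(s))
  if (any(v == 0))
    stopf("constant series in row(s) %s: concordance undefined",
          paste(which(v == 0), collapse = ", "))
  ranks <- apply(signals, 1, rank)      # n x k, midranks for ties
  ri <- rowSums(ranks)
  s <- sum((ri - k * (n + 1) / 2)^2)
  w <- 12 * s / (k^2 * (n^3 - n))
  if (w < -1e-12 || w > 1 + 1e-12)
    warnf("KCC overshoot %g beyond numerical tolerance", w)
  min(max(w, 0), 1)
}

#' Regional-homogeneity (KCC) map
#'
#' Kendall's coefficient of concordance of each pixel with its neighborhood
#' (default the 3 x 3 cluster of 9 neighboring pixels) over the valid frames
#' of an interval. Pixels whose neighborhood leaves the grid or the brain
#' mask, or that contain a constant series, are flagged undefined (`NA`),
#' never zero-filled.
#'
#' @param series a bandpass-filtered [fusi_image()].
#' @param center_min,width_min interval (see [select_interval()]); `NULL`
#'   uses the full series.
#' @param neighborhood odd side length of the square pixel cluster
#'   (default 3, i.e. 9 pixels).
#' @param mask optional logical matrix of in-brain pixels.
#' @param meta session metadata list.
#' @return Object of class `kcc_map`: `kcc` (matrix in `[0, 1]` with `NA`
#'   for undefined pixels), `n_frames`, `neighborhood`, `interval`, `meta`.
#' @export
kcc_map <- function(series, center_min = NULL, width_min = NULL,
                    neighborhood = 3, mask = NULL, meta = list()) {
  stopifnot(inherits(series, "fusi_image"))
  if (neighborhood %% 2 == 0 || neighborhood < 1)
    stopf("neighborhood must be a positive odd integer")
  sub <- if (is.null(center_min)) series else
    select_interval(series, center_min, width_min)
  keep <- sub$valid
  n <- sum(keep)
  if (n < 3) stopf("interval has %d valid frames; at least 3 required", n)
  d <- dim(sub$data)
  nr <- d[1]; nc <- d[2]
  mask <- mask %||% matrix(TRUE, nr, nc)
  m <- matrix(sub$data, nr * nc, d[3])[, keep, drop = FALSE]

  ok <- as.vector(mask) & apply(m, 1, function(s) max(s) > min(s))
  ranks <- matrix(NA_real_, nr * nc, n)
  ranks[ok, ] <- t(apply(m[ok, , drop = FALSE], 1, rank))

  h <- (neighborhood - 1) / 2
  k2 <- neighborhood^2
  acc <- matrix(0, nr * nc, n)
  defined <- matrix(TRUE, nr, nc)
  ra <- array(ranks, c(nr, nc, n))
  oka <- matrix(ok, nr, nc)
  for (di in -h:h) {
    for (dj in -h:h) {
      sh <- shift_matrix3(ra, di, dj)
      oksh <- shift_matrix2(oka, di, dj)
      defined <- defined & oksh
      sh[is.na(sh)] <- 0
      acc <- acc + matrix(sh, nr * nc, n)
    }
  }
  s <- rowSums((acc - k2 * (n + 1) / 2)^2)
  w <- 12 * s / (k2^2 * (n^3 - n))
  w[!as.vector(defined)] <- NA_real_
  w <- pmin(pmax(w, 0), 1)
  structure(list(kcc = matrix(w, nr, nc), n_frames = n,
                 neighborhood = neighborhood,
                 interval = c(center_min = center_min %||% NA_real_,
                              width_min = width_min %||% NA_real_),
                 meta = meta),
            class = "kcc_map")
}

## Shift a rows x cols x time array by (di, dj), padding with NA.
shift_matrix3 <- function(a, di, dj) {
  d <- dim(a)
  out <- array(NA_real_, d)
  ri <- seq_len(d[1]); ci <- seq_len(d[2])
  src_r <- ri + di; src_c <- ci + dj
  vr <- src_r >= 1 & src_r <= d[1]
  vc <- src_c >= 1 & src_c <= d[2]
  out[ri[vr], ci[vc], ] <- a[src_r[vr], src_c[vc], , drop = FALSE]
  out
}

shift_matrix2 <- function(m, di, dj) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  ri <- seq_len(d[1]); ci <- seq_len(d[2])
  src_r <- ri + di; src_c <- ci + dj
  vr <- src_r >= 1 & src_r <= d[1]
  vc <- src_c >= 1 & src_c <= d[2]
  out[ri[vr], ci[vc]] <- m[src_r[vr], src_c[vc], drop = FALSE]
  out
}

#' @export
print.kcc_map <- function(x, ...) {
  cat(sprintf("kcc_map: %d x %d pixels (%d x %d neighborhood), %d frames\n",
              nrow(x$kcc), ncol(x$kcc), x$neighborhood, x$neighborhood,
              x$n_frames))
  cat(sprintf("  defined pixels: %d; mean KCC = %.3f\n",
              sum(!is.na(x$kcc)), mean(x$kcc, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.kcc_map <- function(x, main = "regional homogeneity (KCC)", ...) {
  image(t(x$kcc[nrow(x$kcc):1, ]), zlim = c(0, 1),
        col = hcl.colors(64, "viridis"), axes = FALSE, main = main, ...)
  invisible(x)
}

#' Animal-level z-scoring of KCC maps
#'
#' For one animal, pools the mean and standard deviation over all defined
#' pixels of its 4 maps (baseline and post-ketamine under the two
#' treatments) and z-scores each map with those pooled moments, so that the
#' 4 maps are directly comparable within the animal.
#'
#' @param maps list of exactly 4 [kcc_map()] objects on a shared grid.
#' @return List of 4 `kcc_map` objects whose `kcc` fields hold the z-scored
#'   values (class retained, `zscored = TRUE` attribute), with the pooled
#'   `mean` and `sd` attached as attributes. A zero pooled SD is flagged
#'   degenerate and yields all-zero z maps.
#' @export
zscore_kcc <- function(maps) {
  if (length(maps) != 4)
    stopf("animal-level z-scoring needs exactly 4 maps, got %d (missing: %s)",
          length(maps),
          paste(setdiff(c("baseline/VEH+KET", "baseline/NTX+KET",
                          "post/VEH+KET", "post/NTX+KET"),
                        vapply(maps, function(m)
                          paste(m$meta$time %||% "?", m$meta$condition %||% "?",
                                sep = "/"), "")), collapse = ", "))
  stopifnot(all(vapply(maps, inherits, TRUE, "kcc_map")))
  dims <- vapply(maps, function(m) dim(m$kcc), integer(2))
  if (any(dims != dims[, 1])) stopf("maps must share one pixel grid")
  vals <- unlist(lapply(maps, function(m) m$kcc[!is.na(m$kcc)]))
  mu <- mean(vals); s <- sd(vals)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    warnf("pooled SD is zero across the 4 maps; z set to 0")
    s <- 1
  }
  out <- lapply(maps, function(m) {
    m$kcc <- (m$kcc - mu) / s
    attr(m, "zscored") <- TRUE
    m
  })
  attr(out, "mean") <- mu
  attr(out, "sd") <- if (degenerate) 0 else s
  attr(out, "degenerate") <- degenerate
  out
}

#' Segment z-scored KCC maps into per-ROI means
#'
#' @param zmaps list of (z-scored) [kcc_map()] objects with metadata.
#' @param roi_layout named list mapping ROI label -> pixel indices on the
#'   same grid.
#' @return Tidy data.frame (subject, sex, condition, time, roi, zkcc) ready
#'   for [mixed_anova()]; an ROI with no defined pixel yields `NA` (flagged
#'   missing, not zero).
#' @export
segment_kcc <- function(zmaps, roi_layout) {
  stopifnot(length(zmaps) > 0)
  d <- dim(zmaps[[1]]$kcc)
  check_roi_layout(roi_layout, d[1], d[2])
  rows <- lapply(zmaps, function(m) {
    v <- as.vector(m$kcc)
    means <- vapply(roi_layout, function(idx) {
      x <- v[idx]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    data.frame(subject = m$meta$subject %||% NA_character_,
               sex = m$meta$sex %||% NA_character_,
               condition = m$meta$condition %||% NA_character_,
               time = m$meta$time %||% NA_character_,
               roi = names(roi_layout), zkcc = unname(means),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
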