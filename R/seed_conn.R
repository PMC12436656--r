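#' Seed-based pixel-wise correlation map
#'
#' Correlates the mean signal of a seed pixel set (by default the bilateral
#' PrL + IL medial prefrontal cortex) with every pixel's time series over
#' the valid frames of a drug-anchored interval, storing both r and
#' Fisher-z maps.
#'
#' @param series a bandpass-filtered [fusi_image()].
#' @param seed seed definition: a logical matrix on the pixel grid, a vector
#'   of linear pixel indices, or a character vector of ROI labels resolved
#'   through `roi_layout`.
#' @param roi_layout named list of pixel indices (required when `seed` is a
#'   character vector).
#' @param center_min,width_min interval (see [select_interval()]); `NULL`
#'   uses the full series.
#' @param meta session metadata list.
#' @return Object of class `seed_map`: `r_map`, `z_map` (matrices),
#'   `seed_mask`, `interval`, `n_valid`, `meta`.
#' @export
seed_map <- function(series, seed = c("PrL_L", "PrL_R", "IL_L", "IL_R"),
                     roi_layout = NULL, center_min = NULL, width_min = NULL,
                     meta = list()) {
  stopifnot(inherits(series, "fusi_image"))
  d <- dim(series$data)
  seed_idx <- resolve_pixels(seed, roi_layout, d[1], d[2])
  if (!length(seed_idx)) stopf("seed pixel set is empty")
  sub <- if (is.null(center_min)) series else
    select_interval(series, center_min, width_min)
  keep <- sub$valid
  if (sum(keep) < 3) stopf("fewer than 3 valid frames in interval")
  m <- matrix(sub$data, d[1] * d[2], dim(sub$data)[3])[, keep, drop = FALSE]
  seed_sig <- if (length(seed_idx) == 1) m[seed_idx, ] else colMeans(m[seed_idx, , drop = FALSE])
  suppressWarnings(r <- as.vector(cor(seed_sig, t(m))))
  r_map <- matrix(r, d[1], d[2])
  mask <- matrix(FALSE, d[1], d[2]); mask[seed_idx] <- TRUE
  structure(list(r_map = r_map, z_map = suppressWarnings(fisher_z(r_map)),
                 seed_mask = mask,
                 interval = c(center_min = center_min %||% NA_real_,
                              width_min = width_min %||% NA_real_),
                 n_valid = sum(keep), pixel_mm = series$pixel_mm,
                 meta = meta),
            class = "seed_map")
}

resolve_pixels <- function(seed, roi_layout, n_rows, n_cols) {
  if (is.character(seed)) {
    if (is.null(roi_layout))
      stopf("roi_layout required to resolve seed ROI labels")
    missing <- setdiff(seed, names(roi_layout))
    if (length(missing))
      stopf("seed ROI(s) not in layout: %s", paste(missing, collapse = ", "))
    sort(unique(unlist(roi_layout[seed], use.names = FALSE)))
  } else if (is.logical(seed) && is.matrix(seed)) {
    which(seed)
  } else {
    as.integer(seed)
  }
}

#' @export
print.seed_map <- function(x, ...) {
  cat(sprintf("seed_map: %d x %d pixels, seed of %d px, %d valid frames\n",
              nrow(x$r_map), ncol(x$r_map), sum(x$seed_mask), x$n_valid))
  invisible(x)
}

#' @export
plot.seed_map <- function(x, main = "seed-based correlation", ...) {
  image(t(x$r_map[nrow(x$r_map):1, ]), zlim = c(-1, 1),
        col = hcl.colors(64, "RdBu", rev = TRUE), axes = FALSE,
        main = main, ...)
  invisible(x)
}

#' Median-filter smoothing of a connectivity map
#'
#' Per-pixel median over a square kernel of physical size `kernel_mm`
#' (default 0.3 mm, i.e. 3 x 3 pixels at 0.1 mm resolution); borders are
#' handled by reflection and undefined (`NA`) pixels stay undefined.
#'
#' @param map a [seed_map()] (both r and z maps are re-derived from the
#'   smoothed r map) or a plain numeric matrix.
#' @param kernel_mm kernel side in mm; `kernel_mm / pixel_mm` must round to
#'   an odd integer >= 1.
#' @param pixel_mm pixel size (taken from the map object when available).
#' @return Object of the same class, smoothed.
#' @export
smooth_map <- function(map, kernel_mm = 0.3, pixel_mm = NULL) {
  if (inherits(map, "seed_map")) {
    sm <- smooth_map(map$r_map, kernel_mm, pixel_mm %||% map$pixel_mm)
    map$r_map <- sm
    map$z_map <- suppressWarnings(fisher_z(sm))
    return(map)
  }
  pixel_mm <- pixel_mm %||% 0.1
  k <- as.integer(round(kernel_mm / pixel_mm))
  if (k < 1) stopf("kernel smaller than one pixel")
  if (k %% 2 == 0)
    stopf("kernel of %d pixels is even; use kernel_mm near %g or %g mm",
          k, (k - 1) * pixel_mm, (k + 1) * pixel_mm)
  out <- median_filter_cpp(map, k)
  out[!is.finite(map)] <- NA_real_
  out
}

#' Group-level paired t map
#'
#' Pixel-wise two-tailed paired t statistics on Fisher-z values between two
#' matched sets of seed maps (same subjects, same order, same grid).
#' Zero-variance pixels with a nonzero mean difference are flagged as
#' degenerate (infinite t); pixels with identical values in both conditions
#' get t = 0.
#'
#' @param maps_a,maps_b lists of [seed_map()] objects matched per subject
#'   (the contrast is `b - a`).
#' @return Object of class `tmap`: `t` (matrix), `df`, `n`, `degenerate`
#'   (logical matrix), plus empty cluster fields filled by
#'   [apply_cluster_correction()].
#' @export
paired_tmap <- function(maps_a, maps_b) {
  n <- length(maps_a)
  if (length(maps_b) != n) stopf("map lists differ in length")
  if (n < 3) stopf("need at least 3 matched subjects, got %d", n)
  sub_a <- vapply(maps_a, function(m) as.character(m$meta$subject %||% NA), "")
  sub_b <- vapply(maps_b, function(m) as.character(m$meta$subject %||% NA), "")
  if (!all(is.na(sub_a)) && !identical(sub_a, sub_b))
    stopf("subject mismatch between map lists: %s vs %s",
          paste(sub_a, collapse = ","), paste(sub_b, collapse = ","))
  za <- vapply(maps_a, function(m) m$z_map, maps_a[[1]]$z_map)
  zb <- vapply(maps_b, function(m) m$z_map, maps_b[[1]]$z_map)
  d <- zb - za
  mn <- apply(d, c(1, 2), mean)
  s <- apply(d, c(1, 2), sd)
  tt <- mn / (s / sqrt(n))
  degenerate <- s == 0
  tt[degenerate & mn == 0] <- 0
  tt[degenerate & mn != 0] <- sign(mn[degenerate & mn != 0]) * Inf
  structure(list(t = tt, df = n - 1, n = n, degenerate = degenerate,
                 cluster_labels = NULL, cluster_table = NULL,
                 contrast = "b - a"),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("tmap: %d x %d pixels, paired t with df = %d\n",
              nrow(x$t), ncol(x$t), x$df))
  if (!is.null(x$cluster_table))
    cat(sprintf("  %d surviving cluster(s)\n", nrow(x$cluster_table)))
  invisible(x)
}

#' Connected-component labeling of a binary pixel map
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge-adjacent, default) or 8 (edge or corner).
#' @return Integer matrix: 0 background, 1..K component ids.
#' @export
label_clusters <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  label_components_cpp(mask, as.integer(connectivity))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Determines the minimum cluster size controlling the family-wise error of
#' pixel-wise two-tailed tests, in the spirit of AFNI's 3dClustSim: simulate
#' `n_iter` Gaussian null fields, pass each through the same smoothing
#' applied to the data (so the null smoothness is matched empirically rather
#' than via an analytic FWHM), threshold two-tailed at `alpha_vox` using the
#' field's own robust scale, record the maximum cluster size, and return the
#' smallest size `s` with `P(max cluster >= s) <= alpha_clust`.
#'
#' @param brain_mask logical matrix of analyzed pixels.
#' @param alpha_vox two-tailed cluster-forming voxel threshold (default 0.05).
#' @param alpha_clust target family-wise error (default 0.05).
#' @param n_iter Monte-Carlo iterations (>= 1000 recommended).
#' @param smoother `NULL`, or a function `matrix -> matrix` applied to each
#'   null field (e.g. `function(m) smooth_map(m, 0.3, 0.1)`).
#' @param connectivity pixel connectivity, 4 or 8.
#' @param seed optional integer seed.
#' @return Integer threshold with attributes `max_sizes` (the simulated
#'   maxima) and `attained_fwe` (the estimated `P(max >= s)`).
#' @export
mc_cluster_threshold <- function(brain_mask, alpha_vox = 0.05,
                                 alpha_clust = 0.05, n_iter = 2000,
                                 smoother = NULL, connectivity = 4,
                                 seed = NULL) {
  stopifnot(is.matrix(brain_mask))
  mask <- brain_mask & !is.na(brain_mask)
  if (!any(mask)) stopf("brain mask is empty")
  if (alpha_vox <= 0 || alpha_vox >= 1 || alpha_clust <= 0 || alpha_clust > 1)
    stopf("alpha levels must be in (0, 1]")
  if (alpha_clust < 1 / n_iter)
    stopf("alpha_clust = %g not attainable with n_iter = %d; increase n_iter",
          alpha_clust, n_iter)
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(mask); nc <- ncol(mask)
  zc <- qnorm(1 - alpha_vox / 2)
  mx <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    x <- matrix(rnorm(nr * nc), nr, nc)
    if (!is.null(smoother)) x <- smoother(x)
    v <- x[mask]
    thr <- zc * sd(v)
    supra <- abs(x) > thr & mask
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) next
    lab <- label_components_cpp(supra, as.integer(connectivity))
    mx[i] <- max(tabulate(lab[lab > 0]))
  }
  sizes <- sort(unique(c(1L, mx + 1L)))
  fwe <- vapply(sizes, function(s) mean(mx >= s), numeric(1))
  ok <- sizes[fwe <= alpha_clust]
  s <- min(ok)
  structure(s, max_sizes = mx, attained_fwe = mean(mx >= s))
}

#' Apply cluster-extent correction to a t map
#'
#' Thresholds the map two-tailed at `alpha_vox` (Student t with the map's
#' df), groups supra-threshold pixels under the declared connectivity, and
#' removes clusters smaller than `min_cluster` pixels. Surviving clusters
#' are labeled and tabulated with size, sign and peak statistics.
#'
#' @param tmap a [paired_tmap()] result.
#' @param alpha_vox two-tailed voxel threshold (default 0.05).
#' @param min_cluster minimum surviving cluster size in pixels (>= 1), e.g.
#'   the output of [mc_cluster_threshold()].
#' @param connectivity 4 or 8.
#' @param mask optional logical matrix restricting the analysis.
#' @return The `tmap` with `cluster_labels` (integer matrix) and
#'   `cluster_table` (data.frame: cluster, size, sign, peak_t, row, col)
#'   filled in.
#' @export
apply_cluster_correction <- function(tmap, alpha_vox = 0.05, min_cluster = 1,
                                     connectivity = 4, mask = NULL) {
  stopifnot(inherits(tmap, "tmap"))
  if (min_cluster < 1) stopf("min_cluster must be >= 1")
  tcrit <- qt(1 - alpha_vox / 2, df = tmap$df)
  supra <- abs(tmap$t) > tcrit
  supra[!is.finite(tmap$t)] <- FALSE
  if (!is.null(mask)) supra <- supra & mask
  lab <- label_components_cpp(supra, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster)
  out <- matrix(0L, nrow(lab), ncol(lab))
  tab <- NULL
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    rows <- list()
    for (j in seq_along(keep)) {
      idx <- which(lab == keep[j], arr.ind = TRUE)
      out[lab == keep[j]] <- j
      tv <- tmap$t[lab == keep[j]]
      pk <- which.max(abs(tv))
      rows[[j]] <- data.frame(cluster = j, size = nrow(idx),
                              sign = sign(tv[pk]), peak_t = tv[pk],
                              row = mean(idx[, 1]), col = mean(idx[, 2]))
    }
    tab <- do.call(rbind, rows)
  }
  tmap$cluster_labels <- out
  tmap$cluster_table <- tab %||%
    data.frame(cluster = integer(), size = integer(), sign = numeric(),
               peak_t = numeric(), row = numeric(), col = numeric())
  tmap
}
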