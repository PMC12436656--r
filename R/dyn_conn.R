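#' Sliding-window connectivity sequence
#'
#' ROI pair-wise Pearson correlations from rectangular temporal windows
#' (default 30 s) advanced by `step_s` (default 1 s). Each window's matrix
#' is vectorized column-major into all `p^2` entries (484 columns for the
#' 22-ROI grid: diagonal and both triangles are kept so a row reshapes back
#' to a full symmetric matrix). A session with an inclusive 1 Hz grid from
#' -20 to +40 min (3601 samples) yields `3601 - 30 + 1 = 3572` windows.
#' Windows containing invalid frames use pairwise deletion; windows with
#' fewer than `min_valid_frac` valid frames are flagged.
#'
#' @param roits a bandpass-filtered [fusi_roits()].
#' @param window_s window length in seconds; `fs * window_s` must be a
#'   whole number of samples.
#' @param step_s step between window starts in seconds.
#' @param min_valid_frac windows with a lower valid-frame fraction are
#'   flagged (default 0.5).
#' @param meta session metadata carried along.
#' @return Object of class `swc`: `windows` (`N x p^2` matrix),
#'   `centers_s`, `window_s`, `step_s`, `flagged`, `labels`, `meta`.
#' @export
sliding_window_fc <- function(roits, window_s = 30, step_s = 1,
                              min_valid_frac = 0.5, meta = list()) {
  stopifnot(inherits(roits, "fusi_roits"))
  w <- roits$fs * window_s
  if (abs(w - round(w)) > 1e-9) stopf("fs * window_s must be an integer")
  w <- as.integer(round(w))
  step <- max(1L, as.integer(round(roits$fs * step_s)))
  nt <- ncol(roits$signals)
  if (nt < w)
    stopf("series of %d samples shorter than one %d-sample window", nt, w)
  x <- t(roits$signals)
  x[!roits$valid, ] <- NA
  p <- ncol(x)
  starts <- seq(1L, nt - w + 1L, by = step)
  n <- length(starts)
  out <- matrix(NA_real_, n, p * p)
  centers <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    idx <- starts[i]:(starts[i] + w - 1L)
    xi <- x[idx, , drop = FALSE]
    nval <- sum(roits$valid[idx])
    flagged[i] <- nval < min_valid_frac * w
    r <- if (nval == w) cor(xi) else
      suppressWarnings(cor(xi, use = "pairwise.complete.obs"))
    diag(r) <- 1
    out[i, ] <- as.vector(r)
    centers[i] <- mean(roits$time_s[idx])
  }
  colnames(out) <- flat_labels(roits$labels)
  structure(list(windows = out, centers_s = centers, window_s = window_s,
                 step_s = step_s, flagged = flagged, labels = roits$labels,
                 meta = meta),
            class = "swc")
}

#' @export
print.swc <- function(x, ...) {
  cat(sprintf("swc: %d windows of %g s (step %g s), %d columns, %d flagged\n",
              nrow(x$windows), x$window_s, x$step_s, ncol(x$windows),
              sum(x$flagged)))
  invisible(x)
}

#' Concatenate sliding-window sequences across a cohort
#'
#' Stacks the window matrices of several sessions along the time variable
#' into one global matrix, with a row index that maps every row back to its
#' (subject, condition, window center) exactly.
#'
#' @param swcs list of [sliding_window_fc()] results with consistent column
#'   dimension.
#' @return Object of class `swc_global`: `x` (row-bound matrix), `index`
#'   (data.frame: session, subject, sex, condition, center_s, flagged).
#' @export
concat_cohort <- function(swcs) {
  stopifnot(length(swcs) > 0, all(vapply(swcs, inherits, TRUE, "swc")))
  nc <- vapply(swcs, function(s) ncol(s$windows), integer(1))
  if (length(unique(nc)) != 1)
    stopf("column mismatch across sessions: %s", paste(unique(nc), collapse = ", "))
  idx <- lapply(seq_along(swcs), function(i) {
    s <- swcs[[i]]
    data.frame(session = i,
               subject = s$meta$subject %||% NA_character_,
               sex = s$meta$sex %||% NA_character_,
               condition = s$meta$condition %||% NA_character_,
               center_s = s$centers_s, flagged = s$flagged,
               stringsAsFactors = FALSE)
  })
  structure(list(x = do.call(rbind, lapply(swcs, `[[`, "windows")),
                 index = do.call(rbind, idx),
                 labels = swcs[[1]]$labels),
            class = "swc_global")
}

#' SVD elbow selection of the number of brain states
#'
#' Ranks the singular values of the global window matrix, keeps the
#' smallest leading set whose cumulative variance (squared singular values
#' over total) reaches `var_threshold` (default 99%), and locates the elbow
#' on that reduced spectrum via the discrete second difference of the
#' descending singular values. The default rule returns the index at which
#' the second difference is minimal — the point where the rate of change of
#' the singular values is minimum, i.e. the last component before the
#' spectrum flattens; `rule = "max"` returns the maximum-curvature
#' convention instead (typically one index later on a sharp elbow).
#'
#' @param x numeric matrix (rows = windows) or a [concat_cohort()] result.
#' @param var_threshold cumulative-variance cut in (0, 1].
#' @param rule `"min"` (default) or `"max"`; see Details.
#' @return Object of class `svd_elbow`: `k_opt`, `singular_values`,
#'   `cum_var`, `m` (components kept), `d2` (second differences),
#'   `saliency` (elbow magnitude relative to the median |d2|), `rule`.
#'   Degenerate rank-1 input yields `k_opt = 1` with a warning.
#' @export
svd_elbow <- function(x, var_threshold = 0.99, rule = c("min", "max")) {
  rule <- match.arg(rule)
  if (inherits(x, "swc_global")) x <- x$x
  if (!is.matrix(x) || nrow(x) < 3 || ncol(x) < 3)
    stopf("need a matrix with at least 3 rows and columns")
  ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  sv <- sqrt(pmax(ev, 0))
  tot <- sum(sv^2)
  if (tot == 0) stopf("all-zero input matrix")
  cum_var <- cumsum(sv^2) / tot
  if (cum_var[1] >= 1 - 1e-12) {
    warnf("rank-1 spectrum: k_opt set to 1")
    return(structure(list(k_opt = 1L, singular_values = sv, cum_var = cum_var,
                          m = 1L, d2 = numeric(0), saliency = NA_real_,
                          rule = rule), class = "svd_elbow"))
  }
  m <- which(cum_var >= var_threshold)[1]
  if (m < 3) {
    warnf("fewer than 3 components below the variance cut; k_opt set to 1")
    return(structure(list(k_opt = 1L, singular_values = sv, cum_var = cum_var,
                          m = m, d2 = numeric(0), saliency = NA_real_,
                          rule = rule), class = "svd_elbow"))
  }
  d2 <- diff(sv[seq_len(m)], differences = 2)   # d2[j] centered at j + 1
  k <- if (rule == "min") which.min(d2) + 1L else which.max(d2) + 1L
  ## saliency: relative spectral gap below the chosen elbow; an isotropic
  ## spectrum has no pronounced gap anywhere
  sal <- (sv[k] - sv[k + 1L]) / max(sv[k + 1L], 1e-12)
  structure(list(k_opt = as.integer(k), singular_values = sv,
                 cum_var = cum_var, m = m, d2 = d2, saliency = sal,
                 rule = rule),
            class = "svd_elbow")
}

#' @export
print.svd_elbow <- function(x, ...) {
  cat(sprintf("svd_elbow: k_opt = %d (rule: second-difference %s) over %d components\n",
              x$k_opt, x$rule, x$m))
  if (is.finite(x$saliency %||% NA) && x$saliency < 0.1)
    cat("  note: low elbow saliency; the spectrum has no pronounced elbow\n")
  invisible(x)
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  if (k > 1) for (j in 2:k) {
    prob <- d2 / sum(d2)
    i <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' Cluster brain states from vectorized window connectivity
#'
#' k-means (k-means++ initialization, `n_init` restarts, best total
#' within-cluster sum of squares kept) on the rows of the global window
#' matrix, run on the r values directly. States are sorted by decreasing
#' mean off-diagonal centroid connectivity, so state 1 is always the most
#' connected and state k the most disconnected pattern, and every window
#' receives exactly one state label.
#'
#' @param x matrix or [concat_cohort()] result.
#' @param k number of states (>= 2), e.g. from [svd_elbow()].
#' @param seed integer seed controlling initialization.
#' @param n_init number of k-means++ restarts (default 20).
#' @param iter_max Lloyd iterations per restart.
#' @return Object of class `brain_states`: `k`, `centroids` (`k x p^2`,
#'   sorted), `labels` (per-window state id), `mean_conn` (per-state mean
#'   centroid connectivity), `tot_withinss`, `index` (row index when `x`
#'   was a cohort), `roi_labels`, `seed`, `n_init`.
#' @export
cluster_states <- function(x, k, seed = NULL, n_init = 20, iter_max = 100) {
  index <- NULL; roi_labels <- NULL
  if (inherits(x, "swc_global")) {
    index <- x$index; roi_labels <- x$labels; x <- x$x
  }
  if (!is.matrix(x)) stopf("x must be a matrix")
  if (k < 2) stopf("k must be >= 2")
  if (nrow(x) < k) stopf("fewer rows (%d) than clusters (%d)", nrow(x), k)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- NULL
    for (retry in 1:5) {
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && length(unique(fit$cluster)) == k) break
      fit <- NULL
    }
    if (is.null(fit))
      stopf("k-means produced empty clusters in all retries; reduce k")
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  p <- as.integer(round(sqrt(ncol(x))))
  square <- p * p == ncol(x)
  mean_conn <- vapply(seq_len(k), function(j) {
    if (square) {
      m <- matrix(best$centers[j, ], p, p)
      mean(m[row(m) != col(m)])      # off-diagonal mean connectivity
    } else {
      mean(best$centers[j, ])        # generic features: plain centroid mean
    }
  }, numeric(1))
  ord <- order(mean_conn, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  structure(list(k = k,
                 centroids = best$centers[ord, , drop = FALSE],
                 labels = relabel[best$cluster],
                 mean_conn = mean_conn[ord],
                 tot_withinss = best$tot.withinss,
                 index = index, roi_labels = roi_labels,
                 seed = seed, n_init = n_init),
            class = "brain_states")
}

#' @export
print.brain_states <- function(x, ...) {
  cat(sprintf("brain_states: k = %d states over %d windows\n",
              x$k, length(x$labels)))
  cat("  mean centroid connectivity (state 1 = most connected):\n  ")
  cat(sprintf("%.3f", x$mean_conn), sep = "  ")
  cat("\n")
  invisible(x)
}

#' @export
summary.brain_states <- function(object, ...) {
  tf <- tabulate(object$labels, object$k) / length(object$labels)
  out <- data.frame(state = seq_len(object$k),
                    mean_connectivity = object$mean_conn,
                    time_fraction = tf)
  cat(sprintf("brain_states fit: k = %d, total within-SS = %.1f\n",
              object$k, object$tot_withinss))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
predict.brain_states <- function(object, newdata, ...) {
  if (inherits(newdata, "swc")) newdata <- newdata$windows
  if (inherits(newdata, "swc_global")) newdata <- newdata$x
  if (ncol(newdata) != ncol(object$centroids))
    stopf("newdata has %d columns; model expects %d",
          ncol(newdata), ncol(object$centroids))
  cc <- rowSums(object$centroids^2)
  d <- -2 * newdata %*% t(object$centroids) +
    rep(cc, each = nrow(newdata))
  max.col(-d, ties.method = "first")
}

#' @export
plot.brain_states <- function(x, ...) {
  p <- as.integer(round(sqrt(ncol(x$centroids))))
  if (p * p != ncol(x$centroids))
    stopf("centroids are not vectorized square matrices; nothing to draw")
  op <- par(mfrow = c(1, x$k), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (j in seq_len(x$k)) {
    m <- matrix(x$centroids[j, ], p, p)
    image(t(m[p:1, ]), zlim = c(-1, 1),
          col = hcl.colors(64, "RdBu", rev = TRUE), axes = FALSE,
          main = sprintf("state %d", j))
  }
  invisible(x)
}

#' Instantaneous phase-difference connectivity features
#'
#' A windowing-free alternative to sliding-window correlation: each ROI
#' signal's instantaneous phase is taken from its analytic signal (Hilbert
#' transform via FFT; meaningful for narrowband, i.e. bandpassed, input),
#' and for every ROI pair the per-timepoint cosine of the phase difference
#' is returned, vectorized to the same `p^2` column layout as
#' [sliding_window_fc()].
#'
#' @param roits a bandpass-filtered [fusi_roits()].
#' @return Matrix `T x p^2` of `cos(phase_i - phase_j)` values with the
#'   window column naming; the time axis is attached as attribute
#'   `"centers_s"`. Broadband-looking input (low lag-1 autocorrelation)
#'   triggers a warning since the instantaneous phase is then ill-defined.
#' @export
phase_difference_features <- function(roits) {
  stopifnot(inherits(roits, "fusi_roits"))
  x <- roits$signals
  ac1 <- apply(x, 1, function(s) {
    s <- s - mean(s)
    sum(s[-1] * s[-length(s)]) / sum(s^2)
  })
  if (any(ac1 < 0.5))
    warnf("signals look broadband (lag-1 autocorrelation < 0.5); bandpass before extracting phases")
  ph <- t(apply(x, 1, instantaneous_phase))
  cs <- cos(ph); sn <- sin(ph)
  p <- nrow(x); nt <- ncol(x)
  out <- matrix(NA_real_, nt, p * p)
  for (t in seq_len(nt)) {
    out[t, ] <- as.vector(tcrossprod(cs[, t]) + tcrossprod(sn[, t]))
  }
  colnames(out) <- flat_labels(roits$labels)
  attr(out, "centers_s") <- roits$time_s
  out
}

## Analytic-signal phase via the FFT construction of the Hilbert transform.
instantaneous_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Analysis periods for state metrics
#'
#' Constructors for the drug-anchored analysis periods: the pre-ketamine
#' period spans -18.5 to -1.5 min excluding a 3-min gap centered on the
#' pretreatment injection at -10 min, and the post-ketamine period spans
#' 2.5 to 17.5 min. Runs and transitions never bridge an exclusion gap.
#'
#' @param start_min,end_min closed period bounds in minutes.
#' @param exclude `NULL`, a length-2 vector, or a 2-column matrix of
#'   excluded intervals (minutes).
#' @return A list of class `analysis_period`.
#' @export
analysis_period <- function(start_min, end_min, exclude = NULL) {
  if (end_min <= start_min) stopf("empty period")
  if (!is.null(exclude)) {
    exclude <- matrix(exclude, ncol = 2)
    if (any(exclude[, 2] <= exclude[, 1])) stopf("malformed exclusion")
  }
  structure(list(start_min = start_min, end_min = end_min, exclude = exclude),
            class = "analysis_period")
}

#' @rdname analysis_period
#' @export
pre_ketamine_period <- function() {
  analysis_period(-18.5, -1.5, exclude = c(-11.5, -8.5))
}

#' @rdname analysis_period
#' @export
post_ketamine_period <- function() analysis_period(2.5, 17.5)

## Indices inside the period, and a segment id that breaks at exclusions
## and at non-contiguous label timestamps.
period_segments <- function(times_s, period, step_s) {
  t_min <- times_s / 60
  keep <- t_min >= period$start_min - 1e-9 & t_min <= period$end_min + 1e-9
  if (!is.null(period$exclude)) {
    for (i in seq_len(nrow(period$exclude))) {
      keep <- keep & !(t_min >= period$exclude[i, 1] - 1e-9 &
                       t_min <= period$exclude[i, 2] + 1e-9)
    }
  }
  idx <- which(keep)
  if (!length(idx)) stopf("no label timestamps fall inside the period")
  gap <- c(FALSE, diff(times_s[idx]) > step_s * 1.5)
  list(idx = idx, segment = cumsum(gap) + 1L)
}

#' State occupancy metrics for an analysis period
#'
#' Time fraction (fraction of period timepoints assigned to each state),
#' dwell time (mean uninterrupted run length in seconds, runs clipped at
#' period boundaries and exclusion gaps), the transition-probability matrix
#' over consecutive labels (self-transitions included; transitions never
#' bridge an exclusion gap), and the Markov entropy of those transition
#' probabilities.
#'
#' @param labels integer state labels (1..k), one per window.
#' @param times_s label timestamps in seconds (window centers).
#' @param period an [analysis_period()].
#' @param k number of states (default `max(labels)`).
#' @param step_s label spacing in seconds (default 1).
#' @return Object of class `state_metrics`: `time_fraction` (sums to 1),
#'   `dwell_s` (`NA` for unvisited states), `transition` (row-stochastic
#'   over visited states; all-zero rows for states without outgoing
#'   transitions), `entropy` (nats), `n_points`, `period`.
#' @examples
#' m <- state_metrics(c(1, 1, 2, 2, 2), times_s = 0:4,
#'                    period = analysis_period(-1, 1e3), k = 2)
#' m$time_fraction   # 0.4, 0.6
#' @export
state_metrics <- function(labels, times_s, period, k = max(labels),
                          step_s = 1) {
  stopifnot(inherits(period, "analysis_period"),
            length(labels) == length(times_s))
  seg <- period_segments(times_s, period, step_s)
  lab <- labels[seg$idx]
  n <- length(lab)
  tf <- tabulate(lab, k) / n

  runs <- do.call(rbind, lapply(split(lab, seg$segment), label_runs))
  dwell <- vapply(seq_len(k), function(s) {
    r <- runs$length[runs$value == s]
    if (!length(r)) NA_real_ else mean(r) * step_s
  }, numeric(1))

  p <- transition_counts(lab, seg$segment, k)
  tot <- rowSums(p)
  pm <- p / ifelse(tot > 0, tot, 1)
  pm[tot == 0, ] <- 0
  h <- markov_entropy(pm, allow_empty_rows = TRUE)
  structure(list(time_fraction = tf, dwell_s = dwell, transition = pm,
                 entropy = h, n_points = n, period = period,
                 visited = tabulate(lab, k) > 0),
            class = "state_metrics")
}

#' @export
print.state_metrics <- function(x, ...) {
  cat(sprintf("state_metrics over %d timepoints (%g to %g min)\n",
              x$n_points, x$period$start_min, x$period$end_min))
  print(data.frame(state = seq_along(x$time_fraction),
                   time_fraction = round(x$time_fraction, 3),
                   dwell_s = round(x$dwell_s, 2)), row.names = FALSE)
  cat(sprintf("  Markov entropy = %.3f nats\n", x$entropy))
  invisible(x)
}

transition_counts <- function(lab, segment, k) {
  p <- matrix(0, k, k)
  for (s in unique(segment)) {
    l <- lab[segment == s]
    if (length(l) < 2) next
    from <- l[-length(l)]; to <- l[-1]
    for (i in seq_along(from)) p[from[i], to[i]] <- p[from[i], to[i]] + 1
  }
  p
}

#' Empirical state transition matrix
#'
#' Transition probabilities between consecutive labels: counts from state i
#' to state j divided by the total transitions out of state i
#' (self-transitions included). States without outgoing transitions get an
#' all-zero row, flagged for exclusion from the entropy.
#'
#' @param labels integer state sequence.
#' @param k number of states (default `max(labels)`).
#' @return `k x k` matrix with row-stochastic visited rows; attribute
#'   `"counts"` carries the raw counts.
#' @examples
#' transition_matrix(c(1, 2, 1, 2, 1))   # [[0,1],[1,0]]
#' @export
transition_matrix <- function(labels, k = max(labels)) {
  if (length(labels) < 2)
    stopf("need at least 2 labels to count transitions")
  cnt <- transition_counts(labels, rep(1L, length(labels)), k)
  tot <- rowSums(cnt)
  p <- cnt / ifelse(tot > 0, tot, 1)
  p[tot == 0, ] <- 0
  attr(p, "counts") <- cnt
  p
}

#' Markov entropy of a transition matrix
#'
#' \deqn{H = -\sum_i \sum_j P_{ij} \log(P_{ij})} summed over the visited
#' (row-stochastic) rows, with `0 log 0 := 0`. Natural logarithm by
#' default; for fixed k the maximum `k log k` is attained by uniform rows.
#'
#' @param p transition matrix; every row must sum to 1 (or, with
#'   `allow_empty_rows = TRUE`, to 0 for unvisited states, which then
#'   contribute nothing).
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @param allow_empty_rows tolerate all-zero rows.
#' @return Non-negative scalar entropy.
#' @examples
#' markov_entropy(matrix(0.2, 5, 5))   # 5 * log(5) ~ 8.047
#' @export
markov_entropy <- function(p, base = exp(1), allow_empty_rows = FALSE) {
  check_stochastic(p, tol = 1e-8, allow_empty_rows = allow_empty_rows)
  v <- p[p > 0]
  -sum(v * log(v)) / log(base)
}

#' Leave-one-group-out stability of the state clustering
#'
#' Refits the k-means state model with each (sex, treatment) group held out
#' in turn and reports, per holdout, the optimal matching of refit
#' centroids to the full-data centroids (the assignment minimizing total
#' Euclidean distance over all permutations) and the per-state cosine
#' similarity under that matching. Equivalent clustering across holdouts
#' shows the states are not driven by any single group.
#'
#' @param x matrix or [concat_cohort()] result.
#' @param group factor/character vector with one entry per row of `x`.
#' @param k number of states.
#' @param seed integer seed.
#' @param n_init k-means restarts per fit.
#' @return Object of class `logo_report`: data.frame `similarity`
#'   (holdout, state, cosine), the full-data `model`, and `min_cosine`.
#' @export
leave_one_group_out <- function(x, group, k, seed = NULL, n_init = 10) {
  if (inherits(x, "swc_global")) x <- x$x
  group <- as.character(group)
  if (length(group) != nrow(x)) stopf("one group entry per row required")
  lv <- unique(group)
  if (length(lv) < 2) stopf("need at least 2 groups")
  if (k > 8) stopf("centroid matching is exhaustive; k <= 8 required")
  full <- cluster_states(x, k, seed = seed, n_init = n_init)
  rows <- list()
  for (g in lv) {
    keep <- group != g
    if (!any(keep)) stopf("holdout '%s' removes all rows", g)
    fit <- cluster_states(x[keep, , drop = FALSE], k, seed = seed,
                          n_init = n_init)
    perm <- best_centroid_match(full$centroids, fit$centroids)
    cosine <- vapply(seq_len(k), function(j) {
      a <- full$centroids[j, ]; b <- fit$centroids[perm[j], ]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1))
    rows[[g]] <- data.frame(holdout = g, state = seq_len(k),
                            matched_state = perm, cosine = cosine,
                            stringsAsFactors = FALSE)
  }
  sim <- do.call(rbind, rows)
  rownames(sim) <- NULL
  structure(list(similarity = sim, model = full,
                 min_cosine = min(sim$cosine)),
            class = "logo_report")
}

#' @export
print.logo_report <- function(x, ...) {
  cat(sprintf("leave-one-group-out: %d holdouts, min matched-centroid cosine = %.3f\n",
              length(unique(x$similarity$holdout)), x$min_cosine))
  if (x$min_cosine < 0.9)
    cat("  note: similarity drop detected; at least one group shifts the states\n")
  invisible(x)
}

## Permutation of fit centroids minimizing total distance to ref centroids.
best_centroid_match <- function(ref, fit) {
  k <- nrow(ref)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    d[i, j] <- sum((ref[i, ] - fit[j, ])^2)
  best <- NULL; best_cost <- Inf
  for (p in all_perms(k)) {
    cost <- sum(d[cbind(seq_len(k), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}
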