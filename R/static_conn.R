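#' Fisher Z transform and its inverse
#'
#' `fisher_z()` maps correlations to the variance-stabilized z domain
#' (`atanh`); all averaging and testing in the pipeline happens on z values,
#' with r recovered by `inverse_fisher()` (`tanh`) for display only.
#' Correlations of exactly +/-1 are capped at `+/- atanh(cap)` with a
#' warning rather than mapped to infinity.
#'
#' @param r correlations in `[-1, 1]` (any shape).
#' @param z finite z values (any shape).
#' @param cap magnitude at which |r| = 1 is clipped (default 0.999999).
#' @return Transformed values of the same shape.
#' @examples
#' fisher_z(0.9)          # ~1.4722
#' inverse_fisher(fisher_z(0.37))
#' @export
fisher_z <- function(r, cap = 0.999999) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stopf("|r| > 1 is not a correlation")
  clipped <- abs(r) >= 1 - 1e-15
  if (any(clipped, na.rm = TRUE))
    warnf("%d correlation(s) at |r| = 1 capped at atanh(%g)",
          sum(clipped, na.rm = TRUE), cap)
  atanh(pmin(pmax(r, -cap), cap))
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) tanh(z)

#' ROI-pair functional connectivity matrix
#'
#' Pearson correlations between all ROI pairs over the valid frames of a
#' drug-anchored interval, stored together with their Fisher-z transform.
#' Invalid frames are removed pairwise (per ROI pair), matching the masking
#' contract of the preprocessing stage. A zero-variance ROI produces
#' flagged `NA` entries, never a silent zero.
#'
#' @param roits a [fusi_roits()] (bandpass-filtered signals).
#' @param center_min,width_min interval passed to [select_interval()];
#'   `NULL` uses the full series.
#' @param min_valid minimum number of valid frames required (default 30).
#' @param meta named list of session metadata (subject, sex, condition,
#'   time label ...) carried through to the tidy tables.
#' @return Object of class `fc_matrix` with elements `r`, `z` (matrices with
#'   unit / capped diagonal), `interval`, `n_valid`, `labels`, `meta`,
#'   `degenerate` (logical matrix flagging undefined pairs).
#' @export
fc_matrix <- function(roits, center_min = NULL, width_min = NULL,
                      min_valid = 30, meta = list()) {
  stopifnot(inherits(roits, "fusi_roits"))
  sub <- if (is.null(center_min)) roits else
    select_interval(roits, center_min, width_min)
  x <- t(sub$signals)
  x[!sub$valid, ] <- NA
  n_valid <- sum(sub$valid)
  if (n_valid < min_valid)
    stopf("only %d valid frames in interval; %d required", n_valid, min_valid)
  suppressWarnings(r <- cor(x, use = "pairwise.complete.obs"))
  degenerate <- !is.finite(r)
  diag(r) <- 1
  z <- suppressWarnings(fisher_z(r))
  structure(list(r = r, z = z,
                 interval = c(center_min = center_min %||% NA_real_,
                              width_min = width_min %||% NA_real_),
                 n_valid = n_valid, labels = sub$labels, meta = meta,
                 degenerate = degenerate),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix: %d ROIs over %d valid frames", length(x$labels),
              x$n_valid))
  if (!is.na(x$interval["center_min"]))
    cat(sprintf(" (interval %g +/- %g min)", x$interval["center_min"],
                x$interval["width_min"] / 2))
  cat(sprintf("\n  mean off-diagonal r = %.3f\n",
              mean(x$r[upper.tri(x$r)], na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fc_matrix <- function(x, main = "functional connectivity (r)", ...) {
  p <- length(x$labels)
  image(seq_len(p), seq_len(p), t(x$r[p:1, ]), zlim = c(-1, 1),
        col = hcl.colors(64, "RdBu", rev = TRUE), axes = FALSE,
        xlab = "", ylab = "", main = main, ...)
  axis(1, seq_len(p), x$labels, las = 2, cex.axis = 0.6)
  axis(2, seq_len(p), rev(x$labels), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Long-format connectivity table for a cohort
#'
#' Flattens a list of [fc_matrix()] objects into a tidy table with one row
#' per (session, unordered ROI pair): the 22-ROI grid yields 231 pairs per
#' matrix. Pair labels use the canonical ROI order so `"PrL_L - PrL_R"` is
#' unambiguous. This is the input format of [mixed_anova()].
#'
#' @param fcs list of `fc_matrix` objects whose `meta` carries at least
#'   `subject`; `sex`, `condition` and `time` are included when present.
#' @return data.frame with columns subject, sex, condition, time, pair, r, z.
#' @export
fc_long <- function(fcs) {
  stopifnot(length(fcs) > 0, all(vapply(fcs, inherits, TRUE, "fc_matrix")))
  labels <- fcs[[1]]$labels
  pl <- pair_labels(labels)
  ut <- upper.tri(fcs[[1]]$r)
  rows <- lapply(fcs, function(f) {
    if (!identical(f$labels, labels)) stopf("fc matrices have mixed ROI sets")
    m <- f$meta
    data.frame(subject = m$subject %||% NA_character_,
               sex = m$sex %||% NA_character_,
               condition = m$condition %||% NA_character_,
               time = m$time %||% NA_character_,
               pair = pl, r = t(f$r)[t(ut)], z = t(f$z)[t(ut)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired connectivity contrasts across cohort cells
#'
#' Builds per-pair paired differences of Fisher-z connectivity between two
#' levels of one metadata field (e.g. time "10min" minus "baseline"),
#' preserving the subject-level pairing within every other cell. Sessions
#' must be matched: an unmatched subject set across the contrasted cells is
#' an error listing the asymmetry.
#'
#' @param fcs list of [fc_matrix()] objects (see [fc_long()]).
#' @param field metadata field to contrast on ("time" or "condition").
#' @param level_b,level_a levels contrasted as `level_b - level_a`.
#' @return data.frame with columns subject, sex, condition/time, pair, dz.
#' @export
contrast_pairs <- function(fcs, field = "time", level_b, level_a) {
  tab <- fc_long(fcs)
  if (!field %in% names(tab)) stopf("unknown metadata field '%s'", field)
  other <- setdiff(c("condition", "time"), field)
  a <- tab[tab[[field]] == level_a, ]
  b <- tab[tab[[field]] == level_b, ]
  key <- function(d) paste(d$subject, d[[other]], d$pair, sep = "\r")
  ka <- key(a); kb <- key(b)
  if (!setequal(unique(a$subject), unique(b$subject)) ||
      length(ka) != length(kb) || !setequal(ka, kb)) {
    only_a <- setdiff(unique(a$subject), unique(b$subject))
    only_b <- setdiff(unique(b$subject), unique(a$subject))
    stopf("unmatched sessions across contrast cells (only in %s: %s; only in %s: %s)",
          level_a, paste(only_a, collapse = ",") , level_b,
          paste(only_b, collapse = ","))
  }
  b <- b[match(ka, kb), ]
  out <- a[, c("subject", "sex", other, "pair")]
  out$dz <- b$z - a$z
  rownames(out) <- NULL
  out
}
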