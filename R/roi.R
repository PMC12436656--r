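#' Canonical ROI labels
#'
#' The pipeline segments 11 bilateral regions of interest on a single coronal
#' slice: infralimbic (IL), prelimbic (PrL) and cingulate area 1 (Cg1)
#' cortices, secondary and primary motor cortices (M2, M1), primary
#' somatosensory cortex (S1), granular/dysgranular (GIDI) and anterior (AI)
#' insular cortices, caudate putamen (CPu), and nucleus accumbens core (NAcC)
#' and shell (NAcSh). Each region appears twice, left hemisphere before right,
#' giving 22 signals in a fixed canonical order used by every connectivity
#' matrix in the package.
#'
#' @param regions character vector of region names; the default is the
#'   canonical 11-region set.
#' @return Character vector of `2 * length(regions)` labels, `"<region>_L"`
#'   then `"<region>_R"` for each region in turn.
#' @examples
#' fusi_roi_labels()
#' @export
fusi_roi_labels <- function(regions = fusi_regions()) {
  as.vector(rbind(paste0(regions, "_L"), paste0(regions, "_R")))
}

#' @rdname fusi_roi_labels
#' @export
fusi_regions <- function() {
  c("IL", "PrL", "Cg1", "M2", "M1", "S1", "GIDI", "AI", "CPu", "NAcC", "NAcSh")
}

#' Default rectangular ROI layout for synthetic sessions
#'
#' Tiles the pixel grid into 22 disjoint rectangles: the left half of the
#' image holds the `_L` ROIs and the right half the `_R` ROIs, with the 11
#' regions stacked as horizontal bands. Rows left over when `n_rows` is not a
#' multiple of 11 remain unassigned (background). This is deliberately plain
#' geometry: the pipeline only needs a disjoint pixel->ROI map on a shared
#' grid, as real sessions are assumed atlas-registered upstream.
#'
#' @param n_rows,n_cols grid size in pixels.
#' @return Named list mapping each ROI label to a vector of linear pixel
#'   indices into an `n_rows x n_cols` matrix.
#' @examples
#' layout <- default_roi_layout(64, 64)
#' lengths(layout)[1:4]
#' @export
default_roi_layout <- function(n_rows = 64, n_cols = 64) {
  regions <- fusi_regions()
  band <- n_rows %/% length(regions)
  if (band < 1) stopf("grid too small: need at least %d rows", length(regions))
  half <- n_cols %/% 2
  if (half < 1) stopf("grid too small: need at least 2 columns")
  layout <- list()
  for (i in seq_along(regions)) {
    rows <- ((i - 1) * band + 1):(i * band)
    for (side in c("L", "R")) {
      cols <- if (side == "L") 1:half else (half + 1):n_cols
      idx <- as.vector(outer(rows, (cols - 1) * n_rows, `+`))
      layout[[paste0(regions[i], "_", side)]] <- idx
    }
  }
  layout
}

## Validate a layout: disjoint pixel sets, all labels non-empty.
check_roi_layout <- function(layout, n_rows, n_cols) {
  if (is.null(names(layout)) || any(!nzchar(names(layout))))
    stopf("roi_layout must be a named list")
  empty <- names(layout)[lengths(layout) == 0]
  if (length(empty)) stopf("empty ROI(s): %s", paste(empty, collapse = ", "))
  all_idx <- unlist(layout, use.names = FALSE)
  if (any(all_idx < 1 | all_idx > n_rows * n_cols))
    stopf("roi_layout contains pixel indices outside the %d x %d grid",
          n_rows, n_cols)
  if (anyDuplicated(all_idx))
    stopf("roi_layout pixel sets must be disjoint")
  invisible(TRUE)
}

## Logical matrix marking every pixel assigned to any ROI.
roi_mask <- function(layout, n_rows, n_cols) {
  m <- matrix(FALSE, n_rows, n_cols)
  m[unlist(layout, use.names = FALSE)] <- TRUE
  m
}
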