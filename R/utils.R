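## Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Project a symmetric matrix onto the nearest (in the eigenvalue-clipping
## sense) positive-semidefinite matrix; optionally renormalize to unit
## diagonal so the result stays a correlation matrix.
nearest_psd <- function(m, correlation = TRUE, eps = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < eps) {
    v <- pmax(e$values, eps)
    m <- e$vectors %*% (v * t(e$vectors))
  }
  if (correlation) {
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
  }
  (m + t(m)) / 2
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

## Row-stochastic check used by the Markov-chain operations.
check_stochastic <- function(p, tol = 1e-8, allow_empty_rows = FALSE) {
  if (!is_square(p)) stopf("transition matrix must be square")
  if (any(!is.finite(p)) || any(p < -tol))
    stopf("transition matrix must have finite non-negative entries")
  rs <- rowSums(p)
  bad <- abs(rs - 1) > tol
  if (allow_empty_rows) bad <- bad & rs > tol
  if (any(bad))
    stopf("transition matrix rows must sum to 1 (rows off: %s)",
          paste(which(bad), collapse = ", "))
  invisible(TRUE)
}

## Unordered-pair labels in canonical order: "A - B" with A preceding B.
pair_labels <- function(labels) {
  idx <- combn(seq_along(labels), 2)
  paste(labels[idx[1, ]], labels[idx[2, ]], sep = " - ")
}

## Column names for the full flattened p x p matrix (column-major, all 484
## entries for the 22-ROI grid, diagonal and both triangles included).
flat_labels <- function(labels) {
  as.vector(outer(labels, labels, function(a, b) paste(a, b, sep = "~")))
}

## All permutations of 1..n (small n only; used for centroid matching).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_perms(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

## Contiguous runs of a label vector: data.frame(value, length).
label_runs <- function(x) {
  r <- rle(as.vector(x))
  data.frame(value = r$values, length = r$lengths)
}
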