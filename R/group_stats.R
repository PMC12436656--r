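#' Mixed repeated-measures ANOVA with sphericity handling
#'
#' Univariate mixed ANOVA for balanced complete designs with any number of
#' within-subject factors and optional between-subject factors (e.g. the
#' three-way treatment x time x sex design stratified by ROI pair). Sums of
#' squares and F tests come from the classical error-strata decomposition
#' (`aov` with `Error(subject/within)`); for balanced data this coincides
#' with Type III. For every effect with a within-subject part of more than
#' one degree of freedom, Mauchly's sphericity test and the
#' Greenhouse-Geisser epsilon are computed from orthonormal contrasts of the
#' pooled subject-by-cell covariance; the GG-corrected p value
#' (`pf(F, eps*df1, eps*df2)`) is always reported alongside the raw one,
#' and `p_report` selects the GG value when Mauchly rejects at
#' `alpha_sphericity` (or always, with `gg = "always"`).
#'
#' @param data long-format data.frame.
#' @param dv name of the numeric response column.
#' @param within character vector of within-subject factor columns.
#' @param between character vector of between-subject factor columns (may
#'   be empty).
#' @param subject name of the subject id column.
#' @param gg `"auto"` (GG when sphericity is rejected; default),
#'   `"always"`, or `"never"`.
#' @param alpha_sphericity Mauchly rejection level used by `"auto"`.
#' @return Object of class `mixed_anova` whose `table` has one row per
#'   effect: df1, df2, ss, error_ss, F, p, epsilon_gg, df1_gg, df2_gg,
#'   p_gg, mauchly_W, mauchly_p, p_report, plus a `zero_variance` flag.
#' @export
mixed_anova <- function(data, dv, within, between = character(0), subject,
                        gg = c("auto", "always", "never"),
                        alpha_sphericity = 0.05) {
  gg <- match.arg(gg)
  need <- c(dv, within, between, subject)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stopf("columns not in data: %s", paste(missing_cols, collapse = ", "))
  if (!length(within)) stopf("at least one within-subject factor is required")
  df <- data[, need, drop = FALSE]
  df[[subject]] <- factor(df[[subject]])
  for (f in c(within, between)) df[[f]] <- factor(df[[f]])

  ## balanced complete design: each subject exactly once per within cell
  cell <- interaction(df[c(subject, within)], drop = FALSE)
  counts <- table(interaction(df[c(subject, within)], drop = FALSE))
  tab <- table(df[[subject]], interaction(df[within], drop = FALSE))
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stopf("design not balanced/complete: e.g. subject %s in cell %s observed %d time(s)",
          rownames(tab)[bad[1, 1]], colnames(tab)[bad[1, 2]],
          tab[bad[1, 1], bad[1, 2]])
  }
  ## subjects nested in between groups
  if (length(between)) {
    g <- unique(df[, c(subject, between), drop = FALSE])
    if (anyDuplicated(g[[subject]]))
      stopf("subject(s) appear in more than one between-subjects group")
    per_group <- table(interaction(g[between], drop = TRUE))
    if (any(per_group < 2))
      stopf("each between-subjects group needs >= 2 subjects")
  }

  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject,
                if (length(within)) paste0("/(", paste(within, collapse = " * "), ")") else "",
                ")")
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(form, data = df)
  res <- tidy_aov_strata(fit)

  ## sphericity layer
  sph <- sphericity_info(df, dv, within, between, subject)
  res$epsilon_gg <- NA_real_
  res$p_gg <- NA_real_
  res$mauchly_W <- NA_real_
  res$mauchly_p <- NA_real_
  for (i in seq_len(nrow(res))) {
    wpart <- within_part(res$effect[i], within)
    if (is.null(wpart)) next
    key <- paste(sort(wpart), collapse = ":")
    s <- sph[[key]]
    if (is.null(s)) next
    res$epsilon_gg[i] <- s$epsilon
    res$mauchly_W[i] <- s$W
    res$mauchly_p[i] <- s$p
    if (is.finite(res$F[i]) && s$epsilon < 1 - 1e-12) {
      res$p_gg[i] <- pf(res$F[i], s$epsilon * res$df1[i],
                        s$epsilon * res$df2[i], lower.tail = FALSE)
    } else if (is.finite(res$F[i])) {
      res$p_gg[i] <- res$p[i]
    }
  }
  use_gg <- switch(gg,
                   never = rep(FALSE, nrow(res)),
                   always = !is.na(res$p_gg),
                   auto = !is.na(res$p_gg) & !is.na(res$mauchly_p) &
                     res$mauchly_p < alpha_sphericity)
  res$p_report <- ifelse(use_gg, res$p_gg, res$p)
  zero_var <- all(!is.finite(res$F) | res$error_ss < 1e-300)
  structure(list(table = res,
                 design = list(dv = dv, within = within, between = between,
                               subject = subject,
                               n_subjects = nlevels(df[[subject]])),
                 gg = gg, zero_variance = zero_var),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, digits = 4, ...) {
  d <- x$design
  cat(sprintf("Mixed ANOVA: %s ~ %s (within: %s%s), %d subjects\n",
              d$dv, paste(c(d$between, d$within), collapse = " * "),
              paste(d$within, collapse = ", "),
              if (length(d$between))
                paste0("; between: ", paste(d$between, collapse = ", "))
              else "", d$n_subjects))
  if (x$zero_variance) cat("  !! zero-variance data: F undefined\n")
  tab <- x$table
  tab$ss <- signif(tab$ss, digits)
  tab$F <- signif(tab$F, digits)
  for (col in c("p", "p_gg", "mauchly_p", "p_report"))
    tab[[col]] <- signif(tab[[col]], digits)
  tab$epsilon_gg <- round(tab$epsilon_gg, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

## Flatten summary(aov-with-Error) into one effect table with error terms.
tidy_aov_strata <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    t <- sm[[stratum]][[1]]
    nm <- trimws(rownames(t))
    resid <- nm == "Residuals"
    err_df <- if (any(resid)) t[resid, "Df"] else NA_real_
    err_ss <- if (any(resid)) t[resid, "Sum Sq"] else NA_real_
    for (i in which(!resid)) {
      f_val <- if ("F value" %in% colnames(t)) t[i, "F value"] else NA_real_
      p_val <- if ("Pr(>F)" %in% colnames(t)) t[i, "Pr(>F)"] else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        effect = nm[i], df1 = t[i, "Df"], df2 = err_df,
        ss = t[i, "Sum Sq"], error_ss = err_ss,
        F = f_val %||% NA_real_, p = p_val %||% NA_real_,
        stratum = sub("^Error: ", "", stratum),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Within-factor components of an effect label like "sex:treatment:time";
## NULL when the effect has no within part.
within_part <- function(effect, within) {
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  w <- intersect(parts, within)
  if (length(w)) w else NULL
}

## Greenhouse-Geisser epsilon and Mauchly's test per within-effect
## combination, from orthonormal contrasts of the pooled covariance of the
## subject x within-cell response matrix.
sphericity_info <- function(df, dv, within, between, subject) {
  cells <- do.call(interaction, c(df[within], list(drop = FALSE, lex.order = FALSE)))
  wide <- tapply(df[[dv]], list(df[[subject]], cells), mean)
  lev <- lapply(df[within], levels)
  nlev <- vapply(lev, length, integer(1))
  ## interaction() varies the FIRST factor fastest, matching kronecker of
  ## reversed factor order
  grp <- if (length(between)) {
    g <- unique(df[, c(subject, between), drop = FALSE])
    g <- g[match(rownames(wide), as.character(g[[subject]])), , drop = FALSE]
    do.call(interaction, c(g[between], list(drop = TRUE)))
  } else factor(rep(1, nrow(wide)))
  n <- nrow(wide); ng <- nlevels(grp)
  S <- matrix(0, ncol(wide), ncol(wide))
  for (g in levels(grp)) {
    y <- wide[grp == g, , drop = FALSE]
    S <- S + crossprod(scale(y, center = TRUE, scale = FALSE))
  }
  S <- S / max(n - ng, 1)

  combos <- unlist(lapply(seq_along(within), function(m)
    combn(within, m, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (cmb in combos) {
    mats <- lapply(seq_along(within), function(i) {
      l <- nlev[i]
      if (within[i] %in% cmb) {
        cm <- stats::contr.helmert(l)
        cm %*% diag(1 / sqrt(colSums(cm^2)), ncol(cm))
      } else {
        matrix(1 / sqrt(l), l, 1)
      }
    })
    M <- Reduce(kronecker, rev(mats))
    d <- ncol(M)
    if (d < 2) {
      out[[paste(sort(cmb), collapse = ":")]] <-
        list(epsilon = 1, W = NA_real_, p = NA_real_)
      next
    }
    E <- t(M) %*% S %*% M
    tr <- sum(diag(E))
    eps <- if (tr > 0) tr^2 / (d * sum(E * E)) else NA_real_
    W <- NA_real_; p <- NA_real_
    dfs <- n - ng
    if (dfs > d && tr > 0) {
      dt <- det(E)
      if (dt > 0) {
        W <- dt / (tr / d)^d
        f <- dfs - (2 * d^2 + d + 2) / (6 * d)
        chi2 <- -f * log(W)
        p <- pchisq(chi2, d * (d + 1) / 2 - 1, lower.tail = FALSE)
      }
    }
    out[[paste(sort(cmb), collapse = ":")]] <-
      list(epsilon = eps, W = W, p = p)
  }
  out
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range corrected p values for all pairwise differences of
#' cell means given the error mean square of the ANOVA they came from
#' (Tukey-Kramer standard errors for unequal cell sizes).
#'
#' @param means named numeric vector of cell means.
#' @param mse error mean square.
#' @param df error degrees of freedom.
#' @param n per-cell sample size (scalar or vector matching `means`).
#' @param conf confidence level for the simultaneous intervals.
#' @return data.frame (pair, diff, se, q, p_adj, lwr, upr) of class
#'   `tukey_hsd`; a zero `mse` flags every comparison degenerate (`NA` p).
#' @export
tukey_hsd <- function(means, mse, df, n, conf = 0.95) {
  k <- length(means)
  if (k < 2) stopf("need at least 2 cells")
  if (length(n) == 1) n <- rep(n, k)
  if (is.null(names(means))) names(means) <- paste0("cell", seq_len(k))
  idx <- combn(k, 2)
  degenerate <- mse <= 0
  rows <- lapply(seq_len(ncol(idx)), function(c2) {
    i <- idx[1, c2]; j <- idx[2, c2]
    diffm <- means[i] - means[j]
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q <- if (degenerate) NA_real_ else abs(diffm) / se
    p <- if (degenerate) NA_real_ else
      ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    crit <- if (degenerate) NA_real_ else
      stats::qtukey(conf, nmeans = k, df = df)
    data.frame(pair = paste(names(means)[i], names(means)[j], sep = " - "),
               diff = unname(diffm), se = se, q = unname(q),
               p_adj = unname(p),
               lwr = unname(diffm - crit * se), upr = unname(diffm + crit * se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("tukey_hsd", "data.frame")
  out
}

#' Hedges g effect size
#'
#' Standardized mean difference with the small-sample bias correction
#' `J = 1 - 3 / (4 df - 1)`. For unpaired samples the denominator is the
#' pooled SD (`df = n1 + n2 - 2`); for paired samples the default
#' denominator is the SD pooled across the two conditions (`df = n - 1`),
#' the common convention for reported g magnitudes, with
#' `denom = "difference"` switching to the SD of the paired differences.
#'
#' @param x,y numeric samples (`y` matched to `x` when `paired = TRUE`).
#' @param paired logical.
#' @param denom denominator convention for paired data.
#' @param conf confidence level of the (normal-approximation) interval.
#' @return Object of class `effect_size`: `g`, `se`, `ci`, `J`, `df`,
#'   `paired`, `denom`, `degenerate`.
#' @examples
#' hedges_g(rnorm(10, 1), rnorm(10))
#' @export
hedges_g <- function(x, y, paired = FALSE, denom = c("pooled", "difference"),
                     conf = 0.95) {
  denom <- match.arg(denom)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("need at least 2 observations per sample")
  if (paired && n1 != n2) stopf("paired samples must have equal length")
  md <- mean(x) - mean(y)
  if (paired) {
    dfree <- n1 - 1
    s <- if (denom == "pooled") sqrt((var(x) + var(y)) / 2) else sd(x - y)
    r <- suppressWarnings(cor(x, y))
    if (!is.finite(r)) r <- 0
  } else {
    dfree <- n1 + n2 - 2
    s <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / dfree)
  }
  degenerate <- !is.finite(s) || s == 0
  J <- 1 - 3 / (4 * dfree - 1)
  g <- if (degenerate) { if (md == 0) 0 else sign(md) * Inf } else J * md / s
  se <- if (degenerate || !is.finite(g)) NA_real_ else if (paired) {
    sqrt(2 * (1 - r) / n1 + g^2 / (2 * dfree))
  } else {
    sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
  }
  zc <- qnorm(1 - (1 - conf) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else c(g - zc * se, g + zc * se)
  structure(list(g = g, se = se, ci = ci, J = J, df = dfree,
                 paired = paired, denom = denom, degenerate = degenerate),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges g = %.4f (%s%s), 95%% CI [%.3f, %.3f]%s\n",
              x$g, if (x$paired) "paired, " else "unpaired, ",
              paste0(x$denom, " SD"), x$ci[1], x$ci[2],
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Paired, one-sample and two-sample t tests
#'
#' Thin two-tailed wrapper around the standard t statistics with an
#' explicit degenerate-variance contract: when the relevant SD is zero the
#' result is flagged, with `t = 0, p = 1` for a zero mean difference and
#' `t = +/-Inf, p = 0` otherwise.
#'
#' @param x numeric sample.
#' @param y optional second sample (paired or independent).
#' @param mu null value for the one-sample test (default 0).
#' @param paired logical; `TRUE` tests the paired differences.
#' @return List of class `t_result`: `t`, `df`, `p` (two-tailed),
#'   `estimate`, `method`, `degenerate`.
#' @examples
#' t_tests(c(1, 2, 3), mu = 2)   # t = 0
#' @export
t_tests <- function(x, y = NULL, mu = 0, paired = FALSE) {
  if (is.null(y)) {
    d <- x - mu
    method <- "one-sample"
  } else if (paired) {
    if (length(x) != length(y)) stopf("paired samples must match in length")
    d <- x - y
    method <- "paired"
  } else {
    method <- "two-sample (Welch)"
  }
  if (method == "two-sample (Welch)") {
    if (length(x) < 2 || length(y) < 2) stopf("need n >= 2 per sample")
    if (sd(x) == 0 && sd(y) == 0) {
      est <- mean(x) - mean(y)
      return(degenerate_t(est, length(x) + length(y) - 2, method))
    }
    tt <- stats::t.test(x, y)
    out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, estimate = mean(x) - mean(y),
                method = method, degenerate = FALSE)
  } else {
    n <- length(d)
    if (n < 2) stopf("need n >= 2")
    if (sd(d) == 0) return(degenerate_t(mean(d), n - 1, method))
    t <- mean(d) / (sd(d) / sqrt(n))
    out <- list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1),
                estimate = mean(d), method = method, degenerate = FALSE)
  }
  class(out) <- "t_result"
  out
}

degenerate_t <- function(est, df, method) {
  out <- list(t = if (est == 0) 0 else sign(est) * Inf, df = df,
              p = if (est == 0) 1 else 0, estimate = est,
              method = method, degenerate = TRUE)
  class(out) <- "t_result"
  out
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("%s t test: t(%g) = %.4f, two-tailed p = %.4g%s\n",
              x$method, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
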