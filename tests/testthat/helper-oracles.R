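## Independent oracles used to freeze expected values. These deliberately
## avoid the package's own code paths: everything is spelled out with
## elementary loops and definitional arithmetic.

## Kendall's W by direct rank-table arithmetic.
kcc_oracle <- function(signals) {
  k <- nrow(signals)
  n <- ncol(signals)
  ranks <- matrix(0, n, k)
  for (j in seq_len(k)) ranks[, j] <- rank(signals[j, ])
  rbar <- mean(ranks)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + (sum(ranks[i, ]) - k * rbar)^2
  }
  12 * s / (k^2 * (n^3 - n))
}

## Studentized-range upper tail by direct numerical integration:
## P(Q > q) with k means and df error degrees of freedom.
ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * s))^(k - 1)
    k * integrate(f, -8, 8, rel.tol = 1e-9)$value
  }
  ## density of S = sqrt(chi2_df / df)
  gs <- function(s) {
    2 * s * df * stats::dchisq(df * s^2, df)
  }
  cdf <- integrate(function(s) vapply(s, function(si) inner(si) * gs(si),
                                      numeric(1)),
                   1e-6, 10, rel.tol = 1e-8)$value
  1 - cdf
}

## Classical cell-means sums-of-squares decomposition for a balanced
## split-plot design: one between factor G, two within factors A and B.
## Returns the full effect + error SS table. Additivity against the total
## SS is asserted wherever this oracle is used.
anova_ss_oracle <- function(d, dv, G, A, B, subject) {
  y <- d[[dv]]
  g <- factor(d[[G]]); a <- factor(d[[A]]); b <- factor(d[[B]])
  s <- factor(d[[subject]])
  na <- nlevels(a); nb <- nlevels(b)
  N <- nlevels(s)
  gs <- tapply(as.character(g), s, `[`, 1)[levels(s)]
  ng <- table(gs)
  M <- mean(y)
  m_s <- c(tapply(y, s, mean))
  m_g <- c(tapply(y, g, mean))
  m_a <- c(tapply(y, a, mean))
  m_b <- c(tapply(y, b, mean))
  m_ga <- tapply(y, list(g, a), mean)
  m_gb <- tapply(y, list(g, b), mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_gab <- tapply(y, list(g, a, b), mean)
  m_sa <- tapply(y, list(s, a), mean)
  m_sb <- tapply(y, list(s, b), mean)

  ss <- list()
  ss$G <- na * nb * sum(ng * (m_g - M)^2)
  ss$S_G <- na * nb * sum((m_s - m_g[gs])^2)
  ss$A <- nb * N * sum((m_a - M)^2)
  ss$GA <- nb * sum(rep(ng, na) * (t(t(m_ga) - m_a) - (m_g - M))^2)
  err_a <- 0
  for (si in levels(s)) for (ai in levels(a)) {
    err_a <- err_a + (m_sa[si, ai] - m_s[si] -
                        m_ga[as.character(gs[si]), ai] +
                        m_g[as.character(gs[si])])^2
  }
  ss$err_A <- nb * err_a
  ss$B <- na * N * sum((m_b - M)^2)
  ss$GB <- na * sum(rep(ng, nb) * (t(t(m_gb) - m_b) - (m_g - M))^2)
  err_b <- 0
  for (si in levels(s)) for (bi in levels(b)) {
    err_b <- err_b + (m_sb[si, bi] - m_s[si] -
                        m_gb[as.character(gs[si]), bi] +
                        m_g[as.character(gs[si])])^2
  }
  ss$err_B <- na * err_b
  ss$AB <- N * sum((m_ab - outer(m_a - M, m_b - M, `+`) - M)^2)
  gab_dev <- 0; gab_cell <- array(0, dim(m_gab), dimnames = dimnames(m_gab))
  for (gi in levels(g)) for (ai in levels(a)) for (bi in levels(b)) {
    dev <- m_gab[gi, ai, bi] - m_ga[gi, ai] - m_gb[gi, bi] + m_g[gi] -
      (m_ab[ai, bi] - m_a[ai] - m_b[bi] + M)
    gab_cell[gi, ai, bi] <- dev
    gab_dev <- gab_dev + ng[gi] * dev^2
  }
  ss$GAB <- gab_dev
  err_ab <- 0
  for (r in seq_len(nrow(d))) {
    si <- as.character(s[r]); ai <- as.character(a[r]); bi <- as.character(b[r])
    gi <- as.character(gs[si])
    fit_within <- m_sa[si, ai] + m_sb[si, bi] - m_s[si] +
      (m_gab[gi, ai, bi] - m_ga[gi, ai] - m_gb[gi, bi] + m_g[gi])
    err_ab <- err_ab + (y[r] - fit_within)^2
  }
  ss$err_AB <- err_ab
  ss$total <- sum((y - M)^2)
  lapply(ss, unname)
}

## Zero-phase frequency-response magnitude of the Butterworth bandpass at
## frequency f (squared analogue magnitude since the filter runs twice).
butter_gain_oracle <- function(f, low, high, fs, order = 4) {
  bt <- signal::butter(order, c(low, high) * 2 / fs, type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(bt$b * z^(seq_along(bt$b) - 1)) /
    sum(bt$a * z^(seq_along(bt$a) - 1))
  Mod(h)^2
}
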