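test_that("mixed ANOVA equals the brute-force cell-means decomposition", {
  d <- toy_design(n_per_group = 2, seed = 81)   # 4 subjects, 2x2 within
  fit <- mixed_anova(d, "z", within = c("treatment", "time"),
                     between = "sex", subject = "subject")
  o <- anova_ss_oracle(d, "z", "sex", "treatment", "time", "subject")
  # oracle self-check: the decomposition must be additive
  parts <- sum(o$G, o$S_G, o$A, o$GA, o$err_A, o$B, o$GB, o$err_B,
               o$AB, o$GAB, o$err_AB)
  expect_equal(parts, o$total, tolerance = 1e-10)
  tab <- fit$table
  g <- function(effect) tab$ss[tab$effect == effect]
  expect_equal(g("sex"), o$G, tolerance = 1e-8)
  expect_equal(g("treatment"), o$A, tolerance = 1e-8)
  expect_equal(g("sex:treatment"), o$GA, tolerance = 1e-8)
  expect_equal(g("time"), o$B, tolerance = 1e-8)
  expect_equal(g("sex:time"), o$GB, tolerance = 1e-8)
  expect_equal(g("treatment:time"), o$AB, tolerance = 1e-8)
  expect_equal(g("sex:treatment:time"), o$GAB, tolerance = 1e-8)
  expect_equal(tab$error_ss[tab$effect == "treatment"], o$err_A,
               tolerance = 1e-8)
  expect_equal(tab$error_ss[tab$effect == "treatment:time"], o$err_AB,
               tolerance = 1e-8)
  expect_equal(tab$error_ss[tab$effect == "sex"], o$S_G, tolerance = 1e-8)
  # F ratios follow from the SS and dfs
  expect_equal(tab$F[tab$effect == "sex"],
               (o$G / 1) / (o$S_G / 2), tolerance = 1e-8)
})

test_that("mixed ANOVA reproduces car's univariate repeated-measures table", {
  skip_if_not_installed("car")
  d <- toy_design(n_per_group = 4, a = 2, b = 3, seed = 82)
  fit <- mixed_anova(d, "z", within = c("treatment", "time"),
                     between = "sex", subject = "subject")
  d$cell <- paste(d$treatment, d$time, sep = ".")
  w <- stats::reshape(d[, c("subject", "sex", "cell", "z")],
                      idvar = c("subject", "sex"), timevar = "cell",
                      direction = "wide")
  lev <- expand.grid(treatment = factor(paste0("tr", 1:2)),
                     time = factor(paste0("t", 1:3)))
  Y <- as.matrix(w[, paste0("z.", lev$treatment, ".", lev$time)])
  mod <- lm(Y ~ sex, data = transform(w, sex = factor(sex)),
            contrasts = list(sex = "contr.sum"))
  s <- summary(car::Anova(mod, idata = lev, idesign = ~ treatment * time,
                          type = 3),
               multivariate = FALSE)
  ut <- s$univariate.tests
  for (eff in c("sex", "treatment", "sex:treatment", "time", "sex:time",
                "treatment:time", "sex:treatment:time")) {
    i <- match(eff, trimws(rownames(ut)))
    j <- match(eff, fit$table$effect)
    expect_equal(fit$table$ss[j], unname(ut[i, "Sum Sq"]), tolerance = 1e-8)
    expect_equal(fit$table$F[j], unname(ut[i, "F value"]), tolerance = 1e-8)
    expect_equal(fit$table$p[j], unname(ut[i, "Pr(>F)"]), tolerance = 1e-8)
  }
  pa <- s$pval.adjustments
  for (eff in rownames(pa)) {
    j <- match(eff, fit$table$effect)
    expect_equal(fit$table$epsilon_gg[j], unname(pa[eff, "GG eps"]),
                 tolerance = 1e-6)
    expect_equal(fit$table$p_gg[j], unname(pa[eff, "Pr(>F[GG])"]),
                 tolerance = 1e-6)
  }
  st <- s$sphericity.tests
  for (eff in rownames(st)) {
    j <- match(eff, fit$table$effect)
    expect_equal(fit$table$mauchly_W[j], unname(st[eff, "Test statistic"]),
                 tolerance = 1e-6)
    expect_equal(fit$table$mauchly_p[j], unname(st[eff, "p-value"]),
                 tolerance = 1e-6)
  }
})

test_that("sphericity handling follows the design contracts", {
  d <- toy_design(n_per_group = 4, a = 2, b = 3, seed = 83)
  fit <- mixed_anova(d, "z", within = c("treatment", "time"),
                     between = "sex", subject = "subject")
  tab <- fit$table
  # two-level within factor: epsilon 1, Mauchly skipped
  expect_equal(tab$epsilon_gg[tab$effect == "treatment"], 1)
  expect_true(is.na(tab$mauchly_W[tab$effect == "treatment"]))
  # GG epsilon bounds for the 3-level factor: 1/(levels-1) < eps <= 1
  eps <- tab$epsilon_gg[tab$effect == "time"]
  expect_gt(eps, 0.5)
  expect_lte(eps, 1)
  # GG correction never increases significance where F >= 1 (for F < 1 the
  # heavier-tailed reference with reduced dfs can pull p the other way)
  within_rows <- !is.na(tab$p_gg) & tab$F >= 1
  expect_true(all(tab$p_gg[within_rows] >= tab$p[within_rows] - 1e-12))
  # "always" forces GG into p_report
  fit2 <- mixed_anova(d, "z", within = c("treatment", "time"),
                      between = "sex", subject = "subject", gg = "always")
  t2 <- fit2$table
  expect_equal(t2$p_report[t2$effect == "time"],
               t2$p_gg[t2$effect == "time"])
})

test_that("mixed ANOVA validates design structure and degeneracy", {
  d <- toy_design()
  expect_error(mixed_anova(d[-1, ], "z", within = c("treatment", "time"),
                           between = "sex", subject = "subject"),
               "balanced")
  d2 <- d; d2$z <- 1
  fit <- mixed_anova(d2, "z", within = c("treatment", "time"),
                     between = "sex", subject = "subject")
  expect_true(fit$zero_variance)
  expect_error(mixed_anova(d, "missing_dv", within = "treatment",
                           between = "sex", subject = "subject"),
               "not in data")
})

test_that("type-I error of the mixed ANOVA is nominal under the null", {
  n_rep <- 300
  effects <- c("sex", "treatment", "time", "sex:treatment:time")
  hits <- matrix(0, n_rep, length(effects),
                 dimnames = list(NULL, effects))
  for (r in seq_len(n_rep)) {
    d <- toy_design(n_per_group = 4, seed = 9000 + r)
    fit <- mixed_anova(d, "z", within = c("treatment", "time"),
                       between = "sex", subject = "subject")
    hits[r, ] <- fit$table$p[match(effects, fit$table$effect)] < 0.05
  }
  rates <- colMeans(hits)
  # MC SE at n = 300 is 0.0126; allow ~3 SE around 0.05
  expect_true(all(rates > 0.01), info = paste(rates, collapse = ", "))
  expect_true(all(rates < 0.09), info = paste(rates, collapse = ", "))
})

test_that("Tukey HSD agrees with the studentized-range oracle", {
  means <- c(a = 1.0, b = 1.5, c = 2.4)
  out <- tukey_hsd(means, mse = 0.8, df = 12, n = 5)
  expect_equal(nrow(out), 3)
  for (i in seq_len(3)) {
    expect_equal(out$p_adj[i], ptukey_oracle(out$q[i], k = 3, df = 12),
                 tolerance = 1e-5)
  }
  # identical means -> p ~ 1; monotone in |difference|
  out2 <- tukey_hsd(c(x = 1, y = 1), mse = 1, df = 10, n = 4)
  expect_gt(out2$p_adj, 0.9999)
  ord <- order(abs(out$diff))
  expect_true(all(diff(out$p_adj[ord]) <= 0))
  # relabeling invariance
  out3 <- tukey_hsd(means[c(2, 1, 3)], mse = 0.8, df = 12, n = 5)
  expect_equal(sort(out3$p_adj), sort(out$p_adj))
  expect_true(attr(tukey_hsd(means, 0, 12, 5), "degenerate"))
})

test_that("Hedges g follows its closed form and sign conventions", {
  # unpaired, mean diff 1, pooled SD 1, n = 10 each: g = 1 - 3/71
  x <- rnorm(10); x <- (x - mean(x)) / sd(x) + 1
  y <- rnorm(10); y <- (y - mean(y)) / sd(y)
  g <- hedges_g(x, y)
  expect_equal(g$g, 1 - 3 / 71, tolerance = 1e-12)
  expect_equal(g$J, 1 - 3 / (4 * 18 - 1))
  # antisymmetry and zero cases
  expect_equal(hedges_g(y, x)$g, -g$g)
  expect_equal(hedges_g(x, x)$g, 0)
  # paired convention: pooled across-condition SD vs difference SD
  set.seed(84)
  a <- rnorm(12); b <- a + rnorm(12, 0.5, 0.3)
  gp <- hedges_g(a, b, paired = TRUE)
  gd <- hedges_g(a, b, paired = TRUE, denom = "difference")
  expect_equal(gp$g, (1 - 3 / (4 * 11 - 1)) * (mean(a) - mean(b)) /
                 sqrt((var(a) + var(b)) / 2), tolerance = 1e-12)
  expect_equal(gd$g, (1 - 3 / (4 * 11 - 1)) * mean(a - b) / sd(a - b),
               tolerance = 1e-12)
  expect_true(hedges_g(rep(1, 5), rep(1, 5))$degenerate)
})

test_that("t tests satisfy their trivial and degenerate contracts", {
  x <- c(1, 2, 3)
  one <- t_tests(x, mu = 2)
  expect_equal(one$t, 0)
  expect_equal(one$p, 1)
  paired <- t_tests(x, x, paired = TRUE)
  expect_equal(paired$t, 0)
  expect_equal(paired$p, 1)
  expect_true(paired$degenerate)
  shifted <- t_tests(x + 1, x, paired = TRUE)
  expect_true(is.infinite(shifted$t))
  expect_equal(shifted$p, 0)
  # agreement with stats::t.test when variance is positive
  set.seed(85)
  a <- rnorm(15); b <- rnorm(15, 0.4)
  ours <- t_tests(a, b, paired = TRUE)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  # type-I calibration on null paired samples
  p <- replicate(400, {
    u <- rnorm(8); v <- rnorm(8)
    t_tests(u, v, paired = TRUE)$p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})
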