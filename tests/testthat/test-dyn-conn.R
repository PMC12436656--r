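test_that("window counts follow the inclusive-grid identity", {
  r <- noise_roits(nt = 3601, t0 = -20 * 60, seed = 61)
  s <- sliding_window_fc(r, 30, 1)
  expect_equal(nrow(s$windows), 3572)       # 3601 - 30 + 1
  expect_equal(ncol(s$windows), 484)        # 22 x 22 vectorized
  r2 <- noise_roits(nt = 30, seed = 62)
  expect_equal(nrow(sliding_window_fc(r2, 30, 1)$windows), 1)
  expect_error(sliding_window_fc(noise_roits(nt = 20), 30, 1), "shorter")
  # each row reshapes to a symmetric unit-diagonal matrix
  m <- matrix(s$windows[100, ], 22, 22)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 22))
})

test_that("windowed correlations fluctuate around the planted value", {
  cov <- diag(22)
  cov[1, 2] <- cov[2, 1] <- 0.9
  dimnames(cov) <- list(fusi_roi_labels(), fusi_roi_labels())
  cfg <- session_config(n_rows = 33, n_cols = 12, motion_frame_rate = 0,
                        injection_amp = 0)
  s <- generate_session(cfg, single_state_truth(cov), pixels = FALSE,
                        seed = 63)
  sw <- sliding_window_fc(s$roi, 30, 1)
  vals <- sw$windows[, "IL_L~IL_R"]
  expect_lt(abs(mean(vals) - 0.9), 0.05)
  expect_gt(sd(vals), 0.01)   # n = 30 windows genuinely fluctuate
})

test_that("cohort concatenation preserves exact back-mapping", {
  mk <- function(subject, nt, seed) {
    sliding_window_fc(noise_roits(nt = nt, seed = seed), 30, 1,
                      meta = list(subject = subject, sex = "male",
                                  condition = "VEH+KET"))
  }
  a <- mk("S1", 120, 64); b <- mk("S2", 90, 65)
  g <- concat_cohort(list(a, b))
  expect_equal(nrow(g$x), (120 - 29) + (90 - 29))
  expect_equal(g$x[nrow(a$windows) + 3, ], b$windows[3, ])
  row <- g$index[nrow(a$windows) + 3, ]
  expect_equal(row$subject, "S2")
  expect_equal(row$center_s, b$centers_s[3])
  bad <- b; bad$windows <- bad$windows[, 1:100]
  expect_error(concat_cohort(list(a, bad)), "mismatch")
})

test_that("the SVD elbow finds the planted spectrum break", {
  # construct a matrix with singular values 100, 99, 98 then a long tail of
  # ones: second differences on the reduced spectrum dip at k = 3
  set.seed(66)
  n <- 500; p <- 400
  sv <- c(100, 99, 98, rep(1, p - 3))
  u <- qr.Q(qr(matrix(rnorm(n * p), n, p)))[, 1:p]
  v <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  x <- u %*% (sv * t(v))
  e <- svd_elbow(x, var_threshold = 0.99)
  expect_equal(e$k_opt, 3L)
  expect_gt(e$saliency, 1)   # sv drops 98 -> 1 below the elbow
  # the maximum-curvature convention lands one later on this spectrum
  expect_equal(svd_elbow(x, rule = "max")$k_opt, 4L)
  # rank-1 degenerate input
  expect_warning(e1 <- svd_elbow(tcrossprod(rnorm(50), rnorm(10))), "rank-1")
  expect_equal(e1$k_opt, 1L)
})

test_that("isotropic noise has no pronounced elbow", {
  set.seed(67)
  x <- matrix(rnorm(500 * 80), 500, 80)
  e <- svd_elbow(x)
  expect_lt(e$saliency, 0.1)
})

test_that("k-means state models separate, sort and predict", {
  set.seed(68)
  c1 <- rep(0.8, 484); c2 <- rep(0.1, 484)
  x <- rbind(matrix(rnorm(200 * 484, c1, 0.05), 200, 484, byrow = FALSE),
             matrix(rnorm(150 * 484, c2, 0.05), 150, 484, byrow = FALSE))
  truth <- rep(1:2, c(200, 150))
  bs <- cluster_states(x, 2, seed = 1, n_init = 5)
  expect_equal(ari(bs$labels, truth), 1)       # separable case: exact
  # sorting contract: state 1 must be the most connected centroid
  expect_true(all(diff(bs$mean_conn) <= 0))
  expect_equal(bs$labels[1], 1L)
  expect_equal(bs$labels[250], 2L)
  expect_equal(predict(bs, x[c(1, 250), , drop = FALSE]), c(1L, 2L))
  expect_error(cluster_states(x, 1), "k must be")
})

test_that("state metrics implement the occupancy definitions", {
  m <- state_metrics(c(1, 1, 2, 2, 2), times_s = 0:4,
                     period = analysis_period(-1, 10), k = 2)
  expect_equal(m$time_fraction, c(0.4, 0.6))
  m2 <- state_metrics(c(1, 1, 2, 1), times_s = 0:3,
                      period = analysis_period(-1, 10), k = 2)
  expect_equal(m2$dwell_s, c(1.5, 1))          # runs (2,1) and (1)
  m3 <- state_metrics(rep(3, 10), times_s = 0:9,
                      period = analysis_period(-1, 20), k = 3)
  expect_equal(m3$time_fraction[3], 1)
  expect_equal(m3$dwell_s[3], 10)
  expect_true(is.na(m3$dwell_s[1]))
  expect_equal(sum(m$time_fraction), 1)
  expect_error(state_metrics(1:3, times_s = 0:2,
                             period = analysis_period(100, 200)), "period")
})

test_that("runs and transitions never bridge the exclusion gap", {
  # labels 1,1,1 | gap | 2,2,2: without the gap there would be a 1->2
  # transition and the same runs
  labs <- c(1, 1, 1, 1, 2, 2, 2, 2)
  tm <- state_metrics(labs, times_s = 0:7 * 60,
                      period = analysis_period(-1, 8),
                      k = 2, step_s = 60)
  expect_gt(tm$transition[1, 2], 0)    # without a gap the 1->2 move counts
  gap <- state_metrics(labs, times_s = 0:7 * 60,
                       period = analysis_period(-1, 8, exclude = c(2.5, 4.5)),
                       k = 2, step_s = 60)
  expect_equal(gap$n_points, 6)
  expect_equal(gap$transition, matrix(c(1, 0, 0, 1), 2))  # only self moves
  expect_equal(gap$dwell_s, c(180, 180))
})

test_that("transition matrices count consecutive pairs", {
  expect_equal(transition_matrix(c(1, 2, 1, 2, 1)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  p3 <- transition_matrix(c(3, 3, 3), k = 3)
  expect_equal(p3[3, 3], 1)
  expect_equal(rowSums(p3), c(0, 0, 1))
  # long planted chain: empirical P within 0.02 elementwise
  pu <- matrix(c(0.7, 0.2, 0.1,
                 0.3, 0.5, 0.2,
                 0.1, 0.1, 0.8), 3, byrow = TRUE)
  s <- plant_state_sequence(pu, 50000, seed = 69)
  expect_lt(max(abs(transition_matrix(s, 3) - pu)), 0.02)
})

test_that("Markov entropy matches closed forms and its maximum", {
  # deterministic cycle: every term is 0 log 0 or 1 log 1
  p5 <- diag(5)[, c(2:5, 1)]
  expect_equal(markov_entropy(p5), 0)
  expect_equal(markov_entropy(matrix(0.2, 5, 5)), 5 * log(5))
  expect_equal(markov_entropy(matrix(0.5, 2, 2)), 2 * log(2))
  expect_equal(markov_entropy(matrix(0.5, 2, 2), base = 2), 2)
  expect_error(markov_entropy(matrix(c(0.5, 0.6, 0.4, 0.4), 2)), "sum to 1")
  # random row-stochastic matrices never exceed k log k
  set.seed(70)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- matrix(rexp(k * k), k)
    p <- p / rowSums(p)
    expect_lte(markov_entropy(p), k * log(k) + 1e-12)
  }
})

test_that("dwell-weighted run counts reproduce occupancy", {
  labs <- plant_state_sequence(default_ground_truth(3)$transition_matrix,
                               500, seed = 71)
  m <- state_metrics(labs, times_s = seq_len(500),
                     period = analysis_period(0, 501), k = 3)
  runs <- rle(labs)
  for (s in 1:3) {
    n_runs <- sum(runs$values == s)
    if (n_runs > 0) {
      expect_equal(m$dwell_s[s] * n_runs / 500, m$time_fraction[s],
                   tolerance = 1e-12)
    }
  }
})

test_that("phase features match constructed phase relations", {
  t <- 0:999
  s1 <- sin(2 * pi * 0.05 * t)
  s2 <- sin(2 * pi * 0.05 * t - pi / 2)   # quadrature
  r <- fusi_roits(rbind(a = s1, b = s1, c = s2),
                  time_s = seq(0, by = 1, length.out = 1000))
  ph <- phase_difference_features(r)
  mid <- 200:800
  expect_true(all(abs(ph[mid, "a~b"] - 1) < 1e-6))       # identical signals
  expect_lt(max(abs(ph[mid, "a~c"])), 0.05)              # 90 degrees -> ~0
  expect_equal(ncol(ph), 9)
  expect_warning(phase_difference_features(noise_roits(nt = 300, p = 3)),
                 "broadband")
})

test_that("phase features reproduce the window-based state partition", {
  # two alternating covariance regimes; cluster phase features vs SWC
  cfg <- session_config(n_rows = 33, n_cols = 12, t_start_min = -10,
                        t_end_min = 10, pretreat_time_min = -8,
                        motion_frame_rate = 0, injection_amp = 0)
  gt <- default_ground_truth(2)
  s <- generate_session(cfg, gt, pixels = FALSE, seed = 72)
  sw <- sliding_window_fc(s$roi, 30, 1)
  suppressWarnings(ph <- phase_difference_features(s$roi))
  bs_w <- cluster_states(sw$windows, 2, seed = 1, n_init = 5)
  bs_p <- cluster_states(ph, 2, seed = 1, n_init = 5)
  # compare on window centers (phase features are per-timepoint)
  centers_idx <- floor(sw$centers_s - s$roi$time_s[1]) + 1
  expect_gt(ari(bs_w$labels, bs_p$labels[centers_idx]), 0.6)
})

test_that("leave-one-group-out matches centroids across holdouts", {
  set.seed(73)
  centers <- matrix(rnorm(3 * 40, sd = 2), 3, 40)
  mk_group <- function(n) {
    lab <- sample(1:3, n, replace = TRUE)
    centers[lab, ] + matrix(rnorm(n * 40, sd = 0.2), n, 40)
  }
  x <- rbind(mk_group(150), mk_group(150), mk_group(150), mk_group(150))
  grp <- rep(c("m_veh", "m_ntx", "f_veh", "f_ntx"), each = 150)
  rep_ <- leave_one_group_out(x, grp, k = 3, seed = 2, n_init = 5)
  expect_true(all(rep_$similarity$cosine >= 0.9))
  expect_equal(nrow(rep_$similarity), 12)
  # adversarial: one group drawn from shifted centroids must drop similarity
  x2 <- x
  x2[grp == "f_ntx", ] <- matrix(rnorm(150 * 40, mean = 3, sd = 0.2), 150, 40)
  rep2 <- leave_one_group_out(x2, grp, k = 3, seed = 2, n_init = 5)
  expect_lt(rep2$min_cosine, rep_$min_cosine)
  expect_error(leave_one_group_out(x, rep("g", nrow(x)), 3), "2 groups")
})
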