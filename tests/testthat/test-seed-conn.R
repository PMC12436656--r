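test_that("seed maps are exact on constructed signals", {
  # every pixel equals the seed signal -> r = 1 everywhere
  nt <- 120
  base <- sin(2 * pi * 0.05 * (1:nt))
  img <- fusi_image(array(rep(base, each = 25), c(5, 5, nt)),
                    time_s = seq(0, by = 1, length.out = nt))
  sm <- seed_map(img, seed = matrix(c(TRUE, rep(FALSE, 24)), 5, 5))
  expect_true(all(abs(sm$r_map - 1) < 1e-12))
  expect_error(seed_map(img, seed = matrix(FALSE, 5, 5)), "empty")
})

test_that("independent background pixels decorrelate from the seed", {
  # band-limited seed vs white background pixels over a 901-frame interval:
  # null r has sd ~ 1/sqrt(n), so |r| < 0.1 for nearly all pixels
  cfg <- session_config(n_rows = 35, n_cols = 12, t_start_min = -10,
                        t_end_min = 18, motion_frame_rate = 0,
                        injection_amp = 0, noise_sd = 1, local_corr = 0)
  s <- generate_session(cfg, single_state_truth(diag(22)), pixels = TRUE,
                        seed = 41)
  # background rows (below the 11 ROI bands) are pure white noise
  sm <- seed_map(s$image, seed = c("PrL_L", "PrL_R", "IL_L", "IL_R"),
                 roi_layout = cfg$roi_layout, center_min = 10, width_min = 15)
  bg_rows <- (11 * 3 + 1):35   # beyond the ROI bands
  vals <- sm$r_map[bg_rows, ]
  expect_gt(mean(abs(vals) < 0.1), 0.95)
})

test_that("planted seed-to-M1 coupling is recovered from pixels", {
  labels <- fusi_roi_labels()
  cov <- diag(22)
  seed_idx <- match(c("PrL_L", "PrL_R", "IL_L", "IL_R"), labels)
  m1_idx <- match(c("M1_L", "M1_R"), labels)
  cov[seed_idx, seed_idx] <- 0.95
  cov[m1_idx, m1_idx] <- 0.95
  cov[seed_idx, m1_idx] <- 0.7
  cov[m1_idx, seed_idx] <- 0.7
  diag(cov) <- 1
  dimnames(cov) <- list(labels, labels)
  cfg <- session_config(n_rows = 33, n_cols = 12, t_start_min = -10,
                        t_end_min = 18, motion_frame_rate = 0,
                        injection_amp = 0, noise_sd = 0.15, local_corr = 0.5)
  s <- generate_session(cfg, single_state_truth(cov), pixels = TRUE,
                        seed = 42)
  sm <- seed_map(s$image, seed = c("PrL_L", "PrL_R", "IL_L", "IL_R"),
                 roi_layout = cfg$roi_layout, center_min = 10, width_min = 15)
  m1_px <- unlist(cfg$roi_layout[c("M1_L", "M1_R")])
  expect_lt(abs(mean(sm$r_map[m1_px]) - 0.7), 0.07)
})

test_that("median smoothing follows its definition", {
  # constant map unchanged
  cmap <- matrix(5, 9, 9)
  expect_equal(smooth_map(cmap, 0.3, 0.1), cmap)
  # single impulse on zero background removed
  imp <- matrix(0, 9, 9); imp[5, 5] <- 10
  expect_true(all(smooth_map(imp, 0.3, 0.1) == 0))
  # 3x3 window of 1..9 -> center pixel becomes 5
  w <- matrix(1:9, 3, 3)
  expect_equal(smooth_map(w, 0.3, 0.1)[2, 2], 5)
  # even kernel rejected with advice
  expect_error(smooth_map(cmap, 0.4, 0.1), "even")
  # NA pixels stay undefined
  nam <- matrix(rnorm(81), 9, 9); nam[3, 3] <- NA
  expect_true(is.na(smooth_map(nam, 0.3, 0.1)[3, 3]))
})

test_that("paired t maps satisfy the degenerate contracts", {
  mk <- function(vals, subject) {
    structure(list(r_map = vals, z_map = vals,
                   meta = list(subject = subject)),
              class = "seed_map")
  }
  set.seed(45)
  a <- lapply(1:4, function(i) mk(matrix(sample(-8:8, 16, TRUE) / 4, 4, 4),
                                  paste0("S", i)))
  tm0 <- paired_tmap(a, a)
  expect_true(all(tm0$t == 0))          # identical maps -> t = 0
  # constant difference with zero variance -> infinite t, flagged
  # quarter-unit grid makes the half-unit shift exact in floating point
  b <- lapply(seq_along(a), function(i) {
    m <- a[[i]]
    m$z_map <- m$z_map + 0.5
    m
  })
  tm1 <- paired_tmap(a, b)
  expect_true(all(is.infinite(tm1$t)))
  expect_true(all(tm1$degenerate))
  expect_true(all(tm1$t > 0))
  expect_error(paired_tmap(a[1:2], a[1:2]), "at least 3")
  bad <- b; bad[[1]]$meta$subject <- "other"
  expect_error(paired_tmap(a, bad), "mismatch")
})

test_that("pixel-wise paired t is calibrated on null maps", {
  set.seed(43)
  mk <- function(subject) {
    v <- matrix(rnorm(900), 30, 30)
    structure(list(r_map = v, z_map = v, meta = list(subject = subject)),
              class = "seed_map")
  }
  a <- lapply(1:10, function(i) mk(paste0("S", i)))
  b <- lapply(1:10, function(i) mk(paste0("S", i)))
  tm <- paired_tmap(a, b)
  rate <- mean(abs(tm$t) > qt(0.975, tm$df))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("cluster labeling respects connectivity and size filters", {
  m <- matrix(FALSE, 8, 8)
  m[1:2, 1:2] <- TRUE          # 4-blob
  m[5, 5] <- TRUE; m[6, 6] <- TRUE   # diagonal touch
  lab4 <- label_clusters(m, 4)
  lab8 <- label_clusters(m, 8)
  expect_equal(max(lab4), 3)   # diagonal pixels separate under 4-conn
  expect_equal(max(lab8), 2)   # merge under 8-conn
  expect_equal(sum(lab4 == lab4[1, 1]), 4)
})

test_that("cluster-extent correction keeps only large-enough blobs", {
  df <- 9
  tcrit <- qt(0.975, df)
  t <- matrix(0, 20, 30)
  # one 40-pixel blob and one 36-pixel blob, plus a 38-pixel blob
  t[2:5, 2:11] <- tcrit + 1          # 40 pixels
  t[10:13, 2:10] <- tcrit + 1        # 36 pixels
  t[16:17, 10:28] <- -(tcrit + 2)    # 38 pixels, negative
  tm <- structure(list(t = t, df = df, n = df + 1,
                       degenerate = matrix(FALSE, 20, 30)), class = "tmap")
  out <- apply_cluster_correction(tm, alpha_vox = 0.05, min_cluster = 37)
  expect_equal(nrow(out$cluster_table), 2)
  expect_equal(sort(out$cluster_table$size), c(38, 40))
  expect_equal(out$cluster_table$sign[out$cluster_table$size == 38], -1)
  # no supra-threshold pixels -> zero clusters
  tm0 <- tm; tm0$t <- matrix(0, 20, 30)
  expect_equal(nrow(apply_cluster_correction(tm0, 0.05, 1)$cluster_table), 0)
})

test_that("Monte-Carlo cluster thresholds behave as expected", {
  mask <- matrix(TRUE, 40, 40)
  thr_raw <- mc_cluster_threshold(mask, alpha_vox = 0.05, alpha_clust = 0.05,
                                  n_iter = 400, seed = 44)
  expect_lte(as.integer(thr_raw), 5)   # unsmoothed white noise: tiny clusters
  med3 <- function(m) smooth_map(m, 0.3, 0.1)
  thr_sm <- mc_cluster_threshold(mask, alpha_vox = 0.05, alpha_clust = 0.05,
                                 n_iter = 400, smoother = med3, seed = 44)
  expect_gt(as.integer(thr_sm), as.integer(thr_raw))  # smoothing inflates
  expect_equal(as.integer(mc_cluster_threshold(mask, 0.05, 1.0,
                                               n_iter = 50, seed = 1)), 1L)
  expect_error(mc_cluster_threshold(mask, 0.05, 1e-5, n_iter = 100),
               "increase n_iter")
  expect_error(mc_cluster_threshold(matrix(FALSE, 4, 4)), "empty")
})
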