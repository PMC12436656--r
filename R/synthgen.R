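#' Session configuration for the synthetic generator
#'
#' Describes the acquisition geometry and noise structure of one synthetic
#' fUSI session. Defaults emulate the study conditions of the pharmacological
#' protocol the pipeline targets: 1 frame/s power Doppler sampling on a
#' 100 um x 100 um grid, recording from -20 to +40 min around the ketamine
#' injection (inclusive grid, 3601 frames), with a pretreatment injection at
#' -10 min.
#'
#' @param n_rows,n_cols pixel grid size.
#' @param pixel_mm pixel size in mm (default 0.1).
#' @param fs frame rate in frames/s (default 1).
#' @param t_start_min,t_end_min recording span in minutes relative to the
#'   ketamine injection; the time grid includes both endpoints.
#' @param pretreat_time_min time of the pretreatment injection (minutes).
#' @param roi_layout named list mapping ROI label -> pixel indices; defaults
#'   to [default_roi_layout()] on the requested grid. Pixel sets must be
#'   disjoint.
#' @param noise_sd pixel-level noise standard deviation (a.u.).
#' @param local_corr within-ROI pixel noise coupling in `[0, 1]`: 0 gives
#'   independent pixel noise, 1 makes all pixels of an ROI share one noise
#'   process (maximal local synchrony for the regional-homogeneity analysis).
#' @param motion_frame_rate expected fraction of frames corrupted by motion.
#' @param motion_amp amplitude of the artifact offset added to corrupted
#'   frames, in units of the latent signal SD.
#' @param injection_amp,injection_tau_s amplitude and decay constant of the
#'   exponential injection transient added at each injection time. The
#'   transient exists to exercise interval selection; it is not a calibrated
#'   hemodynamic model.
#' @param latent_sd marginal SD of the band-limited ROI latent signals.
#' @param band_hz,filter_order passband and Butterworth order used to shape
#'   the latent signals; identical to the preprocessing defaults so that the
#'   generated power concentrates in the analysis band (0.01-0.1 Hz).
#' @param seed optional integer seed consumed by [generate_session()].
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_rows = 64, n_cols = 64, pixel_mm = 0.1, fs = 1,
                           t_start_min = -20, t_end_min = 40,
                           pretreat_time_min = -10, roi_layout = NULL,
                           noise_sd = 0.5, local_corr = 0.5,
                           motion_frame_rate = 0.02, motion_amp = 10,
                           injection_amp = 1, injection_tau_s = 60,
                           latent_sd = 1, band_hz = c(0.01, 0.1),
                           filter_order = 4, seed = NULL) {
  if (local_corr < 0 || local_corr > 1) stopf("local_corr must be in [0, 1]")
  if (motion_frame_rate < 0 || motion_frame_rate >= 1)
    stopf("motion_frame_rate must be in [0, 1)")
  if (t_end_min <= t_start_min) stopf("t_end_min must exceed t_start_min")
  roi_layout <- roi_layout %||% default_roi_layout(n_rows, n_cols)
  check_roi_layout(roi_layout, n_rows, n_cols)
  nt <- as.integer(round(fs * (t_end_min - t_start_min) * 60)) + 1L
  structure(list(n_rows = n_rows, n_cols = n_cols, pixel_mm = pixel_mm,
                 fs = fs, t_start_min = t_start_min, t_end_min = t_end_min,
                 pretreat_time_min = pretreat_time_min,
                 roi_layout = roi_layout, noise_sd = noise_sd,
                 local_corr = local_corr,
                 motion_frame_rate = motion_frame_rate,
                 motion_amp = motion_amp, injection_amp = injection_amp,
                 injection_tau_s = injection_tau_s, latent_sd = latent_sd,
                 band_hz = band_hz, filter_order = filter_order,
                 n_time = nt, seed = seed),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("session_config: %d x %d px, %g Hz, %g..%g min (%d frames), %d ROIs\n",
              x$n_rows, x$n_cols, x$fs, x$t_start_min, x$t_end_min,
              x$n_time, length(x$roi_layout)))
  invisible(x)
}

#' Ground truth for a synthetic cohort
#'
#' Bundles the planted quantities every downstream stage is checked against:
#' the per-state ROI covariance matrices, the Markov transition matrix that
#' drives state switching (optionally a different matrix after the ketamine
#' injection), and group effects applied to selected (sex, condition) cells.
#'
#' @param state_covariances list of symmetric positive-semidefinite matrices,
#'   one per state, all of the same dimension (22 for the canonical layout).
#' @param transition_matrix row-stochastic `k x k` matrix governing the
#'   latent state chain.
#' @param post_transition_matrix optional row-stochastic matrix used from the
#'   ketamine injection (t >= 0) onward; `NULL` keeps the baseline chain.
#' @param group_effects list of effect specifications; each element is a list
#'   with fields `sex`, `condition`, and either `pair` + `dz` (a Fisher-z
#'   shift added post-injection to one ROI-pair correlation in every state
#'   covariance) or `post_transition` (a replacement post-injection
#'   transition matrix), applied only to sessions in that (sex, condition)
#'   cell by [generate_cohort()].
#' @param labels ROI labels the covariances refer to.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(state_covariances, transition_matrix,
                         post_transition_matrix = NULL,
                         group_effects = list(),
                         labels = fusi_roi_labels()) {
  if (!is.list(state_covariances) || !length(state_covariances))
    stopf("state_covariances must be a non-empty list")
  p <- nrow(state_covariances[[1]])
  for (i in seq_along(state_covariances)) {
    s <- state_covariances[[i]]
    if (!is_square(s) || nrow(s) != p)
      stopf("state covariance %d is not %d x %d", i, p, p)
    if (max(abs(s - t(s))) > 1e-8) stopf("state covariance %d not symmetric", i)
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stopf("state covariance %d is not positive semidefinite", i)
  }
  if (length(labels) != p)
    stopf("labels length (%d) must match covariance dimension (%d)",
          length(labels), p)
  k <- length(state_covariances)
  check_stochastic(transition_matrix, tol = 1e-12)
  if (nrow(transition_matrix) != k)
    stopf("transition matrix must be %d x %d", k, k)
  if (!is.null(post_transition_matrix)) {
    check_stochastic(post_transition_matrix, tol = 1e-12)
    if (nrow(post_transition_matrix) != k)
      stopf("post transition matrix must be %d x %d", k, k)
  }
  structure(list(state_covariances = state_covariances,
                 transition_matrix = transition_matrix,
                 post_transition_matrix = post_transition_matrix,
                 group_effects = group_effects, labels = labels,
                 k = k),
            class = "ground_truth")
}

#' Default planted brain-state covariances
#'
#' Builds `k` (up to 5) strongly separated 22-ROI correlation matrices.
#' The states sit at the vertices of a regular simplex spanned by four
#' orthonormalized bipolar connectivity modes — frontal-vs-limbic,
#' mPFC-vs-motor, insula-vs-striatum coupling, and homotopic-vs-
#' crosshemispheric coupling — on top of a common pattern of moderate
#' global and strong left-right homotopic correlation, plus a graded global
#' connectivity offset. The simplex placement makes all pairwise state
#' contrasts comparably strong in the 484-dimensional vectorized-
#' connectivity space (so no contrast drowns in windowed-correlation
#' sampling noise), while the global grade orders the states from most
#' connected (state 1) to most disconnected (state k), mirroring the
#' sorted recurring patterns the clustering stage recovers. Each matrix is
#' projected to the nearest valid correlation matrix.
#'
#' @param k number of states (1 to 5; default 5).
#' @param labels ROI labels (length 22 canonical set by default).
#' @param amplitude simplex amplitude controlling state separation.
#' @param grade peak-to-peak scale of the graded global offset.
#' @return List of `k` correlation matrices sorted by decreasing mean
#'   off-diagonal connectivity.
#' @export
default_state_covariances <- function(k = 5, labels = fusi_roi_labels(),
                                      amplitude = 8, grade = 1) {
  p <- length(labels)
  if (k < 1 || k > 5) stopf("k must be between 1 and 5")
  regions <- sub("_[LR]$", "", labels)
  blocks <- list(mpfc = c("IL", "PrL", "Cg1"),
                 motor = c("M2", "M1", "S1"),
                 insula = c("GIDI", "AI"),
                 striatum = c("CPu", "NAcC", "NAcSh"))
  inb <- function(...) regions %in% unlist(blocks[c(...)])
  off <- !diag(p)
  homotopic <- outer(regions, regions, `==`) & off
  sym_pat <- function(pos, neg = NULL) {
    m <- matrix(0, p, p)
    m[outer(pos, pos, `&`)] <- 1
    if (!is.null(neg)) m[outer(neg, neg, `&`)] <- -1
    diag(m) <- 0
    m
  }
  pats <- list(
    sym_pat(inb("mpfc", "motor"), inb("insula", "striatum")),
    sym_pat(inb("mpfc"), inb("motor")),
    sym_pat(inb("insula"), inb("striatum")),
    { m <- matrix(-0.3, p, p); m[homotopic] <- 1; diag(m) <- 0; m })
  u <- qr.Q(qr(vapply(pats, as.vector, numeric(p * p))))
  m0 <- matrix(0.15, p, p)
  m0[homotopic] <- 0.6
  diag(m0) <- 1
  if (k == 1) {
    out <- nearest_psd(m0, correlation = TRUE)
    dimnames(out) <- list(labels, labels)
    return(list(out))
  }
  ## regular (k-1)-simplex coordinates for k vertices, unit circumradius
  v <- qr.Q(qr(t(diag(k) - 1 / k)))[, seq_len(k - 1), drop = FALSE] *
    sqrt(k / (k - 1))
  u <- u[, seq_len(min(k - 1, 4)), drop = FALSE]
  v <- v[, seq_len(ncol(u)), drop = FALSE]
  gdir <- as.vector(off) / sqrt(sum(off))
  gr <- grade * seq(1, -1, length.out = k)
  covs <- lapply(seq_len(k), function(i) {
    m <- matrix(as.vector(m0) + amplitude * as.vector(u %*% v[i, ]) +
                  gr[i] * gdir, p, p)
    m <- pmin(pmax(m, -0.95), 0.95)
    diag(m) <- 1
    nearest_psd((m + t(m)) / 2, correlation = TRUE)
  })
  mean_conn <- vapply(covs, function(m) mean(m[upper.tri(m)]), numeric(1))
  covs <- covs[order(mean_conn, decreasing = TRUE)]
  lapply(covs, function(m) {
    dimnames(m) <- list(labels, labels)
    m
  })
}

#' Default ground truth
#'
#' `k` graded covariance states from [default_state_covariances()] driven by
#' a sticky Markov chain (self-transition probability `self`, remaining mass
#' spread uniformly), giving mean dwell times of roughly
#' `1 / (fs * (1 - self))` seconds at 1 Hz.
#'
#' @param k number of states.
#' @param self self-transition probability of the baseline chain.
#' @param labels ROI labels.
#' @return A [ground_truth()] object.
#' @export
default_ground_truth <- function(k = 5, self = 0.985,
                                 labels = fusi_roi_labels()) {
  p0 <- if (k == 1) matrix(1, 1, 1) else {
    m <- matrix((1 - self) / (k - 1), k, k)
    diag(m) <- self
    m
  }
  ground_truth(default_state_covariances(k, labels), p0, labels = labels)
}

#' Sample a planted Markov state sequence
#'
#' @param transition_matrix row-stochastic `k x k` matrix.
#' @param n_steps sequence length (>= 1).
#' @param seed optional integer seed.
#' @param start optional initial state; by default the initial state is drawn
#'   from the stationary distribution of the chain (uniform if the stationary
#'   distribution is not unique).
#' @return Integer vector of length `n_steps` over states `1..k`. Empirical
#'   transition frequencies converge to `transition_matrix` as `n_steps`
#'   grows.
#' @examples
#' p <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
#' plant_state_sequence(p, 6, start = 1)  # forced 1,2,1,2,1,2
#' @export
plant_state_sequence <- function(transition_matrix, n_steps, seed = NULL,
                                 start = NULL) {
  check_stochastic(transition_matrix)
  if (n_steps < 1) stopf("n_steps must be >= 1")
  k <- nrow(transition_matrix)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) {
    start <- sample.int(k, 1, prob = stationary_distribution(transition_matrix))
  }
  if (start < 1 || start > k) stopf("start state must be in 1..%d", k)
  out <- integer(n_steps)
  out[1] <- as.integer(start)
  if (n_steps > 1) {
    u <- runif(n_steps - 1)
    cum <- t(apply(transition_matrix, 1, cumsum))
    for (t in 2:n_steps) {
      out[t] <- sum(u[t - 1] > cum[out[t - 1], ]) + 1L
    }
  }
  out
}

## Stationary distribution of a row-stochastic matrix (left eigenvector of
## eigenvalue 1); falls back to uniform when numerically ambiguous.
stationary_distribution <- function(p) {
  k <- nrow(p)
  e <- eigen(t(p))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (all(abs(v) < 1e-12)) return(rep(1 / k, k))
  v <- abs(v) / sum(abs(v))
  if (any(!is.finite(v))) rep(1 / k, k) else v
}

#' Generate one synthetic fUSI session
#'
#' ROI latent signals are drawn per timepoint from the covariance of the
#' planted state, then passed through the same zero-phase Butterworth
#' bandpass used downstream so the generated power concentrates in the
#' analysis band without committing to a specific autoregressive spectrum.
#' Pixels inherit their ROI's latent plus spatially shared local noise
#' (weight `local_corr`) and independent noise; an exponential transient is
#' added at each injection; motion-corrupted frames get a global intensity
#' offset and are flagged in the ground-truth validity mask (the data itself
#' retains the artifact so frame censoring can be exercised).
#'
#' @param config a [session_config()].
#' @param truth a [ground_truth()] whose covariance dimension matches the
#'   number of ROIs in `config$roi_layout`.
#' @param pixels logical; generate the full pixel stack (`fusi_image`) or
#'   only the ROI latents (cheaper, sufficient for ROI-level analyses).
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list of class `fusi_session` with elements `image` (a
#'   [fusi_image()] or `NULL`), `roi` (a [fusi_roits()] holding the latent
#'   ROI signals), and `truth` (planted state sequence, covariances,
#'   transition matrices and motion flags).
#' @export
generate_session <- function(config, truth, pixels = TRUE, seed = NULL) {
  stopifnot(inherits(config, "session_config"), inherits(truth, "ground_truth"))
  labels <- names(config$roi_layout)
  p <- length(labels)
  if (nrow(truth$state_covariances[[1]]) != p)
    stopf("truth covariances are %d x %d but the layout has %d ROIs",
          nrow(truth$state_covariances[[1]]),
          nrow(truth$state_covariances[[1]]), p)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  nt <- config$n_time
  time_s <- seq(config$t_start_min * 60, config$t_end_min * 60,
                by = 1 / config$fs)
  pre_idx <- which(time_s < 0)
  post_idx <- which(time_s >= 0)

  ## latent state chain: baseline matrix before injection, post matrix after
  state_seq <- integer(nt)
  state_seq[pre_idx] <- plant_state_sequence(truth$transition_matrix,
                                             length(pre_idx))
  p_post <- truth$post_transition_matrix %||% truth$transition_matrix
  if (length(post_idx)) {
    start <- if (length(pre_idx)) {
      cum <- cumsum(p_post[state_seq[max(pre_idx)], ])
      sum(runif(1) > cum) + 1L
    } else NULL
    rest <- plant_state_sequence(p_post, length(post_idx), start = start)
    state_seq[post_idx] <- rest
  }

  ## per-state Cholesky factors; optional distinct post-injection covariances
  chol_of <- function(covs) lapply(covs, function(s) {
    t(chol(nearest_psd(s, correlation = FALSE, eps = 1e-8)))
  })
  ch_pre <- chol_of(truth$state_covariances)
  ch_post <- if (!is.null(truth$post_covariances))
    chol_of(truth$post_covariances) else ch_pre

  eps <- matrix(rnorm(p * nt), p, nt)
  lat <- matrix(0, p, nt)
  seg <- data.frame(state = rle(state_seq)$values,
                    len = rle(state_seq)$lengths)
  pos <- 0L
  for (i in seq_len(nrow(seg))) {
    idx <- (pos + 1L):(pos + seg$len[i])
    pre_part <- idx[time_s[idx] < 0]
    post_part <- idx[time_s[idx] >= 0]
    if (length(pre_part))
      lat[, pre_part] <- ch_pre[[seg$state[i]]] %*% eps[, pre_part, drop = FALSE]
    if (length(post_part))
      lat[, post_part] <- ch_post[[seg$state[i]]] %*% eps[, post_part, drop = FALSE]
    pos <- pos + seg$len[i]
  }

  ## shape into the analysis band; per-series rescaling preserves correlations
  lat <- bandpass(lat, config$band_hz[1], config$band_hz[2], fs = config$fs,
                  order = config$filter_order)
  sds <- apply(lat, 1, sd)
  sds[sds == 0] <- 1
  lat <- lat / sds * config$latent_sd

  ## injection transients (shared across ROIs)
  transient <- numeric(nt)
  for (t_inj in c(config$pretreat_time_min * 60, 0)) {
    on <- time_s >= t_inj
    transient[on] <- transient[on] +
      config$injection_amp * exp(-(time_s[on] - t_inj) / config$injection_tau_s)
  }
  lat_out <- lat + rep(transient, each = p)
  rownames(lat_out) <- labels

  ## motion-corrupted frames
  motion <- runif(nt) < config$motion_frame_rate
  valid <- !motion

  roits <- fusi_roits(lat_out, time_s, fs = config$fs, valid = valid,
                      labels = labels)

  image <- NULL
  if (pixels) {
    npix <- config$n_rows * config$n_cols
    dat <- matrix(rnorm(npix * nt, 0, 1), npix, nt)  # unit noise, scaled below
    dat <- dat * (config$noise_sd * sqrt(1 - config$local_corr))
    for (lab in labels) {
      idx <- config$roi_layout[[lab]]
      shared <- rnorm(nt) * (config$noise_sd * sqrt(config$local_corr))
      add <- lat_out[lab, ] + shared
      dat[idx, ] <- dat[idx, ] + rep(add, each = length(idx))
    }
    if (any(motion)) {
      amp <- config$motion_amp * config$latent_sd
      dat[, motion] <- dat[, motion] + amp
    }
    image <- fusi_image(array(dat, c(config$n_rows, config$n_cols, nt)),
                        time_s, fs = config$fs, pixel_mm = config$pixel_mm,
                        valid = valid)
  }

  structure(list(image = image, roi = roits,
                 truth = list(state_sequence = state_seq,
                              state_covariances = truth$state_covariances,
                              post_covariances = truth$post_covariances,
                              transition_matrix = truth$transition_matrix,
                              post_transition_matrix = truth$post_transition_matrix,
                              motion_frames = which(motion)),
                 config = config),
            class = "fusi_session")
}

#' @export
print.fusi_session <- function(x, ...) {
  cat(sprintf("fusi_session: %d ROI signals, %d frames, %s pixel stack\n",
              nrow(x$roi$signals), length(x$roi$time_s),
              if (is.null(x$image)) "no" else "with"))
  invisible(x)
}

#' Generate a synthetic crossover cohort
#'
#' Emulates the repeated-measures design: every subject is imaged once per
#' treatment condition with a subject-consistent baseline covariance (a small
#' subject-specific perturbation of the planted state covariances, shared
#' across that subject's sessions). Group effects in `truth$group_effects`
#' are applied only post-injection and only to sessions in the designated
#' (sex, condition) cells.
#'
#' @param n_per_sex subjects per sex (>= 1).
#' @param conditions character vector of treatment conditions, a subset of
#'   `c("VEH+KET", "NTX+KET", "NTX+VEH", "VEH+SAL")`.
#' @param config a [session_config()] shared by all sessions.
#' @param truth a [ground_truth()].
#' @param seed master integer seed. All randomness flows from it: subject
#'   perturbations and per-session seeds are drawn from one stream seeded
#'   here, then each session is generated from its own derived seed.
#' @param pixels generate pixel stacks (expensive) or ROI latents only.
#' @param subject_sd SD of the subject-level perturbation added to every
#'   state correlation (0 disables inter-subject variability).
#' @return A list of class `fusi_cohort`: `sessions` (list of
#'   `fusi_session`), `meta` (data.frame with subject, sex, condition,
#'   session_order, seed).
#' @export
generate_cohort <- function(n_per_sex, conditions = c("VEH+KET", "NTX+KET"),
                            config = session_config(), truth = default_ground_truth(),
                            seed = 1, pixels = FALSE, subject_sd = 0.03) {
  if (n_per_sex < 1) stopf("n_per_sex must be >= 1")
  allowed <- c("VEH+KET", "NTX+KET", "NTX+VEH", "VEH+SAL")
  if (!all(conditions %in% allowed))
    stopf("conditions must be a subset of: %s", paste(allowed, collapse = ", "))
  set.seed(seed)
  n_sub <- 2L * n_per_sex
  subjects <- sprintf("S%02d", seq_len(n_sub))
  sexes <- rep(c("male", "female"), each = n_per_sex)
  p <- length(truth$labels)

  ## subject-specific baseline covariances, shared across conditions
  subject_covs <- lapply(seq_len(n_sub), function(s) {
    if (subject_sd <= 0) return(truth$state_covariances)
    d <- matrix(rnorm(p * p, 0, subject_sd), p, p)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    lapply(truth$state_covariances, function(m)
      nearest_psd(m + d, correlation = TRUE))
  })
  session_seeds <- sample.int(.Machine$integer.max, n_sub * length(conditions))

  sessions <- list()
  meta <- list()
  i <- 0L
  for (s in seq_len(n_sub)) {
    for (ci in seq_along(conditions)) {
      i <- i + 1L
      cond <- conditions[ci]
      st <- truth
      st$state_covariances <- subject_covs[[s]]
      for (eff in truth$group_effects) {
        if (!identical(eff$sex, sexes[s]) || !identical(eff$condition, cond))
          next
        if (!is.null(eff$pair)) {
          st$post_covariances <- lapply(
            st$post_covariances %||% st$state_covariances,
            function(m) shift_pair_z(m, eff$pair, eff$dz))
        }
        if (!is.null(eff$post_transition)) {
          check_stochastic(eff$post_transition, tol = 1e-12)
          st$post_transition_matrix <- eff$post_transition
        }
      }
      sess <- generate_session(config, st, pixels = pixels,
                               seed = session_seeds[i])
      sessions[[i]] <- sess
      meta[[i]] <- data.frame(subject = subjects[s], sex = sexes[s],
                              condition = cond, session_order = ci,
                              seed = session_seeds[i],
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(sessions = sessions, meta = do.call(rbind, meta)),
            class = "fusi_cohort")
}

#' @export
print.fusi_cohort <- function(x, ...) {
  cat(sprintf("fusi_cohort: %d sessions, %d subjects (%d female), conditions: %s\n",
              nrow(x$meta), length(unique(x$meta$subject)),
              length(unique(x$meta$subject[x$meta$sex == "female"])),
              paste(unique(x$meta$condition), collapse = ", ")))
  invisible(x)
}

## Shift one ROI-pair correlation by dz in the Fisher-z domain and project
## back to the nearest correlation matrix.
shift_pair_z <- function(m, pair, dz) {
  i <- match(pair[1], rownames(m))
  j <- match(pair[2], rownames(m))
  if (is.na(i) || is.na(j))
    stopf("group-effect pair (%s, %s) not found in covariance labels",
          pair[1], pair[2])
  r <- tanh(atanh(min(max(m[i, j], -0.999999), 0.999999)) + dz)
  m[i, j] <- m[j, i] <- r
  nearest_psd(m, correlation = TRUE)
}
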