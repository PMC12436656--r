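## Small fixture builders shared across tests. Everything is generated in
## code at test time; no stored data.

## ROI time series of white noise with the canonical 22 labels.
noise_roits <- function(nt = 200, p = 22, fs = 1, t0 = -20 * 60, seed = 1) {
  set.seed(seed)
  fusi_roits(matrix(rnorm(p * nt), p, nt),
             time_s = seq(t0, by = 1 / fs, length.out = nt), fs = fs,
             labels = fusi_roi_labels()[seq_len(p)])
}

## Pixel image filled with a single deterministic or random pattern.
noise_image <- function(nr = 20, nc = 20, nt = 100, fs = 1, t0 = 0,
                        seed = 1) {
  set.seed(seed)
  fusi_image(array(rnorm(nr * nc * nt), c(nr, nc, nt)),
             time_s = seq(t0, by = 1 / fs, length.out = nt), fs = fs)
}

## A small fast session configuration for pixel-level tests.
small_config <- function(motion_frame_rate = 0, injection_amp = 0, ...) {
  session_config(n_rows = 33, n_cols = 12, t_start_min = -8, t_end_min = 4,
                 pretreat_time_min = -6,
                 motion_frame_rate = motion_frame_rate,
                 injection_amp = injection_amp, ...)
}

## Single-state ground truth with a custom covariance list.
single_state_truth <- function(cov) {
  ground_truth(list(cov), matrix(1, 1, 1))
}

## Adjusted Rand index (mclust) guarded for environments without it.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Toy mixed design: between factor sex, within factors treatment x time.
toy_design <- function(n_per_group = 2, a = 2, b = 2, seed = 81,
                       effect = 0) {
  set.seed(seed)
  subj <- sprintf("S%d", seq_len(2 * n_per_group))
  grp <- rep(c("m", "f"), each = n_per_group)
  d <- expand.grid(subject = subj,
                   treatment = paste0("tr", seq_len(a)),
                   time = paste0("t", seq_len(b)),
                   stringsAsFactors = FALSE)
  d$sex <- grp[match(d$subject, subj)]
  d$z <- rnorm(nrow(d)) +
    effect * (d$sex == "m") * (d$treatment == "tr2") * (d$time == "t2")
  d
}
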