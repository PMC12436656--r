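---
title: "Static and dynamic functional connectivity analysis of pharmacological fUSI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional connectivity analysis of pharmacological fUSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusiconn)
```

## The analysis problem

Functional ultrasound imaging (fUSI) measures cerebral blood volume (CBV)
through power Doppler intensity at high spatiotemporal resolution. In a
pharmacological experiment a rat is imaged continuously — here from 20 min
before to 40 min after an intravenous ketamine injection at 1 frame/s, with a
pretreatment injection (naltrexone or vehicle) at −10 min — and the slow
(0.01–0.1 Hz) CBV fluctuations serve as a hemodynamic proxy for neural
activity. `fusiconn` implements the downstream analysis chain for such
recordings:

1. **Preprocessing** — zero-phase Butterworth bandpass filtering, censoring of
   motion-corrupted frames, ROI extraction, drug-anchored interval selection.
2. **Static connectivity** — ROI-pair Pearson correlation matrices with
   Fisher-Z normalization, and seed-based pixel-wise correlation maps with
   median-filter smoothing, group paired-t maps and Monte-Carlo cluster-extent
   correction.
3. **Regional homogeneity** — pixel-wise Kendall's coefficient of concordance
   (KCC) over 9-pixel neighborhoods, animal-level z-scoring and ROI
   segmentation.
4. **Dynamic connectivity** — 30-s/1-s sliding-window correlation, SVD-elbow
   selection of the number of brain states, k-means state clustering, state
   occupancy metrics (time fraction, dwell time), transition probabilities
   and Markov entropy, with leave-one-group-out and phase-difference
   cross-checks.
5. **Group statistics** — mixed repeated-measures ANOVA with Mauchly /
   Greenhouse-Geisser sphericity handling, Tukey HSD post-hoc tests, Hedges g
   and t tests.

Raw recordings of this kind are not publicly archived, so the package ships a
synthetic-session generator with known ground truth; every stage of the chain
is validated against what was planted.

## Containers and conventions

Two containers carry the data: `fusi_image` (pixels × time CBV stack with
frame-validity mask and a time axis in seconds anchored to the ketamine
injection) and `fusi_roits` (labeled ROI-mean signals on the same axis). The
canonical segmentation has 11 bilateral regions — IL, PrL, Cg1, M2, M1, S1,
GIDI, AI, CPu, NAcC, NAcSh — ordered left-then-right per region
(`fusi_roi_labels()`), giving 22 signals.

Two conventions matter everywhere:

* **Closed intervals on an inclusive grid.** The time axis includes both
  endpoints, so a 9-min interval at 1 Hz has 541 frames, a 15-min interval
  901 frames, and a −20..+40 min session 3601 frames; a 30-sample window with
  1-sample steps over that session yields 3601 − 30 + 1 = 3572 windows.
* **Masking, never deletion.** Invalid frames stay in the containers and are
  removed pairwise inside each correlation; this avoids fabricating in-band
  signal by interpolation.

## Preprocessing choices

`bandpass()` applies a fourth-order Butterworth bandpass (0.01–0.1 Hz at
1 Hz sampling by default) forward and backward. Zero-phase filtering was
chosen over causal filtering so that no temporal shift is introduced relative
to the injection events; the cost is a doubled effective attenuation order,
which is immaterial here because the analyses only use the passband. Edge
transients are suppressed by odd-reflection padding of three times the
effective filter length. Filtering is linear, so it commutes with ROI
averaging — a property the tests verify at numerical precision.

`censor_frames()` flags frames whose global mean deviates from a centered
rolling median (default 121 frames ≈ 2 min) by more than `zmax` robust SDs
(MAD-scaled). A rolling reference rather than a global mean makes the filter
insensitive to the slow injection response; the default `zmax = 5` flags
essentially nothing on clean synthetic sessions while recovering ≥ 95% of
planted motion artifacts at `zmax = 4`.

## Static connectivity

`fc_matrix()` computes Pearson correlations between all unordered ROI pairs
(231 for 22 ROIs) over the valid frames of an interval, with a configurable
floor (default 30) on the number of valid frames. All averaging and testing
downstream uses the Fisher z transform `z = atanh(r)`; r is re-derived by
`tanh` for display only. Correlations of exactly ±1 (possible for degenerate
inputs) are capped at `atanh(0.999999)` with a warning rather than mapped to
infinity. A zero-variance ROI yields flagged `NA` pairs, never a silent zero.

The default intervals mirror the pharmacological design: baseline is the
9-min interval centered at −5 min, and the post-injection intervals are
15-min windows centered at +10 and +40 min.

`seed_map()` correlates the mean signal of a seed pixel set — by default the
bilateral PrL + IL, i.e. the medial prefrontal cortex — with every pixel.
Maps are smoothed with a 0.3 × 0.3 mm median filter (3 × 3 pixels at 0.1 mm
resolution) and compared across matched conditions by pixel-wise paired t
tests. Family-wise error control uses a cluster-extent threshold:
`mc_cluster_threshold()` simulates Gaussian null fields, passes each through
*the same smoother applied to the data*, thresholds two-tailed at the
cluster-forming level, and returns the smallest cluster size whose maximal
null occurrence has probability ≤ `alpha_clust`. Matching the null smoothness
empirically (rather than through an analytic FWHM) was chosen because a
median filter has no Gaussian-kernel equivalent. Pixel connectivity is
4-adjacency by default (8 available); the threshold value depends on this
choice, so it is part of the reported parameters. The cluster-forming voxel
threshold defaults to two-tailed p < 0.05 and is exposed as an argument.

## Regional homogeneity

For `k` series of `n` time points with within-series ranks \(R_{ij}\),

\[
W \;=\; \frac{12}{k^2\,(n^3-n)} \sum_{i=1}^{n}\Big(\sum_{j=1}^{k} R_{ij} - k\bar R\Big)^2 ,
\]

with \(\bar R = (n+1)/2\). `kcc_map()` evaluates W for each pixel with its
8 neighbors (k = 9) over an interval; pixels whose neighborhood leaves the
grid or brain mask are flagged undefined rather than zero-filled. Ties are
midranked and the statistic is used in the uncorrected form above — exact
ties have measure zero for continuous CBV data, and this keeps the
implementation faithful to the printed formula; the divergence from the
tie-corrected form of Kendall's W is deliberate and documented here.
`zscore_kcc()` normalizes at the animal level with the pooled mean and SD of
the animal's 4 maps (baseline and post-ketamine under both treatments), and
`segment_kcc()` reduces the z maps to per-ROI means for group analysis. The
KCC intervals reuse the static-connectivity defaults (9-min baseline, 15-min
post window).

## Dynamic connectivity and brain states

`sliding_window_fc()` computes windowed correlation matrices (30-s windows,
1-s steps, rectangular weighting) and vectorizes each into all 484 entries of
the 22 × 22 matrix. Keeping the diagonal and both triangles is redundant —
231 entries are informative — but preserves the exact reshape/concatenate
arithmetic of the design, and k-means is invariant to duplicated coordinates
up to a uniform reweighting of the pair space. Sessions are concatenated
along time (`concat_cohort()`) with an index that maps every row back to its
(subject, condition, window center).

The number of states is selected by `svd_elbow()`: rank the singular values
of the global matrix, keep the smallest leading set reaching 99% cumulative
variance (squared singular values over total), and locate the elbow with the
discrete second difference of the reduced spectrum. Two readings of the
elbow rule are defensible; both are implemented. The default (`rule =
"min"`) takes the index at which the second difference is minimal — the last
component before the spectrum flattens, which returns k on a spectrum with k
strong values and a flat tail. The alternative (`rule = "max"`) takes the
maximum-curvature point, which lands one index later on a sharp elbow. The
returned object carries the full diagnostic curve and a saliency measure
(the relative spectral gap below the chosen elbow); saliency below 0.1 means
the spectrum has no pronounced elbow and `k_opt` should not be trusted.

`cluster_states()` runs k-means (k-means++ initialization, 20 restarts by
default, best within-SS kept) on the r values directly — no Fisher transform,
since windowed matrices are clustered as-is — and sorts the centroids by
decreasing mean off-diagonal connectivity, so state 1 is always the most
connected pattern and state k the most disconnected. Occupancy is summarized
by `state_metrics()` over drug-anchored periods: the pre-ketamine period is
−18.5 to −1.5 min excluding a 3-min gap centered on the −10 min pretreatment
injection (the exclusion endpoints −11.5..−8.5 are a convention; the design
names only the gap's duration), and the post-ketamine period is 2.5 to
17.5 min. Labels are timestamped at window centers; windows whose centers
fall inside an exclusion are dropped, and neither dwell-time runs nor
transition counts ever bridge a gap. Time fraction is the fraction of period
labels in each state; dwell time is the mean uninterrupted run length times
the step. The transition matrix divides i→j counts (self-transitions
included) by total transitions out of i, and the Markov entropy is
\(H = -\sum_{ij} P_{ij}\log P_{ij}\) in natural log (the base is an
argument), with \(0\log 0 = 0\); rows without outgoing transitions are
excluded. H is maximized at \(k\log k\) by uniform rows.

Two stability checks accompany the clustering. `leave_one_group_out()`
refits the model with each (sex, treatment) group held out and reports
matched-centroid cosine similarities (matching by exhaustive permutation,
feasible for k ≤ 8). `phase_difference_features()` provides a
windowing-free feature set — per-timepoint cosines of analytic-signal phase
differences, valid for narrowband input — whose clustering should reproduce
the sliding-window partition.

## Group statistics

`mixed_anova()` handles balanced complete designs with within-subject
factors (treatment, time, ROI pair, …) and between-subject factors (sex).
Sums of squares and F ratios come from the classical error-strata
decomposition (`aov` with `Error(subject/within)`), which for balanced data
coincides with Type III and remains computable when a within factor has many
levels (e.g. 231 ROI pairs, where the multivariate route is singular).
Mauchly's W and the Greenhouse-Geisser epsilon are computed from orthonormal
contrasts of the pooled subject-by-cell covariance; the GG-corrected p value
is always reported alongside the raw one, and the reported `p_report` column
uses GG when Mauchly rejects at 0.05 (a flag forces it always on or off).
Sphericity is untestable (W = NA) when the contrast covariance is singular —
fewer subjects than within-contrast dimensions — while epsilon remains
computable. Note one boundary property: the usual statement "GG never
increases significance" holds for F ≥ 1; for F < 1 the heavier-tailed
reference with reduced degrees of freedom can pull p slightly the other way.

`tukey_hsd()` computes studentized-range corrected p values from cell means,
the error mean square and its df (Tukey-Kramer for unequal n).
`hedges_g()` applies the small-sample correction `J = 1 − 3/(4 df − 1)`; for
paired data the default denominator is the SD pooled across the two
conditions (`df = n − 1`), the common convention for reported g magnitudes,
with the SD-of-differences denominator behind a flag. `t_tests()` wraps the
paired, one-sample and Welch two-sample t statistics with an explicit
degenerate-variance contract (t = 0, p = 1 for an exactly zero difference;
±Inf, p = 0 otherwise). Stratified per-ROI-pair ANOVAs are reported
uncorrected — the design presents per-pair p values — and any multiplicity
layer (`p.adjust`) is left to the caller.

## The synthetic-data generator

`generate_session()` builds sessions from planted ground truth:

* **Temporal structure.** ROI latents are white Gaussian draws with the
  planted per-state covariance, passed through the same 0.01–0.1 Hz
  zero-phase bandpass used downstream. This guarantees in-band power without
  committing to an autoregressive model the design does not state.
  Per-series rescaling to a target SD preserves all correlations.
* **State switching.** A Markov chain on the ROI latents with baseline
  self-transition 0.985 (mean dwell ≈ 67 s at 1 Hz) — long enough that 30-s
  windows resolve the states, short enough that a 20–60 min session visits
  every state many times. A different post-injection transition matrix
  and/or covariance shift can be planted per (sex, treatment) cell.
* **Planted states.** `default_state_covariances()` places 5 states at the
  vertices of a regular simplex spanned by four orthonormalized bipolar
  connectivity modes (frontal-vs-limbic, mPFC-vs-motor, insula-vs-striatum,
  homotopic-vs-crosshemispheric) over a base pattern of moderate global
  (0.15) and strong homotopic (0.6) correlation, plus a graded global offset
  that orders the states from most to least connected. The simplex placement
  makes every pairwise state contrast comparably strong in the vectorized
  pair space. This matters because windowed-correlation noise is strongly
  anisotropic: a 30-sample window of 0.01–0.1 Hz signals has only ~5
  effective samples, and estimation errors are most correlated along the
  global-connectivity direction. States separated only by overall
  connectivity level (an earlier design) sit along exactly that noisy
  direction and cannot be recovered reliably; pattern-separated states can.
* **Pixels.** Each pixel carries its ROI latent plus shared within-ROI noise
  (weight `local_corr`) and independent noise, so `local_corr` directly
  controls the regional-homogeneity signal. Spatial correlation is modeled
  at ROI granularity, not as a continuous spatial kernel.
* **Injections and motion.** An exponentially decaying offset (default
  amplitude 1, τ = 60 s) is added at each injection — it exists to exercise
  interval selection, not as a calibrated hemodynamic response — and a
  configurable fraction of frames receives a large global offset and a
  ground-truth motion flag.
* **Randomness.** One master seed per cohort; subject covariance jitter and
  per-session seeds are drawn from the master stream, then each session is
  generated from its own derived seed, so cohorts are bit-reproducible.

What the generator does **not** emulate: real fUSI noise spectra beyond
band-limited Gaussianity, vascular anatomy, continuous spatial noise
correlation, registration error, or physiological confounds (cardiac,
respiratory). Passing tests therefore demonstrate that the pipeline's
operations are correct and calibrated on data with known structure — not
that the biological conclusions of any particular study replicate.

## Validation strategy and problem sizes

The test suite checks three kinds of properties, at sizes chosen to keep a
full run within a few minutes:

* **Analytic values.** KCC bounds (1 for identical series, 0 for a reversed
  pair) and agreement with a brute-force rank-arithmetic oracle to 1e-12;
  Markov entropy closed forms (0 for deterministic chains, \(5\ln 5 \approx
  8.047\) for uniform 5 × 5); window-count and vectorization-width
  identities (3572 windows, 484 columns); Fisher round-trips; Hedges g
  closed forms; the mixed-ANOVA table against an independent cell-means
  decomposition (1e-8) and against `car::Anova`'s univariate
  repeated-measures output.
* **Calibration.** Type-I rates of the ANOVA (1000 null replicates of an
  8-subject 2 × 2 design), of pixel-wise paired t maps, and of the
  cluster-extent correction (a threshold from 2000 median-filtered null
  fields on a 64 × 64 grid must admit surviving clusters in ~5% of 2000
  fresh null fields, within 2 Monte-Carlo SEs).
* **Parameter recovery.** Twenty seeded replicates of a reduced cohort —
  6 subjects (3 per sex), 2 conditions, 20-min sessions — run through the
  full generate → filter → SWC → SVD-elbow → k-means → metrics chain must
  recover k = 5 in ≥ 80% of replicates with adjusted Rand ≥ 0.8 against the
  planted labels (transition-straddling windows excluded), and must report
  the planted post-injection time-fraction and entropy increases only in the
  male VEH+KET subgroup.

## Known limitations

* The elbow rule on real spectra is only as good as the spectral gap; the
  saliency diagnostic should always be inspected before trusting `k_opt`.
* `mixed_anova()` requires balanced complete designs; unbalanced data need a
  mixed-effects model (out of scope here).
* The Monte-Carlo cluster threshold reproduces the logic and calibration of
  the AFNI-style correction, not any specific program's bit-level output;
  thresholds depend on the declared connectivity and cluster-forming level.
* HDF5 serialization is not provided; containers are plain R lists and tidy
  tables are standard data.frames writable with `write.csv()`.
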