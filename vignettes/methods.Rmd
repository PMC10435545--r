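---
title: "Methods: behavior segmentation and striatal population encoding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior segmentation and striatal population encoding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spncode` implements a complete analysis chain for one-photon calcium
imaging of striatal projection neuron (SPN) populations in freely moving
mice: from pose-estimation output to a per-frame behavior catalog, and
from deconvolved event rasters to tuning statistics, cell classes,
decoders and longitudinal stability measures. This vignette documents the
models, their assumptions, the tunable parameters and their defaults, the
synthetic-data generator the test suite relies on, and the numerical
choices made where the procedure left freedom.

## Posture features

Eight body parts (nose, neck, left/right ear, head-mounted camera, body
center, tail start, tail end) are tracked at 40 frames/s in the top-down
arena view. Coordinates with tracking likelihood below 0.9 are removed
(`filter_low_confidence()`; masked, never interpolated — frames needing a
masked part are themselves masked, which is the conservative reading of
"removed"). Six features are computed per frame (`compute_features()`):

* **body speed** (cm/s): projection of the body-center velocity on the
  body axis (body center toward neck);
* **head speed** (cm/s): norm of the difference between body-center and
  camera velocities;
* **movement angle** (rad): signed angle between the body-center velocity
  at the previous and the subsequent frame. With the image y axis
  pointing down, positive angles are right turns;
* **body length** (cm): distance(neck, body center) + distance(body
  center, tail start);
* **neck elongation** (cm): distance(neck, body center);
* **head elevation** (cm): distance between the neck and the orthogonal
  projection of the camera onto the inter-ear line. In a top-down view
  this is a proxy for head pitch, not a true height.

Velocities use central differences (one-sided at the ends); the smoothing
step (`smooth_features()`) is a mask-aware centered moving average over 20
frames (0.5 s). Whether the upstream procedure used central or one-sided
differences, or a different smoothing kernel, is not documented; these
choices are ours and are stated here once.

All features are translation- and rotation-invariant; lengths and speeds
scale linearly with the coordinate units (property-tested).

## Unsupervised behavior identification

The segmentation pipeline (`segment_behaviors()`) chains:

1. **Embedding** (`embed_features()`): features are z-scored, a quarter of
   the valid frames is subsampled (capped at `max_points`, default 1500),
   and 10 replicate t-SNE embeddings into 3 dimensions are computed. The
   3-dimensional choice is validated against the criterion that the
   leading principal components explain at least 70% of the feature
   variance (a warning reports a mismatch). The t-SNE is an exact
   (quadratic-cost) implementation in compiled code, perplexity 30,
   500 iterations, early exaggeration 12 for 100 iterations — exactness
   is affordable because only the subsample is embedded.
2. **Mixture clustering** (`cluster_embeddings()`): per embedding, the
   Gaussian-mixture component count is selected by BIC over 8–30
   (full-covariance model). The range deliberately exceeds the 12-class
   catalog so that over-segmentation precedes merging. Fifty replicate
   fits with random initializations (EM started from random subsets) per
   embedding give 500 partitions at the defaults.
3. **Consensus** (`consensus_clusters()`): frames are grouped by their
   pairwise co-assignment frequency across partitions. The procedure on
   the Hamming disagreement matrix is not specified upstream; we use
   average-linkage agglomeration cut at dissimilarity 0.5 (i.e. frames
   co-assigned in a majority of partitions end up together). Consensus
   clusters with fewer than 20 frames are dropped.
4. **Wasserstein merging** (`merge_clusters_wasserstein()`): clusters are
   merged in ascending order of their distance — the sum over the six
   features of exact 1-D Wasserstein-1 distances between the clusters'
   empirical feature distributions, computed from sorted samples with no
   binning — until no pair is closer than the cutoff of 1. Features are
   z-scored first so the cutoff is in SD units; without standardization
   the cutoff would be unit-dependent.
5. **Registration** (`register_clusters()`): each surviving cluster is
   mapped to one of the 12 behaviors. In the original workflow this is a
   manual, video-based step; the package accepts an explicit cluster map
   (which always wins) and otherwise applies an ordered rule list on
   cluster-median features implementing the qualitative behavior
   definitions (fast locomotion above 15 cm/s, turns by the sign of the
   movement angle, sniffing postures by body length and neck elongation,
   rearing/head-up by head elevation, grooming by head speed with a
   compact body or high movement-angle variability, immobility by a
   still head). A cluster matching no rule raises an error that prints
   its feature medians.
6. **Frame assignment** (`assign_frames_max_likelihood()`): a
   full-covariance Gaussian in the 6-D feature space is fitted per
   registered behavior and every valid frame of the session — including
   frames outside the clustering subsample — takes the behavior with the
   highest likelihood (ridge regularization with a warning if a
   covariance is singular; ties go to the lower behavior id).
7. **Episode post-processing** (`postprocess_labels()`): episodes shorter
   than 4 frames (100 ms at 40 frames/s) are removed; every unlabeled run
   is then split, first half to the preceding behavior, second half to
   the following one (odd lengths: the extra frame goes to the preceding
   behavior; runs at the sequence edge take their single neighbor). The
   output provably has no unlabeled frames and no short episodes
   (property-tested on random label streams).

`partition_agreement()` provides the pair-counting Rand index used to
quantify agreement between replicate partitions.

## Neural activation similarity

`activation_map()` computes the per-neuron mean deconvolved activity
(events/s) during one behavior inside a time window; maps sampled for
less than 5 s are flagged invalid and excluded. The similarity between
two maps is the negative Euclidean distance between the unit-normalized
vectors — 0 for proportional maps, −√2 for orthogonal ones, −2 at the
antipode; it is scale-invariant, so the choice of activity units does not
matter. `similarity_partitions()` implements the four time partitions
(session halves; all 10 balanced two-colorings of six 5-min slices;
odd/even frames; alternating episodes), `spatial_shuffle_similarity()`
the 10-permutation neuron-identity control, and
`dot_product_similarity()` the cosine alternative. Neurons silent in both
windows contribute zeros and are retained; an entirely zero vector makes
the comparison undefined (error), not zero.

`behavioral_distance()` sums the six 1-D Wasserstein distances between
two behaviors' feature distributions; behavioral similarity is its
negative. `similarity_coupling()` correlates (Spearman) the 66 pairwise
neural similarities with the 66 pairwise behavioral similarities.

The inverse coefficient of variation of episode-wise activation is not
precisely defined upstream; `inverse_cv()` defaults to the per-neuron
mean/SD ratio of episode rates averaged over neurons, with an
`"ensemble"` alternative — a documented decision, not an inherited fact.

## Behavior information and cell classes

`behavior_information()` computes BI = Σᵢ pᵢ (fᵢ/f) log₂(fᵢ/f) in bits
per event, with occupancies pᵢ over labeled frames and the fᵢ = 0 terms
contributing zero. Significance uses 1000 random permutations of the
cell's events among the labeled frames; a cell is **behavior-active**
when its BI exceeds the shuffled mean by more than 4 shuffled SDs
(`classify_behavior_active()`; the threshold is configurable, and a
circular-shift null that preserves the train's autocorrelation is
available via `method = "circular"` — the permutation null is the default
because it matches the plain reading of "random permutations of the
events", but it is liberal for strongly autocorrelated trains, which is
exactly when the circular option matters). A per-behavior variant
compares in-behavior rates to the same shuffles
(`classify_active_per_behavior()`).

**Activation occurrence** is the fraction of a behavior's episodes with
at least one event (any positive deconvolved amplitude; no further
thresholding). A cell is **behavior-silent** below 0.025 (strict), and
**behavior-inactive** below a mean in-behavior rate of 0.1 events/s
(strict); behaviors sampled under 5 s are excluded. A shuffle-based
silent classification against the 2.5th percentile of permuted
occurrences is also provided, and `silent_flag_probability()` gives the
exact Poisson-binomial probability that a homogeneous Poisson cell is
flagged, used to calibrate the false-flag rate.

Longitudinal stability uses registered cell pairs: `jaccard_stability()`
(intersection over union of (cell, behavior) attributes) and
`registry_controls()` (pair shuffling without fixed points, and
closest-centroid-neighbor replacement).

## Decoding

`preprocess_activity()` convolves each event train with a centered 500 ms
boxcar (10 frames at 20 frames/s). `train_decoder()` fits one linear SVM
per unordered behavior pair — 66 classifiers for the full catalog — with
an 80/20 train/test split and per-pair 5-fold cross-validation of the
cost over 10^(−2..2). Numerical choices the upstream description leaves
open, fixed here: the test set is a contiguous block by default (a random
frame split would leak information through the 500 ms convolution; a
`block_split = FALSE` option mirrors the uninformed reading); features
are z-scored per neuron on training frames (SVMs are scale-sensitive);
training frames are capped per class (default 400; 150 during
cross-validation) for tractability. Prediction is by majority vote with
ties to the lower behavior id; accuracy is the fraction of correct test
frames; the reconstruction error is the mean behavioral distance between
predicted and observed behaviors; one-vs-rest separation uses the simple
matching coefficient (TP+TN)/N.

The chance level (`time_lag_null()`) flips the behavior series and
applies a cyclic shift by a random lag (|lag| > 30 s so lagged and
original labels decorrelate), retrains the full decoder on the lagged
labels (same split, fixed cost) and evaluates against the original
labels; 10 lags are averaged. The construction preserves both the label
marginals and the neural autocorrelations.

`subset_decode()` restricts the decoder to a neuron subset and applies
the session-eligibility floors (40 neurons for behavior-active subsets,
20 for behavior-silent/inactive subsets; under-threshold analyses return
a discarded marker, not an error). `longitudinal_decode()` trains on one
session's registered cells and tests on the other session's partners,
each session standardized by its own per-neuron statistics so that
session-level gain changes are not mistaken for tuning changes.

## The synthetic-data generator

No public recording accompanies the upstream study, so the generator
provides every input with known ground truth. What it emulates — and
what it deliberately does not — determines what a passing test suite
shows about real data.

* **Behavior stream** (`generate_behavior_sequence()`): a stationary
  Markov chain over the 12 behaviors; dwell times geometric at frame
  resolution (mean 2.5 s by default, uniform off-diagonal transitions).
  Real open-field sessions are not stationary (locomotion is more
  frequent early in a session); none of the analyses here depend on that
  drift.
* **Features** (`generate_feature_series()`): per-frame draws from
  per-behavior Gaussians (`default_feature_params()`), whose means
  satisfy the registration rules' qualitative definitions and are ≥5 SDs
  apart in at least one feature. These emulate the *smoothed* features:
  consequently the segmentation tests run directly on generator output.
  Real feature distributions are heavier-tailed and temporally
  autocorrelated within episodes.
* **Pose** (`generate_pose_track()`): an inverse construction that
  integrates a trajectory from body speed and movement angle and places
  the skeleton around it, with posture channels low-passed over 0.5 s
  (rigid per-frame jumps are not physically realizable) and head speed
  realized as rotation of the head offset plus a 4 Hz head-bob matched in
  RMS. Round-trip accuracy through `compute_features()` (documented
  tolerances, on 20-frame-smoothed features): body speed 0.6 cm/s MAE,
  movement angle 0.03 rad, lengths/elevation 0.1 cm, head speed 25%
  relative.
* **Rasters** (`generate_event_raster()`): inhomogeneous Poisson counts
  at 20 frames/s. Planted classes: **active** cells whose rate is
  multiplied by up to `active_gain` (default 5 over a 0.5 events/s
  baseline), decaying with ground-truth behavioral distance from a
  preferred behavior over scale `tuning_width`; **silent** cells with
  rate 0 for every behavior within `silent_radius` of their preferred one
  (so cells are silent during one to a few behaviors); **untuned** cells,
  homogeneous. Episode-to-episode variability is an independent
  per-neuron, per-episode lognormal gain (mean 1) applied to active
  cells. Untuned cells carry no episode gain: they are the null class
  against which detection false-positive rates are measured, and
  episode-locked gain would make them behavior-informative by
  construction. Calcium indicator kinetics, imaging noise and motion
  artifacts are out of scope — rasters model *deconvolved* events.
* **Pathway presets** (`dspn_tuning()`, `ispn_tuning()`): the dSPN-like
  preset (25% active, 8% silent, episode gain SD 0.25, tuning width 3)
  and the iSPN-like preset (15% active, 25% silent, episode gain SD 1.0,
  tuning width 0.75) encode the qualitative contrast observed in vivo:
  consistent, behaviorally graded activation in the direct pathway versus
  variable activation and silencing-biased encoding in the indirect
  pathway. In this generator the width of graded tuning is what couples
  neural to behavioral similarity, and the episode gain is what degrades
  split-half similarity; both asymmetries were fixed at design time.
* **Session pairs** (`generate_session_pair()`): `round(overlap × n)`
  shared cells (e.g. 102 of 300 at overlap 0.34), optionally remapped
  tuning in session B, plus centroids for the registration controls.
* **Perturbation** (`scramble_tuning()`): per-neuron circular time
  shifts destroy behavior locking while conserving event counts and
  autocorrelation, emulating a pharmacological disruption.

## Problem sizes and calibration checks

The acceptance checks (test suite and `scripts/acceptance.R`) use:
30-min, 300-neuron sessions with 10% planted active (gain 5), 1000
shuffles and the 4-sigma rule for detection sensitivity/false-positive
rate; a 15-min, 150-neuron session with the 10-lag time-lag null for
decoding calibration; 12-min, 300-neuron sessions for the pathway
contrasts; a 15-min session segmented with 5 t-SNE × 10 GMM replicates on
a 1000-frame subsample for end-to-end recovery (the replicate counts are
reduced from the 10 × 50 defaults — the consensus is already stable well
below 500 partitions on well-separated synthetic features); and 2000
simulated null datasets at 2000 permutations each for the type-I error of
the permutation t-test. The permutation p-value uses the add-one rule and
is never exactly zero: a zero is an artifact of finite resampling.

## Known limitations

* The registration rule engine encodes the qualitative behavior
  definitions with fixed thresholds; real clusters near rule boundaries
  need the explicit map (as the original manual registration did).
* The BI permutation null is liberal for bursty trains; use the
  circular-shift option when autocorrelation is a concern.
* Linear mixed-effects omnibus modelling is intentionally not
  re-implemented; only the permutation post hoc t-test is provided.
* Exact t-SNE limits the clustering subsample to a few thousand frames;
  this matches the subsampling design but caps how much of a session the
  archetype discovery sees (frame assignment then labels every frame).
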