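---
title: "Methods: video-based quantification and classification of motor seizure semiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based quantification and classification of motor seizure semiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Scope and model

`ictalmotion` quantifies the motor semiology of seizures captured on bedside
video and classifies three motor seizure types — hyperkinetic, tonic and
tonic-clonic — from signals derived from the pixels alone. The chain is:

1. **Motion signal.** An adaptive per-pixel Gaussian-mixture background model
   labels each pixel of each frame foreground or background; the proportion
   of foreground ("moving") pixels per frame is a one-dimensional time
   series $m_t \in [0,1]$.
2. **Oscillation signal.** Sparse corner features are tracked frame-to-frame
   by pyramidal Lucas-Kanade refinement into path histories. Within each
   non-overlapping 1-s window, paths unbroken across the window are scanned
   for *direction reversals* — changes of movement direction exceeding 90°
   between successive displacement vectors. One oscillation cycle contains
   two reversals, so a path's frequency is `reversals / 2` Hz. A 2.5 Hz
   threshold separates ictal (clonic) oscillation from slower paroxysmal
   movement.
3. **Features.** The catch22 statistic collection summarises each clip's
   motion series into 22 numbers, either on the raw series ("static") or on
   its lag-delta series $d_i = m_{i+L} - m_i$ with a 1-s lag ("temporal").
   Backward elimination reduces the 22 statistics to 5.
4. **Embedding and clustering.** Standardised (correlation) PCA fitted on
   the training cohort maps feature vectors to 2-D; testing clips are
   projected through the *frozen* transform (training means, scales and
   loadings, never refit). Agglomerative clustering (Ward linkage, k = 2 by
   default) discovers clusters in the diagram; purity against the true
   labels measures how well the unsupervised structure reflects semiology.
5. **Classification.** An MLSTM-FCN — two stacked LSTM layers (200 hidden
   units) in parallel with three temporal convolution blocks with
   squeeze-excite attention, concatenated into a softmax head, dropouts
   0.05 — classifies the motion series directly. Performance is estimated by
   leave-one-seizure-out cross-validation repeated with fresh random
   initialisations, reporting per-class accuracy (recall), one-vs-rest F1,
   and normal-approximation confidence half-widths across repeats.

## The synthetic-data generator

No public seizure-video corpus with per-frame ground truth exists, so the
package ships a generator whose clips have exactly the kinematic structure
the pipeline assumes, plus exact ground truth (per-frame body centre and
mask) for oracle testing.

A clip is a graded-intensity ellipse (the "body") over a static textured
background with i.i.d. Gaussian sensor noise (default sd 2 intensity units,
8-bit scale). The three archetypes move as:

* **hyperkinetic** — mean-reverting (Ornstein-Uhlenbeck-style) random-walk
  velocity, giving large, erratic, bounded motion (velocity relaxation 3/s,
  centre pull 4/s, displacement clamped to the amplitude box);
* **tonic** — a 1-s half-cosine ramp into a displaced posture, then a hold
  with slow drift (default 0.5 px/s at 240-px frame height);
* **tonic-clonic** — tonic kinematics for `tonic_fraction` (default 0.5) of
  the clip, then sinusoidal oscillation at `clonic_freq_hz` (default 3 Hz)
  along a fixed random axis.

Defaults: 30 fps, 240x320 frames, body 80x50 px, amplitudes 45/20/12 px for
hyperkinetic/tonic/tonic-clonic, clip durations uniform 10–120 s. Amplitude
and body size scale with frame height so smaller frames remain geometrically
faithful. Per-patient log-normal offsets (sd 0.15) and per-clip jitter
(sd 0.08) emulate inter-patient and inter-seizure variability. The generator
rejects parameter sets whose body could leave the frame and clips whose
frame rate cannot represent the clonic frequency (fps < 4 x f, a
Nyquist-style guard).

What the generator deliberately does **not** emulate: photorealistic human
figures, blankets and occlusions, caregivers entering the frame, camera
auto-exposure, depth/stereo structure, audio. Passing tests therefore show
that the *algorithms* behave as specified on data with known kinematics —
not that the pipeline's clinical accuracy on real patients is reproduced.
The paper-scale clinical numbers are not reproducible without the patient
recordings.

## Background model

Each pixel keeps up to K = 3 Gaussian components over intensity with
weights, means and variances updated online (learning rate alpha = 0.01 by
default; match gate = squared Mahalanobis distance 16, i.e. about 4 sigma;
variance floor 4, initial variance 100). A pixel is foreground when no
component with weight at least 0.2 matches the incoming intensity. The model
is initialised from the first frame (so a fresh model labels its first frame
all-background), and the first `ceiling(2/alpha)` frames are flagged as
burn-in — kept in the signal, excluded from featurization.

The depth (stereo-correspondence) filter used by hardware with a stereo
camera is out of scope here; in its place sits a pluggable chain of
binary-mask filters, defaulting to a single 3x3 morphological opening.

Validation uses two regimes. At the default slow adaptation, a body that
holds a position and then jumps produces, on the arrival frame, a foreground
mask equal to the union of vacated and occupied areas — compared against the
ground-truth changed-pixel mask (symmetric difference of consecutive truth
masks) with IoU >= 0.7. In a fast-adaptation regime (alpha = 0.5) the
model's foreground approximates the *instantaneous* changed-pixel set, and
the median motion proportion of a continuously circling body must match the
truth fraction within 25%.

## Oscillation detection choices

* Sparse corner tracking (Shi-Tomasi minimum-eigenvalue detection, 3-level
  pyramidal Lucas-Kanade, 9x9 windows) rather than dense flow: path
  histories need stable point identities.
* Steps shorter than `min_step_px = 0.5` px carry no direction information
  (sub-pixel jitter would otherwise produce spurious >90° flips); direction
  is compared between the retained steps in order.
* Windows are non-overlapping 1-s blocks; a window's frequency is the
  median over qualifying paths (robust to stray tracks), and
  `osc_fraction` is the fraction of qualifying paths at or above the
  threshold.
* The clip-level oscillation descriptor is deliberately *not* fed into the
  default feature set or classifier: on this generator, as in the
  clustering experiments the package mirrors, it does not improve cluster
  formation. `featurize_clip(..., oscillation = )` re-enables it.

## catch22 conventions

The 22 statistics are computed on the z-scored series (sample SD). The
published definitions leave a few micro-choices open; the package fixes
them as follows, and the test suite pins every statistic against an
independent numpy/scipy implementation of the same definitions (relative
tolerance 1e-6 on ten seeded series):

* autocorrelations use the denominator-N convention;
* histogram bins are right-closed, with mode = mean centre of the maximal
  bins;
* Welch spectra use a rectangular window, segment length `floor(n/4.5)`,
  50% overlap, `nfft = max(256, next power of two)`, angular frequency
  units; the centroid is the frequency where cumulative power passes half
  the total;
* fluctuation analysis uses 50 log-spaced window sizes in [5, n/2] and a
  shared-endpoint two-segment fit with at least 6 points per segment;
* constant series return the all-zero vector with a warning; non-finite
  statistics are replaced by 0 with a warning, so PCA never sees missing
  values. Series shorter than 30 samples are rejected — the statistics are
  unstable below that.

## Feature selection

Backward elimination operationalises "remove redundant statistics while the
cluster diagram stays unchanged": at each step the candidate whose removal
(a) perturbs the current 2-D embedding least (symmetric Procrustes
disparity, which allows rotation, reflection and global scaling) and (b)
drops the mean silhouette width of the true labels by at most
`sil_tol = 0.02` is removed, until `target_k = 5` remain. If no candidate
passes the silhouette guard, disparity and excess silhouette drop are
weighted 1:1. A column exactly equal to another remaining column carries no
information and is always removed first. Ties break lexicographically, so
the selection is deterministic. The embedding-stability invariant asserts
Procrustes disparity below 0.25 between the full-set and kept-5 embeddings
on the training cohort.

The five surviving statistics depend on the cohort; the selection is stored
(JSON) and user-overridable rather than hard-coded.

## Embedding and clustering choices

* Correlation PCA (standardise, then rotate): the statistics live on
  heterogeneous scales.
* Component signs are fixed (largest-magnitude loading positive) so plots
  and tests reproduce exactly.
* Default k = 2 with Ward linkage; the cluster-purity summary is computed
  on the hyperkinetic and tonic clips alone. Tonic-clonic clips are
  excluded because they say nothing about whether the two majority classes
  separate: on real data they tend to fall inside the hyperkinetic region,
  while on some synthetic cohorts their clean oscillation makes them the
  most distinct group of all, and a k = 2 cut then isolates them instead.
* Embedding axes are unitless; plots label them only PC1/PC2.

## Classifier

The MLSTM-FCN is implemented from first principles in RcppArmadillo
(forward pass, manual backpropagation, Adam). Architecture: 2 stacked LSTM
layers, hidden 200, the hidden state read at each sequence's true length;
convolutional branch with kernel sizes 8/5/3 and 128/256/128 filters, batch
norm (momentum 0.1, eps 1e-5; running statistics used at prediction),
ReLU, squeeze-excite (reduction 16) after blocks 1 and 2; masked global
average pooling over the valid region; concatenation into a softmax head;
dropouts 0.05 on both branches. Finite-difference gradient checks in the
test suite guard every parameter group.

Input preparation: the motion series (burn-in excluded) is z-scored per
clip; series longer than `max_len` are uniformly resampled down, shorter
ones zero-padded at the tail with true lengths recorded. A constant series
becomes zeros with a warning (the same degenerate convention as the feature
module).

Numerical and determinism choices:

* training and prediction run in single precision — the arithmetic
  bottleneck is the recurrent GEMM chain; the gradient-check entry point
  instantiates the identical templated code in double precision;
* all stochastic elements (shuffling, dropout) draw from a local mt19937
  stream seeded per fold, and initial parameters come from R's RNG under
  `with_seed`, so a full run is bit-reproducible for a given seed — repeat
  r of `repeated_cv()` uses `base_seed + r`, fold k of `loocv()` a seed
  derived from (seed, k);
* the default training schedule (epochs 50, batch 16, learning rate 1e-3)
  is an engineering default; no schedule is prescribed by the protocol the
  package follows.

Evaluation: per-class accuracy is the recall of the class — the only
reading under which per-class and overall accuracies are mutually
consistent; per-class F1 is one-vs-rest; overall F1 is the macro average
(classes with no true instances are excluded with a warning). Confidence
half-widths are `z_{1-alpha/2} * sd / sqrt(n_repeats)` with the exact
normal quantile (1.9600 at alpha = 0.05). The cross-validation unit
defaults to the seizure; `unit = "patient"` gives leave-one-patient-out.

## Problem sizes used by the tests and the acceptance script

Unit tests run on small frames (48x64 to 80x100) and short clips (2–9 s),
with faster background adaptation (alpha = 0.05) where burn-in would
otherwise consume the clip. The end-to-end study uses a cohort of 30
hyperkinetic + 30 tonic + 12 tonic-clonic clips over 12 patients — the
tonic-clonic scarcity mirrors the clinical class imbalance — rendered at
80x100 px, 25 fps, 12–20 s, and evaluated with 10-repeat
leave-one-seizure-out CV at `max_len = 24`, 2 epochs, batch 24, learning
rate 3e-3. These sizes are the package's chosen study conditions for a
desk-scale synthetic experiment; the expected behaviour is qualitative:
near-ceiling accuracy for the two majority classes, poor and *unstable*
tonic-clonic accuracy (widest confidence interval), because only 12
training examples exist for that class and its motion series resembles the
hyperkinetic ones. This minority-class behaviour is itself seed-sensitive:
with the short training schedule some cohorts never carve out a
tonic-clonic decision region at all, which is the same failure mode in a
more extreme form.

## Known limitations

* The generator's single-ellipse scenes cannot probe multi-person
  disambiguation, occlusion robustness or exposure changes.
* The background model assumes a static camera and grayscale input; shadow
  handling is disabled (near-infrared scenario).
* Corner tracking fails for very fast motion (more than a few px/frame at
  the coarsest pyramid level); broken paths simply drop out of the reversal
  analysis, which is the designed behaviour but reduces sensitivity.
* The 2.5 Hz filter and the reversal rule assume approximately sinusoidal
  clonic movement; irregular jerking counts reversals conservatively.
* Single-precision training means two machines with different BLAS
  libraries can diverge; bit-reproducibility is guaranteed only within one
  environment.
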