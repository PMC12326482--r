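---
title: "Robust domain-adaptive possibilistic clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust domain-adaptive possibilistic clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dadpc)
```

## The problem

EEG-based emotion recognition (and multi-subject biosignal classification in
general) suffers from severe inter-subject variability: a classifier trained
on one set of subjects degrades badly on a new subject because the feature
distributions shift between recording units. Unsupervised domain adaptation
transfers a model trained on a labeled *source* domain to an unlabeled
*target* domain. Mean-matching criteria (maximum mean discrepancy, MMD) are
the classical tool, but they compare domain *means* and are therefore
sensitive to exactly the pathology they are supposed to fix: noise- and
outlier-induced mean shifts.

`dadpc` implements a robust alternative that couples three ingredients:

1. an **adaptive robust loss** (the sigma-norm) on every residual group,
2. **possibilistic clustering with fuzzy-entropy regularization** as the
   domain-alignment criterion, replacing mean matching by cluster matching,
3. an **encoder--decoder feature learner** with a source classifier head and
   a **memory bank** of normalized features for nearest-centroid
   pseudo-labeling of the target.

## The loss family

For a matrix $Q$ with rows $q^i$ the adaptive loss is

$$\|Q\|_\sigma \;=\; \sum_i \frac{(1+\sigma)\,\|q^i\|_2^2}{\|q^i\|_2+\sigma},$$

which tends to the $\ell_{2,1}$ norm as $\sigma \to 0$ (row-wise robust,
linear growth in large residuals) and to the squared Frobenius norm as
$\sigma \to \infty$. One residual group is always one data sample; matrices
whose samples sit in columns are transposed before evaluation. The default
operating point is $\sigma = 10^{-3}$, close to the robust end.

Minimization uses iterative reweighting: at residual norm $z$ the weight

$$d(z) = \frac{(1+\sigma)(z+2\sigma)}{2(z+\sigma)^2}$$

makes the quadratic surrogate $d\,z^2$ gradient-matched to the loss
($s'(z) = 2\,d(z)\,z$), so alternating between freezing $d$ and minimizing
the smooth surrogate descends the true objective. The weight is finite at
$z=0$ (value $(1+\sigma)/\sigma$), so no epsilon floor is needed. `solve_adaptive()`
implements this scheme for arbitrary residual lists; the tests verify the
gradient match by finite differences and the descent property on random
instances.

## Possibilistic alignment instead of mean matching

The empirical squared mean discrepancy between two domains can be bounded by
a one-centroid clustering cost around the blended centroid
$\mu = \delta\mu_s + (1-\delta)\mu_t$. `mmd_clustering_bound()` reports two
versions of that bound: the form with per-domain weights $1/n^2$, and a
corrected form
$2\bigl[\tfrac1{n_s}\sum\|x^s-\mu\|^2 + \tfrac1{n_t}\sum\|x^t-\mu\|^2\bigr]$
whose proof keeps the factor 2 of the triangle inequality and the
Cauchy--Schwarz constant. Only the corrected form is guaranteed: for the
one-dimensional domains $\{0\}$ and $\{2\}$ with $\delta = 1/2$ the
discrepancy is 4 while the first form evaluates to 2. The report carries
both numbers; nothing in training uses the bound numerically — it is the
conceptual bridge from mean matching to clustering, and a diagnostic.

The actual alignment term is a *possibilistic* clustering cost on latent
features $h_i$ with class centroids $c_k$:

$$J_3 = \lambda_3 \sum_{i,k}\Bigl( v_{ik}^2\,\|h_i-c_k\|_\sigma
      + v_{ik}^2\ln v_{ik}^2 - v_{ik}^2 \Bigr),$$

where the memberships $v_{ik}\in(0,1]$ are per-cluster typicalities, not a
partition: an outlier far from every centroid receives uniformly small
memberships and is effectively ignored by the alignment — this is what makes
the criterion robust to mean shift. Stationarity of the fuzzy-entropy
objective in $u=v^2$ gives $\ln u = -D$, i.e. the closed form

$$v_{ik} = \exp\!\bigl(-\|h_i - c_k\|_\sigma / 2\bigr),$$

independent of $\lambda_3$. A printed variant of this update that sums the
distances over all $i,k$ inside the exponent (and keeps a $\lambda_3$
factor) would make every membership identical; a one-dimensional numeric
minimization oracle confirms the closed form above and rejects that variant,
so the package implements the derived form.

## Network, objective and optimization

The feature learner is a fully connected encoder--decoder with an even
number of layers $M$, bottleneck at $M/2$, and tanh activations by default.
A dedicated $K$-logit affine head on the bottleneck provides source class
probabilities (the reconstruction layer has input dimension $d$, so a
$K$-way softmax cannot index it directly). Predictions are sharpened with a
temperature, $\tilde p_k \propto p_k^{1/\tau}$ (the exponent $1/\tau$ is the
form that converges to a point mass as $\tau \to 0$); because
$p = \mathrm{softmax}(z)$, sharpening is exactly $\mathrm{softmax}(z/\tau)$.
Default $\tau = 0.5$.

The joint objective is $J = J_1 + J_2 + J_3$ with the adaptive-loss
reconstruction error $J_1 = \|H^{(M)}-X\|_\sigma^2$ over both domains, and
the sharpened source cross-entropy $J_2$ with a $\lambda_1$ sigma-norm
penalty on all weight matrices (per-row residual groups, the
feature-selection reading) and a plain $\lambda_2\,\ell_2$ ridge on biases
(biases play no role in feature selection). Whether the sigma-norm terms in
$J_1/J_2$ are reported squared (the literal reading) or unsquared (common
robust-loss practice) is a `square_sigma_terms` switch; the default is the
literal square.

Training alternates four blocks per epoch:

1. reweighting coefficients from the current residuals: per-sample
   reconstruction weights, per-row weight-matrix weights, and
   per-sample-per-cluster clustering weights;
2. gradient steps on the frozen quadratic surrogate, by exact
   backpropagation (`ae_gradients()`), on balanced minibatches holding both
   domains — full batch if `batch_size = NULL`. The surrogate is written
   without the stray $1/2$ factors so that it majorizes the unsquared
   sigma-norm objective exactly; a finite-difference test pins the gradients
   to 1e-4 relative error;
3. memory-bank refresh, pseudo-labels and centroids (below);
4. closed-form membership update.

The per-epoch surrogate and true objective, pseudo-label churn, centroid
drift and (when a truth is supplied) target accuracy are recorded in the
history; `converged()` stops when every relative change in a trailing
five-epoch window falls below `tol` (default 1e-6, default cap 200 epochs —
at full-model scale the objective stabilizes within roughly 60).

**Warm-up.** The clustering pull only makes sense once latent distances are
informative; at initialization the latent scale is so small that
$\exp(-D/2)\approx 1$ for *every* cluster, and the pull contracts the whole
representation to its barycenter. Following standard deep-clustering
practice the first `warmup_epochs` (default 20) train reconstruction and
source classification only.

## Memory bank, pseudo-labels and centroids

The bank stores one L2-normalized row per sample plus $K$ normalized
centroids; rows are replaced directly (no momentum) whenever their samples
pass through a batch. Target samples receive pseudo-labels by nearest
centroid; source labels never change. Centroids start as source class means
of the latent features (every class must be non-empty — an empty class at
initialization is an error, while an emptied cluster at refresh keeps its
previous centroid with a warning, or is re-seeded from the farthest sample
under `empty_policy = "reseed"`).

Two refresh conventions exist in the lineage of this method — averaging
source and target features together, or counting only the pseudo-labeled
target features in the numerator (the printed refresh rule does the latter
while normalizing by the pooled count, which under scale-invariant cosine
assignment is the same as a pure target mean). The package exposes both as
`centroid_source = "target"` (default) and `"pooled"`. The target-tracking
default lets centroids snap onto the target clusters — the pooled variant
anchors them halfway between domains and, before features are aligned,
misplaces the decision boundary by half the domain shift.

The trainer keeps raw-latent centroids (label-wise means) for the clustering
loss, and their unit-normalized copies in the bank; cosine assignment is
invariant to that normalization, so the two views agree. The assignment
metric is `distance = "cosine"` by default (suited to normalized
high-dimensional deep features); `"euclidean"` is available and is the
natural choice for low-dimensional standardized features such as the
synthetic study below. With `lambda3 = 0` the clustering term and the
target pooling are both ablated: the model reduces to a source-only
encoder--decoder classifier, the reference point for measuring what
adaptation adds.

Refresh cadence is per batch by default (`centroid_refresh = "epoch"`
available); reweighting is per epoch by default (`reweight_each = "batch"`
available).

## Differential-entropy features

`eeg_segment()` cuts a multichannel recording into non-overlapping 1-s
windows (trailing remainder dropped); `de_features()` computes, per window,
channel and band (Delta 1--3, Theta 4--7, Alpha 8--13, Beta 14--30, Gamma
31--50 Hz), the Gaussian differential entropy
$\mathrm{DE} = \tfrac12\ln(2\pi e\,\hat\sigma^2)$ in nats of the
band-filtered signal — the standard convention in this literature; the log
base (natural) is a documented choice. Band filtering is a zero-phase
Butterworth high-/low-pass cascade applied to the *continuous* recording
before windowing (a 1-s window cannot settle a 1-Hz high-pass). Because
forward--backward filtering squares the magnitude response, the design
places the half-power points of the zero-phase response on the band edges
and divides window variances by the filter's band-average power gain
(standard filter-bank calibration, exact for a flat in-band spectrum). With
this calibration, band-limited noise of variance $v$ recovers
$\tfrac12\ln(2\pi e v)$ to within a few thousandths of a nat; 62 channels
yield exactly $62\times5 = 310$ columns. The broadband front-end filter
(`eeg_bandpass()`, 0.3--50 Hz) suppresses DC entirely and leaves under 5% of
a 60 Hz tone at 200 Hz sampling.

## The synthetic study

`synth_recipe()`/`synth_generate()` emulate the statistical structure the
method assumes, with no external data: per-class Gaussian clusters (unit
within-class standard deviation) around simplex-spread class means per
(subject, session); a subject-specific affine shift; far-field outliers;
and optional source-label noise applied by `corrupt_labels()` (exactly
$\mathrm{round}(\eta\%\cdot n)$ labels replaced by uniformly random *wrong*
labels, so $\eta$ is an effective noise rate).

The reference conditions are 3 classes in $d=20$ dimensions, 150 samples
per class per domain, a 15-degree rotation plus a random translation of
norm 1, and 5% outliers. Two choices were genuinely open and are worth
recording:

* **Shift structure.** A generic random rotation in 20 dimensions spreads
  its displacement over all axes and barely moves class boundaries; real
  inter-subject EEG shifts are structured. The generator therefore gives
  the class means a common baseline offset (norm 9) inside the band-power
  subspace and pins the rotation's first plane to turn that baseline toward
  a random class-contrast direction: a subject-specific baseline drift
  along discriminative axes, which is precisely the mean-shift pathology
  the method targets. The remaining rotation planes are random.
* **Calibration.** Separation (4.5) and baseline norm (9) were fixed once
  so that a source-trained nearest-class-mean classifier lands mid-way
  between chance and ceiling on the shifted target (the bundled check
  asserts the [0.55, 0.85] band), leaving measurable headroom while keeping
  the target clusters recoverable by centroid tracking.

What the generator does **not** emulate: temporal structure and
autocorrelation of real EEG features, session-to-session nonstationarity
within a recording, class imbalance, and label shift. Passing the bundled
study therefore demonstrates the mechanism — robust cluster-based alignment
recovering a structured mean shift — not performance on any real dataset.

`synth_eeg()` additionally synthesizes brick-wall band-limited Gaussian
noise with exact per-band variances (frequency-domain synthesis) to exercise
the feature pipeline end to end.

The reference training configuration (`synth_study_config()`) uses a
d-64-16-64-d tanh network — compact and adequate for 20-dimensional input;
the d-500-300-500-d template remains the package default for
high-dimensional feature tables — balanced minibatches of 64, 20 warm-up
epochs, 120 epochs total, learning rate $10^{-3}$,
$\lambda_1=\lambda_2=0.01$, $\lambda_3=0.5$, and Euclidean assignment. On
the reference recipe this recovers roughly 93% target accuracy, against
roughly 77% for the $\lambda_3=0$ source-only ablation — the qualitative
collapse expected when the clustering constraint is removed — and degrades
by about one point under 25% source-label noise. The run is bit-reproducible
under a fixed seed. These numbers are recomputed from scratch by
`scripts/acceptance.R` and asserted (at their stated thresholds) by the test
suite; none are hard-coded anywhere.

## Evaluation protocols

`run_protocol()` implements the four standard validation protocols over a
(subject, session) manifest: CUCE (leave-one-subject-out, all sessions of
the held-out subject are the target; optionally one fold per held-out
session), CUSE (first session only), WUCE (per subject: sessions 1--2
source, session 3 target), and CDCV (one dataset entirely source, the other
entirely target, both directions). Accuracy is reported in percent as mean
± standard deviation over folds with a pooled confusion matrix.
`noise_sweep()` runs the label-noise robustness experiment over
$\eta \in \{0,5,10,15,20,25\}$.

`mutual_info_map()` estimates the mutual information between each feature
column and each class's prediction (hardened to labels, one class versus
rest), giving a $K \times d$ matrix min--max scaled to $[0,1]$. The default
estimator is the mixed continuous--discrete k-nearest-neighbour estimator
($k=3$; digamma identity), with a quantile-histogram plug-in fallback; a
constant feature has mutual information 0 by definition. Rendering the
matrix as a scalp topography is out of scope — the matrix itself is the
deliverable.

## Numerical choices and limitations

* Distances of exactly zero are legal everywhere: membership 1, reweight
  $(1+\sigma)/\sigma$, cross-entropy probabilities floored at $10^{-12}$.
* Assignment ties break to the lowest class index, deterministically.
* Same seed and configuration give bit-identical histories and parameters;
  there is no hidden parallelism.
* The inner solver of `solve_adaptive()` is BFGS restarted at the current
  iterate; a non-convergent inner solve is flagged in the result, and the
  outer update is only accepted if it does not increase the surrogate, so
  the descent guarantee survives inner-solver failure.
* The clustering-based alignment assumes the target classes remain
  cluster-structured and that the initial source-seeded assignment is
  majority-correct per cluster; under shifts large enough to carry a whole
  cluster into a neighbour's basin, no centroid-tracking method can recover
  the labels, and accuracy degrades sharply rather than gracefully.
* Kernelized (non-identity) MMD, convolutional or recurrent encoders, and
  pretrained deep feature extraction are out of scope; externally computed
  features can be supplied as plain tables.
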