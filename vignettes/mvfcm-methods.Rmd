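---
title: "Entropy-regularized multiview fuzzy c-means: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-regularized multiview fuzzy c-means: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvfcm)
```

## The model

A multiview dataset observes the same $K$ samples through $N$ feature
representations ("views"); view $i$ is a $K \times n_i$ matrix $X^{(i)}$.
`mvfcm()` fits one shared fuzzy partition $U = (u_{c\mu})$ ($C \times K$,
columns on the simplex), per-view cluster centers $O^{(i)}$ ($C \times n_i$),
and a simplex of view weights $W = (w_i)$ by minimizing

$$
P(U, O, W) \;=\; \sum_{i=1}^{N} w_i \sum_{c=1}^{C} \sum_{\mu=1}^{K}
u_{c\mu}^m \,\lVert x_\mu^{(i)} - o_c^{(i)} \rVert^2
\;+\; T_w \sum_{i=1}^{N} w_i \ln w_i ,
$$

subject to $\sum_c u_{c\mu} = 1$ and $\sum_i w_i = 1$. The first term is the
view-weighted fuzzified within-cluster scatter; the second is a negative
entropy penalty that keeps the weights away from the degenerate solution
(all weight on the single lowest-scatter view). Distances are squared
Euclidean, accumulated coordinate-wise — the only convention under which the
center update below is the exact stationary point.

Alternating optimization applies four closed-form coordinate minimizers per
sweep, in this order:

1. **Centers** — fuzzified means,
   $o_{cp}^{(i)} = \sum_\mu u_{c\mu}^m x_{\mu p}^{(i)} / \sum_\mu u_{c\mu}^m$.
2. **Memberships** — with aggregated distances
   $A_{c\mu} = \sum_i w_i \lVert x_\mu^{(i)} - o_c^{(i)} \rVert^2$,
   $u_{c\mu} = \big[\sum_e (A_{c\mu}/A_{e\mu})^{1/(m-1)}\big]^{-1}$.
3. **Dispersions** — per-view scatter
   $D_l = \sum_c \sum_\mu u_{c\mu}^m \lVert x_\mu^{(l)} - o_c^{(l)} \rVert^2$.
4. **Weights** — the entropy-regularized softmax
   $w_i = \exp(-D_i/T_w) / \sum_l \exp(-D_l/T_w)$.

Because each step minimizes $P$ exactly in its own block, the objective
trace is non-increasing; the fit stops when $|\Delta P| < \text{tol}$
(default $10^{-6}$) or after `max_iter` (default 300) sweeps. The
per-iteration simplex deviations are recorded in `fit$diagnostics` so
constraint conservation can be audited after the fact, not just at
convergence.

One modelling question deserves note: the membership symbol can be read
per view or shared. Training here uses a single shared partition driven by
the weight-aggregated distances — the reading consistent with a single
column normalization constraint. Genuinely per-view memberships appear only
at prediction time (below), where each view votes independently.

## Parameters

* **`m` (fuzzifier, default 2, must exceed 1).** Near 1 the partition is
  almost crisp; large values flatten memberships toward $1/C$. The update
  exponent $1/(m-1)$ is undefined at $m = 1$, so `m` is validated to be at
  least $1 + 10^{-6}$; no annealing is attempted.
* **`temperature` ($T_w$, default 1, positive).** Units of the dispersion:
  weight ratios are $\exp(-\Delta D / T_w)$. Because dispersions grow
  linearly in $K$ and in the view dimensionality, the practically useful
  range depends on problem size: $T_w \gg \max_l D_l$ pins the weights to
  uniform, $T_w \to 0$ concentrates all weight on the lowest-dispersion
  view. The default is deliberately sharp at the package's desk scales —
  with a few hundred samples it behaves like a soft view selector.
* **`centers` ($C$, default 2).** For seizure detection the natural choice
  is one cluster per class; more clusters per class are supported and then
  pooled by the cluster-to-label map.
* **`init`.** `random_membership` (default) draws each membership column
  from a flat Dirichlet; `sample_centers` seeds centers from $C$ distinct
  samples. `nstart` restarts keep the lowest-objective fit. All randomness
  flows from `seed`, and the caller's RNG state is restored on exit.
* **`scale` (default `FALSE` in `mvfcm()`, `TRUE` in
  `mvfcm_classifier()`).** See the next section.

## Why the classifier standardizes views

The weight update compares views *only* through their within-cluster
scatter, so the weights are meaningful only when the views are on a common
scale. This is sharper than the usual "normalize your features" advice.
Consider equally noisy views with identity within-cluster covariance: an
informative view (classes separated) and a pure-noise view (one Gaussian)
then have essentially *equal* within-cluster dispersion — and early in the
fit, before the partition forms, the informative view's dispersion is
*larger* by the between-class scatter, so the softmax locks onto the noise
view and the fit never recovers. After per-view z-scoring the picture
inverts: standardization shrinks the informative view's within-cluster
variance below 1 (its total variance includes the class separation), while
a noise view keeps within-cluster variance 1, so informative views are
systematically tighter and earn larger weights. `mvfcm_classifier()`
therefore standardizes every view on training statistics by default and
re-applies the stored transform to new samples; `mvfcm()` keeps `scale =
FALSE` so the bare objective can be studied on data as given.

## Classification rule

`mvfcm_classifier()` trains unsupervised, then labels each cluster by
majority vote over the training samples hard-assigned to it (argmax
membership; ties toward the lower cluster index, vote ties toward the lower
label, empty clusters inherit the global majority). For a new sample $x$,
each view computes its own membership row from view-local distances,
$u^{(i)}_c(x) = [\sum_e (d_i(x, o_c)/d_i(x, o_e))^{1/(m-1)}]^{-1}$, and the
class score is the view-weighted combination
$s_c(x) = \sum_i w_i\, u_c^{(i)}(x)$, pooled over clusters sharing a label;
the predicted class is the argmax (ties toward the lower label). The
"maximal view-weighted membership" rule is read as a sum over views of
weighted memberships rather than a maximum over views: a max over views
would discard every view but one, defeating the point of learning the
weights. View-local distances (not the weight-aggregated training form) are
used per view so that the view weights enter exactly once.

## Numerical choices

* **Memberships in log space.** $u_{c\mu} \propto A_{c\mu}^{-1/(m-1)}$ is
  evaluated as a max-shifted softmax of $-\log A_{c\mu}/(m-1)$, immune to
  overflow and underflow for distances anywhere in the double range.
* **Zero distances.** A sample coinciding with one or more centers takes
  the analytic limit: membership split uniformly over exactly the
  zero-distance clusters, zero elsewhere.
* **Weight softmax.** Computed with the max-shift; results are clamped to
  at least `1e-300` and renormalized, since the analytic softmax is
  strictly positive but `exp` underflows for dispersion gaps beyond
  ~$700\,T_w$.
* **Empty clusters.** If a cluster's total fuzzified membership falls below
  $10^{-12}$, its centers are re-seeded from one randomly drawn sample
  (same sample in every view), under the fit's seeded RNG, instead of
  producing NaN centers.
* **Ties.** All argmax ties resolve toward the lowest index, everywhere.

## EEG view construction

Segments are 1-second, 23-channel windows at 256 Hz (a geometry under which
DFT bins fall on integer frequencies). Three views are built per segment:

* **Time view**: the raw $23 \times 256$ matrix, untouched.
* **Spectral view**: per-channel one-sided DFT magnitudes at the integer
  frequencies 4–30 Hz inclusive — 27 bins covering the band where seizure
  spectral energy concentrates. Magnitude (not power) is used, making the
  view exactly linear in the signal amplitude.
* **Time-frequency view**: a level-6 wavelet packet decomposition splits
  each channel into 64 uniform 2 Hz subbands. The filter bank uses the
  orthonormal Daubechies db4 pair with periodized convolution (energy is
  conserved to machine precision), and packet nodes are ordered by
  frequency via the binary-reflected Gray code. The 14 subbands covering
  4–32 Hz are retained; a 13-band 4–30 Hz reading is arithmetically
  incompatible with a 14-deep third axis at 2 Hz resolution, so the band
  count wins and the upper edge lands at 32 Hz. Each retained node's 4
  coefficients are nearest-neighbour upsampled to the 256-point time axis
  and their magnitudes taken, giving $256 \times 23 \times 14$.

The wavelet family is a package choice (db4: compactly supported,
orthonormal, good frequency selectivity at short lengths) and the
subband-to-frequency mapping was validated against an independent wavelet
library on pure tones across the band. No filtering, artifact rejection or
re-referencing is applied; segments enter as-is.

`build_views()` flattens the three views row-major into one
`multiview_dataset` with widths 5888 / 621 / 82432 and carries labels
through.

## Deep feature extractors

Optional per-view convolutional stacks reduce the flattened views to 1024
(time), 512 (spectral) and 2048 (time-frequency) features. The layer
tables these stacks transcribe are internally inconsistent in places
(declared feature-map shapes that no stride/kernel arithmetic reproduces);
the declared output shapes are treated as authoritative, and each
convolution carries the minimal zero-padding or center-cropping per
dimension that makes the arithmetic exact. Every such adjustment is
recorded in the layer's `note` field, and `validate_extractor_spec()`
re-checks the whole chain. ReLU follows every convolution and every hidden
fully connected layer; the final feature layer is linear.

`train_extractor()` deliberately trains only a logistic readout head on the
seeded random convolutional features (full-batch gradient descent on binary
cross-entropy): random convolutional features plus a trained linear readout
are a standard, fully reproducible CPU baseline, and the multiview
clustering core never depends on this module. No claim is made that these
features match any particular trained network.

## Synthetic data: what it emulates, and what it does not

`gen_multiview_gaussian()` produces two classes as spherical unit-variance
Gaussians, `separation` standard deviations apart along the first
coordinate of every informative view; non-informative views draw both
classes from the same standard normal. Defaults (200 samples per class, two
informative 2-D views, separation 6) make the single-view Bayes error
$\Phi(-3) \approx 0.13\%$ — a regime where a correct implementation should
classify held-out samples nearly perfectly, so failures signal defects
rather than statistical bad luck.

`gen_synthetic_eeg()` emulates seizure phenomenology at toy scale: unit
white (or 1/f) channel noise, with seizure segments adding a rhythmic
sinusoid (default 5 Hz, amplitude 4 times the noise SD, random phase) on a
random subset of at least 8 channels. The 5 Hz default keeps the discharge
inside the 4–30 Hz spectral view; classic spike-wave rhythms near 3 Hz can
be configured but fall below the retained band. Neither generator attempts
physiological realism — no 1/f fits to real recordings, no artifacts, no
channel covariance — so passing tests demonstrate algorithmic correctness
and the advertised invariances, not clinical performance. Results on real
intracranial EEG depend on recording conditions, preprocessing and
train/test protocol, none of which are modelled here.

## Validation scales

The shipped checks run at desk scale, chosen to finish in minutes on one
CPU while leaving no statistical ambiguity: 50 random fits (up to 100
samples, 4 views, 4 clusters) for constraint and monotonicity audits; 100
fuzzed instances for oracle equivalence of every closed-form update
($10^{-10}$); an exhaustive $9^6$-point grid scan of the fixed 6-sample
instance for global-optimality comparison (the best-of-20-restart fit lands
within 0.1% of the grid optimum); 100 seeds for the noise-view
down-weighting property; and 20 replicate 70/30 experiments for held-out
accuracy and sensitivity.

## Known limitations

* The entropy temperature does not auto-scale with $K$ or $n_i$; weight
  sharpness is therefore problem-size dependent, and at large $K$ with
  $T_w = 1$ the weights are effectively a hard view selection.
* The shared-partition reading of the membership update is a modelling
  choice; a genuinely per-view training partition would be a different
  algorithm.
* Cluster-to-label mapping needs labelled training data and can be
  degenerate when a class never dominates a cluster.
* The alternating optimizer finds local optima; use `nstart` for anything
  beyond well-separated data.
* No streaming or per-patient protocols; decisions are per-segment with no
  temporal smoothing.
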