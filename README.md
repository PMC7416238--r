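# mvfcm

Entropy-regularized multiview fuzzy c-means clustering, with a
clustering-based classifier for seizure vs non-seizure EEG segments.

Automatic seizure detection is a binary classification problem on short
EEG windows, and the same window can be described from several
perspectives at once: the raw time series, its 4–30 Hz Fourier magnitudes,
and its wavelet-packet time–frequency envelopes. Rather than picking one
representation, `mvfcm` clusters all of them jointly — one shared fuzzy
partition, per-view cluster centers, and learned view weights that tell
you which representation carried the signal — and turns the fitted model
into a classifier. The package is aimed at researchers studying
multiview/soft clustering methods and at anyone who wants a transparent,
fully seeded reference implementation of this family of algorithms,
testable end to end without access to clinical EEG data.

## The model

For $K$ samples seen through $N$ views ($X^{(i)}$, $K \times n_i$),
the fit minimizes

$$
P(U,O,W)=\sum_{i=1}^{N} w_i \sum_{c=1}^{C}\sum_{\mu=1}^{K}
u_{c\mu}^{m}\,\lVert x^{(i)}_{\mu}-o^{(i)}_{c}\rVert^{2}
+T_w\sum_{i=1}^{N} w_i \ln w_i,
\qquad \sum_c u_{c\mu}=1,\ \sum_i w_i=1,
$$

by alternating four closed-form updates: fuzzified means for the centers,
a ratio rule on view-weight-aggregated distances for the shared
memberships $U$, per-view dispersions $D_l$, and the entropy-regularized
softmax $w_i \propto \exp(-D_i/T_w)$ for the view weights. Low-dispersion
(informative) views earn large weights; the temperature $T_w$ sets how
sharply. A new sample is classified by combining each view's local
membership row with the learned weights and pooling clusters into class
labels learned by majority vote.

The objective decreases monotonically by construction, every update has a
nested-loop oracle test, and the whole pipeline — synthetic data, view
construction, fitting, prediction, metrics — is deterministic under a
single seed.

## Worked example

Three views of the same 60 samples; views 1 and 2 carry the cluster
structure, view 3 is pure noise:

```r
library(mvfcm)

sim <- gen_multiview_gaussian(
  mv_gaussian_scenario(n_per_class = 30, n_views = 3,
                       informative = c(TRUE, TRUE, FALSE), seed = 42))
fit <- mvfcm(sim$dataset, centers = 2, scale = TRUE, seed = 42)
fit
#> Entropy-regularized multiview fuzzy c-means
#>   60 samples, 3 views, 2 clusters (m = 2, T_w = 1)
#>   objective 45.3761 after 18 iterations (converged)
#>   view weights: 1.641e-07 1 2.551e-20
```

The weights tell the story: the noise view (third) is crushed to
essentially zero, and at this problem size the default temperature acts as
a near-hard selector among the two informative views. `fit$membership`
holds the shared partition, `coef(fit)` the per-view centers, and
`plot(fit)` the objective trace.

A seeded end-to-end seizure-detection experiment — generate two-view
Gaussian data (200 samples per class, class centers 6 SDs apart), split
70/30 stratified, train the classifier, score the held-out samples:

```r
rep <- run_experiment(list(data = mv_gaussian_scenario(seed = 1)), seed = 1)
rep
#> Multiview FCM experiment report
#>   seed 1, 280 train / 120 test samples
#>   view weights: 1.239e-25 1
#>   confusion: tp=60 fn=0 fp=0 tn=60
#>   accuracy    1.0000
#>   sensitivity 1.0000
```

Accuracy is `(TN+TP)/(TP+TN+FP+FN)` and sensitivity `TP/(TP+FN)` with
seizure (label 1) as the positive class; at separation 6 the Bayes error
is ~0.1%, so a correct fit should recover the held-out labels almost
perfectly, as here.

For real or synthetic EEG, `gen_synthetic_eeg()` produces labelled
23×256-sample segments, `build_views()` turns them into the three-view
dataset, and `mvfcm_classifier()` / `predict()` complete the pipeline.
Models persist to JSON (`write_mvfcm_model()` / `read_mvfcm_model()`) with
bit-identical reloaded predictions. A thin command-line interface covering
`simulate`, `train`, `predict`, `evaluate` and `run` ships in
`inst/cli/mvfcm-cli.R`.

## Documentation

The methods vignette (`vignettes/mvfcm-methods.Rmd`) describes the model
and its assumptions, the parameters and their defaults, why the classifier
standardizes views before weighting them, the EEG view construction
conventions, the numerical safeguards, and what the synthetic generators
do and do not emulate.
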