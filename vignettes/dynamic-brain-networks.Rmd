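---
title: "Continuous-time dynamic brain networks: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time dynamic brain networks: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braindynet)
bdVerbose(FALSE)
```

## From windows to a continuous-time system

The package starts where fMRI preprocessing ends: a matrix of `m` regional
BOLD series over `T` volumes. Sliding windows of length `t` moved by step
`s` produce `floor((T - t)/s) + 1` fully contained windows (starts `0, s,
2s, ...`, half-open on a 0-based volume axis; a trailing partial window is
dropped, since only whole windows define a correlation estimate). Each
window yields a Pearson correlation matrix — an *observed snapshot* — whose
nominal time is the window center `start + (t - 1)/2`, so that predictions
and reference windows live on one common volume axis. The default scheme is
`t = 6`, `s = 5`: for `T = 140` that gives 27 observed snapshots.

Window correlations with a zero-variance segment are undefined; they are
recorded as 0 with a warning rather than propagating NaN, since a constant
segment carries no linear association evidence. Raw correlations are used
throughout (no Fisher-z transform); Pearson correlation is scale-invariant,
so no per-region normalization is applied before windowing.

## The dynamics model

The snapshot sequence is treated as sparse observations of a continuous-time
dynamical system on the brain graph. The state is the full `m x m`
correlation matrix: each node's feature vector is its correlation profile
(`d = m`). Three maps define the model:

* **Encoder** `X_h = tanh(X W_e + b_e)`, one linear layer into a hidden
  width `d_h` per node (default 16).
* **Hidden dynamics** `dX_h/dt = tanh(Phi X_h W_h + b_h)`, a single
  graph-convolutional layer. `Phi = D^{-1/2}(A + I) D^{-1/2}` is the
  renormalized operator of a static coupling graph; its spectral norm is at
  most 1, which keeps the flow well conditioned.
* **Decoder** `X = X_h W_d + b_d`, linear.

This is the minimal faithful instantiation of the encode / hidden-dynamics /
decode constraints; the activation can be switched to linear, which turns
the model into exact graph-linear dynamics and is how the integrator is
checked against closed forms (exponential decay, two-node diffusion).

An optional terminal label loss exists as a disabled hook: no node-level
semantic labels occur anywhere in this pipeline, so the objective is the
running loss alone. Subject-level classification happens downstream on graph
features instead.

**The coupling graph.** Nothing in the windowed data singles out one static
interaction graph, so the most defensible summary is used: the element-wise
mean of the observed absolute correlation matrices, proportionally
thresholded to keep the strongest 15% of off-diagonal weights (density is a
first-class knob, echoed into every output). Self-loops enter through the
`A + I` renormalization.

**Training.** The running loss is the mean per-entry discrepancy (L1 by
default; L2 available) between the decoded trajectory at the observed
snapshot times and the observed matrices. The initial value problem is
solved with a fixed-step classical fourth-order scheme (step 0.2, with a
first-order Euler option whose error visibly halves as the step halves);
gradients are accumulated in reverse through the unrolled solver steps —
the discrete adjoint of exactly the computation the forward pass performs —
and weights are updated with Adam (learning rate 0.02, 300 epochs, weight
decay 1e-4, gradient norm clipped at 5). A single seed fixes the weight
initialization, making training bit-reproducible.

Two numerical choices matter in practice and are deliberate:

* **Time is nondimensionalized by the snapshot spacing.** Internally the
  median spacing between training snapshot times becomes one time unit.
  Without this, a 140-volume subject asks the solver to integrate a
  randomly initialized nonlinear flow over ~130 time units, where tiny
  weight perturbations compound into enormous states and the loss surface
  is nearly untrainable. All user-facing times remain in volume units; the
  stored `timeScale` makes the conversion invisible.
* **The dynamics layer starts at zero.** With `W_h = 0`, `b_h = 0` the
  initial right-hand side is exactly `tanh(0) = 0`, so the first trajectory
  is constant; together with a decoder bias initialized at the mean
  observed pattern, optimization starts from a sensible stationary model
  and grows dynamics from there, instead of fighting an arbitrary drift.

**Prediction.** The trained span is `[0, T)` in volume units. In-snapshots
are interpolations at the integer volume indices `0 ... T-1` (140 for a
140-volume scan), symmetrized as `(M + M')/2`; out-snapshots continue the
integration to `T, T+1, ..., T+h-1` (default horizon 70) and are
additionally clamped to `[-1, 1]`, because extrapolated correlations may
drift out of range. Clamping never enters the training loss.

## Snapshot validation and features

Each snapshot is binarized by proportional thresholding (strongest 15% of
absolute off-diagonal weights; ties at the cutoff broken lexicographically
so the edge set is run-to-run identical). On the binary graph:

* global clustering coefficient (transitivity): `3 x triangles / connected
  triples`;
* characteristic path length: mean shortest path over connected pairs,
  computed on the largest component when the graph is disconnected (the
  common brain-network convention; the record is flagged);
* small-world indices against 20 degree-preserving rewired null graphs
  (10 attempted double-edge swaps per edge): `gamma = C/C_R`,
  `lambda = L/L_R`, `sigma = gamma/lambda`, small-world when `sigma > 1`.
  If the null ensemble has zero clustering the ratios are reported as NA
  rather than dividing by zero. Null seeds derive from one master seed plus
  the snapshot index.

The classification feature vector concatenates the clustering coefficients
of the in-snapshots and then the out-snapshots (210 values for 140 + 70).
Binary group contrasts are evaluated by stratified 5-fold cross-validation
with features standardized inside each training fold only; sensitivity is
computed on the disease group, specificity on the control group, AUC from
pooled decision scores. SVM uses a radial kernel with default
regularization, KNN uses k = 5, naive Bayes is Gaussian — all configurable,
and the fold scheme and seed are always printed in reports. An ablation
helper reruns the contrast on in-only, out-only and combined tables under
identical folds.

## What the synthetic data emulates — and what it does not

`generateSubject` draws each volume independently from a modular
correlation matrix: `nModules` contiguous region blocks with correlation
`withinCorr` inside and `betweenCorr` across blocks, plus white observation
noise (`noiseSd`, attenuating correlations by `1/(1 + noiseSd^2)`). Drift
models make the covariance time-varying: `linear_mixing` interpolates
toward a shifted block partition, `oscillatory` modulates the within-module
level sinusoidally (amplitude 0.15, period 40 volumes). A `groupEffect`
shifts the within-module correlation of one simulated group, so the induced
difference lives in network topology — exactly what the clustering feature
measures — rather than in signal amplitude. Defaults (30 regions, 140
volumes, 3 modules, within 0.6, between 0.1, noise sd 0.2) are desk-scale
stand-ins for a ~264-region, 140-volume resting-state acquisition; the full
region count generates fine but no test requires it.

What this generator does **not** emulate: hemodynamic response dynamics and
temporal autocorrelation, scanner drift and motion artifacts, spatial
heterogeneity of module sizes, and subject-level variability beyond the
seed. Consequently, passing tests demonstrate that the machinery recovers
known structure under controlled conditions — they do not certify effect
sizes or accuracies on clinical data.

`generateDynamicsTruth` provides the dynamics oracle: symmetric
matrix-valued diffusion `dX/dt = -(beta/2)(L X + X L)` on a random connected
graph, with the exact trajectory
`X(t) = e^{-beta L t/2} X_0 e^{-beta L t/2}` available in closed form via
the Laplacian eigendecomposition. Emitted snapshots carry small seeded
observation noise (sd 0.02 by default) so that additional training
snapshots genuinely carry additional information; held-out interpolation
error then decreases in expectation as training snapshots increase, which
is how recovery is tested (4, then 7, then 10 snapshots at fixed seeds).

## Evaluation conventions

Predicted snapshots at volume index `i` are compared against the Pearson
network of the BOLD segment starting at `i - 3` with the training window
length — i.e. a window centered near `i` for length 6. Indices whose
reference window would leave the series are skipped and counted, not
padded. L1 and L2 are sums over the upper triangle excluding the diagonal
(the matrices are symmetric with fixed diagonal); a per-edge normalization
is available behind a flag, and every report states which convention it
used. For out-snapshots this comparison needs BOLD data beyond the trained
span, which only synthetic data can supply; on real-length data the
evaluator refuses with an explanatory error. A window-size sweep refits the
model per candidate length and tabulates mean L1/L2 for plotting.

## Problem sizes and reproducibility

All shipped tests and the acceptance script run at desk scale: 30-region,
140-volume subjects for the end-to-end checks (one such fit takes well
under a minute on a single CPU), 5-node diffusion systems for dynamics
recovery, 10 subjects per group for classification power. One master seed
per entry point determines generators, weight initialization, null-model
rewirings and fold assignment; rerunning any stage with the same seed
reproduces its outputs bit for bit.

## Known limitations

* The static coupling graph is a modeling convenience; the dynamics layer
  sees one fixed `Phi` even though the data are time-varying.
* Fixed-step integration requires the step to resolve the snapshot spacing;
  there is no adaptive error control.
* The L1 running loss is non-smooth at zero residual; Adam with
  subgradients handles it, but very small final losses fluctuate at the
  subgradient scale instead of converging quadratically.
* Extrapolation inherits no uncertainty estimate: out-snapshots are point
  predictions of a deterministic flow.
* Disconnected binarized graphs use the largest-component path-length
  convention, which flatters very sparse densities; the disconnection flag
  is recorded per snapshot.
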