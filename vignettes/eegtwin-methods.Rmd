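---
title: "Motor-imagery EEG recognition with least-squares twin SVMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG recognition with least-squares twin SVMs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Motor-imagery brain-computer interfaces decode which movement a subject is
imagining from multichannel scalp EEG. The usable signal is an attenuation
of band-limited sensorimotor rhythm power (event-related
desynchronization, ERD) over class-specific scalp regions, typically in
the mu (8--12 Hz) or beta (13--30 Hz) range. Decoding is hard for three
reasons this package addresses explicitly: the informative frequency band
differs between subjects; recordings are contaminated by high-amplitude
ocular artifacts; and per-subject training sets are small, which favors
classifiers with strong small-sample behavior over deep models.

`eegtwin` implements the full recognition chain — artifact removal,
band-pass filter bank, Common Spatial Pattern (CSP) features with
per-subject adaptive band selection, and twin-SVM-family classification
with metaheuristic hyperparameter tuning — together with a synthetic
motor-imagery generator so that every stage is testable without any
external recording.

# Pipeline

`run_pipeline()` executes, in order:

1. **Artifact removal** (`remove_artifacts`): per-trial least-squares
   regression of every data channel on the reference (EOG) channel(s),
   with the fitted contribution subtracted. Re-estimating the mixing
   coefficients on every trial is the "adaptive" element; it tracks slow
   changes in electrode coupling. ICA-based removal is deliberately out of
   scope: regression on a measured reference is simpler, deterministic,
   and sufficient for ocular contamination.
2. **Filter bank** (`apply_filter_bank`): zero-phase Butterworth band-pass
   per band. The default bank is 4-Hz-wide bands from 4--40 Hz with 2 Hz
   overlap, covering mu and beta and giving the selection stage a grid.
3. **CSP per band** (`fit_csp`, `csp_features`): two-class CSP by
   generalized eigendecomposition; log-variance features.
4. **Adaptive band selection** (`select_band`): stratified k-fold CV
   accuracy of the classifier on each band's training-fold features;
   argmax band, ties to the lower band.
5. **Hyperparameter tuning** (`optimize_params`): PSO, chaotic PSO, GA, or
   quantum-inspired GA maximizing stratified 10-fold CV accuracy
   (`cv_fitness`) on the training folds.
6. **Held-out evaluation**: stratified outer CV; CSP fitting, band
   selection and tuning all see training folds only.

# Classifiers

**Soft-margin SVM.** `train_svm` minimizes
$\tfrac12 w^\top w + \lambda \sum_i \xi_i$ subject to
$\beta_i(w^\top \alpha_i + b) \ge 1 - \xi_i$, $\xi_i \ge 0$, solved in the
dual by SMO with maximal-violating-pair selection so arbitrary kernels are
supported. For separable data the geometric margin is $2/\lVert w\rVert$,
which the tests assert.

**Twin SVM.** Instead of one separating hyperplane, TWSVM fits one
*near-end* plane per class: plane $k$ minimizes its own class's squared
plane distances plus a hinge penalty $c_k$ on the other class's violations
of unit distance. Each plane costs one small QP of the size of the
*opposite* class; classification is by the nearer plane (perpendicular
distance; kernel-metric distance for nonlinear kernels). This geometry
handles "cross"-shaped classes that defeat a single linear hyperplane —
the package's tests construct exactly that case.

**Least-squares Twin SVM.** The package's central trainer,
`train_lstwsvm`, replaces the inequality constraints with equalities and
the hinge with a squared loss. With $H = [A\;e]$ (own class) and
$G = [B\;e]$ (other class), plane 1 solves the single SPD linear system

$$\left(G^\top G + \tfrac{1}{c_1} H^\top H + \epsilon I\right) u_1
  = -G^\top e, \qquad u_1 = (w_1, b_1),$$

and symmetrically for plane 2. Training therefore costs two linear solves
— no QP — which is the speed advantage that motivates the method for
real-time BCI. $\epsilon = 10^{-8}$ is a pure conditioning ridge; the
tests require agreement with an explicit normal-equations solve to
$10^{-8}$. For nonlinear kernels the planes are kernel expansions over the
full training set (no reduced-set approximation).

**Multiclass.** One-vs-one decomposition (`train_multiclass`), because
twin models are inherently pairwise and one-vs-rest imbalance distorts the
near-plane geometry. Prediction is by majority vote; vote ties are broken
by summed signed plane-distance margins, any remaining tie by the lower
class label. All tie-break rules (including "equidistant point goes to
class +1") are fixed so runs are reproducible.

# CSP details

Per-trial channel covariances are trace-normalized (so high-amplitude
trials do not dominate), averaged within class, and shrunk toward the
identity by a fraction `regularization` (default 0.05) for small-sample
stability. The filters solve $C_1 w = \lambda (C_1 + C_2) w$, computed by
whitening $C_1 + C_2$ and eigendecomposing the whitened $C_1$; the
retained components are pairs from both ends of the spectrum
(`n_components = 4`, i.e. two pairs, by default). Features are
$\log(v_j / \sum_k v_k)$ over retained components, invariant to global
trial scaling — plain variance would make SVM margins depend on amplitude
units.

Band selection runs *inside* the outer CV loop, on training folds only.
The alternative — selecting the band once on all data — leaks label
information into the held-out estimate; the package treats the
leakage-free reading as the only defensible one, and a dedicated audit
test poisons held-out labels and asserts that every training artifact
(selected band, tuned parameters, predictions) is bit-identical.

# Optimizers

All four optimizers maximize a user-supplied fitness (here: stratified
10-fold CV accuracy), work internally on the unit hypercube, decode
through linear or log scales, report the elitist best-so-far trace
(non-decreasing by construction), and are bit-identical under a fixed
seed. Defaults follow the study settings:

| Parameter | Value |
|---|---|
| max iterations (all) | 300 |
| population (GA, QGA) | 40 |
| bits per parameter (GA, QGA) | 20 |
| generation gap (GA) | 0.95 |
| crossover / mutation probability (GA) | 0.7 / 0.01 |
| rotation angle (QGA) | 0.01 rad |
| population (PSO, CPSO) | 20 |
| acceleration constants (PSO, CPSO) | 1.5, 1.70 |
| inertia weight (PSO, CPSO) | 0.9 linearly decaying to 0.4 |

Choices the settings above do not pin down, decided here: the PSO inertia
schedule is the canonical linearly decaying one; the chaotic sequences of
CPSO come from the logistic map $x \mapsto 4x(1-x)$ (the standard fully
chaotic choice), used once for initialization and once for a per-iteration
perturbation of the global best with linearly decaying radius, accepted
only if fitter; the QGA encodes each bit as a qubit amplitude pair
initialized to $1/\sqrt2$, measures by amplitude-squared sampling, and
rotates amplitudes toward the best individual's bits by the fixed
rotation angle (quantum "crossover/interference" operators are named in
the literature but not defined; only measurement plus rotation is
implemented). "Individual length 20" is read as 20 bits per encoded
parameter. The default search space is the standard SVM tuning range:
$c_1, c_2 \in [2^{-8}, 2^8]$ and RBF $\gamma \in [2^{-10}, 2^4]$,
log-scaled.

# Synthetic data: what it emulates, and what it does not

`generate_subject` builds each trial as 1/f^a background noise
(spectral synthesis, exact slope $-a$; default $a = 1$, RMS 5 µV) plus a
band-limited stochastic rhythm (band-pass filtered white noise — not a
pure sinusoid, which would make CSP unrealistically easy; RMS 10 µV with
10% lognormal trial-to-trial amplitude jitter). Channels are assigned
round-robin to one designated group per class; on class-k trials the
rhythm *power* on group-k channels is attenuated by $1-\mathrm{erd\_depth}$.
The informative band is the configured band shifted per subject by a
uniform draw within ±`band_jitter` (default ±2 Hz), which is what gives
adaptive band selection something real to find. Optional ocular artifacts
are high-amplitude (100 µV × gain) Gaussian blink transients (<4 Hz)
mixed into the frontal quarter of the montage with decaying weights; the
appended EOG channel carries the same waveform plus 1 µV sensor noise, so
regression-based removal can be applied and scored against the returned
ground-truth reference.

The rhythm RMS is set well above the in-band background power so that the
measured class-conditional band-power ratio tracks $1-\mathrm{erd\_depth}$
closely (the residual in-band background biases the ratio upward by a few
percent, which the generator's property test accounts for). Amplitudes are
nominal microvolts; scale is irrelevant to CSP and the SVMs but fixed for
readability.

Deliberately **not** emulated: volume conduction / realistic forward
models (channels are independent up to the class structure), within-trial
non-stationarity, mains interference, and any specific public
competition dataset's trial structure. Passing tests on this generator
therefore demonstrate correct recovery of the class-discriminative
band-power structure, not performance on real recordings.

# Numerical choices

- Filtering is an overall order-4 Butterworth band-pass applied
  forward-backward (zero phase), the de facto BCI standard, which
  preserves the covariance structure CSP relies on. Each series is
  demeaned and reflect-padded by three filter lengths before filtering;
  the first and last 0.25 s are excluded from any RMS-based assertion.
- Degenerate inputs fail loudly and early: bands at or above Nyquist,
  epochs shorter than the filter warm-up, rank-deficient covariances at
  zero shrinkage, singular LS systems at zero ridge, non-positive costs
  and bandwidths all raise targeted errors (with advice where a
  parameter can fix the problem). Constant-zero reference channels are
  skipped with a message rather than crashing the regression.
- Zero-variance trials get floored log-features with a warning.
- The LDA baseline uses a pooled covariance with ridge $10^{-6}$; the PNN
  baseline is a Parzen-window classifier with equal priors by default
  (with `priors = "proportional"` the infinite-bandwidth limit degenerates
  to the majority class, the classical sanity check).
- Reported accuracies are percentages; summaries give the mean, the
  sample standard deviation (n−1 denominator) *and* the standard error
  SD/√n. Both dispersion statistics are emitted deliberately: published
  per-subject tables of this kind sometimes label a dispersion row "SE"
  that is numerically consistent with neither, so the package always
  prints both rather than guessing. For the bundled reference table the
  recomputed means match the printed means exactly; its printed "SE" row
  matches neither statistic, and is reproduced only as data.

# Problem sizes used in tests

The bundled tests run the full pipeline at desk scale, chosen to finish
on one CPU while keeping every statistical assertion meaningful: 2
classes × 100 trials, 8 channels, 2 s epochs at 250 Hz, a 9-band
non-overlapping 4--40 Hz bank, 5 outer folds, and a PSO budget of 8
particles × 10 iterations for the tuned pipeline (the optimizer defaults
remain 300 iterations; the sphere-function benchmarks use the full
budget). Under these conditions the tuned pipeline reaches ≥ 90% held-out
accuracy at `erd_depth = 0.8`, stays inside the binomial chance band at
`erd_depth = 0` and under label shuffling, and the modal selected band
overlaps the subject's true band in ≥ 90% of seeded repeats.

# Known limitations

- CSP is strictly two-class; multiclass problems use one-vs-one pairwise
  CSP with concatenated features, not joint diagonalization.
- One band is selected per subject; features are not concatenated across
  bands (filter-bank-CSP style), matching the strict
  "optimal frequency band" reading of the pipeline.
- No probabilistic outputs or calibration; no online/incremental training.
- The EDF reader is minimal: uncompressed EDF, one shared sampling rate.
- Artifact removal operates on epochs, not continuous data.
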