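---
title: "Linking ion-channel genes to neuronal physiology with simulation-based inference"
author: "neurosbi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking ion-channel genes to neuronal physiology with simulation-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`neurosbi` implements a hybrid statistical-biophysical pipeline for
current-clamp electrophysiology. A single-compartment conductance-based
neuron model with 13 inferable parameters is fitted to voltage recordings by
neural posterior estimation (NPE), made robust to systematic model-data
mismatch by noise-augmented training (the noise-robust schedule, NPE-N), and
the fitted parameters are then predicted from ion-channel gene expression
with a rank-2 sparse reduced-rank regression (sRRR). Everything runs on
synthetic cohorts generated by the package itself, so the full pipeline is
testable without external data archives.

# The biophysical model

The membrane equation is

$$C\,\frac{dV}{dt} = \sum_i \bar g_i\, x_i(V,t)\,(E_i - V) + I_{\mathrm{inj}} + I_{\mathrm{noise}},$$

with seven currents: two sodium currents (a minimal-model Na⁺ with gates
$m^3h$ and a fast inactivating Na⁺ with gates $\hat m^3\hat h$), a delayed
rectifier K⁺ ($n^4$), a slow muscarinic K⁺ ($p$, with time-constant scale
$\tau_{\max}$), a fast non-inactivating K⁺ of the Kv3.1 family ($v$), a
high-threshold Ca²⁺ current ($q^2r$), and an Ohmic leak. Gates relax as
$dx/dt = \alpha_x(V)(1-x) - \beta_x(V)x$, so each gate approaches
$\alpha/(\alpha+\beta)$ with rate $\alpha+\beta$.

The 13 inferable parameters (see `hhParameterNames()` and
`defaultPriorBox()`) are the capacitance density $C$, input resistance
$R_\mathrm{input}$, charging time constant $\tau$, six maximal conductance
densities, the leak reversal $E_\mathrm{leak}$, $\tau_{\max}$, a threshold
adjustment $V_T$ shifting the minimal-model Na⁺/K⁺ kinetics, and $r_{SS}$, a
dimensionless multiplier on the $\alpha$ and $\beta$ of the minimal-model
Na⁺ and delayed-rectifier K⁺ gates that controls how fast those gates reach
steady state (and with it the action-potential width). The prior is uniform
and independent over the 13 ranges.

Three conventions deserve justification:

* **Units.** $C$ and the $\bar g$ are per-area densities while
  $R_\mathrm{input}$, $\tau$ and the 300 pA stimulus are absolute. The
  package derives a membrane area $A = \tau/(R_\mathrm{input}\,C)$ — the
  unique choice for which the total capacitance times the input resistance
  equals $\tau$ — and a leak density $g_\mathrm{leak} = C/\tau$; absolute
  currents convert to densities through $A$. The passive response then has
  time constant exactly $\tau$ and steady-state deflection exactly
  $R_\mathrm{input} I_\mathrm{inj}$, which is what the closed-form oracle
  tests check.
* **Kinetics and temperature.** The rate functions come from the two public
  channel model families the model is assembled from; they are frozen in the
  C++ source and pinned by tests at $-60$, $-40$ and $0$ mV. Rates are scaled
  by $Q_{10}^{(T_\mathrm{exp}-T_\mathrm{ref})/10}$ with $Q_{10}=2.3$,
  $T_\mathrm{exp}=25\,°C$, and per-family reference temperatures (36 °C for
  the minimal-model gates, 21 °C for the perisomatic ones) because the two
  families were characterized at different temperatures. All of this is
  configurable through `physConstants()`.
* **Noise.** Gaussian current noise $\mathcal N(10\,\mathrm{pA},
  1\,\mathrm{pA}^2)$ is drawn once per integration step and held for `dt`.
  Because the noise statistics are therefore coupled to the step size, the
  default `dt = 0.05` ms is part of the model definition, not merely a
  numerical knob.

Integration uses a simultaneous exponential-Euler scheme (every state
variable is conditionally linear given the others), the standard choice for
this model class. It is exact for passive membranes, keeps gates in
$[0,1]$ by construction, and bounds the voltage by the reversal potentials,
so divergence is essentially impossible; a guard still flags non-finite
states on the trace instead of raising.

# Electrophysiological features

`extractFeatures()` computes 23 summaries per trace
(`ephysFeatureNames()`): first- and third-spike threshold, amplitude,
half-height width and afterhyperpolarization depth; five spike counts (the
whole 100–700 ms stimulus window plus its first eighth, first quarter, first
half, second half); amplitude adaptation (first/second amplitude), average
consecutive-amplitude adaptation, amplitude CV; interspike-interval
adaptation (second/first ISI) and CV; latency from stimulus onset to the
first threshold; and the resting mean plus stimulus-window mean, SD and
skewness of the voltage.

Spikes are detected where the voltage derivative crosses 20 mV/ms upward;
the peak is the next local maximum; the width is measured at half of
(peak − threshold) with linear interpolation; the AHP is the drop from
threshold to the voltage minimum before the next spike (or the stimulus
end). Two refinements keep the detector honest around the stimulus step:
several criterion crossings on one upstroke collapse to the last one before
the peak, and when an upstroke's maximal dV/dt far exceeds the criterion the
threshold is re-found at 5% of that maximum (never below the fixed
criterion). Without these, the passive charging transient at stimulus onset
claims the first spike's threshold and its latency quantizes to exactly
zero.

Count-like features are log-transformed (natural log, no offset — a zero
count is genuinely undefined), the average amplitude adaptation is passed
through a logistic sigmoid, and everything else stays raw
(`transformFeatures()`). A simulation is **valid** when all 23 transformed
features are defined; because of the log rule this requires at least three
spikes *and* at least one spike in every count window and a strictly
positive latency. The fraction of valid simulations under the prior is the
headline sanity number of a campaign, and its complement is the "fail"
percentage used throughout the evaluation protocol.

Campaign features are z-scored with the mean and SD of the valid rows only
(undefined entries make any other choice impossible); `FeatureStandardizer`
objects carry that scale everywhere, and all distances are Euclidean in the
z-scored 23-dimensional space.

# Neural posterior estimation

The posterior over the 13 parameters given 23 features is a conditional
masked autoregressive flow: five stacked MADE-style blocks (50 tanh hidden
units each, order-reversing permutations between blocks) that output
per-dimension shift and soft-clamped log-scale, over z-scored parameters
conditioned on z-scored features. The flow, its exact log-density, its
sequential inverse for sampling, manual backpropagation and Adam training
with a 10% validation split and early stopping (patience 20) are implemented
in plain R; gradients are verified against numerical differentiation and the
density is checked to integrate to one. Training is deterministic under a
seed.

Training schedules (`trainingSchedule()`):

* **standard** — all valid prior simulations;
* **best_euclidean** — only the union over observations of the `k` nearest
  valid simulations in z-space (`k` defaults to `min(10000, nValid/10)`; a
  k-nearest-neighborhood union is the natural notion of "close to the
  observations" that scales from desk-size to very large campaigns);
* **noise_features** — the same subset with isotropic Gaussian noise added
  to the features, *in z-units*, so "0.1 SD" means a tenth of each feature's
  campaign SD. This is the noise-robust schedule: it smooths the feature
  manifold so the density estimator generalizes across a systematic
  simulator-data offset;
* **noise_features_params** — noise on features and parameters;
* **data_augmentation** — clean plus perturbed copies concatenated.

Sampling rejects draws outside the prior box. The MAP estimate is the
highest-density draw out of 10,000 samples, refined by box-constrained
L-BFGS-B on the flow log-density (the refinement can only increase the
density; tests assert this monotonicity). Posterior uncertainty per cell is
the Monte-Carlo entropy score $-\sum_{k=1}^{n}\log q(\theta_k\mid x_o)$ over
$n = 1000$ draws, normalized across cells by the least-entropy cell.

`evaluateFit()` implements the evaluation protocol: for each observation,
simulate the MAP parameters and 10 random posterior draws; report the
percentage of simulations with at least one undefined feature (fails),
counting fails only in the percentage, and the mean ± SD feature-space
distance over the non-failed simulations, separately for the MAP and
posterior columns.

# Gene-expression linkage

Counts are depth-normalized to CPM, log(1+x)-transformed and gene z-scored
(`preprocessExpression()`; the normalization is a package choice, recorded
with the model). `fitSRRR()` minimizes
$\|Y - XWV^\top\|_F^2$ with a row-wise (gene-wise) sparse elastic-net
penalty on the encoder $W$ by alternating a multi-response elastic-net
update of $W$ given the orthonormal decoder $V$ (via `glmnet`'s grouped
multi-Gaussian family) and an orthogonal Procrustes update of $V$ given $W$,
followed by an unpenalized reduced-rank refit on the selected genes (relaxed
fit) to remove shrinkage bias. Cross-validation pools the held-out $R^2$
over all 13 z-scored targets; when a single operating point is needed the
one-standard-error rule picks the sparsest penalty within one SE of the best
mean $R^2$ — the conventional choice when support recovery matters as much
as prediction. Group-level agreement between fitted and predicted parameter
matrices is the Frobenius distance between label-averaged matrices after
z-scoring both by the fitted set's mean and SD, and label information in
parameter space is quantified by multinomial logistic regression on a
stratified 80/20 split.

# Synthetic cohorts

`makeCells()` draws family centers uniformly in the central 60% of the
prior box and jitters cells around them with SD equal to 5% of each
parameter range (truncated to the box), keeping only parameter sets whose
simulation is feature-valid. `makeObservations()` simulates each cell,
z-scores the features, and adds a constant shift δ (z-units) plus optional
measurement noise — a nonzero δ reproduces, by construction, the situation
where experimental observations occupy a region systematically offset from
the simulation manifold. `makeExpression()` gives informative genes
log-rates `baseline + loading · z(θ)` and draws negative-binomial counts
(dispersion 0.5) with lognormal library-size variation (CV 0.3) — Smart-seq
scale overdispersion conventions. The default cohort shape (6 families,
~150 cells, 400 genes of which 20 informative) mirrors a desk-scale
Patch-seq study. `makePlantedSRRR()` is the matching fully-Gaussian plant
for benchmarking support recovery at a controlled signal-to-noise ratio.

What the synthetic data do *not* emulate: recording artifacts, electrode
drift, non-stationary firing, transcriptomic dropout structure beyond NB
sampling, or a realistic gene-gene correlation network. Passing tests
therefore demonstrate that the machinery is correct and that the
misspecification mechanism behaves as designed — not that the pipeline's
numbers transfer to any particular real dataset.

# Problem sizes, tolerances and numerical choices

* Reference campaigns in the test suite and acceptance script use
  10,000–20,000 prior simulations (the validity fraction stabilizes to
  within a percentage point by a few thousand draws); the study-scale
  campaigns this emulates are in the millions, which only sharpens the same
  quantities.
* The misspecification benchmark uses 50 synthetic observations with a
  0.5 z-unit shift in every feature, a converged standard-NPE model and an
  NPE-N model at 0.1 SD feature noise; MAP estimates in the test suite scan
  2,000 posterior samples (the acceptance script uses the full 10,000).
* The linear-Gaussian toy (`x = θ + ε`, `ε ~ N(0, 0.1²)`, `θ ~ U(-1,1)`)
  has an analytic truncated-Gaussian posterior; flow quality is asserted
  within 3 Monte-Carlo standard errors on the mean and 20% on the SD, plus a
  χ² test on simulation-based-calibration ranks.
* sRRR support recovery is asserted on a 500 × 400 plant with 20 informative
  genes at SNR 1: selected-support F1 ≥ 0.8 and cross-validated R² within
  0.05 of the oracle least-squares refit on the true support.
* Degenerate inputs: constant feature columns abort standardizer fitting;
  all-zero genes abort preprocessing; non-finite integration flags the trace
  instead of raising; a posterior whose mass leaks out of the prior box
  (acceptance < 0.1%) raises an error naming the worst dimensions; ties in
  the best-Euclidean match break to the lowest row index.

# Known limitations

* Single compartment, no calcium dynamics, fixed reversal potentials; the
  published ranges for a 13-parameter model are built in, and the visual
  cortex variant (different sodium reversal, 34 °C, inferable step
  amplitude) is reachable only through `physConstants()`/`stimProtocol()`
  configuration.
* The prior failure percentage is sensitive, at the level of a few
  percentage points, to modeling details the assembled channel variants
  leave open: the exact rate-function forms, reference temperatures, the
  unit reconciliation between per-area and absolute quantities, and the
  spike-extractor criteria.
* The flow trains on CPU in R; minutes for desk-scale campaigns, but not
  meant for million-simulation libraries.
* The latency of cells that spike within one integration step of stimulus
  onset quantizes to zero and is treated as undefined (the log transform
  demands a positive latency); such cells count as failed simulations.
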