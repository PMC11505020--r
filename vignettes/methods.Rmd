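---
title: "Models, parameters and design choices in eegensembles"
author: "eegensembles authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in eegensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery behind the five ensemble
pipelines, the parameters a user may want to touch, the synthetic data the
package uses in place of clinical EEG, and the places where the design was
genuinely open and a choice had to be made.

## The classification problem

Every sample is one epoch of multichannel scalp EEG — a window of
`epochSeconds` seconds across `nChannels` channels — carrying a binary
label: 0 (normal background activity) or 1 (abnormal, epileptiform).
Labels are per recording and inherited by all epochs cut from it;
evaluation is per epoch. All five pipelines consume a `FeatureTable`
(samples x named features) produced either by the general feature bank
(`extractFeatures`) or the Hilbert-Huang extractor (`hhtFeatures`).

## The synthetic two-class generator

Clinical EEG corpora are license-gated and far beyond desk scale, so the
package ships a generator (`generateSynthetic`) whose defaults define the
study conditions used throughout the tests:

* background: pink (1/f) noise, SD 10 µV — the typical amplitude scale of
  adult scalp EEG — plus a 10 Hz alpha rhythm of 5 µV with random phase and
  1 µV white sensor noise;
* abnormal class: Ricker-shaped spike bursts at 2 Hz whose amplitude is
  `(burstAmplitude − 1)` times the background SD (so `burstAmplitude = 1`
  is exactly the null), and additional band-limited 2–8 Hz activity scaled
  per epoch so the class-1 delta/theta band power is `bandPowerRatio` times
  the class-0 level;
* determinism: a fixed `seed` yields byte-identical arrays.

The "easy benchmark" exercised by the tests and by `scripts/acceptance.R`
uses 100 epochs per class, 4 channels at 128 Hz, 4 s epochs,
`burstAmplitude = 6` and `bandPowerRatio = 4` — a deliberately large,
cleanly separable effect. These sizes keep the full battery (including EMD
on every channel of every epoch) at desk scale; they are the package's own
benchmark definition.

What the generator does *not* emulate matters for interpreting green
tests: no artifacts (eye blinks, EMG, electrode pops), no montage or
volume-conduction structure beyond shared burst timing, no non-stationary
background drift, and a single stereotyped abnormality. Passing the
benchmark therefore demonstrates that the pipelines are implemented
correctly and can exploit band-power/spike contrasts; it says nothing
about clinical sensitivity on real corpora.

## Feature bank

Per channel and epoch: mean, variance, skewness, kurtosis, energy, peak
amplitude, absolute sum, zero crossings, line length, Hjorth mobility
`sqrt(var(Δx)/var(x))` and complexity, Shannon spectral entropy of the
normalised Welch spectrum, band powers (delta 0.5–4, theta 4–8, alpha
8–13, beta 13–30, gamma 30–45 Hz) and average spectral power, db4 DWT
sub-band energies (4 levels, periodic extension), dominant FFT magnitude,
Higuchi fractal dimension (k_max 10), rescaled-range Hurst exponent,
order-1 DFA exponent (log-spaced windows 4..n/4), and the mean absolute
inter-channel Pearson correlation. These are the most common defaults in
the EEG-feature literature; all of them are scalar per channel so the
table width is `nChannels x 28`.

Degenerate inputs are handled by rule, never by NaN: constant signals
return 0 for every variance-normalised feature, and any residual
non-finite cell is imputed with the column median (`imputeFailures`),
dropping columns with no finite entries.

Zero crossings are counted as strict sign changes between neighbouring
samples plus one event per run of exact zeros, which matches the analytic
count for sampled sinusoids regardless of phase.

## Hilbert-Huang front end

The analytic signal is built by the FFT method (negative-frequency bins
zeroed, positive doubled, DC/Nyquist kept); no quadrature evaluation of
the principal-value integral is attempted. EMD sifts with natural cubic
splines through the local extrema, mirroring the outermost extrema across
the boundaries (plain endpoint anchoring lets the envelope collapse at the
edges and manufactures large spurious low-frequency components). A
candidate IMF is accepted when the Cauchy criterion
`Σ(h_prev − h)² / Σh_prev² < 0.2` holds *and* its extrema and
zero-crossing counts differ by at most one, or after 50 sifts;
decomposition stops at `maxImfs` or a residual with fewer than two
interior extrema. The HHT feature vector is, per channel: energy fraction,
mean and SD of instantaneous frequency (interior 90% of samples, to avoid
edge effects of the phase difference), and mean instantaneous amplitude
for each of the first five IMFs (zero-filled when fewer exist), the
residual energy fraction, and marginal Hilbert-spectrum band energies on a
64-bin log-spaced frequency grid. The composition is configurable; it
replaces (rather than augments) the general bank in the HHT pipeline.

## ESCD feature selection

`escdSelect` scores features by `C_i + D_i`: relevance
`C_i = |PCC(F_i, l)| ∈ [0, 1]` and independence `D_i`, the mean Euclidean
distance of (z-scored) feature column i to all others. The two terms are
not commensurate on their raw scales — `D_i` is unbounded — so `D_i` is divided by
its maximum, landing in `[0, 1]`. A min-max stretch was considered and
rejected: after z-scoring, inter-feature distances are nearly tied, and
min-max rescaling blows that near-tie up to the full unit interval,
burying the bounded relevance term under uniform noise and measurably
degrading planted-signal recovery. Division by the maximum keeps the
relative spread and lets relevance dominate, which is what the selection
condition `max(C_i + D_i)` is for. Ties break toward the lower feature
index.

## Genetic algorithm

One gene per feature, chromosomes are 0/1 masks. Fitness is
`accuracy − λ·(selected/Q)` with `λ = 0.01`, so accuracy dominates and
smaller masks win ties. Selection is fitness-proportional roulette
(a `reciprocal = TRUE` switch weights by inverse fitness instead, which
favours the worst chromosomes); crossover is single-point with
probability 0.6; mutation hits a chromosome with probability 0.2 and then
flips each bit with probability 1/Q; ten elites survive unchanged, which
makes the best-fitness history non-decreasing. Defaults are population 300,
250 generations, iteration cap 500; the tests
and the acceptance script use reduced populations/generations suited to
their problem sizes. An all-zero mask is repaired by setting one random
bit. The hyperparameter tuner for the tree-ensemble trio uses the same
loop with real-coded genes (uniform initialisation within bounds,
single-point crossover on the gene vector, gene-resampling mutation).

## Ranking-determination ensemble

Equidistant assessment evaluates each roster model over its parameter grid
(`steps` equally spaced values, endpoints included, integer grids rounded
half-up and deduplicated — `"k, 2, 16, 4"` gives {2, 7, 11, 16}); every
grid value is fitted under the same seed, so the winner cannot depend on
evaluation order. Pruning clusters the models' 0/1 validation prediction
vectors with k-means (10 seeded restarts; at most as many centers as
distinct vectors) and keeps the most accurate model per cluster. The
ranking-determination annealer then searches inclusion vectors: start bits
Bernoulli(0.4); neighbour = flip one model drawn proportionally to its
selection probability; objective = majority-vote validation accuracy with
ties preferring fewer members; worse moves accepted with probability
`exp(−Δ/T)` under T₀ = 1 and geometric cooling 0.95 over 500 iterations;
probabilities of models inside accepted improving solutions are multiplied
by 1.1 (capped at 0.95); the best-ever vector is returned and an empty
selection is repaired to the best single model. Kappa diversity is
computed for the final member set as a diagnostic only — nothing
downstream consumes it.

The divide-and-conquer voter is a pure correctness contract: blocks of
instances (threshold 10,000 by default) are voted independently and
concatenated, and the tests check bit-identity with the plain majority
vote exhaustively for small pools and on a thousand random matrices. Ties
at exactly half the votes go to class 1 (the threshold is a `≥`); the
weighted variant thresholds the weighted sum at 1/2, the only reachable
bound when weights sum to one.

## Infinite ICA

The model is `Z = H (W ⊙ B) + E` with `Z` features x samples, mask rows
governed by `π_q ~ Beta(α/Q, 1)` (finite truncation `Q = 16` by default,
`α = 2`), unit-variance Gaussian priors on `H` and `W`, and conjugate
inverse-gamma noise. The Gibbs sampler updates the mask entry-wise with
the sample's source weights integrated out of the likelihood
(column-collapsed update). This is the one place the implementation
deliberately departs from the textbook per-entry conditional: with
explicit weights, a redundant source entry is always *individually*
essential given everything conditioned on it, so split or duplicated
sources can never be dismantled and the inferred source count sticks near
the truncation level; collapsing the weights lets redundancy die
entry-by-entry. The chain is initialised from the truncated SVD of the
centered data with an empty mask, so entries are born only where the
collapsed Bayes factor demands them and the recorded error trace falls
from the zero-model level (the trace's first entry is the pre-sweep
error; a sampler's residual is not otherwise monotone, and on pure-noise
data the final state sits at the zero-model level up to posterior
jitter). The sampler is written in RcppArmadillo so that hundreds of
sweeps on feature-table-sized problems stay cheap. The per-sample latent
representation used by the classifier is the least-squares projection
onto the active mixing columns, applied identically to training and test
samples; the posterior mask-state features (`iicaFeatures`) are also
exposed.

The random-subspace stage partitions the latent features into S disjoint
near-equal blocks (default 5). Mode `"svm"` trains one RBF-SVM per block
with its cost chosen by internal cross-validation; mode `"hybrid"` adds a
one-hidden-layer sigmoid MLP (32 units, 500 epochs by default) and an
extended KNN per block. The extended KNN assigns a query to the class
that maximises the total class-wise neighbourhood coherence of the
augmented training set — among the extended-nearest-neighbour variants
this is the classic coherence rule; on well-separated data it
coincides with plain KNN, which a test checks. With few subspaces and
class signal concentrated in a couple of features, a pure-noise subspace
can outvote an informative one — an inherent property of random-subspace
ensembles, visible in the tests' data design, not a defect.

## Bagging and the tree-ensemble trio

Bagging draws R = 25 bootstrap resamples (size n, with replacement;
single-class draws are redrawn up to ten times), fits an RBF-SVM per bag
and records the *in-bag* misclassification fraction (the error is
deliberately computed on the training subset; an out-of-bag reading is a
one-line change and was left off by design). Prediction is majority vote.

The HHT pipeline's learners are a random forest (100 trees, at most 10
leaf nodes, minimum node size 15), a gradient-boosted tree model
(eta 0.4, max depth 4, min child weight 2, gamma 0.2, max delta step 1.5,
L1/L2 = 1, 100 rounds) and a histogram/leaf-wise boosted model (10
leaves, eta 0.4) realised via xgboost's `tree_method = "hist"`,
`grow_policy = "lossguide"` — the same algorithm family as LightGBM,
which has no R build here. The GA bounds are centered on these defaults.
The tuner's fitness is 1 − CV error rate — the classification counterpart
of an average-relative-error criterion, to which it collapses for a
binary 0/1 target. The three-member vote cannot tie.

## Factor analysis and layered KNN

`fitFactorModel` runs EM for the maximum-likelihood factor model on
centered data (spectral initialisation, log-likelihood tolerance 1e-4,
at most 500 iterations, noise variances floored at 1e-6 of the mean
variance so the implied covariance stays positive definite even on
rank-deficient samples). Reconstruction `W Wᵗ + Ψ` is rotation-invariant,
which is how the tests cross-check against `stats::factanal`. On
pure-noise data any ML fit, including `factanal`, still loads a nontrivial
share of sampling structure (column norms far above 0.1), so the null
check asserts a small captured-variance fraction (at most 15%) rather
than a near-zero loading norm. Scores are posterior means.

The layered KNN uses Tukey hinges (median-of-halves) for the quartiles,
the natural convention for splitting distances into four portions; the
upper fence is the standard Tukey `Q3 + 1.5·IQR` (a stricter
`Q1 + 1.5·IQR` variant is available via `tightFence = TRUE`). Points
below the
lower fence are only labelled "class expressive"; no rejection happens
there because none is described. Layer width is `F_max/L` with
`F_max` the largest per-class farthest retained distance; layer `i`
carries weight `L − i + 1`, the reading under which inner (more typical)
members weigh more. Defaults `L = 4`, `k = 5`. The association rate is `1/distance` with an
exact-match short-circuit at zero distance; affiliation degrees are
normalised so scores sum to one and the argmax (ties toward class 0) is
the label. Fence-based rejection cascades on refit roughly 10% of the
time on Gaussian classes (removing the farthest member pulls the hinges
in), which is inherent to Tukey fences, not an implementation artifact.

## Evaluation harness

`evaluateMethod` runs stratified k-fold CV (folds balanced within class to
±1 sample) and refits *everything* — ESCD, GA, annealing, Gibbs sampling,
factor analysis — inside each training fold; a regression test
demonstrates that the honest path stays at chance on permuted labels while
a deliberately leaked variant (selection on the full data) inflates.
Metrics come from pooled confusion counts (fold-mean accuracy is also
reported); the positive class is label 1. Note that cross-validated
accuracy on permuted labels is mildly biased *below* 0.5 for flexible
learners (overfit noise rules anti-generalise); the chance-control band
used by the tests (±7 percentage points at n = 200) absorbs this.

Every fitting function takes a seed and routes all randomness through a
local RNG scope, so reports and manifests are byte-identical across runs;
KNN is implemented internally with index-ordered tie-breaks for the same
reason.

## Problem sizes

Unit tests run on tables of tens of samples; the acceptance checks use the
reference scales (ESCD: n = 200, 50 features, 100
seeds; infinite ICA: 16 x 300, 200 sweeps; factor analysis: n = 5000;
OneMax: Q = 20, population 30, 50 generations) and the package's benchmark
scale (200 epochs, 4 channels, 128 Hz, 4 s) for the end-to-end pipelines,
with reduced GA/annealer budgets (populations 8-30, 3-5 generations, 200
annealing iterations) appropriate to those sizes.

## Known limitations

* Binary labels only; no multiclass voting.
* EDF support covers uniformly sampled 16-bit recordings (one rate across
  channels); EDF+ annotations are ignored.
* The ICA preprocessing hook mentioned alongside the pipelines is exposed
  as a pass-through default; no artifact-rejection rule is guessed.
* The infinite-ICA truncation is finite (Q = 16 default); no unbounded
  Indian-buffet sampling.
* Ensemble EMD variants (EEMD/CEEMDAN) and multivariate EMD are out of
  scope.
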