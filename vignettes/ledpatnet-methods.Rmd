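---
title: "Methods: S-box textural features, TQWT and hybrid selection for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-box textural features, TQWT and hybrid selection for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledpatnet)
```

## The problem

Emotion recognition from EEG asks whether the affective state of a subject
(e.g. the emotion a computer game or film clip induces) can be decoded from
scalp potentials. The pipeline implemented here is a hand-crafted,
channel-wise approach: every electrode is treated as an independent
classification problem over fixed-length signal frames, and each frame is
described by deterministic textural and statistical features computed at
multiple wavelet scales. No deep network is involved; the learning part is a
conventional kernel SVM, which keeps the method transparent, cheap and
reproducible.

## The Led-Pattern descriptor

The core novelty is a one-dimensional *nonlinear* textural descriptor.
Classic local binary patterns compare each sample of a window against a
fixed linear template (its neighbours). Here the comparison template is the
4-bit substitution box (S-box) of the LED lightweight block cipher — a fixed
bijection on $\{0,\dots,15\}$ designed for maximal nonlinearity. For each
16-sample overlapping window $v$ of the signal, bit $k$ is

$$b_k = \mathbb{1}\left[v_k - v_{S[k]+1} \ge 0\right], \qquad k = 1,\dots,16,$$

where $S$ is the S-box (0-based values) — i.e. every position is compared
against the position the cipher's substitution table points at, with ties
($v_k = v_{S[k]+1}$) mapping to 1. Bits 1–8 and 9–16 are packed LSB-first
into a *left* and a *right* 8-bit code, and the two code streams over all
$L-15$ windows are histogrammed over 256 bins each. The concatenated
histograms give 512 features per signal.

Two consequences are worth noting and are enforced by tests:

* each histogram sums to exactly $L-15$ (mass conservation), and
* the codes depend only on *signs of differences*, so the descriptor is
  invariant to adding a constant and to positive rescaling — it describes
  waveform shape, not amplitude.

The S-box values are hard-coded from the LED cipher's published
specification (identical to the PRESENT cipher's S-box).

## Statistical moments

Each signal additionally contributes a 14-component statistical vector:
mean, sample SD, sum, an entropy-like statistic, mean absolute first
difference, corrected skewness, corrected kurtosis, median, min, max,
energy, RMS, range, and max − mean. Three conventions are deliberate and
documented because the printed formulas leave room for interpretation:

* **Entropy term.** With $p_i = x_i/\mathrm{RMS}(x)$ the statistic is
  $-\sum_{p_i > 0} p_i \log p_i$ (natural log); non-positive $p_i$
  contribute 0, which keeps the formula total on signed signals. This is
  the largest interpretive step in the module and is isolated in one place
  so it can be swapped out.
* **Median.** Element $\lceil M/2 \rceil$ of the ascending-sorted signal —
  the lower-middle element for even lengths, no interpolation, following
  the printed index arithmetic rather than the conventional median.
* **Degenerate inputs.** Zero-variance signals return skewness and kurtosis
  0 instead of dividing by zero; TQWT sub-bands of constant signals make
  this case reachable in practice.

Skewness and kurtosis use the textbook bias-corrected sample forms; the
test suite pins them against `e1071::skewness`/`kurtosis` (type 2) to
1e-10.

## Tunable Q-factor wavelet transform

The multilevel structure comes from the TQWT, an oversampled two-channel
filter bank iterated $J$ times, parameterized by Q-factor $Q$, redundancy
$r > 1$, and level count $J$. Derived scaling factors are
$\beta = 2/(Q+1)$ (high-pass) and $\alpha = 1 - \beta/r$ (low-pass), with
$\alpha + \beta > 1$. The implementation works in the DFT domain with
unitary transforms: at each level the current spectrum is split into a
low-pass part of length $2\,\mathrm{round}(\alpha^j N/2)$ and a high-pass
sub-band of length $2\,\mathrm{round}(\beta\alpha^{j-1} N/2)$, joined over
a Daubechies-style transition band
$\theta(\omega) = \tfrac12(1+\cos\omega)\sqrt{2-\cos\omega}$, which
satisfies $\theta(\omega)^2 + \theta(\pi-\omega)^2 = 1$ and therefore gives
*perfect reconstruction*; the test suite verifies round trips to 1e-8
(measured errors are ~1e-15). Band order is fixed: details from finest to
coarsest, then the final low-pass band — fusion concatenates by this index.

Numerical conventions:

* odd-length signals are zero-padded by one sample before analysis; the pad
  is recorded and stripped on reconstruction;
* `max_levels()` guards the feasible depth by simulating the size recursion
  and requiring a coarsest low-pass band of at least 8 samples (a
  documented floor avoiding degenerate bands);
* the pipeline default is $Q=2, r=3, J=17$, i.e. 18 sub-bands per frame.

## Fusion: 540 features per signal, 10,260 per frame

For one signal, the fused descriptor is the concatenation of (1) the 512
Led-Pattern features, (2) the 14 moments of the signal, and (3) the 14
moments *of the 512 Led-Pattern features themselves* — 540 features. For
one frame, the fused descriptor is computed for the raw frame and each of
the 18 sub-bands, in band order: $19 \times 540 = 10{,}260$ features, each
column carrying a provenance tag (source signal, feature kind, within-kind
index). Block boundaries are bit-exact: slicing the long vector at
540-element boundaries reproduces the per-signal extractor outputs, which
is asserted in tests.

Channel handling: each electrode is an independent pipeline (its own
feature matrix, selection and classifier), matching the per-channel
reporting convention of this literature. Long recordings are segmented into
non-overlapping 7650-sample frames (≈ one minute at 128 Hz); trailing
remainders are discarded. Variable-length trial data (the DREAMER-style
reader) is used whole per trial, since every extractor is length-agnostic.

## RFIChi2 feature selection

The hybrid selector combines the complementary strengths of two classical
rankers:

1. **ReliefF** (hand-implemented; multi-class, $k=10$ neighbours, all
   observations, Manhattan distance on min-max scaled features, miss
   contributions weighted by class prior over one minus the observation
   class's prior, uniform neighbour weighting). ReliefF produces signed
   weights; *negative-weight features are pruned* as redundant — this
   removes the threshold-selection problem.
2. **Chi-square ranking** of the survivors: each feature is discretized
   into 10 equal-width bins over its range and scored by the contingency
   chi-square statistic against the class label (empty bins dropped,
   constants score 0, ties broken by original column index). The bin count
   is a documented choice isolated behind one function.
3. **Iterative sweep**: for every candidate size $s$ in $[100, 1000]$
   (step 1, i.e. 901 candidates), the top-$s$ features are scored by the
   misclassification rate of the cubic SVM under stratified 10-fold
   cross-validation. One seeded fold partition is reused across all sizes
   so the loss curve is comparable; the minimizing size wins, ties going to
   the smallest size (parsimony). Top-$s$ sets are nested by construction.

The selection partition and the final evaluation partition are drawn from
independent seeds.

## Classification and metrics

The classifier is a *cubic SVM*: degree-3 polynomial kernel
$(\gamma\langle u,v\rangle + 1)^3$, one-vs-one multi-class coding (libsvm's
native scheme via `e1071`), box constraint 1. Features are standardized
with training-fold statistics only. The "automatic kernel scale" is
realized as a documented heuristic: $\gamma = 1/\sigma^2$ with $\sigma$ the
median pairwise Euclidean distance among up to 64 evenly spaced training
rows — deterministic, so identical seeds give identical reports. A single
seeded CV run is performed (repetitions would be a trivial extension; the
seed is exposed precisely so users can do that).

Out-of-fold predictions accumulate into one confusion matrix, from which
five metrics are computed: accuracy (trace over total), macro average
recall, macro average precision, F1 as the harmonic mean of the two macro
averages, and — reported separately because it is not part of the canonical
four — the geometric mean of per-class recalls. For balanced classes,
accuracy equals macro recall exactly.

## The synthetic generator

Real gaming-emotion and film-clip EEG corpora cannot be shipped, so the
package includes a generator whose defaults emulate their structure: 14
EMOTIV channel names, 128 Hz, 4 classes, recordings of 38,252 samples
framing into five 7650-sample segments. Each recording is a sum of two
fixed sinusoids per canonical EEG band (delta 2/3, theta 5/7, alpha 9/11,
beta 18/24, gamma 35/40 Hz) with random phases, band powers following a
class-specific profile (distinct, physiologically flavoured profiles for
the four classes), a ±20% per-recording gain jitter, and AR(1) noise
(coefficient 0.9, innovation SD 1 — a pink-ish background at roughly unit
SNR). Generation is a pure function of the seed.

The default subject count is 4 (80 frames per channel, 20 per class): large
enough for stratified 10-fold CV and a stable selection sweep, small enough
that a full default channel runs in about three minutes on one CPU core.
These sizes are the package's own study conditions for its self-tests.

What the generator does *not* emulate: 1/f broadband scaling beyond AR(1),
eye-blink/muscle artifacts, non-stationarity within a recording,
inter-channel correlation, and volume-conduction structure. Passing the
end-to-end tests therefore shows the pipeline separates classes whose
spectral band powers differ — the mechanism the method targets — but says
nothing about artifact robustness on real recordings.

## Data interfaces

Two plain-text readers cover the common corpus layouts: a gaming-emotion
CSV reader accepting both one-file-per-recording (channel columns) and
one-file-per-channel layouts, and a DREAMER-style trial reader over
`ratings.csv` plus per-trial channel CSVs, with the low/high label obtained
by thresholding the chosen affective dimension's self-rating
(`rating >= threshold` is "high"; the threshold is an explicit required
argument, since no canonical cutoff exists). Both have writer counterparts
used for round-trip testing; values are serialized with 17 significant
digits so round trips are bit-exact. Binary MAT containers are out of
scope for this package; trial data is exchanged in the documented text
layout instead.

## Known limitations

* **Select-then-cross-validate optimism.** Following the published
  procedure, RFIChi2 runs once on the full feature matrix and the final
  cross-validation then scores the selected columns. Because the selection
  step has seen every observation, the out-of-fold estimate is optimistic —
  the classic bias of non-nested selection. The package makes this
  measurable: running the full pipeline on *permuted* labels does not fall
  to chance (≈ 0.7 instead of 0.25 at the default 80 frames/channel),
  whereas permuting labels at the classifier stage alone does. An unbiased
  estimate would nest the entire selection sweep inside every CV fold, at
  roughly tenfold the cost; users comparing channels or methods should bear
  in mind that the per-channel accuracies produced by this pipeline family
  share this upward bias, which shrinks as the number of independent
  observations grows.
* The sweep refits the SVM 901 × folds times per channel; on wide feature
  matrices this dominates runtime (~3 min per channel at the defaults on
  one core). Channels are independent, so users can parallelize across
  channels without affecting results.
* The entropy-like moment follows one defensible reading of an ambiguous
  formula (see above); alternatives (absolute values, squared ratios) would
  change feature 4 but nothing else.
* ReliefF uses uniform neighbour weighting; distance-decayed variants exist
  and would slot into the same function.
* The chi-square sweep assumes the feature ranking is meaningful down to
  size 100; with fewer than 100 surviving features the range is clipped and
  logged.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes every headline
quantity from scratch: the structural feature counts, the Led-Pattern
oracle-equivalence mismatch count, the TQWT reconstruction error, the
moment-reference error, planted-feature recovery, and the end-to-end
synthetic accuracies including a permuted-label chance control. All
randomness derives from `--seed`.
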