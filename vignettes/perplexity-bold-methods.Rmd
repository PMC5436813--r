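---
title: "Stream-wise perplexity regressors for naturalistic fMRI: models and methods"
author: "perplexityBOLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stream-wise perplexity regressors for naturalistic fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

A listener processing continuous speech can be modelled as maintaining
predictive distributions over upcoming linguistic units at several levels
at once: which word comes next, which grammatical category, which phoneme.
This package quantifies the moment-to-moment unpredictability of a speech
stimulus at those three levels with trigram (second-order Markov) language
models, and asks where in the brain the blood-oxygenation-level-dependent
(BOLD) signal covaries with that unpredictability. Per word, three
perplexity covariates (lexical, part-of-speech, phonological) enter a
voxelwise GLM as hemodynamically convolved parametric modulators, together
with frequency and motion nuisance regressors. Reversed-speech runs,
fitted with the *same* regressors, act as an acoustic control: the effect
of interest is the real-minus-reversed difference of the modulator
coefficients, tested over subjects with a one-sample t statistic and
corrected by a Monte-Carlo cluster-extent threshold. Overlap between
streams is assessed with a conjunction-null (logical AND) analysis.

## Language models

For a symbol stream $w_1,\dots,w_n$ the trigram assumption is
$P(w_t \mid w_1,\dots,w_{t-1}) = P(w_t \mid w_{t-2}, w_{t-1})$. Each
token's **surprisal** is $-\log_2 P(w_t \mid w_{t-2}, w_{t-1})$ bits and
its **perplexity** is $2^{\text{surprisal}}$, i.e. the reciprocal
probability — the effective branching factor of the predictive
distribution at that token. Both identities are enforced exactly: a token
with probability 1 has surprisal 0 and perplexity 1.

Conditional probabilities are Jelinek–Mercer interpolations
$$P(w \mid u, v) = \lambda_3\,\hat P_3(w \mid u,v) +
  \lambda_2\,\hat P_2(w \mid v) + \lambda_1\,\hat P_1(w),$$
with maximum-likelihood estimates at each order, add-$k$ smoothing at the
unigram level ($k = 1$ by default), and fixed weights
$\lambda = (0.1, 0.2, 0.7)$ from unigram upward. When a history is
unattested its term falls back to the next lower-order estimate, so the
distribution over the vocabulary sums to exactly 1 for *any* history —
a property the test suite verifies against a brute-force oracle to
$10^{-12}$. This scheme was chosen over discounting methods
(Kneser–Ney, Good–Turing) because it is deterministic, normalizing by
construction, and verifiable against a trivial independent implementation;
the original analyses used an external toolkit whose smoothing
configuration is not recoverable, so exact reproduction of its perplexity
values is not attempted anywhere in this package.

Sentences are padded with two begin markers and one end marker; histories
never cross sentence boundaries, and a begin pad is never a predicted
event. Symbols rarer than `minCount` in training (default 1, i.e. no
pruning) map to an unknown marker, as do out-of-vocabulary stimulus
symbols at scoring time — they are never dropped.

Phoneme models are trained and applied **within word** by default: each
word's phoneme sequence is treated as its own padded sequence, matching
the per-word transcription pipeline and the per-word averaging of the
phonological covariate (a configuration switch enables continuous
cross-word context). A word's phonological perplexity is the arithmetic
mean of its phonemes' perplexities; its phonological frequency covariate
is the mean per-phoneme log2 relative frequency.

## Covariates and design

Per token the covariate table holds six values: trigram perplexity and
unigram log2 relative frequency at each of the three levels. Perplexities
are the regressors of interest; frequencies are nuisance covariates that
factor out sheer familiarity. The diagnostic `covariateCorrelations()`
reports their pairwise Pearson correlations; on Zipfian synthetic data
the perplexity–frequency correlations are reliably negative (rarer items
are less predictable), which the acceptance suite asserts as a sign, not
a magnitude.

Each run contributes its own design block: a word-duration boxcar
regressor, the three perplexity modulators, the three frequency
modulators, six motion parameters and a run constant, stacked
block-diagonally so real and reversed runs of the same story receive
separate coefficients for identical story-derived regressors. Parametric
modulators are built by scaling duration-matched boxcars with
mean-centered amplitudes at microtime resolution (16 bins per TR, TR =
0.88 s), convolving with the HRF, and downsampling to the TR grid.
Mean-centering makes the modulator carry only the covariate's variance
around its mean; no further orthogonalization is applied, so shared
variance among modulators is partialled by the joint OLS fit itself
rather than by an order-dependent scheme.

The HRF is a canonical double-gamma difference (peak 6 s, undershoot
16 s, dispersions 1 s, undershoot ratio 1/6, 32 s support),
peak-normalized to 1. Each gamma is parameterized so that its *mode* sits
exactly at the stated delay (shape = delay/dispersion + 1); with the
common alternative parameterization the "6 s peak" kernel actually peaks
at 5 s, which we regard as a misnomer. No temporal or dispersion
derivatives are included. No high-pass filter is applied by default
(none is part of the modelled acquisition); the GLM is plain OLS without
prewhitening — group inference runs on contrast differences, which is
robust to subject-level autocorrelation misspecification.

## Group statistics and cluster correction

Per subject and covariate, the contrast is the voxelwise
$\beta_{\text{real}} - \beta_{\text{reversed}}$, averaged over story
pairs. The group map is the one-sample t over subjects
(df = n − 1); voxels with zero between-subject variance are flagged NA
rather than infinite. Voxel thresholding is one-tailed positive at
p < 0.005 by default (the modelled analyses report activations;
two-tailed is available).

Spatial smoothness is estimated from the per-axis variance of first
differences of standardized residual fields: with
$\rho = 1 - \mathrm{var}_{\text{diff}}/2$ the FWHM of the equivalent
Gaussian *smoothing kernel* is
$\text{voxel} \cdot \sqrt{-2\ln 2 / \ln \rho}$ (a field smoothed with a
kernel of sd $\sigma$ has autocorrelation $e^{-\Delta^2/4\sigma^2}$,
hence the factor 2 difference from the field-ACF formula). In the
pipeline the smoothness entering the cluster simulation is estimated
from each subject's GLM residual series and averaged over subjects.
Residuals are the right substrate because the model has absorbed the
stimulus-locked signal: estimating smoothness from contrast or stat
maps instead lets any sharp spatial structure of real effects
masquerade as roughness, biasing FWHM low and the extent threshold
anticonservative (we measured exactly this on synthetic data with
box-shaped planted effects).

The cluster-extent threshold k is calibrated by Monte-Carlo simulation
(1,000 iterations by default): white Gaussian noise is smoothed to the
estimated FWHM, standardized within the mask, thresholded at the upper
voxel-p quantile, and the maximal cluster extent recorded; k is the
smallest size whose familywise exceedance proportion is ≤ 0.05, and
clusters of size exactly k survive (the threshold is inclusive).
Connectivity is 26-neighbor by default and is enforced to match between
simulation and application. Sub-voxel FWHM axes skip smoothing.
Conjunctions are voxelwise logical ANDs of significant maps —
commutative, associative, idempotent set intersections.

## What the synthetic generator emulates

The generator stands in for resources the analysis normally takes from
corpora and a scanner, and is a first-class, tested module:

* **Lexicon** — `vocabSize` (default 500) word types with Zipfian
  frequency weights (exponent 1). Base tags come from a 3-category
  tagset (N/WW/LID with 4/3/2 subcategories); assignment is
  mass-balanced so each category's realized Zipf mass matches its target
  share, keeping the token-level word distribution globally Zipfian.
  The target shares are the stationary distribution of the tag
  transition matrix, so chain-generated text realizes the same masses.
  Phoneme transcriptions come from a shared consonant–vowel phonotactic
  process over a 30-symbol inventory with Zipf-weighted symbol choice.
  An early design that drew phoneme strings i.i.d. per word made
  phonological perplexity a proxy for word rarity (the phoneme trigrams
  of rare words were themselves rare), coupling the streams far more
  strongly than real data; shared phonotactics restores the near
  decoupling seen in real stimuli.
* **Corpora** — sentences sample a base-tag Markov chain (articles
  prefer nouns, nouns prefer verbs) and then a word per tag by
  within-category Zipf weights; the default training set is 50,000
  sentences of mean length 8. Word, PoS and phoneme corpora are
  token-aligned.
* **Transcripts** — word onsets accumulate exponential inter-word gaps
  (2 words/s), durations scale with phoneme count (60 ms/phoneme,
  120 ms floor); three stories of 150 s each (~300 words), each with a
  reversed-speech partner run.
* **BOLD** — 20×20×20 voxels of 3.5 mm, TR 0.88 s, 12 subjects.
  Signal: each covariate's design regressor times a planted amplitude
  inside its ROI, in real runs only (reversed runs carry no
  stimulus-locked signal — the operational meaning of the control
  condition). Amplitudes are stated as `effectSD`, the standard
  deviation of the planted signal time course in BOLD units (default 1,
  equal to the noise sd), which fixes effect size independently of
  covariate scale. Noise: voxelwise AR(1) (coefficient 0.3) with white
  innovations, spatially smoothed to 7 mm FWHM and restandardized; the
  signal itself is not smoothed, so planted ROIs have sharp edges and
  noiseless recovery is exact. Between-subject amplitude jitter is 10%.
  Motion parameter series are slow random walks regenerated per subject.
* **Ground truth geometry** — three ROI boxes spanning fixed fractions
  of the volume: lexical and phonological cores at opposite ends, the
  PoS ROI bridging both, pairwise overlaps non-empty but the three-way
  intersection empty. The lexical/phonological gap is about a third of
  the x extent (21 mm at default scale, roughly three noise FWHMs) —
  deliberately wide, because cluster-extent inference carries no
  voxel-level localization guarantee: suprathreshold noise voxels on
  the edge of a genuine cluster survive with it, so exclusive zones
  separated by less than a few correlation lengths would show spurious
  conjunction voxels at the boundary.

What passing tests on these data do **not** show about real data:
synthetic phonology is not a real phonotactic grammar, the tag chain has
no long-range syntax, noise has no physiological or scanner artifacts,
and planted effects are spatially uniform boxes. The simulations
validate the estimator chain (unbiasedness, calibration, error control,
selectivity), not linguistic or neural claims.

## Numerical and degenerate-input decisions

* N-gram keys join symbols with the unit-separator character; corpus
  symbols may not collide with the reserved markers.
* Zero probability can occur only with smoothing disabled; surprisal
  then returns `Inf` with a warning.
* A zero-count symbol's log2 frequency uses the add-k estimate so
  covariate tables stay finite.
* Event intervals are half-open [onset, onset + duration); events
  beyond the run end are rejected with their index.
* Rank-deficient designs are rejected with the offending columns named
  (QR with pivoting).
* Residuals rougher than white noise on an axis
  ($\mathrm{var}_{\text{diff}} \ge 2$) flag a warning and fall back to
  FWHM = voxel size; spatially constant residuals are an error.
* The extent-threshold search is over integers; ties in cluster
  labeling are broken by decreasing size, then first occurrence.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state on exit; derived stage seeds stay below $2^{31}$.

## Problem sizes used by the validation suite

Unit tests run on toy corpora (≤ 50 tokens) where brute-force oracles
are exact. The acceptance checks use: 10 seeds × 2,000 training
sentences for the correlation-sign test; a 20³ volume with 12 null
subjects for voxel-level calibration; 1,000 extent simulations plus 200
fresh null volumes for familywise error; and one full default-scale
pipeline run (50,000 training sentences, 3 story pairs, 12 subjects,
20³ voxels, 1,000 simulations) for end-to-end selectivity. These sizes
were chosen to preserve every statistical structure the analysis relies
on while keeping a desk-scale footprint.

## Known limitations

* Fixed interpolation weights rather than held-out optimization; the
  weights are configurable but not tuned.
* OLS without prewhitening at the subject level (AR(1) prewhitening is
  a config flag away but off by default, matching the modelled
  analysis).
* The Monte-Carlo null assumes stationary Gaussian smoothness; real
  fields with nonstationary smoothness would need a different
  correction.
* Smoothness estimation from n = 12 contrast maps is noisy; the
  simulation uses whatever the estimator returns, which keeps the
  procedure internally consistent but inherits that variance.
* The conjunction analysis tests the conjunction null (significance in
  every map), which is conservative relative to global-null conjunction
  tests.
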