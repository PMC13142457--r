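---
title: "Decoding and geometry of compositional speech-preparatory codes"
author: "phonoplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and geometry of compositional speech-preparatory codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoplan)
```

# The scientific problem

When a speaker prepares to say a word, premotor population activity during
the instructed delay of a cue–delay–go task carries information about the
*whole* upcoming phoneme sequence, not just its first element. phonoplan
implements the analysis toolchain for characterizing such preparatory codes
from binned multielectrode array features (threshold-crossing counts and
spike-band power at 20 ms resolution): diagonal-regularized linear
discriminant decoding with cross-validated AUC, decoder generalization
across time, task epochs and sequence positions, displacement-vector
representational geometry, a position-specific linear encoding model, and
the supporting electrode-level statistics.

Because raw clinical-trial recordings of this kind are not publicly
deposited, the package is built around a synthetic session generator that
realizes the generative structure the analyses presuppose, with an exactly
known ground truth. Every stage of the pipeline is validated by parameter
recovery on simulated sessions rather than by comparison to irreproducible
neural data.

# The task model

Cue conditions are ordered consonant sequences embedded in a fixed-vowel
template (e.g. `KahNahSH` for a CVCVC frame with consonant slots
C1, C2, C3). `buildFullFactorial()` enumerates the full factorial of an
inventory over a number of slots (4 consonants x 3 slots = 64 conditions;
3 x 3 slots = 27) in deterministic lexicographic order, so condition
indices are reproducible. `buildWordBoundarySet()` doubles a factorial set
into matched one-word and two-word presentations of the same consonant
string (3 consonants x 4 slots = 81 sequences, 162 conditions), differing
only in a phonological word boundary after a chosen slot. Slot indexing in
every user-facing interface is 1-based, matching the C1VC2VC3 convention.
The do-nothing control is a reserved `NA` label, never counted among the
factorial conditions.

# The generator and its ground truth

`makeGroundTruthCode()` draws, in a latent space of one dimension per
electrode, a linear compositional code:

* **Phoneme vectors** `b[p, j]` per slot `p` and consonant `j`: unit norm,
  mutually equidistant, and zero-sum within each slot. The zero-sum gauge
  is the identifiability convention under which the one-hot + intercept
  encoding model has a unique recoverable answer.
* **Cross-position alignment.** The like-phoneme cosine between slots `p`
  and `q` equals a requested Gram matrix entry exactly (to numerical
  precision), by factoring the alignment matrix with an eigen square root
  and mixing banks of orthonormal latent directions. An alignment target
  that is not positive semidefinite is rejected as infeasible.
* **Position gains**, a **sequence-length axis** and a **word-boundary
  axis**, both orthogonal to all phoneme vectors; a **boundary gain** in
  [0, 1] that multiplies phoneme vectors of slots after the first word
  boundary during the preparatory epoch only (0 = the plan is truncated at
  the boundary); **per-epoch gains** scaling the shared code in the cue,
  preparatory and speech epochs; and optional **epoch-private codes**,
  orthogonal across epochs and to the shared code. With the default
  epoch-private gain of 0, cross-epoch generalization is perfect by
  construction; setting the shared epoch gains to 0 and the private gain
  above 0 makes within-epoch decoding succeed while cross-epoch
  generalization fails — the two regimes that make generalization analyses
  testable.

`simulateSession()` renders a trial plan into a trials x bins x features
tensor. Each latent channel is read out as two feature streams (count and
power) with independent noise, mirroring how both estimates of multiunit
activity are concatenated in array analyses. Noise is additive Gaussian on
the latent z-score scale by default (every in-scope analysis consumes
z-scored features); a Poisson-count mode clips rates at zero and draws
integer counts. Slow drift is a per-block constant offset, which
block-wise mean subtraction in `zscoreSession()` removes — the same
correction used on real sessions.

**Signal-to-noise convention.** `snr` is defined at the population level:
the total standard deviation of the noiseless preparatory-epoch condition
means across the latent population vector, divided by the per-bin,
per-channel noise standard deviation. At the default `snr = 2` with 64
electrodes, an individual channel carries weak per-bin signal (on the
order of 0.25 noise SD), as in real array data, and decoding power comes
from pooling channels and time bins. We chose a population-level rather
than per-channel definition deliberately: it keeps per-channel variances
nearly homogeneous, so whole-session z-scoring is close to a uniform
rescaling and does not distort the code's cosine geometry. A per-channel
definition of the same nominal value would concentrate so much variance in
signal-bearing channels that z-scoring itself would attenuate recovered
cosines by 20-30% — an artifact of the scaling convention, not of the
analyses.

**The non-compositional control.** `makeNonCompositionalCode()` draws an
independent random mean per condition and projects out the entire additive
subspace (position x phoneme one-hots, length, boundary, intercept),
leaving pure interaction structure. This is the strongest possible
negative control: an unstructured random draw still contains additive main
effects by chance (roughly half the marginal group-mean variance in a
3-consonant factorial), which a linear encoding model legitimately
captures; projecting the additive part out is what makes "no compositional
structure" literally true of the ground truth.

# Preprocessing conventions

All window times are in seconds relative to a named trial event
(`cue_onset`, `cue_offset`, `go_cue`, `speech_onset`); bins are half-open
`[start, start + 0.02)` with bin 0 starting at the event, so a bin starting
exactly at a window's end is excluded. Sliding windows of width `w` advance
in steps `s` from the span start while they fit, giving
`floor((span - w)/s) + 1` windows. PSTH smoothing uses a Gaussian kernel
(sigma 60 ms = 3 bins) truncated at four sigma and renormalized at the
edges rather than padded, so constants are preserved everywhere including
boundaries. Trials whose recording does not cover a requested window are
dropped and counted, never silently imputed.

# The decoder

`fitDiagLDA()` implements Fisher discriminant analysis with the pooled
within-class scatter replaced by its diagonal: with tens of trials and a
hundred-plus features, the full within-class covariance is unestimable,
and treating features as conditionally independent given the class is the
regularization of choice. The discriminant directions are the eigenvectors
of `D^-1 B`, computed through the symmetric form
`D^-1/2 B D^-1/2` in the K-dimensional class-mean row space for numerical
stability, and verified in the test suite against a literal dense
eigensolve of `D^-1 B` (principal angles below 1e-8, measured with the
sine-based formulation, since the arccosine form saturates at the square
root of machine epsilon). Degenerate variances are guarded by a floor of
`1e-8 + 1e-6 * mean(d)`; eigenvalue order is descending and each
component's sign is fixed so its largest-magnitude entry is positive —
conventions the underlying mathematics leaves free, fixed here for
reproducibility.

Binary decoders score a trial by the inner product between its projection
(relative to the projected class-mean midpoint) and the projected
class-mean difference; the logistic of that score is the class
probability. AUC is rank-based with midrank tie handling; since AUC is
invariant under strictly monotone transforms, the logistic is a
convenience, not a modeling choice (this invariance is itself tested).
Multiclass decoding scores a trial by negative distance to the projected
class means and evaluates with one-vs-rest AUC averaged over classes, plus
balanced accuracy normalized as `(BA - 1/K)/(1 - 1/K)`.

Cross-validation pools held-out scores across folds — every sample is
scored exactly once by a model never trained on it — with leave-one-out
for pairwise decoders and stratified k-fold for multiclass analyses. One
estimator property worth knowing: on signal-free data, pooled
cross-validated decoding sits slightly *below* chance, because removing
the held-out trial pulls its own class mean away from it; the effect is
strongest for leave-one-out and grows with cluster structure in the
features. The package treats this as what it is — a small, well-understood
pessimistic bias — and the leakage sentinel checks are accordingly
one-sided where a single small session is used, or averaged over label
shuffles (and run with stratified folds, which roughly halve the bias)
where a two-sided chance band is asserted.

# The analyses

* **Pairwise position decoding** fits one binary decoder per pair of
  conditions differing in exactly one slot, pools held-out probabilities
  per pair, and averages AUC over pairs; significance is a one-sided
  one-sample t-test of per-pair AUCs against 0.5 with BH-FDR across the
  family the caller declares. Window defaults follow the figure each
  analysis mirrors (0.8 s preparatory for the pairwise summary, 0.7 s for
  geometry and encoding, 0.6 s for sequence length, 0.5 s for the
  word-boundary analyses) and are explicit arguments everywhere.
* **Cross-time generalization** trains at every sliding fit window
  (100 ms width, 60 ms step) under leave-one-out and scores each held-out
  trial at every test window, masking fit times covered by fewer than
  `minTrials` trials (default 900, the convention for large sessions;
  configurable because synthetic sessions are smaller — the mask is
  reported, never silently applied).
* **Cross-epoch generalization** anchors 0.5 s cue and speech windows on
  each epoch's peak within-window decoding time (first bin on ties), takes
  the 0.5 s before the go cue as the preparatory window, trains on cue
  features and tests on all three windows.
* **Cross-position generalization** trains a multiclass decoder on
  consonant identity at one slot and evaluates the same held-out scores
  against another slot's labels, normalized as
  `(AUCcross - 0.5)/(AUCwithin - 0.5)` so that 1 means full transfer and
  0 chance; this ratio is invariant to joint feature rescaling.
* **Geometry**: wildcard marginal means (`*ah*ahSH`-style groupings),
  displacement vectors between nested groupings (count-weighted zero-sum
  within each base group on balanced designs), best-fit 2-D plane variance
  by SVD, and the leave-one-condition-out compositional predictor. The
  donor scaling rule — the ratio of mean displacement norms between target
  and donor lengths, with the held-out class excluded from its own
  length's estimate — is the simplest rule consistent with
  magnitude-matched donation, and is pluggable (`scale`, `donors`
  arguments). R-squared in discriminant space is a single multivariate
  statistic (pooled sums of squares), which weights components by their
  variance.
* **Encoding model**: closed-form ridge (`alpha = 0.5` on the summed
  squared coefficients, intercept unpenalized, predictors uncentered) of
  window-averaged z-scored activity on one-hot position x phoneme
  predictors; stratified 3-fold held-out predictions pooled; single-trial
  R-squared averages per-feature R-squared uniformly so every electrode
  counts equally; condition-averaged R-squared is computed on group means
  after marginalizing slot 1. Coefficient similarity refits on all trials
  and summarizes each slot pair by the mean cosine over like-phoneme
  coefficient pairs. Note the condition-averaged metric is
  noise-ceiling-relative: it is meaningful when condition structure
  exists, but on *label-shuffled* data the pooled-CV group means correlate
  with the model's fitted marginals and the metric does not sit at zero —
  the leakage sentinel therefore uses the single-trial metric.
* **Statistics**: Welch tests with the propagated standard error
  `sqrt(s1^2/n1 + s2^2/n2)` and Welch–Satterthwaite degrees of freedom
  (the standard square-root form of the propagated SE); Kruskal–Wallis
  position-tuning tests; BH step-up FDR over explicitly declared families;
  percentile bootstrap (10,000 default); permutation p as the raw fraction
  of null draws at or beyond the observed value, with the resolution floor
  `1/nPerm` reported so `p < 1e-4`-style statements are reproducible.

# What the generator does and does not emulate

The generator reproduces the structural features the analyses rely on:
factorial condition designs with balanced repeats, epoch structure with
optional delay jitter, two feature streams per electrode, block drift,
controllable alignment/gain/length/boundary/epoch structure, and Gaussian
or Poisson observation noise. It does not emulate temporal dynamics within
epochs (ramps, transients, oscillations), electrode failure or
nonstationary tuning, correlated noise across channels beyond the shared
latent signal, behavioral variability in speech onset, or annotation
error. Passing tests therefore demonstrate that the analysis chain
recovers the truth *under the stated generative assumptions* — they bound
implementation correctness, not the validity of those assumptions for real
recordings.

# Problem sizes and reproducibility

Simulations in the test and acceptance suites use 27-condition factorial
sessions with 12–30 trials per condition, 128 features (64 electrodes),
and population SNR 2; the word-boundary analyses use the 162-condition set
with 5 repeats; resampling procedures in tests run at reduced counts
(tens to hundreds) while package defaults remain at the conventional
10,000. These sizes were chosen once as representative desk-scale study
conditions: decoding and recovery saturate well below them, and all
reported properties (alignment recovery within 0.1, compositional vs
random R-squared separation, epoch-transfer contrast, boundary truncation)
are stable across seeds at these sizes. Every stochastic step takes an
explicit seed; identical configurations reproduce bit-identical sessions
and summaries.

# Known limitations

* The diagonal within-class approximation ignores noise correlations; on
  data with strong shared noise a full-covariance or shrinkage LDA would
  differ. The diagonal form is the implemented, tested contract.
* Chance-level AUC from pooled cross-validation is biased slightly below
  0.5 on null data (see above); comparisons against chance are one-sided
  by design.
* The compositional predictor's donor scaling assumes displacement
  magnitude differences across lengths are a scalar; a per-direction
  rescaling is not modeled.
* Session tensors are dense in memory; a full session at the defaults is
  tens of megabytes, and very long recordings would need chunked storage.

# A worked example

```{r example, eval = FALSE}
set <- buildFullFactorial(c("K", "N", "SH"), 3)
cfg <- generatorConfig(nFeatures = 128, snr = 2)
code <- makeGroundTruthCode(set, cfg, alignment = 0.6, seed = 1)
plan <- makeTrialPlan(set, 20, seed = 2)
ses <- zscoreSession(simulateSession(code, plan, set, cfg, seed = 3))

pairwisePositionDecoding(ses, 2, epochWindow("go_cue", -0.8, 0))$meanAUC
g <- crossPositionGeneralization(ses, 3, 2, seed = 4)
g$normalizedGeneralization

ext <- extractWindows(ses, epochWindow("go_cue", -0.7, 0), mode = "average")
cs <- coefficientSimilarity(set, trialLabels(ses)[ext$trials], ext$matrix)
cs$summary   # like-phoneme cosines per slot pair, ~0.6 by construction
```

The scenario runner wraps these chains end to end
(`runScenario(list(scenario = "fig2_geometry_encoding", seed = 1))`), and
`scripts/acceptance.R` recomputes the package's headline quantities from
scratch for a given seed.
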