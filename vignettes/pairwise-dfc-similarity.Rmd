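---
title: "Pairwise dynamic-FC similarity for few-shot early-MCI detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise dynamic-FC similarity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early mild cognitive impairment (eMCI) is the prodromal stage of
Alzheimer's disease at which intervention is most useful and detection is
hardest: structural change is minimal, labeled cohorts are small, and the
most promising markers are functional — altered statistical coupling
(functional connectivity, FC) between brain regions in resting-state fMRI.
`siamfcn` implements a metric-learning classifier for this setting.  Rather
than learning a decision boundary in feature space, it learns to *compare*
subjects: a query scan is assigned the class whose labeled support scans it
most resembles, which is the natural formulation when only a handful of
labeled examples per class (a "2-way K-shot episode") can be assumed.

The package consumes ROI-by-time BOLD matrices (parcellation and all image
preprocessing are upstream) plus a manifest binding scans to subjects and
labels ("NC" or "patient").

## The model

**Dynamic FCN.** For a scan with N ROIs and M time points, a sliding
window of length `w` and step `s` (both in time points) yields
K = ⌊(M − w)/s⌋ + 1 windows; windows are half-open `[o, o + w)` with
0-based offsets `o = 0, s, 2s, …`, and trailing time points not covered by
a full window are dropped.  Within each window the short-term FC between
two ROIs is their Pearson correlation, giving K symmetric unit-diagonal
N×N matrices.  At the defaults `w = 30`, `s = 2` and M = 137 this gives
K = 54.  A 30-point window corresponds to 90 s at a 3 s repetition time —
long enough for a stable correlation estimate, short enough to resolve
slow connectivity fluctuations; conversion between seconds and time points
is deliberately left to the caller.

**Vectorization.** Each slice being symmetric, only the strict lower
triangle is kept: P = N(N−1)/2 ROI pairs, each contributing a length-K
*FC series*.  Pairs are ordered row-major over the lower triangle —
(2,1), (3,1), (3,2), (4,1), … in 1-based indices — and this order is fixed
across the whole package, including serialized containers.

**Self-attention weighting.** Not all ROI pairs are equally informative,
so the P×K FC-series matrix F is reweighted by single-head
scaled-dot-product attention in which the *tokens are the P ROI pairs* and
the feature axis is the K windows:

  Query = F·W_Q′, Key = F·W_K′ (P×d_k), Value = F·W_V′ (P×K),
  output = softmax(Query·Key′ / √d_k)·Value.

Because W_V is K×K, the output has exactly the input's P×K shape, so every
downstream operation accepts weighted and unweighted series
interchangeably (the unweighted path is retained as an ablation).  One
attention module serves both branches of the Siamese comparison — weight
sharing is structural: there is a single parameter object.

**Similarity.** Two subjects are compared pair-by-pair: the cosine
similarity of their length-K FC series at each ROI pair, aggregated across
the P pairs.  The element-wise cosine needs no alignment of window phases
between subjects — permuting the K windows jointly in both subjects leaves
every value unchanged (a property the tests verify exactly).  The default
aggregation is the *mean*, which keeps the subject similarity in [−1, 1]
regardless of N, so the contrastive margin below has a scale-free meaning;
the plain sum is available behind a switch.

**Contrastive Siamese training.** Labeled scan pairs (y = 1 same class,
y = 0 different) are pushed through the shared attention module and scored
with

  L = (1 − y)·s² + y·max(margin − s, 0)²,

where s is the aggregated similarity.  Note the convention: y = 1 means
*same* category here.  Gradients of L with respect to W_Q, W_K, W_V are
computed by hand-derived backpropagation through the attention, cosine and
aggregation chain (the model is small enough that no autodiff framework is
warranted); the test suite checks them against central finite differences
at ≥ 20 random parameter points to 10⁻⁴ relative tolerance.  Optimization
is Adam at learning rate 10⁻³ for 50 epochs over 256 sampled pairs
(balanced same/different, never pairing a scan with itself); the same pair
sample is reused each epoch by default so the loss history tracks one
fixed empirical objective.

**Few-shot evaluation.** Cohorts are split 60/20/20 into
train/validation/test at the *subject* level (all scans of one subject in
one part, largest-remainder rounding, stratified by class), so no subject
leaks across parts.  Evaluation builds episodes from the test split: 5
support scans per class (2-way 5-shot) and up to 5 query scans per class,
support and query disjoint within an episode.  A query is assigned the
class whose support scans have the greater mean aggregated similarity
(a nearest-single-support rule is available); exact ties go to "NC".
The positive class is "patient", so TP counts correctly detected patients;
ACC, SPE, PPV and NPV follow the standard confusion-matrix formulas, with
NA (never an error) when a denominator is empty.  Confusion counts are
pooled over episodes (micro-average); the per-episode accuracy mean and sd
(macro view) are reported alongside, since either convention is defensible.

## Design decisions that were genuinely open

**Attention initialization.** A conventional zero-mean Gaussian
initialization (sd 1/√K) is provably degenerate here: with P ≈ 190 tokens
the attention scores are O(10⁻¹), the softmax is numerically uniform
(measured row entropy equals log P to four decimals), every output row
collapses to the value-matrix column mean, and all subject similarities
saturate near 1 — gradient descent does not recover from this rank
collapse.  The default is therefore *identity-anchored*: W_Q = W_K = γ·I
(γ = 8) and W_V = I, each plus a small seeded perturbation.  At this
starting point the attention scores are scaled inner products between FC
series, i.e. each ROI pair attends to pairs with similar dynamics (itself
included), and per-pair information survives.  The random initialization
is kept behind `identityScale = 0` as an ablation.

**Margin.** With mean aggregation, a margin of 1.0 is satisfiable only by
*exact* similarity 1, so the same-class hinge never switches off and its
gradient pressure degenerates into pushing all similarities together.  The
default margin is 0.5: same-class pairs above 0.5 are left alone and the
loss concentrates on separating different-class pairs.

**Validation-based selection.** The train/validation/test partition gives
the validation split its standard few-shot role: during training, pooled
episodic accuracy on validation episodes is evaluated every 5 epochs (the
initial state included) and the best checkpoint is returned.  This guards
against a failure mode we observed reproducibly: the contrastive objective
can be driven to ~0 on the training scans while test-episode accuracy
*degrades*, because ~8,700 parameters fit ~100 training scans easily.  On
the synthetic cohorts below, the selected checkpoint is frequently the
identity-anchored initialization itself — an honest reflection that at
this cohort size the attention prior, not the contrastive fine-tuning,
carries most of the performance.  `trainSiamese` reports the validation
trajectory so users can see exactly this.

**Decision rule and tie-break.** The mean-similarity argmax rule and the
NC tie-break are conventions (the comparison graphic of the original
setting shows similarity computation but no explicit rule); both are fixed
and documented, and the alternative rule is a configuration switch.

## The synthetic cohort generator

No clinical rs-fMRI can ship with the package, so `generateCohort` builds
two-group cohorts in which the ground truth is known by construction.
Every scan is a latent-factor Gaussian mixture: a global factor shared by
all ROIs (background coupling b), one factor per *altered* ROI pair
carrying the planted group difference, an idiosyncratic factor per ROI,
and measurement noise of sd σ.  All components pass through the same
unit-energy band-pass FIR filter (`signal::fir1`; band as a fraction of
Nyquist, default 0.09–0.9, matching a 0.015–0.15 Hz pass band at a 3 s
repetition time), which shapes the spectrum without touching instantaneous
cross-correlations.  The expected windowed correlation is
(b + c(t))/(1 + σ²) at altered pairs of patient scans and b/(1 + σ²)
elsewhere — a closed form the tests verify by Monte Carlo.  The planted
coupling c(t) oscillates slowly by default (period 60 time points, relative
depth 0.5, random phase per scan, clamped to the variance budget 1 − b),
so FC *series*, not only their means, differ between groups; the
ground-truth record stores the phase-averaged expectation.

Two defaults deserve their rationale spelled out:

- **Background coupling b = 0.35.**  Parcellated, band-passed rs-fMRI
  exhibits substantial shared signal; mean pairwise FC around 0.2–0.4 is
  typical.  Beyond realism this matters structurally: at near-zero
  background coupling the FC series are noise-dominated and their cosines
  carry little but correlation-estimation noise, a regime real FC matrices
  are not in.
- **Effect sign: patient coupling = b − effect (default effect 0.6, so
  −0.25 at altered pairs).**  The cosine in this method is scale-invariant,
  so a group difference in coupling *magnitude only* (same sign) produces
  subject similarities with rank-one structure c_a·c_b in which the
  more-similar support class is the same for every query — no argmax rule
  can separate the groups, and contrastive training provably collapses the
  patient-side factor.  The regime in which pairwise cosine similarity
  discriminates — and the one consistent with reported average-similarity
  matrices in this literature, where cross-class cosines turn negative —
  is opposite-signed (hypo-/anti-connectivity) alteration.  The sign is a
  configuration field; the default plants the detectable regime.

What the generator deliberately does **not** emulate: hemodynamic response
shapes, scanner drift and motion artifacts, spatial autocorrelation
between ROIs, site effects, and any subject-level consistency across
repeat scans (scans of one subject are independent draws given the group).
Passing tests on these cohorts therefore demonstrates that the *pipeline*
recovers a planted, well-posed dynamic-FC group difference — not that the
method attains any particular accuracy on clinical data.

## Numerical choices

- Zero-variance window sub-series make the Pearson correlation undefined:
  the FC entry is set to 0 with a warning (neutral in cosine similarity).
- Zero-norm FC series likewise make the cosine undefined: 0 with a warning.
- Correlations are clamped to [−1, 1] and matrices symmetrized against
  floating-point drift; the softmax subtracts row maxima before
  exponentiation.
- The hinge at s = margin takes subgradient 0.
- Non-finite training loss aborts with a training error rather than
  propagating NaNs into the parameters.
- Refolded similarity matrices set the diagonal to 1 (self-FC is not in
  the pair set); this is cosmetic.
- Discriminative-pair scores are the absolute patient-minus-NC difference
  in mean similarity, averaged over the two support classes; the signed
  per-support-class differences are kept in the output table, and ties
  break by pair order.

## Problem sizes used by the test and acceptance code

All checks run on synthetic cohorts sized so the full suite completes in
minutes on one CPU: oracle equivalences at N ≤ 6, M ≤ 40; the
null-calibration experiment at 20 ROIs, 137 time points, 50 subjects per
group, effect 0, 60 episodes; the recovery experiment at 20 ROIs, 137 time
points, 40 subjects per group × 2 scans (half the scan count of a typical
clinical cohort of this kind), 5 altered pairs, effect 0.6.  The
full-atlas case (N = 116, P = 6670) is supported but not the default: the
P×P attention matrix then holds ~44.5 million entries (~356 MB as doubles),
which is the main memory cost to plan for.

## Known limitations

- Because the per-pair cosine ignores row scale, the attention influences
  the similarity only through row *directions* (mixing FC series across
  pairs), not through per-pair amplitude weighting; "weighting" should be
  read in that sense.
- Magnitude-only group differences with a common sign are structurally
  invisible to the summed-cosine statistic (see the effect-sign rationale
  above).
- The oscillating planted coupling has a random phase per scan, so linear
  features of the oscillation carry no class signal; class information
  enters through coupling levels and their sign, as in the detectable
  regime discussed above.
- Training improves on the attention prior only when the training split is
  large relative to the parameter count; the validation-selection
  machinery makes this visible rather than hiding it.
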