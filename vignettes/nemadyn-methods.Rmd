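---
title: "Models and methods behind nemadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nemadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemadyn)
```

This vignette documents the models the package implements, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic-data generators do and do not emulate.

# Locomotion-state inference

## The six-state model

Worm tracking yields, per frame (2 frames/s over 30 min assays), a
centroid position, a body-axis unit vector, and a body elongation
obtained by fitting an ellipse through the second central moment of the
body pixels (`elongation_from_points()`; the proportionality constant in
"elongation = 2·sqrt(largest eigenvalue)" is irrelevant because only the
*relative* elongation enters the model). Because head and tail are not
distinguishable in low-resolution video, the axis sign is arbitrary;
`preprocess_track()` enforces frame-to-frame sign continuity and projects
each displacement onto the axis, giving a signed series Δx whose
*relation* to forward/backward movement is fixed within a track but whose
absolute direction must be inferred.

The hidden state alphabet is: forward and backward crawling, each
duplicated into `+`/`−` orientation bookkeeping states, plus a forward
turn and an omega turn. Permitted transitions are: self-loops; sign-
preserving reversals (`forward± ↔ backward±`); `forward± ↔ forward_turn`;
and the omega sequence `backward± → omega_turn → forward±`. All other
entries are structural zeros and remain exactly zero through
re-estimation.

Emissions are fixed, not fitted:

* relative elongation r: Gaussian(1, σ = 0.075) while crawling; while
  turning, 1 for r ≤ 1 with a Gaussian tail above 1. The turning factor
  is deliberately unnormalized — per-frame posterior normalization
  cancels any constant.
* direction: crawling states carry σ(Δx/(cΔt)) or its complement, with
  σ(x) = (1 + erf(2x))/2 and c = 0.1 mm/s — a fraction of the typical
  0.25 mm/s crawl speed, so small positional jitter of a paused worm is
  not scored as movement. Turning states carry the constant ½ (the
  direction is uninformative there; the constant cancels).

## Fitting and decoding

`baum_welch()` re-estimates only the transition matrix and initial
distribution, pooling expected counts over all tracks of a movie. The
initializer gives backward→forward a five-fold higher rate than
forward→backward; because real backward bouts are much shorter than
forward bouts, this single asymmetry anchors which direction is labeled
"forward".

One design choice goes beyond the obvious implementation: the `+`/`−`
split exists only to track the arbitrary axis orientation, so the
behavioral transition rates cannot depend on the sign. We therefore tie
the parameters under the sign-swap permutation (pooling the
corresponding expected counts each M-step, `tie_sign = TRUE`). Without
tying, EM on data where each track uses only one sign can repurpose an
unused backward sign-state as a second long-lived "forward" state (the
two share the same direction factor), silently destroying the
brief-backward asymmetry. Tying is a linear constraint on the M-step, so
the likelihood ascent property is preserved — the suite checks
monotonicity explicitly.

Decoding follows the posterior threshold rule: a frame is backward iff
the summed posterior of the two backward states exceeds ½. No Viterbi
pass is used.

# Forward-bout survival and the repetitive index

Bouts are segmented from the threshold rule; intervals touching a track
boundary are censored (tracks end when worms exit the field of view or
collide). `forward_survival()` estimates the discrete hazard
p_{f→b}(i) = events at step i / bouts at risk at step i, with censored
bouts leaving the risk set silently, and the survival
p_f(n) = Π_{i<n}(1 − p_{f→b}(i)). A bout lasting n frames reverses
*during* its n-th step, so p_f(n) equals the empirical fraction of bouts
with duration > n when nothing is censored.

The reversal model r(t) = r₀ + δr·e^(−t/τ) integrates to
log p_f(t) = −r₀t − δl(1 − e^(−t/τ)) with δl = τδr, which is *linear* in
(r₀, δl) once τ is fixed; `fit_reversal_model()` is weighted least
squares on log p_f with 1/variance weights (Greenwood-type variances
accumulated from the hazards by default; across-movie variances can be
supplied). τ is fixed at 20 s for all fits to keep a consistent split of
early versus late reversal rates. The repetitive index is RI = δl/ln 2;
the natural logarithm is forced by the anchor that RI = 1 corresponds to
a 50% asymptotic deficit of p_f relative to e^(−r₀t)
(`long_time_suppression()`), since e^(−ln 2) = ½. δl is unconstrained in
sign; negative values are reported and flagged as anti-repetitive.

Numerical choices: bins run at native frame steps (0.5 s) from n = 1 up
to the last bin with ≥ 5 bouts at risk; bins with p_f = 0 are dropped
(log undefined) rather than pseudo-counted; a fit is refused as
non-identifiable when the observed times never approach τ (the δl
regressor is then proportional to t). One regression detail departs from
the minimal design: a free intercept (`boundary_offset = TRUE`) is
included by default. Posterior-threshold decoding cannot resolve bouts at
the single-frame scale, which depresses the first-step hazard; because
log-survival is cumulative, that error appears as a *constant* offset on
every later bin, and without an intercept it is absorbed by δl, biasing
RI downward by ~0.05–0.15 on decoded data. On curves that follow the
model exactly the intercept fits to zero, so noiseless recovery is
unchanged (the suite asserts machine-precision recovery).

Goodness of fit uses the weighted sum of squared residuals
S = Σ Δr²/σ² against a χ² distribution whose degrees of freedom equal
the number of binned time points (no parameter subtraction; a
`subtract_params` argument exposes the alternative). The optogenetic
summary `normalized_r_multiple()` computes
(R_multiple+ − R_multiple−)/(R_total+ − R_total−).

# Neural-trace analysis

## Conditioning, responsiveness, onset

Traces are 1 frame/s. `condition_trace()` applies a Gaussian low-pass
filter (sd 1 s by default; kernel truncated at ±4 sd, reflected
boundaries) and min–max normalization to [0, 1] (or zero-mean unit
variance for the motion analysis). The derivative is the one-frame
difference divided by **2Δt**, applied exactly in that form: the
thresholds that follow (0.05 for cue responsiveness within ±5 s of a
removal; 0.15 at a single frame or 0.05 on two consecutive frames for
spontaneous-activity onset, scanned over the 540 s pre-cue window) are
calibrated on that half-slope scale, so the formula and thresholds must
travel together.

## Wavelet spectra

`wavelet_transform()` computes W(t, f) = Σ φ(t − t′, f) S(t′) Δt with the
complex Morlet wavelet φ(t, f) = sqrt(π/σ)·e^(−t²/2σ²)·e^(i2πft),
σ = ξ/(2πf), ξ = 4 — resolving frequency changes on scales of about two
periods — over 0.01–0.2 Hz. The 1/sqrt(σ) normalization makes the L2
norm π^{3/2} at every frequency, so amplitudes are comparable across the
band. The signal mean is removed first; edges are handled by reflecting
the full signal on both ends; the kernel is truncated at ±4σ and the
convolution is done by FFT.

The default grid has 40 logarithmically spaced points rather than a
denser one. The wavelet's relative frequency resolution at ξ = 4 is
σ_f/f = 1/ξ = 25%; an ~8% grid step samples that resolution about three
times over. A much finer grid adds no information but interacts badly
with the constant-norm normalization: the amplitude response to a
narrowband signal carries a sqrt(σ) ∝ 1/sqrt(f) prefactor, and at
sub-resolution spacing that tilt exceeds the response falloff between
adjacent bins, displacing the argmax one bin below the true frequency.

Per-animal spectra are time-averaged from onset to the end of the 540 s
window; each animal is weighted by its active fraction in genotype means
(`genotype_spectrum()`), and animals with no onset carry zero weight.

## Group comparison

`compare_spectra()` implements a permutation test from bootstrapped
ensembles: in each of n_boot iterations (10⁴ by default) animals are
resampled with replacement from the pooled set, labels are randomly
permuted, and the weighted-mean difference is recomputed per frequency;
the two-sided p-value is (1 + #{|null| ≥ |obs|})/(1 + n_boot). The null
is constructed on a canonically ordered pooled set with the unordered
size pair, so swapping the two groups negates the observed difference
and leaves p-values bit-identical. Per-frequency testing is pointwise at
α = 0.05 (matching the shaded-band presentation this mirrors);
`family_wise = TRUE` switches to a max-statistic null. The suite checks
the pointwise false-positive rate on null ensembles against binomial
bounds.

## Motion–calcium association

`calcium_state_phi()` smooths position (sd 3 s) and calcium (sd 1.5 s),
scales calcium to unit variance, and marks transitions where the
derivative crosses +0.1 from below (into the high state) or −0.1 from
above (into the low state). Each episode's net position change labels it
forward or backward; association is Pearson's phi of the 2×2 state ×
motion table. Partial first/last episodes are kept when at least 3
frames long. `peak_crosscorr()` reports the maximal Pearson correlation
over integer lags (±30 s default); positive lag means the first channel
leads.

# Synthetic data: what it emulates, and what it does not

The generators exist so that every downstream stage can be tested with
known ground truth; their defaults are the assay conditions the analyses
target.

* `simulate_track()` — 20 worms, 30 min, 2 frames/s, 0.25 mm/s crawl
  speed. Forward periods end with per-step probability
  1 − exp(−r(t)Δt) under the planted hazard r(t) = r₀ + δr·e^(−t/τ)
  (r₀ = 0.02 s⁻¹ ≈ 1.2 reversals/min by default, τ = 20 s), so
  forward-bout durations obey the target survival law by construction —
  the suite verifies this with Dvoretzky–Kiefer–Wolfowitz bands at
  α = 0.01. Turn substates modulate only the observables (depressed
  elongation with mean 0.7, rapid reorientation), never the reversal
  clock, keeping the law exact. Backward bouts end at a constant 0.5 s⁻¹
  hazard after a minimum duration of 1 s: a reversal involves at least
  about one body bend, and sub-second reversals are neither realistic
  nor resolvable by any frame-wise decoder. Omega turns occur only on
  backward→forward transitions, forward turns only from forward
  crawling, mirroring the permitted topology. The axis sign is
  re-randomized every frame to exercise the orientation-continuity
  logic, and `lost_rate` splits trajectories into censored fragments to
  exercise the censoring-aware estimator.
* `simulate_trace_pair()` — quiescent baseline, onset at 120 s, transient
  trains (25 s spacing by default, periodic with jitter or Poisson),
  alpha-function-like kernels (differences of exponentials: glutamate
  rise 0.5 s/decay 3 s; calcium rise 1 s/decay 8 s, lagged 3 s), cue
  responses at two removals (20 s and 10 s cycles) after the 540 s
  window, and additive Gaussian noise. The kernel shape is a modeling
  convenience — any smooth transient would do — chosen for two
  interpretable time constants. The calcium rise of 1 s matches fast
  genetically encoded indicators and keeps onset detection within the
  ±3 s smoothing tolerance the detector is specified to.
* `simulate_motion_calcium()` plants a phi coefficient by drawing each
  episode's motion sign to agree with its calcium state with probability
  (1 + φ)/2.
* `simulate_expression()` plants a target cell type whose enriched set
  receives orthologs of worm-enriched genes with a configurable
  probability; all other cell types stay at background.

None of the generators emulate video artifacts, motion/bleaching
artifacts in fluorescence, pharmacology, optogenetic light delivery, or
real neural circuit dynamics. Passing tests therefore demonstrate the
*estimators* are correct and calibrated under the stated observation
models — not that those models capture every property of real
recordings.

# Expression enrichment

FE tables are rank-transformed (highest FE = rank 1, average ranks on
ties) for clustering-style displays. For scoring, mouse cell-type sets at
each cutoff contain only genes uniquely enriched in that cell type; the
enrichment score compares, among ortholog-mapped genes, the proportion of
the worm set with an enriched mouse ortholog to the same proportion over
the whole worm universe ("any ortholog present" counts, with genes
lacking orthologs excluded from both proportions). The cutoff grid is
log2 FE ∈ {1, 1.5, 2, 2.5} (worm) × {1, …, 4} (mouse). The association
score corrects residual ortholog-mapping bias with an
observed/expected construction: the expected score at each cutoff pair
is the across-cell-type mean, association = observed/expected (the
reciprocal is available behind `invert = TRUE`; the default direction
makes higher = more associated), summarized per cell type by the mean
over the grid.

# Problem sizes used in the validation suite

The suite exercises: nine 20-worm × 30-min cohorts for planted-RI
recovery (pooled per planted level, the same 180-worm scale at which the
estimator's sampling spread supports a ±0.25 check); brute-force
enumeration of all state sequences on tracks of up to 6 frames; 10⁴
replicates for χ² calibration at 20 bins; 100 replicate null spectral
comparisons at 400 bootstrap iterations; and 20 seeds of the
planted-association expression generator. These sizes were chosen so each
check's sampling error is several times smaller than the tolerance it
asserts.

# Known limitations

* Absolute-direction inference rests entirely on the brevity of backward
  bouts; data violating that premise (e.g. roller mutants) would swap
  labels.
* The per-frame posterior threshold cannot resolve sub-frame bouts; the
  intercept in the survival fit compensates on average but single-frame
  reversal statistics remain unreliable at 2 frames/s.
* The χ² dof convention (no parameter subtraction) makes the tabulated
  p-values conservative when the fitted curve has been estimated from
  the same data.
* Wavelet amplitudes inherit the constant-norm convention; power-law
  comparisons across widely separated frequencies should account for the
  sqrt(σ) response tilt discussed above.
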