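---
title: "Resting-state functional connectivity and dynamic brain states for fUS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state functional connectivity and dynamic brain states for fUS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Functional ultrasound (fUS) imaging records power-Doppler images of the rodent
brain whose pixel intensity tracks cerebral blood volume (CBV). Under
neurovascular coupling, slow CBV fluctuations carry a resting-state signature:
brain regions whose hemodynamic signals co-fluctuate are considered
functionally connected. `fusfc` implements a complete analysis chain for such
recordings in a chronic-inflammatory-pain setting (control vs arthritic rats):

1. **Static functional connectivity** — seed-based pixel maps and ROI–ROI
   Pearson correlation matrices, compared between groups through the Fisher
   z-transform, a normality-gated Welch / Mann-Whitney test, and
   Benjamini-Hochberg (BH) false-discovery control.
2. **Dynamic functional connectivity (dFC)** — instantaneous phases by the
   Hilbert transform, per-frame phase-locking matrices
   $M_{PL}(i,j,t) = \cos(\varphi_i(t) - \varphi_j(t))$, and unsupervised
   decomposition of the pooled frames into recurring *brain states* by
   k-means under the cityblock (L1) distance, followed by group statistics on
   per-animal state occurrence rates.
3. **Behaviour links** — three-block Spearman correlation matrices relating
   connectivity alterations, state occurrences and behavioural measures
   across individual animals.
4. **Diagnostics** — a composite connectivity biomarker (sum of selected
   ROI-pair correlations, or a logistic model on them), its empirical ROC and
   AUC with a DeLong confidence interval, Youden threshold selection on a
   test cohort, and frozen-threshold external validation on a disjoint
   cohort.

Because raw in-vivo recordings are not bundled, every stage is validated
against a **synthetic cohort generator with planted ground truth**; the
generator is itself first-class, tested code.

## Acquisition geometry

The pipeline starts from ROI-averaged (or pixel-level) Doppler series, but the
acquisition arithmetic is kept explicit in `acquisition_geometry()`: a 600 s
acquisition at one frame per 0.4 s gives 1500 frames; 500 Hz compounding gives
200 compound images per frame; plane-wave tilts from −10° to +10° in 2° steps
give 11 angles and a pulse repetition frequency of 11 × 500 Hz = 5.5 kHz.
All derived counts must be exact integers; anything else is a configuration
error. Ultrasound physics itself (beamforming, clutter filtering) is out of
scope — the pipeline's inputs begin at the Doppler movie / ROI series level.

## The synthetic generator

The generator is a **Markov state-switching oscillator**. Its design
rationale: the dFC analysis (band-pass, Hilbert phase, cosine phase
differences, L1 clustering) is *exactly identifiable* under a model in which
a shared narrow-band carrier drives every ROI with state-dependent phase
offsets. Concretely, for ROI $i$ at frame $t$:

$$x_i(t) = w_i \cos(2\pi f t + \theta_{s(t), i}) + \sqrt{1 - w_i^2}\,\eta_i(t) + \varepsilon_i(t)$$

* $s(t)$ — a first-order Markov chain over $k$ planted states, started from
  its stationary distribution. Default transition matrices are
  $P = (1 - 1/d)\,I + (1/d)\,\mathbf{1}\pi'$, whose stationary law is exactly
  the target occupancy $\pi$ with switching probability $1/d$ per frame.
* $\theta_{s,i}$ — per-state phase offsets. The five default states are
  binary $0/\pi$ patterns over the 10 default ROIs (bilateral S1HL, M1, M2,
  Cg1, Cg2): global in-phase, hemispheric, cingulate-vs-rest, motor-vs-rest,
  and a mixed pattern. Binary patterns put the phase-locking entries at
  $\pm 1$, giving maximal L1 separation between states.
* $f$ — carrier frequency, 0.08 Hz by default, inside the resting-state band.
* $\varepsilon_i$ — white measurement noise, SD 0.1 of the unit carrier
  amplitude by default.
* $w_i$ — shared-carrier weight. Controls and unperturbed ROIs have
  $w_i = 1$. In arthritic animals the designated sub-network ROIs (default:
  both S1HL) are attenuated in proportion to a latent severity, with the lost
  variance replaced by an independent band-limited private component
  $\eta_i$. **Why this construction:** multiplying a whole ROI signal by a
  constant barely changes its Pearson correlations (correlation is
  scale-free; only the signal-to-noise dilution moves r, by a fraction of a
  percent at these noise levels). Attenuating only the *shared* component
  while preserving total power makes the pairwise correlation scale as
  $w_i w_j$ — a physically sensible "partial decoupling" that produces the
  planted, detectable group effect.
* Phase offsets are linearly interpolated over a 2-frame ramp at each state
  switch, so switches do not inject broadband transients through the
  band-pass filter.

**Latent severity.** Arthritic animals draw a severity
$\in \mathcal{U}(0.5, 1)$ (controls: 0). Severity scales both the
sub-network attenuation ($w = 1$ at severity 0, $w =$ `subnetwork_attenuation`
at the mean severity) and, through per-variable loadings `behavior_link`,
the behavioural variables. This single latent factor is what makes
connectivity alterations and behaviour correlated *by construction*, so the
Spearman-block stage has a planted signed truth.

**Behavioural model.** Group means default to the generative targets: weight
gain 136.00 g (control) vs 49.44 g (arthritic), inflammation score medians 0
vs 22 (scale 0–60), bilaterally reduced von Frey thresholds, foot-bend scores
0–5. The ± values printed with such means are treated as SEM at n = 9, so the
generative SD is about 35 g. With a loading of zero the arthritic variable is
drawn from the control model (useful for null checks); with the default
loading of one the group means above are reproduced at the mean severity.
Bounded scores are clipped to their valid ranges; within-group variances for
most behavioural measures are configurable defaults, not claims of fidelity.

**Dwell time.** The mean dwell scale is 50 frames (20 s). This was chosen at
design time from the physics of the band: a 0.05–0.2 Hz band-pass has an
impulse response of several seconds, so phase transitions smear over roughly
5–10 frames; dwell times much shorter than ~20 s would leave a substantial
fraction of frames in transition and make frame-exact recovery impossible
for *any* method, while much longer dwells leave too few switches per 600 s
acquisition to estimate occupancy. 20 s dwells are also in the range reported
for hemodynamic dFC states in anesthetized rodents.

**What the generator does not emulate:** vascular physiology, spatial
autocorrelation of real Doppler speckle, residual tissue-motion clutter,
anesthesia depth drift, or non-stationary noise. Passing tests therefore
demonstrate correctness of the *analysis machinery* under the stated model,
not robustness of the science to real-data confounds.

## Preprocessing choices

The resting-state band-pass is a 4th-order Butterworth applied
forward-backward (`signal::filtfilt`), i.e. zero-phase: any phase distortion
here would corrupt the Hilbert-phase stage directly. The filter family and
order are a package choice; the band (0.05–0.2 Hz) is the standard
resting-state band for this preparation. The row mean is removed before
filtering (harmless; improves edge behaviour). Each ROI is then normalized by
the square root of its energy — Pearson correlations are invariant to this,
and it standardizes the analytic-signal amplitude. Filtering keeps full
length; the dynamic stage's truncation of 100 samples at each end (1500 →
1300 frames, 600 s → 520 s) absorbs both filter and Hilbert edge transients.

## Dynamic-state extraction

The analytic signal is built by the standard FFT construction (doubling
positive frequencies); the phase is the four-quadrant arctangent of the
imaginary over the real part. A literal "ratio" arctangent would lose
quadrant information and contradict the cosine-difference usage, so the
four-quadrant form is used.

Frames from **all animals of both groups** are pooled into one clustering —
states are defined on the whole cohort, then occurrence rates are split by
group. Features are the strict upper triangle of each frame's phase-locking
matrix (45 features for 10 ROIs); the diagonal is constantly 1 and the lower
triangle redundant. Clustering is k-means under the **cityblock (L1)
distance** with the component-wise median as centroid update (the L1-optimal
center). Each run uses 200 random restarts (k distinct frames each), keeps
the minimum-objective replicate, stops when assignments stabilize or after
300 iterations, and repairs empty clusters by splitting off the farthest
point. The model is fit independently for each k in `k_list` (default 5–7);
`match_states()` aligns state identities across k (or against planted truth)
by exhaustive minimal-L1 assignment, which is exact for k ≤ 8.

Numerical notes: ties in the L1 assignment resolve to the lowest cluster
index; the replicate selection and all label sequences are bit-reproducible
given the R random seed, because initial centroids are drawn with R's RNG
and the C++ Lloyd loop is deterministic.

## Group statistics

Correlations are Fisher-z transformed before testing. The normality gate is
Shapiro-Wilk at α = 0.05 on each group; Welch's unequal-variance t test is
used only if both groups pass, otherwise the two-sided Mann-Whitney U test —
exact for group sizes up to 12 (the study's sizes) and a tie-corrected
normal approximation beyond. Degenerate input (all values identical in both
groups) returns p = 1. BH correction is applied **within each family**: the
45 ROI pairs of a plane for the static stage, the k states for occurrence
rates, and all unique variable pairs for the Spearman blocks. With many true
positives, BH at FDR 0.05 *by design* admits a false flag in roughly a third
of cohorts — per-pair error rates, not zero-false-flag cohorts, are the
controlled quantity.

Spearman correlations use midranks (tie-corrected); p-values default to the
t approximation, with a permutation option (exhaustive to n = 8, Monte Carlo
beyond) for small-sample exactness. The pooled control + arthritic cohort is
the default correlation population, matching the individual-differences
reading of the design; restriction to one group is a filter away.

## Diagnostics

The composite biomarker has two modes. `sum` adds the raw pair correlations
— this is the scale on which a multi-pair "correlation threshold" (e.g. a
cut at 3.06 for four pairs whose healthy correlations are near 0.8) lives.
`logistic` fits group on the pair correlations by maximum likelihood on the
test cohort only and scores every animal by the linear predictor. At these
sample sizes complete separation is common; the fit then falls back to a
ridge-stabilized fit (penalty 1e-4) that preserves the score ordering, which
is all the ROC consumes, and the result is flagged. The empirical AUC equals
the normalized Mann-Whitney U statistic (ties half-weighted); its CI is
DeLong's. Score orientation is auto-detected and recorded: when the
biomarker is *reduced* in arthritic animals, positives are called at or
below threshold. Candidate thresholds sit at midpoints between consecutive
observed scores (the usual ROC convention), so a frozen threshold lies
centrally in its empirical equivalence interval rather than on a training
data point. The Youden threshold maximizes sensitivity + specificity −
1 with ties broken toward sensitivity; external validation applies the
frozen threshold (and frozen coefficients) to a disjoint cohort, rejecting
any animal overlap. Note that in-sample AUC is not guaranteed monotone when
predictors are added to a nested logistic fit (likelihood, not AUC, is
optimized); the guaranteed nested property is non-increasing deviance, and
that is what the tests assert.

## Problem sizes used in the validation suite

The validation suite regenerates everything from code: full-size cohorts
(9 + 9 animals, 10 ROIs, 1500 frames) for state recovery and FDR control
(500 null cohorts), 100-seed power runs for sub-network detection and for
the test/validation diagnostic round trip (9 + 17 animals split 14/12), and
small analytic fixtures for the oracle checks. These sizes reproduce the
study's sample sizes while keeping the whole suite runnable on a laptop.

## Known limitations

* The generator's states are global phase patterns; real dFC likely mixes
  amplitude and phase dynamics and regional noise structure.
* The Mann-Whitney exact branch defers to `stats::wilcox.test`, which falls
  back to the tie-corrected normal approximation when ties occur even at
  small n.
* Seed-based maps treat pixels independently; no spatial inference is
  provided.
* `match_states()` is exhaustive and limited to k ≤ 8 — ample for the 5–7
  states considered, not for large state spaces.
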