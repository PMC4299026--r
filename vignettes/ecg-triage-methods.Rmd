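---
title: "Methods: early triage of pathological heartbeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early triage of pathological heartbeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A wearable single-lead ECG monitor cannot afford to run a full morphological
delineation on every heartbeat: most beats are normal, and the detailed
analysis (and its wireless transmission) dominates the energy budget. The
approach implemented here is *triage*: a very cheap classifier looks at each
beat right after R-peak detection and either discards it as normal or
forwards it for detailed analysis. Two rates summarize the triage quality:

* **NDR** (Normal Discard Rate): the fraction of truly normal beats labeled
  `N` and therefore discarded. Higher is better for energy.
* **ARR** (Abnormal Recognition Rate): the fraction of truly pathological
  beats (premature ventricular contractions `V`, left bundle branch block
  beats `L`) labeled `V`, `L` or `U` (unknown) and therefore forwarded.
  Higher is better for safety, and the design holds it above a bound
  (default 95%) as the primary constraint.

Confusing `V` with `L` is not a triage error: both route the beat to
detailed analysis. `U` counts as pathological for the same reason.

## Pipeline

1. **Baseline removal** (`baseline_filter`): morphological opening (flat
   structuring element, 0.2 s) followed by closing (0.28 s); the result is
   subtracted as the baseline estimate. The element widths bracket the QRS
   and T-wave durations so beat morphology passes through. Erosion/dilation
   use the van Herk running-extrema algorithm, O(n) and fully vectorized.
2. **R-peak detection** (`detect_r_peaks`): an à trous dyadic wavelet
   decomposition with the quadratic-spline smoothing kernel [1,3,3,1]/8 and
   a zero-phase central-difference detail filter. The zero-phase variant of
   the spline detail keeps modulus-maxima zero-crossings aligned with wave
   extrema, avoiding per-scale group-delay bookkeeping. Candidates are
   regions where the scale-2³ modulus exceeds 0.6 × its trailing 2-s RMS
   (see *Numerical choices*), must show an opposite-signed modulus-maxima
   pair at scale 2² above the analogous scale-2² threshold, and pass two
   rejection rules: a 200 ms refractory period (keeping the larger beat) and
   a T-wave rule (a candidate within 360 ms of the previous accepted peak
   with less than half its modulus is a T wave).
3. **Segmentation** (`segment_beats`): windows of d = 201 samples — the R
   sample plus the 100 samples preceding and the 100 following it at
   360 Hz. Edge beats whose window would cross a record boundary are
   dropped, not padded, keeping the classifier input contract exact. d is a
   configuration knob because the windowing convention could also be read
   as 200 samples; 201 keeps the window symmetric with R at the center.
4. **Dimensionality reduction** to k = 8 or 16 coefficients, by one of:
   * **Random projection** (`sample_achlioptas`, `project_rp`): a sparse
     ternary matrix with i.i.d. entries +1 (p = 1/6), −1 (p = 1/6),
     0 (p = 2/3). The projection is a signed accumulation — no
     multiplications — and the matrix packs into 2 bits per entry
     (`pack_achlioptas`), a quarter of an 8-bit encoding.
   * **PCA** (`fit_pca`, `project_pca`): the k leading eigenvectors of the
     sample covariance (1/N)Σ(vᵢ−E[v])(vᵢ−E[v])ᵀ, computed by power
     iteration with deflation (tolerance 1e−9, ≤1000 iterations per
     component; the sign convention makes each component's
     largest-magnitude element positive so results are reproducible).
   * **Fiducial points** (`delineate_fpd`): 8 signed sample offsets relative
     to R — onset/peak/end of P and T, onset/end of QRS — found from the
     same wavelet decomposition (QRS at scale 2², P/T at scale 2⁴; search
     windows ±60 ms for QRS, [−200, −60] ms for P, [+80, +400] ms for T). A
     wave whose modulus maximum is below 0.1 × the QRS modulus at the same
     scale, or that lacks an opposite-signed maxima pair with an interior
     zero crossing, is undetected; its points take the position of the
     detected neighbor closer to R (falling back to R itself). Offsets are
     kept in samples, not milliseconds, because integers feed the embedded
     path directly.
   * **Combinations** (`combine_features`): 8 projection coefficients
     concatenated with the 8 fiducial offsets, projections first.

5. **Neuro-fuzzy classifier** (`init_model`, `train_model`, `classify`):
   per-(coefficient, class) gaussian membership functions
   μ(u) = exp(−(u−c)²/2σ²); per-class fuzzy values are the product of the k
   grades; the decision compares the top-two margin against α times the
   total: if (M1 − M2) ≥ α·S the argmax class is assigned, otherwise the
   beat is `U`. The decision is scale-invariant in the fuzzy values, which
   is what makes the integer implementation below possible.

6. **GA optimization** (`evolve`): the projection matrix is trained jointly
   with the classifier. Each candidate matrix is scored by the NDR its
   tuned classifier achieves on a larger tuning set (train_set_2) under the
   ARR bound; selection is a size-3 tournament with elitism 2, row-wise
   uniform crossover (rate 0.9) and per-entry Achlioptas resampling
   mutation (rate 0.02). The reference configuration is 20 matrices over 30
   generations; the package default is a desk-scale 10 × 10, which already
   converges on the synthetic data (see *Problem sizes*).

7. **Quantization** (`quantize_model`, `int_fuzzify`, `int_defuzzify`): see
   below.

## Training choices

The literature this classifier family comes from prescribes gradient-type
training but not a loss. The package minimizes the mean squared error
between the normalized fuzzy vector fₗ/Σf and the one-hot class target by
batch gradient descent (default 200 epochs, learning rate 0.05), updating
all centers and widths; widths are floored at 1e−3 to prevent degenerate
spikes. The normalized-output MSE keeps the product layer's gradients simple
and, because the normalized outputs are exactly the quantities the decision
rule uses, aligns the loss with the decision. A conjugate-gradient optimizer
over the identical objective is available (`method = "cg"`, via
`stats::optim`; Fletcher–Reeves family rather than a scaled variant) since
both optimizers appear in this classifier's lineage; gradient descent is the
default.

Features are normalized per coefficient to zero mean and unit variance on
train_set_1, and the affine map is stored in the model. Without this, a
fixed learning rate would be meaningless across feature families whose
scales differ by orders of magnitude (random-projection sums versus sample
offsets).

Membership initialization is per-class sample means and standard deviations
of the normalized coefficients — the maximum-likelihood diagonal-gaussian
fit — so training starts from a sensible classifier and mostly refines
boundaries.

α is tuned on train_set_2 by scanning the grid {0, 0.001, …, 1} for the
smallest value whose ARR meets the bound. ARR is non-decreasing in α (a
larger α only moves beats into `U`, which is a pathological call), so the
smallest feasible grid point is unique. If even α = 1 fails — possible only
when an abnormal beat wins class `N` with the runner-up fuzzy values exactly
zero — the tuner returns 1 with a warning flag, and the GA penalizes such
candidates below every feasible one. At run time a different `alpha_test`
may be supplied to trade NDR against ARR without retraining
(`pareto_sweep` traces the curve).

## Integer inference

The deployment target admits only integer arithmetic: no exponentials, no
divisions, 32-bit accumulators.

* **Membership linearization** (`linearize_mf`): each gaussian is mapped
  onto [0, 65535] and replaced by a piecewise-linear function of the offset
  δ = |c − x| with breakpoints at S = 2.35σ: the chord from (0, 65535) to
  (S, G_S) below S; the chord from (S, G_S) to (2S, 1) on [S, 2S); the
  plateau 1 on [2S, 4S); 0 beyond 4S. G_S = round(65535·e^(−2.35²/2)) = 4143
  is the scaled gaussian value at S, so the segment endpoints interpolate
  the true curve. Keeping the value 1 (the smallest nonzero integer) out to
  4S makes all-zero fuzzy vectors rare. Chord slopes are precomputed in
  Q0.16 fixed point; evaluation is one subtract, one multiply, one shift.
  The worst-case deviation of this two-chord construction from the scaled
  gaussian is ≈5674 (≈8.7% of full scale) near δ = 0.73 S — an intrinsic
  property of interpolating chords through those breakpoints, not a tuning
  choice; no single line on [0, S) can do better than ≈3890. The test suite
  asserts the measured ≤5700 envelope.
* **Feature quantization**: each normalized coefficient maps affinely from
  ±4.7 units onto the 16-bit grid. 4.7σ is half the MF support 4S for a
  unit-width membership function, so the grid spans everything the MFs can
  see.
* **Shift-truncate fuzzification** (`int_fuzzify`): the three class
  accumulators start from the first coefficient's grades; after each
  subsequent 16×16-bit multiply, all three are left-shifted by the largest
  common amount that overflows none of them past 2³², then the low 16 bits
  are dropped. Only ratios between the three accumulators matter to the
  decision, and a common shift followed by truncation preserves pairwise
  ratios to <2⁻¹⁴ relative error while the shifted values stay within a
  factor two of the 32-bit ceiling.
* **Division-free defuzzification** (`int_defuzzify`): the rule
  (M1 − M2) ≥ α·S becomes (M1 − M2)·2¹⁶ ≥ α_q16·S with α_q16 =
  round(α·2¹⁶), evaluated in widened integer arithmetic. All integer
  arithmetic in the package is carried in doubles; every intermediate stays
  far below 2⁵³, so the operations are bit-exact images of the hardware
  integer path.
* **Parity** (`parity_audit`): on the default 10,000-beat synthetic set the
  integer path agrees with the float path on ≥99% of labels (the
  regression bar; in practice agreement is essentially complete because the
  synthetic classes are well separated — disagreements can only occur for
  beats near the decision boundary).

## The synthetic generator

`generate_beat` builds each beat as a sum of gaussian bumps for P, Q, R, S
and T. Class `V` drops the P wave, widens the QRS 2.5×, and inverts the
T wave; class `L` widens the QRS 1.8×, notches the R wave (a narrow dip on
its right shoulder), and inverts the T wave. Q and S move outward with the
widening but only half-proportionally, keeping the complex clear of the P
search window. A seeded ±5% amplitude and ±3% width jitter varies every
beat, so per-class feature distributions are smooth clouds rather than
atoms. Records add RR jitter (clipped so beat windows never overlap, which
keeps the record exactly the concatenation of its beats), white noise
(default 0.03 mV RMS) and sinusoidal baseline wander (default 0.05 mV at
0.3 Hz); the default class mix follows the 74,064 / 6,608 / 8,032 census
proportions of the three classes in the reference arrhythmia database, and
the default dataset size is 3,000 beats.

What the generator does *not* emulate: real inter-patient morphology
variability, electrode artifacts, rhythm context (e.g. compensatory pauses),
fusion beats, or any physiologically validated dynamics. Consequently the
synthetic classes are much better separated than MIT-BIH beats: the
cross-validated NDR/ARR of ≈1.0 on synthetic data says the machinery is
correct, not that real-data performance would match. Full-scale replication
requires feeding real records through `read_record` (CSV or an
rdsamp-style multi-lead text export; binary WFDB files are not parsed — use
`rdsamp -c`/`rdann` style digests).

## Numerical choices

* R-peak threshold factor: 0.6 × trailing RMS (2 s window) of the scale-2³
  details. A factor of 0.3 admitted broadband noise bursts at the
  generator's default noise level (positive predictivity dropped to ≈92%);
  0.6 keeps a ≥5× margin to the smallest QRS modulus across all three
  classes while rejecting noise. Exposed as `threshold_factor`.
* Stratified folding sends remainder beats to the lowest-numbered folds —
  deterministic and testable.
* Power iteration initializes each component from the covariance column of
  the largest diagonal entry; ties in the decision rule (M1 = M2) and
  all-zero fuzzy vectors yield `U`, the conservative pathological call.
* The α grid step of 0.001 resolves ARR changes on sets far larger than any
  used here.
* All seeded operations (`with_seed`) save and restore the caller's RNG
  state, so package calls never perturb user randomness.

## Problem sizes

The test suite and the acceptance script use a 3,000-beat dataset for the
cross-validated end-to-end run (with the desk-scale GA: population 10, 10
generations, ≈6–7 minutes on one CPU), 10,000 beats for the float/integer
parity audit, 10⁵–10⁶ sampled entries for the ternary-law checks, and the
exhaustive 16-bit axis for linearization sweeps. These sizes were chosen as
the smallest at which the stochastic checks are stable across seeds.

## Known limitations

* FPD onset/end points are threshold crossings of wavelet moduli; they are
  reproducible but not claimed identical to any published delineator's
  boundaries (those thresholds are not public).
* The baseline comparison tunes a decision threshold on each baseline's
  scores to meet the ARR bound; classifiers without a tunable score would
  need the 1-percentage-point relaxation loop, which is implemented but
  rarely triggered.
* The GA's selection scheme and rates (tournament 3, elitism 2, crossover
  0.9, mutation 0.02) are declared package defaults; the reference work
  names the operators but not these values.
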