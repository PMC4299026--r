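# ecgtriage

Early triage of pathological heartbeats for embedded, battery-powered ECG
monitors.

A wearable single-lead ECG sensor cannot run a detailed morphological
analysis (or transmit a full description) of every heartbeat. Since most
beats in long-term recordings are normal, a cheap on-node classifier can
*triage*: discard beats it confidently labels normal and forward only
suspected pathology — premature ventricular contractions (V) and left
bundle branch block beats (L) — for detailed analysis. This package
implements that triage pipeline end to end, including the integer-only
inference path such a microcontroller would actually execute, plus the
synthetic data, training, optimization and evaluation machinery around it.

## The method

Each detected beat is a window **v** of d = 201 samples centered on the R
peak (100 samples each side at 360 Hz). It is reduced to k ∈ {8, 16}
coefficients **u** by one of:

* **Sparse ternary random projection** — **u** = **P v** with Pᵢⱼ ∈
  {−1, 0, +1} drawn i.i.d. with probabilities (1/6, 2/3, 1/6), computable by
  signed accumulation alone and storable at 2 bits/entry. **P** is optimized
  jointly with the classifier by a genetic algorithm.
* **PCA** — **u** = **T**(**v** − E[**v**]), **T** the leading eigenvectors
  of the sample covariance, computed by power iteration with deflation.
* **Fiducial points** — 8 signed sample offsets (P onset/peak/end, QRS
  onset/end, T onset/peak/end) relative to R, from a dyadic-wavelet
  delineator; optionally concatenated with 8 projection coefficients.

The classifier is a three-layer neuro-fuzzy network: gaussian membership
functions μₖ,ₗ(uₖ) = exp(−(uₖ−cₖ,ₗ)²/2σₖ,ₗ²) per coefficient and class;
fuzzy values fₗ = Πₖ μₖ,ₗ(uₖ); and the decision rule

> label = argmaxₗ fₗ  if  (M1 − M2) ≥ α · S,  else  U (unknown)

where M1, M2 are the two largest fuzzy values and S = Σₗ fₗ. V, L and U all
count as *pathological* (forwarded); only N is discarded. Performance is
reported as the **Normal Discard Rate** (NDR, fraction of true normals
discarded) and **Abnormal Recognition Rate** (ARR, fraction of true
pathology forwarded); α is tuned to the smallest value with ARR ≥ 95% on a
tuning set, and can be retargeted at run time without retraining.

For deployment, `quantize_model()` produces a bit-exact integer mirror:
piecewise-linear membership functions on a 16-bit grid (breakpoints at
S = 2.35σ, 2S and 4S), overflow-driven shift-truncate products in 32-bit
accumulators, and a division-free decision (M1 − M2)·2¹⁶ ≥ α_q16·S.

## Worked example

```r
library(ecgtriage)

# 600 labeled synthetic beats (N/V/L mix mirroring the reference census)
ds <- generate_dataset(record_spec(n_beats = 600, seed = 101))
ds
#> <beat_set> 600 beats x 201 samples, classes: L=50 N=505 V=45

# random projection to 16 coefficients, then train + tune the classifier
P     <- sample_achlioptas(16, ds$d, seed = 77)
feats <- ds$windows %*% t(unclass(P))
tr    <- ds$fold != 4
model <- train_model(init_model(feats[tr, ], ds$labels[tr]),
                     feats[tr, ], ds$labels[tr])
model$alpha <- as.numeric(tune_alpha(model, feats[tr, ], ds$labels[tr],
                                     arr_min = 0.95))
model
#> <nfc_model> k=16 coefficients, 48 gaussian MFs (trained), alpha=0

# evaluate triage on the held-out fold
pred <- vapply(which(!tr),
               function(i) classify(model, feats[i, ])$label, "")
compute_ndr_arr(pred, ds$labels[!tr])
#> <eval_report> n=149  NDR=1.0000  ARR=1.0000
#>       N   V   L   U
#>   N 126   0   0   0
#>   V   0  11   0   0
#>   L   0   0  12   0
```

An NDR of 1.0 means every true-normal test beat was discarded; an ARR of
1.0 means every V and L beat was forwarded. (Synthetic classes are far
better separated than real arrhythmia data — see the methods vignette for
what this does and does not demonstrate.) The quantized integer path is one
call away:

```r
qm <- quantize_model(model)
parity_audit(model, qm, feats, ds$labels)$agreement
#> [1] 1
```

The full pipeline — synthesis, GA-driven training, quantization, streaming
classification of a record CSV, cross-validation, Pareto sweeps, baseline
comparison — is scriptable via `run_pipeline()` or the thin CLI at
`inst/cli/ecgtriage` (subcommands `synth`, `train`, `quantize`, `classify`,
`evaluate`, `sweep`, `compare`).

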