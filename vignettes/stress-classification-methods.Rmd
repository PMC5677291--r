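---
title: "Classifying five stress states from PPG, EDA and SKT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying five stress states from PPG, EDA and SKT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresskelm)
```

## The problem

Mental stress shifts the balance of the autonomic nervous system:
sympathetic activation raises heart rate and sudomotor (sweat gland)
activity and changes peripheral temperature, while parasympathetic
(vagal) tone — visible as beat-to-beat heart-rate variability —
withdraws. `stresskelm` implements a complete pipeline that turns three
wearable-grade biosignals — a photoplethysmogram (PPG), electrodermal
activity (EDA) and skin temperature (SKT) — into a 24-feature panel per
6-second epoch and classifies five protocol states: baseline (BA-S),
mild (MIS-S), moderate (MOS-S) and severe (SES-S) stress, and recovery
(RE-S).

The protocol emulated throughout is: five sessions of 240 s per
subject, all channels sampled at 400 Hz; the first 35 s of each session
are discarded as unstable and the remainder is cut into 6-s epochs,
giving 34 epochs per session, 170 per subject, and 2040 for a
12-subject cohort.

## Feature panel

**HRV (15 features).** The PPG is band-pass filtered to 0.5–4 Hz
(zero-phase 4th-order Butterworth, forward–backward so pulse timing is
preserved; the signal is demeaned and reflect-padded to suppress edge
transients). Pulse peaks are local maxima above an adaptive threshold
(median + 0.5 IQR of the filtered signal) with a 0.3 s refractory
period, and successive peak differences form the NN intervals. From
them: `HRavg`, `NNavg`, `SDNN`, `SDSD`, `RMSSD`, `pNN20`, `pNN50`
(time domain); `LFnormal`, `HFnormal`, `LF/HF` from a Burg
autoregressive spectrum of the cubic-spline NN tachogram resampled at
4 Hz, with band areas 0.04–0.15 Hz and 0.15–0.4 Hz (frequency domain);
approximate and sample entropy (`m = 2`, `r = 0.2 × SDNN`, Chebyshev
distance; ApEn includes self-matches, SampEn excludes them) and
Poincaré `SD1`, `SD2`, `SD1/SD2` (nonlinear).

Two conventions deserve note. The `pNNx` denominator is the *total
number of NN intervals*, not the number of successive pairs; the more
common pairs convention is available via
`pnn_denominator = "pairs"`. All dispersion statistics use the
sample-SD (n−1) convention, and the Poincaré identity
`SD1² = SDSD²/2` is exact under it.

**EDA (6 features).** Skin conductance is decomposed per session into
a tonic level (SCL) and a phasic component (SCR) driven by discrete
sudomotor events. The decomposition is a joint penalized least-squares
fit `y ≈ tonic + driver ⊛ Bateman` on an 8 Hz decimated grid — the
tonic carries a stiff second-difference penalty (its null space
contains linear drifts), the driver is ridge-penalized and constrained
non-negative by active-set refinement — followed by a full-rate
orthogonal-matching-pursuit refit of each event's onset and amplitude
against the Bateman kernel `exp(-t/τ2) − exp(-t/τ1)` (τ1 = 0.75 s,
τ2 = 2 s, peak-normalized). Features per epoch: `SCavg`, `SCLavg`,
`SCLslope` (the tonic excursion max−min, a range by definition),
`SCRavg`, `SCRmax`, and `SCRpeak` (phasic local maxima ≥ 0.01 µS).
This decomposition is written from first principles; it is functionally
analogous to, but not a re-implementation of, the established
continuous-decomposition tools.

**SKT (3 features).** `SKTavg`, `SKTslope` (max−min) and `SKTstd` per
epoch.

Epochs too short on information (fewer than 3 NN intervals, or an
undefined entropy) carry `NA` markers that are imputed with the
subject-session median so the classifier input stays rectangular; the
imputed cell count is recorded on the feature table.

## The classifier

The extreme learning machine (ELM) is a single-hidden-layer network
whose input weights `w_j` and biases `b_j` are random (here uniform on
[−1, 1] and [0, 1], seeded; sigmoid activation). With hidden matrix
`H[i,j] = g(w_j' x_i + b_j)` and one-hot targets `T`, the output
weights have the ridge-regularized closed form

    B = H' (I/C + H H')^{-1} T

(or the algebraically equivalent `(I/C + H'H)^{-1} H' T` when the
hidden layer is smaller than the training set — the package uses
whichever is cheaper and unit-tests their agreement). As `C → ∞` this
approaches the minimum-norm least-squares solution through the
Moore–Penrose pseudo-inverse of `H`.

The kernel ELM replaces the explicit hidden map with a Mercer kernel
`Ω[i,j] = k(x_i, x_j)`:

    f(x) = [k(x, x_1), …, k(x, x_N)] (I/C + Ω)^{-1} T

solved as a symmetric positive-definite system by Cholesky (never an
explicit inverse; an LU fallback covers systems driven to the edge of
positive definiteness by extreme `C`). The default kernel is the RBF
`k(x, x') = exp(-γ ||x − x'||²)`. When the kernel is the inner product
of a fixed hidden map the K-ELM reproduces the ELM exactly; this
identity is an acceptance-tested invariant. Class decisions are the
argmax of the score vector with ties resolved to the lowest class
index. Features are z-scored with *training* statistics only (no
leakage into held-out epochs); zero-variance features pass through
centered.

## Evaluation protocol

Cross-validation is leave-one-out *within subject*: each of a
subject's 170 epochs is held out once while the classifier trains on
the remaining 169, so no subject-level information leaks across folds
but session structure within a subject is exploited, exactly as in the
emulated protocol. Cohort accuracy is reported both epoch-weighted and
subject-weighted (identical for equal-size subjects). The (C, γ) grid
search scores every cell by the same LOOCV it reports — deliberately
replicating the emulated (optimistically biased) model-selection
protocol; ties resolve to the smallest C, then the smallest γ. The
conventional screening grid is the 15-point ladder `10^(-8..6)` for
both parameters; the packaged benchmark uses a 5×5 subgrid
(C ∈ 10^{−2,0,2,4,6}, γ ∈ 10^{−3..1}) to keep the full-cohort run in
the minutes range.

Feature statistics use one-way ANOVA (`F = MS_between/MS_within`, via
`stats::aov`) with Tukey HSD pairwise comparisons (studentized-range
`q = |mean_i − mean_j| / sqrt(MS_within/n)`, equal group sizes
required). A type-I calibration check (3 groups × 12, 10⁴ null
replicates) is part of the acceptance suite.

The self-organizing map is a batch SOM on a 10×10 hexagonal lattice
(Gaussian neighborhood, radius decaying linearly to 0.5; inputs
z-scored because the panel mixes ms, µS and °C scales), with a
U-matrix view (mean weight-space distance to hex neighbors) and
k-means (k = 5, 10 restarts) on the neuron weights. Batch training
was chosen over online updates for determinism under a seed.

## What the synthetic generator emulates — and what it does not

No public recordings exist for this protocol, so validation rests on a
seeded generator whose parameters encode the expected autonomic
gradient:

```{r}
str(default_session_params()[["SES-S"]], give.attr = FALSE)
```

* **PPG**: heart periods follow `mean_rr + sd_rr·AR(1)` plus a
  respiratory sinus-arrhythmia sinusoid; a Gaussian systolic lobe
  (width 0.35 s — wide enough to be band-limited to the 0.5–4 Hz
  analysis band; a narrower lobe makes the band-pass ring and its
  sidelobes masquerade as pulse peaks at slow heart rates) is placed
  at each beat over a slow baseline.
* **EDA**: tonic level + linear drift + slow wander, plus a Poisson
  train of Bateman-shaped events with log-normal amplitudes.
* **SKT**: mean + drift + slow wander.

The default session ladder runs heart period
1000/840/760/670/920 ms with heart-period noise 34/29/23/16/44 ms and
RSA amplitude 30/24/16/8/30 ms (vagal withdrawal), SCR rates 2–12 /min
with amplitudes 0.30–0.75 µS over tonic levels 2.0–3.0 µS, and SKT
means 33.0–33.4 °C. These were chosen once, by epoch-level
signal-to-noise arithmetic, to realize the intended channel ordering —
heart rate most informative, skin conductance intermediate,
temperature weakest: with ~7 beats per 6-s epoch the epoch-mean heart
period resolves session gaps of ~100 ms at ≥4 standard errors, while
the SKT session gaps (0.10–0.15 °C) are deliberately comparable to its
slow wander (0.10 °C). `separability = "high"` scales session
contrasts by 1.3 and the wander down by 0.7 for the benchmark cohort;
`"low"` halves the contrasts.

The generator does **not** emulate: realistic PPG morphology (dicrotic
notch), motion artifacts or electrode drift, ectopic beats,
respiration as a measured channel, between-session carry-over, or
circadian temperature structure. A pipeline that passes the packaged
benchmarks is therefore validated for *algorithmic correctness and
end-to-end recoverability*, not for field performance on real
wearable data.

## Numerical choices and degenerate inputs

* 6-s epochs contain ~5–9 NN intervals. The low-frequency band
  (0.04–0.15 Hz) is formally unresolvable on such epochs; the spectral
  features are computed anyway, matching the emulated protocol, and
  behave as weakly informative noise. The Burg order (default 16) is
  capped at `floor(n/2) − 1`; a zero-variance tachogram returns a zero
  spectrum; `LF/HF` is capped at 100 when the HF integral vanishes.
* Constant series have entropy 0 by convention (perfect regularity);
  an undefined SampEn (no template matches) is a missing-feature
  marker, not a number.
* The EDA deconvolution cannot separate events closer than about one
  second — they merge into one fitted event. Exact event-count
  recovery is guaranteed (and acceptance-tested) for well-separated
  zero-noise trains; dense Poisson bursts may merge.
* Peak detection at slow heart rates is sensitive to filter ringing;
  the refractory rule drops the smaller of two candidates closer than
  0.3 s (capping heart rate at 200 bpm).
* LOOCV folds whose ridge system loses positive definiteness under
  extreme `C` fall back to an LU solve rather than failing the fold.

## Known limitations

* The grid search reuses the reporting LOOCV, so its best accuracy is
  an optimistically biased estimate — kept because the package's
  purpose is to reproduce that protocol faithfully. Nested
  cross-validation is the obvious extension.
* Within-subject LOOCV accuracy does not transfer to subject-independent
  deployment; no cross-subject generalization claim is made.
* The 5-class chance control uses within-subject label permutation;
  LOOCV predictions are weakly dependent, so the binomial reference
  interval is approximate.
* Benchmark problem sizes (12 subjects × 240 s, 5×5 grid, 10⁴ ANOVA
  replicates, 200 entropy oracle series) are the package's validation
  defaults; all are arguments and can be scaled up.
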