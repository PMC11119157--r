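---
title: "Task-specific connectivity graphs and attention for trial-wise EEG classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-specific connectivity graphs and attention for trial-wise EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model implemented by **emognn**, the
assumptions behind it, the tunable parameters and their defaults, the
synthetic data the package uses to validate itself, and the design choices
made where the architecture left genuine freedom.

## 1. The classification problem

The unit of analysis is an EEG *trial*: a `C × T` real matrix (channels ×
samples, microvolts) recorded at a fixed sampling rate `fs`, carrying one
of two class labels (e.g. positive vs negative emotional stimulus, or
high vs low valence). Trials are cut into overlapping windows
("segments") that inherit the trial's label; the segment is what the model
actually sees. Windows are half-open sample ranges `[s, s + w)` advancing
by `window_s − overlap_s` seconds; an incomplete tail is dropped; seconds
convert to samples by rounding half away from zero. A 60 s trial at
128 Hz with a 4 s window and 2 s overlap therefore yields 29 segments.

Preprocessing is a zero-phase 4th-order Butterworth band-pass (applied
forward and backward with `signal::filtfilt`), by default 4–45 Hz — the
theta-through-gamma range conventionally retained in affective EEG work.
The filter family is a package choice; any zero-phase band-pass with
comparable roll-off would serve.

## 2. Node features: multi-scale log-power encoding with kernel attention

Each channel is convolved ("valid", stride 1) with three parallel banks of
`K = 9` learned kernels. Kernel lengths follow the sampling rate:

\[ S_r = \mathrm{round}(0.5^r \cdot fs), \quad r = 1, 2, 3, \]

i.e. half-, quarter- and eighth-second filters — matched filters for
rhythms down to ~2 Hz, ~4 Hz and ~8 Hz respectively. Each filter output is
squared, average-pooled and log-transformed, giving a log-power profile
over time per kernel — the classic band-power feature, but with learned
rather than fixed filters.

Within each scale, *kernel attention* scores each kernel's feature row by
its normalized scalar projection onto a trainable direction `q_r`,
softmaxes the nine scores, and rescales the rows by the resulting weights.
Kernels and `q_r` are shared across channels, so the encoder is
channel-permutation equivariant. Concatenating the weighted per-scale
blocks gives the node-feature matrix `Z ∈ R^{C×SK}`,
`SK = K · Σ_r F_r`.

Choices the architecture left open, and what this package does:

* **The kernel index and length.** The kernel-sizing rule carries a
  per-kernel index but no per-kernel dependence; we read it as nine
  *distinct learned filters per scale, all of length `S_r`* (consistent
  with "nine kernels for each scale"), rather than nine different lengths.
* **Pooling.** Pool length and stride are unstated upstream; the default
  is `pool_len = pool_stride = round(fs/4)` — non-overlapping
  quarter-second power bins, a standard compromise between temporal
  resolution and variance. Both are configurable.
* **Log floor.** `log(x + ε)` with `ε = 1e-6` keeps silent inputs finite;
  every feature of an all-zero channel equals `log ε`.
* **Attention sharing.** One `q_r` per scale, shared across channels and
  kernels, mirroring the sharing of the kernels themselves.

## 3. Task-specific adjacency pairs

Functional connectivity between channels is measured four ways
(`conn_spec(method = ...)`):

* **Cor** — Pearson correlation over time (linear covariation, signed);
* **Coh** — magnitude-squared coherence `|S_ab|²/(S_aa S_bb)` from Welch
  cross-spectra (Hann window, 1 s segments, 50% overlap by default),
  averaged with equal weight over the frequency bins inside the analysis
  band (the reduction of the coherence spectrum to a scalar is a package
  choice; nothing upstream specifies it);
* **PLV** — the magnitude of the mean phase-difference phasor
  `|E[e^{iΔϕ}]|`, phases taken from the analytic signal after band-pass,
  with 1 s discarded at each edge to suppress filter and transform
  transients (segments must therefore be at least 3 s long);
* **PLI** — the phase-lag index `|E[sign(sin Δϕ)]|`. The source prints
  `sign(Δϕ)` without the sine, which is ill-defined for wrapped phases;
  `sign(sin Δϕ)` is the standard phase-lag index and reproduces the stated
  analytic endpoints (0 at zero lag, 1 at a constant +π/2 lag).

The *task-specific* graph pair is built per class: the adjacency for class
`l` is the element-wise mean of the per-segment connectivity matrices over
that class's **training** segments. Correlation matrices pass through the
absolute value per segment first — symmetric normalization requires
nonnegative weights, and anticorrelation is as much "connectivity" as
correlation. The diagonal is then set to 1 (the usual self-loop
convention; the raw PLI diagonal is 0 and would otherwise delete a node's
own contribution), and the matrix is symmetric-normalized,
`Ã = D^{-1/2} A D^{-1/2}` with `D_aa = Σ_b A_ab`.

Two leakage rules are enforced by construction and asserted at run time:
adjacencies are estimated from training segments only, and segments are
assigned to folds by their parent trial. Whether connectivity should be
averaged over trials or segments, and over which split, was unstated
upstream; averaging over training segments uses all available training
data and keeps the estimator consistent with the unit the model consumes.

## 4. Graph aggregation with adjacency attention

Per connectivity variant, the node features pass through a two-stage graph
convolution over the pair of class graphs:

1. `Z_l = relu(Ã_l Z W_l)`, one weight matrix per class
   (`W_l ∈ R^{SK×SK/2}`); the rectifier is a package choice, the
   activation being unnamed upstream.
2. *Adjacency attention*: each class branch scores every ordered channel
   pair by a logistic-squashed linear function of the concatenated pair
   features, `score_l[a,b] = σ(c(Z_l[a,], Z_l[b,]) · P_l)`, and the gate is
   the sum `ascore = score_l1 + score_l2 ∈ (0, 2)` — the logistic realizes
   the required "weighted elements tend towards 1, unweighted towards 0"
   behaviour. The gate multiplies both normalized adjacencies element-wise
   (uniformly, self-loops included); we deliberately do *not* re-normalize
   afterwards, which would erase the attention magnitudes.
3. `Z̄_l = relu((ascore ⊙ Ã_l) Z_l W_as)` with a single `W_as ∈
   R^{SK/2×SK/4}` shared by the two class branches (the notation upstream
   shows one symbol).

`SK` is validated to be divisible by 4 at model build so the halvings are
exact. With zero projection vectors the gate is exactly 1 everywhere and
the stage reduces to a plain two-layer GCN — the ablation switch
`adjacency_attention = FALSE` removes `P_l1`, `P_l2` entirely.

## 5. Fusion, loss, training

Per variant, the two `C × SK/4` branch outputs are concatenated and
flattened (length `C·SK/2`), passed through that variant's MLP
(hidden size `h1 = 64`) and softmaxed into a two-class score pair — the
softmax is *within* the variant, weighting its two class scores; a softmax
across variants would discard the per-variant class structure. The score
pairs are concatenated (length `2·|variants|`) and classified by a shared
MLP (hidden size `h2 = 16`). Hidden sizes are package defaults; nothing
upstream fixes them.

The loss is mean cross-entropy plus `λ Σ θ²` over weights (not biases),
`λ = 1e-4` by default. Optimization is Adam (`lr = 1e-3`, batch 64).
Backpropagation is implemented analytically in base R; the test suite
verifies gradients against central finite differences to 1e-4 relative on
small instances, and verifies that the batched gradient path used in
training is numerically identical to per-segment backpropagation.

**Epoch budget.** Defaults are `max_epochs = 6`, `patience = 2`,
`fine_tune_epochs = 3`. These are deliberately small: on the desk-scale
synthetic problems this package targets, validation accuracy saturates
within one or two epochs while validation loss keeps creeping downward, so
a long patience never triggers and only adds runtime. For harder or real
data, raise `max_epochs` and `patience` in `emognn_control()`.

## 6. Nested cross-validation

`emognn_cv()` implements the full protocol: trials of each class are
shuffled (seeded) and split into 5 near-equal outer folds; per outer fold,
the remaining trials form 4 inner train/validation folds per class. Each
inner fold trains with early stopping — training halts once validation
loss has failed to improve for more than `patience` consecutive epochs —
and the model with the highest validation accuracy is selected (ties:
lowest validation loss, then lowest fold index; the selection metric is a
package choice, "best model" being otherwise unspecified). That model is
fine-tuned for `fine_tune_epochs` on all training + validation segments,
with adjacencies rebuilt from that pooled set, and evaluated once on the
outer test segments. Metrics (ACC, Precision, Recall, F1) are reported per
segment — the sample unit after windowing — per fold and as mean ± sd
across folds; a trial-level majority-vote table is emitted as a secondary
report. One master seed drives fold shuffling, weight initialization and
batch order; the whole protocol is bit-reproducible from it.

Per-segment connectivity matrices are computed once and averaged per fold,
which is algebraically identical to rebuilding each fold's adjacencies
from scratch.

## 7. The synthetic data generator

`simulate_eeg_dataset()` produces the class structure the adjacency
construction assumes, with no real data required:

* every channel carries 1/f-amplitude ("pink") background noise, built by
  spectral shaping of white noise (amplitude `∝ 1/√f`, so power `∝ 1/f`),
  scaled to standard deviation `noise_amp`;
* trials of class `l` add `coupling_amp · sin(2π f0 t + φ)` on that
  class's coupled channel set, with one random starting phase per trial
  (shared within the trial) and fixed per-channel offsets drawn once per
  dataset — so within-set phase locking is perfect before noise and, by
  the once-per-dataset offsets, *stable across trials*, matching the
  stationarity the class-conditional adjacency assumes;
* an optional per-class band-power boost (off by default) adds
  band-filtered noise to chosen channels, exercising the encoder's
  spectral sensitivity separately from connectivity.

The default configuration is the package's benchmark condition: 16
channels, 128 Hz, 10 s trials, 40 trials per class, a 10 Hz rhythm on
channels 1–4 (class 1) versus 5–8 (class 2), amplitude 1 against noise 0.2
(ratio 5 — a strong-coupling regime in which the planted edges dominate
the adjacency difference and the classes are cleanly separable). Where no
value was prescribed, these were chosen once as a realistic-but-favourable
testbed and are not revisited.

What passing tests on this generator do and do not show: the synthetic
signals have the right second-order structure (1/f background, planted
narrow-band coupling, class-conditional graphs) but none of real EEG's
hard parts — volume conduction, artifacts, non-stationarity across a
session, inter-subject variability. Results on it validate the
*implementation* (that the pipeline recovers structure it provably
contains), not the method's performance on real recordings.

## 8. Numerical choices and degenerate inputs

* Seconds → samples via round-half-away-from-zero everywhere (R's default
  `round()` is round-half-even).
* A zero-variance channel yields zero off-diagonal correlation entries and
  a warning, not an error; a zero row sum in an adjacency (which would
  make the normalization undefined) is an error naming the channel.
* Precision/Recall/F1 with zero denominators are reported as 0 with a
  warning; an empty confusion table is an error.
* Softmaxes and log-softmax are max-shifted for overflow safety; the
  encoder's log floor guarantees finite features for any finite input.
* Ties in prediction (`max.col`) resolve to the first (positive) class;
  trial-level majority votes at exactly 0.5 resolve to the positive class.
* Convolutions run as im2col matrix products; sliding-window index tables
  and pooling plans are cached per shape, and the im2col matrices are
  precomputed once per segment within a training run (they depend only on
  the data).
* EDF output quantizes to the format's native 16 bits over each channel's
  observed range; a round trip is exact to ~1/65000 of that range.
  On-disk datasets are EDF files plus a `labels.csv` manifest
  (`trial_id,label`).

## 9. Known limitations

* Binary classification only; the fusion head is two-class by design.
* Undirected, scalar-per-pair connectivity: no directed or lagged measures
  and no frequency-resolved (per-band vector) adjacencies.
* The nested CV is within-dataset; leave-subject-out evaluation is out of
  scope.
* Training is single-threaded CPU matrix algebra; it is sized for
  desk-scale experiments (seconds per epoch at C = 16, T = 512), not for
  large-scale studies.
* The benchmark problem sizes used in the automated checks (16 channels,
  40 trials per class, 10 s trials, 4 s non-overlapping windows) were
  chosen to make the full nested protocol run in minutes on one core
  while leaving the planted structure comfortably recoverable.
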