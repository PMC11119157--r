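# emognn

Trial-wise binary classification of multichannel EEG — positive versus
negative emotional condition — with a temporal–spatial attention network
built on *task-specific* functional-connectivity graphs, implemented
natively in R (forward pass and backpropagation included; no external
deep-learning runtime).

## Who this is for

Researchers working on EEG-based affective state decoding who want a
self-contained, inspectable R implementation of a graph-neural-network
classifier whose graph structure is estimated from the data per class,
together with the surrounding machinery a study needs: band-pass filtering,
overlapping-window segmentation, EDF input/output, a synthetic EEG
generator with planted class structure, and a leakage-safe nested
cross-validation protocol.

## The model

An EEG segment is a matrix `X ∈ R^{C×T}` (C channels, T samples at `fs` Hz)
with a binary label `y ∈ {l1, l2}`.

**Node encoding.** Each channel is encoded by three parallel banks of nine
learned 1-D convolution kernels whose lengths follow the sampling rate,
`S_r = round(0.5^r · fs)`, r = 1, 2, 3 (half-, quarter-, eighth-second
filters). Filter outputs are squared, average-pooled and log-transformed
into band-power-like features. Within each scale a *kernel attention*
softmax weights the nine kernels by their normalized scalar projection onto
a trained direction `q_r`. Concatenating scales gives node features
`Z ∈ R^{C×SK}`; kernels and `q_r` are shared across channels.

**Task-specific graphs.** For each connectivity measure
θ ∈ {Cor, Coh, PLV, PLI} and each class `l`, an adjacency
`adj_l = mean over class-l training segments of the C×C connectivity
matrix` (absolute value first for correlation), with unit diagonal, is
symmetric-normalized: `Ã_l = D^{-1/2} adj_l D^{-1/2}`. The pair (Ã_l1,
Ã_l2) encodes how channel dependencies differ between the two conditions.

**Graph aggregation.** Per variant: first-stage graph convolutions
`Z_l = relu(Ã_l Z W_l)` (one per class, `W_l ∈ R^{SK×SK/2}`); an *adjacency
attention* gate `ascore[a,b] = σ(pair(Z_l1)·P_l1) + σ(pair(Z_l2)·P_l2)
∈ (0,2)` modulates both graphs element-wise; a shared second stage
`Z̄_l = relu((ascore ⊙ Ã_l) Z_l W_as)` gives `C × SK/4` outputs per class.

**Fusion and loss.** Per variant the two class branches are flattened into
a vector of length `C·SK/2`, passed through a per-variant MLP and softmaxed
into a two-class score pair; the pairs of all variants are concatenated and
classified by a shared second MLP. Training minimizes mean cross-entropy
plus `λ Σ θ²` (weights only) with Adam; analytic gradients are verified
against finite differences in the test suite.

**Evaluation.** Stratified trial-wise nested cross-validation: a 5-fold
outer loop for unbiased testing, a 4-fold inner loop for early stopping and
model selection, fine-tuning of the best inner model on all
training + validation data, and a single evaluation on the untouched outer
test trials. Segments always follow their parent trial, and task
adjacencies are built from training segments only — no segment of a test
trial ever influences training. ACC, Precision, Recall and F1 come from
the confusion counts.

## Worked example

Simulate 8-channel EEG where the positive class carries a shared 10 Hz
rhythm on channels 1–3 and the negative class on channels 6–8, recover the
planted graph structure, and run the full nested cross-validation:

```r
library(emognn)

cfg <- sim_config(n_channels = 8, fs = 64, duration_s = 10,
                  trials_per_class = 8, coupled_l1 = 1:3, coupled_l2 = 6:8,
                  seed = 42)
trials <- simulate_eeg_dataset(cfg)

segs <- segment_trials(trials, window_s = 4, overlap_s = 0)
ta <- build_task_adjacency(segs, conn_spec("PLV", band = c(4, 30)))
round(ta$adj[["positive"]][1:4, 1:4], 2)
#>      ch1  ch2  ch3  ch4
#> ch1 1.00 0.99 0.99 0.16
#> ch2 0.99 1.00 0.99 0.16
#> ch3 0.99 0.99 1.00 0.16
#> ch4 0.16 0.16 0.16 1.00

planted_edge_report(ta, cfg)
#>   n_edges precision recall
#> 1       6         1      1

cv <- emognn_cv(trials, window_s = 4, overlap_s = 0,
                config = emognn_config(fs = 64, variants = "PLV",
                                       band = c(4, 30)),
                control = emognn_control(seed = 1))
cv
#> Nested cross-validation (5 outer x 4 inner folds, seed 1)
#>   variants: PLV
#>   mean ACC       0.9000 (sd 0.2236)
#>   mean Precision 0.9000 (sd 0.2236)
#>   mean Recall    1.0000 (sd 0.0000)
#>   mean F1        0.9333 (sd 0.1491)
```

The adjacency block shows the planted positive-class phase coupling
(within-set PLV ≈ 0.99 against a ≈ 0.16 noise floor); the edge report
confirms all six planted pairs rank first in `|adj_l1 − adj_l2|`; the
cross-validation accuracy is the mean over the five outer test folds of
this deliberately small demonstration (one fold misclassifies some of its
few test segments; the package's benchmark configuration `sim_config()`,
with 16 channels and 40 trials per class, is exercised in
`tests/testthat/test-acceptance.R`).

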