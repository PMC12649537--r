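---
title: "Local-global EEG emotion decoding: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-global EEG emotion decoding: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2geeg)
```

## The problem and the model

Affective state is usually described on continuous dimensions — valence (how
pleasant), arousal (how activating), dominance (how in-control) — rated by the
subject on a 1–9 self-assessment scale after each stimulus. Decoding these
dimensions from scalp EEG is hard because the class-relevant signal is spread
over both *local* oscillatory structure (band power in particular scalp
regions, e.g. frontal alpha asymmetry) and *global* relations between regions,
and because EEG transfers poorly across subjects.

`c2geeg` implements a cluster-to-global ("C2G") architecture for this task:

1. **Electrode clustering.** The montage's channels are grouped into nine
   spatial clusters in a fixed order — prefrontal, frontal, left temporal,
   central, right temporal, left parietal, mid-parietal, right parietal,
   occipital. The assignment is a configuration file, not a hard-coded rule;
   shipped defaults cover 32- and 62-channel 10–20 layouts plus a 9-channel
   toy montage with one channel per cluster. Cluster maps are strict
   partitions: overlapping assignments are rejected by
   `validate_cluster_map()`.

2. **Per-cluster Deformer.** Each cluster's windows pass through an EEG
   Deformer: a shallow feature encoder (SFE: temporal convolution with kernel
   `round(0.1 * fs)` rounded up to odd, a channel-mixing convolution,
   BatchNorm, ELU, temporal max-pooling, token rearrangement and sinusoidal
   positional encoding), then L hierarchical coarse-to-fine transformer (HCT)
   blocks. Each block runs two parallel paths over the token sequence: a
   coarse path `FFN(LayerNorm(MSA(W_p MaxPool(F) + b_p) + MaxPool(F)))`
   (multi-head self-attention on stride-2-pooled tokens with a residual from
   the pooled tokens), and a fine path
   `MaxPool(ELU(BatchNorm(Conv(Dropout(F)))))`. Both halve the token count and
   are concatenated along time, so the block preserves an even token count.
   Each block's fine embedding is tapped by the dense information
   purification (DIP) module: the IP-unit computes a log power
   `log(mean_t x^2 + 1e-8)` per feature, and the per-block vectors are densely
   concatenated. The fused cluster vector is a learned linear projection of
   `[mean_t(final tokens), DIP]` to dimension d.

3. **Global integration.** The nine cluster vectors are stacked into a 9 x d
   matrix and refined by bidirectional cross-attention (BCA): per layer,
   scaled dot-product attention among the nine rows (`alpha[i, j]` is the
   attention cluster i pays to j; both directions of each pair appear in one
   softmax pass), a depthwise temporal convolution across the trial's window
   sequence, and a GELU feed-forward network, each wrapped in residual +
   LayerNorm. Per window the refined matrix is flattened; the trial's window
   sequence then feeds a causal dilated temporal convolutional network (TCN),
   temporal average pooling, and an MLP softmax head. The default TCN
   (3 blocks, kernels 3/5/7, dilations 1/2/4) has a receptive field of
   `1 + sum(2 (k_b - 1) d_b) = 69` windows.

Full-scale defaults follow the published configuration: 64 SFE filters,
3 HCT layers with 16 heads of dimension 16 and FFN width 16, dropout 0.2,
4 BCA layers (16 heads, temporal kernel 13, dilations 1/2/4/8, FFN 128),
TCN with 64 filters, Adam at learning rate 0.001 with weight decay 1e-5,
batch 32, 100 epochs, cross-entropy loss.

## Preprocessing

`preprocess_recording()` applies, in order: optional polyphase resampling, an
optional leading-baseline drop, a zero-phase Butterworth band-pass (4–47 Hz),
common-average re-referencing, optional stacked-sparse-autoencoder denoising,
4-s windowing, and per-window per-channel z-scoring. Choices worth noting:

* **Filter order.** The band-pass defaults to order 6 (forward–backward, so
  12 poles effective). Order 4 leaves a 55 Hz tone only ~17 dB down after the
  zero-phase pass; order 6 gives ~25 dB while the 4–47 Hz passband stays flat
  to better than 0.1%. The order is a parameter.
* **Ordering.** Filtering precedes re-referencing; both are linear, so the
  order only matters in the presence of the optional nonlinear denoiser,
  which runs after re-referencing on the broadband-cleaned signal.
* **z-scoring** is per window and per channel, with constant channels mapped
  to zero (and counted in a warning). It removes absolute amplitude, so any
  class signal must live in the *relative* spectral and temporal structure —
  which is also what transfers across subjects.
* **The SSAE denoiser** is a two-layer-encoder autoencoder over one-second
  per-channel segments with an L1 penalty on the code, trained on clean
  windows. It is optional and off by default: reconstruction through a
  low-dimensional code attenuates transients (blinks) that the clean manifold
  cannot express, at the cost of a few percent signal distortion.

## The synthetic benchmark

Real rating datasets are licensed and far too large to train on in a test
suite, so the package ships a class-conditional generator
(`synthetic_spec()`, `generate_trial()`, `generate_dataset()`) and a fixed
desk-scale study (`benchmark_spec()`, `run_benchmark()`).

Each channel is a sum of four band-limited Gaussian oscillations (theta
4–8 Hz, alpha 8–13, beta 13–30, gamma 30–45) whose variances follow a
class-by-cluster signature, plus a 1/f background, plus Poisson-timed 300-ms
raised-cosine blink transients on prefrontal channels. The oscillations are
*stochastic* narrowband processes (spectrally shaped noise with a soft
subject-jittered peak), not pure tones: real rhythms wander in amplitude and
instantaneous frequency, and a constant-frequency tone would let a classifier
memorise per-trial carrier frequencies instead of band structure. Per-subject
variability enters as a multiplicative band gain (log-sd 0.1) and a spectral
peak jitter (sd 0.5 Hz). Band powers are exact by construction;
`verify_spectral_signature()` checks Welch estimates against the targets plus
the analytically known 1/f band contribution.

The default class signatures encode high valence as a left-to-right alpha
asymmetry over temporal/parietal clusters (x0.4 left, x2.0 right; reversed
for low valence) and high arousal as elevated beta and gamma (x2.5) over
frontal, central and mid-parietal clusters (x0.6 when low). This gives the
clustering and cross-attention stages genuinely cluster-localised signal —
the architectural premise under test. What passing the benchmark does *not*
show: robustness to real artifact structure, volume conduction, non-stationary
label noise, or the far weaker effect sizes of real affective EEG.

The benchmark itself: 6 subjects x 16 trials (4 per quadrant class), 20-s
trials at 128 Hz on the 9-channel toy montage, leave-one-subject-out. The
reduced model keeps the architecture but narrows it: d = 16, 2 HCT layers,
4 heads (dimension 3), 12 SFE filters, SFE stride 4 and pool 8 (16 tokens per
4-s window), 1 BCA layer (kernel 3), 2 TCN blocks (kernels 3/3, dilations
1/2, 32 filters), MLP width 32. These sizes keep a full LOSO run in the
low minutes on one core while leaving the model comfortably above its
accuracy requirement.

## Training at benchmark scale

Training minimises trial-level cross-entropy with Adam. Three choices matter
at this scale and are deliberate:

* **No dropout inside the tiny Deformer** (classifier-head dropout 0.2 only).
  With ~75 optimisation steps, dropout inside the feature extractor prevents
  convergence altogether; at full scale the published 0.2 applies.
* **Cosine learning-rate decay with gradient clipping** (peak 0.02, global-norm
  clip 10). Constant-rate Adam at this batch size oscillates chaotically and
  occasionally diverges on single folds; decaying to zero makes the final
  epoch — the parameters actually evaluated — a stable point. Both are
  exposed in `train_config()` and off (`constant`, clip 10) by default.
* **Residual-friendly initialisation of the BCA layer**: the attention output
  projection, the depthwise temporal convolution and the FFN's second linear
  map start at zero, so a fresh BCA layer is a near-identity refinement.
  Adding the layer then cannot hurt the optimisation start, which keeps the
  full model's accuracy at or above its BCA-free ablation.

Determinism: given a seed, `run_experiment()` derives one RNG stream per fold
(model initialisation, batch partition, dropout masks), so two runs with the
same seed produce bit-identical fold accuracies on one thread.

## Labels, metrics, protocols

Ratings map to classes exactly as the two- and three-level tables define:
1–5 Low / 6–9 High, and 1–3 / 4–6 / 7–9 for the three-level scheme. Note the
three-level *arousal* naming runs 1–3 "Activated" and 7–9 "Deactivated" —
inverted relative to the usual SAM direction — and is preserved as printed;
`trinarize_rating()` documents the quirk. Four-quadrant labels combine the
binarized valence and arousal (so (5,5) is LVLA and (6,6) HVHA). SEED-style
−1/0/1 valence passes through unmapped as a 3-class scheme. Accuracy is the
confusion-matrix trace over the total; `paired_ttest()` wraps the classical
paired t-test on per-fold accuracies and reports `t = 0, p = 1` for identical
inputs and a degenerate flag for constant non-zero differences.

Two evaluation protocols are provided: leave-one-subject-out (train on all
other subjects, test on the held-out one) and within-subject stratified
5-fold, grouped by trial so windows of one trial never straddle the split.
Trial predictions come from the trial's full window sequence through the
TCN; per-window probabilities are available through `full_model_forward()`
on single-window inputs.

## Ablation variants

`model_variants()` enumerates the comparison models: the full
`C2G-DF-BCA-TCN`; `C2G-DF-TCN` (no cross-attention); `C2G-DF-BCA` (no TCN,
temporal average pooling straight after the BCA); `C2G-DF-LSTM` and
`C2G-DF-BGRU` (two-layer unidirectional-LSTM / bidirectional-GRU integrators
in place of the TCN); `EEG-DF` (one Deformer over all channels, no
clustering); `DF-woDIP` (no dense log-power branch); and `DF-woHCTDIP`
(shallow-encoder features straight to the global stage). All variants train
through the same loop and backpropagation machinery and are checked against
finite-difference gradients in the test suite. The nine cluster Deformers
hold independent parameters by default; `c2g_model(share_deformers = TRUE)`
ties them to a single parameter set (gradients pooled across clusters) when
the clusters have equal channel counts.

## Numerical notes and limitations

* All layers are implemented in the package (R with compiled inner kernels
  for attention, batch-norm scale/shift, max-pooling and ELU); gradients are
  exact reverse-mode derivations verified against central differences at
  1e-6 tolerance.
* BatchNorm keeps running statistics by reference inside the parameter tree;
  inference uses them, training uses batch statistics (momentum 0.1).
* The IP-unit's epsilon (1e-8) bounds its output below by `log(1e-8)`; the
  unit is monotone in mean-square power.
* Max-pooling breaks ties toward the earliest element; with stride-2 pooling
  an odd token count pads with `-Inf` (coarse) so counts follow
  `ceil(n / 2)` exactly.
* The depthwise temporal convolution inside a BCA layer acts across the
  *windows* of a trial (the architecture's temporal unit), not across tokens
  within a window; with a single window it reduces to a (zero-initialised)
  pointwise map.
* Welch band power uses Hann tapers with 50% overlap; adjacent strong bands
  leak a few percent into each other at 4-s segments, which is why
  `verify_spectral_signature()` uses 8-s segments.
* Known limitations: no ICA or bad-channel handling (out of scope), no
  pre-trained weights, electrode-space only (attention weights are
  channel-statistical, not cortical connectivity), and the generator does not
  model volume conduction or realistic head geometry.
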