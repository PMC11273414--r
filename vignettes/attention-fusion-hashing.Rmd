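---
title: "Attention-fusion hashing: model, objective and evaluation protocol"
author: "dafh package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-fusion hashing: model, objective and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science and the design decisions behind `dafh`:
what the model computes, why each loss term is there, which knobs matter,
what the synthetic generator does and does not emulate, and where the design
was genuinely open and a choice had to be made.

## The retrieval problem

Content-based medical image retrieval must return, for a query slice, the
database images most likely to share its diagnostic category. Exhaustive
comparison in a deep feature space is too slow at archive scale, so deep
supervised hashing learns a mapping from images to short binary codes such
that same-class images land close in Hamming space. Retrieval then costs one
XOR + popcount per database entry.

The corpus protocol is an 8:2 stratified split: the 80% side is
simultaneously the training corpus and the retrieval database, and the 20%
side is the query/test set. This is encoded directly in the `split` field
of `labeled_image` ("database" vs "query").

## Architecture

The encoder has four stages:

1. **Backbone.** Any feature extractor exposing a final map
   `f_backbone` and an intermediate tap map `f_tap` plugs in. The built-in
   `"tiny"` backbone is four conv(3×3)–ReLU–avgpool(2×2) blocks with
   channel widths 8/16/32/32, tapped at its penultimate block — deep enough
   to carry spatial hierarchy into the attention branch, small enough to
   train on one CPU in seconds per epoch. The tap point mirrors the
   rationale of tapping the penultimate mobile-inverted-bottleneck block of
   a compound-scaled backbone; it is a named, configurable layer because the
   "penultimate block" is inherently backbone-specific.
2. **Block attention on the tap.** Channel attention first: global average-
   and max-pooled channel descriptors pass through a shared two-layer
   bottleneck (reduction r = 4), are summed, and a sigmoid produces one
   weight per channel. The reweighted map then gets spatial attention: its
   channelwise mean and max maps are stacked and convolved (7×7), and a
   sigmoid yields one weight per position. Both gates lie in (0,1), so the
   attention output never exceeds its input in magnitude — a property the
   test suite checks directly.
3. **Inter-layer fusion.** The attention output and the backbone output are
   globally average-pooled, concatenated, and mapped by a first linear
   layer. Its output feeds (a) a linear classifier with softmax, and (b) —
   concatenated with the *raw flatten* of the attention map — a second
   linear layer producing the pre-code. The pooling choice before the first
   concatenation is deliberately asymmetric: the fusion operands are pooled
   vectors (keeping the first linear layer small and translation-tolerant),
   whereas the hashing branch keeps the full flattened attention map, which
   the formulation explicitly routes through a flatten step. This is one of
   the places where the published formulation omits a vectorization step;
   the choice here is recorded as the package's own.
4. **Learnable quantizer.** The code is `tanh(alpha * z + b)` with the
   second linear layer's bias appearing both inside `z` and as the
   quantizer offset — exactly as the formulation writes it. A config flag
   (`separate_quant_bias`) decouples the two biases for ablation. The
   steepness is reparameterized as `alpha = 1 + softplus(a_raw)`, so
   `alpha > 1` holds *by construction* at every optimizer step rather than
   by clipping; it is initialized near 1.1 so early training sees a smooth,
   nearly linear quantizer. An adversarial test drives alpha toward 0.5 for
   500 Adam steps and verifies it never crosses 1.

Binarization is the elementwise sign with exact zeros mapped to +1 — a
deterministic tie rule for a measure-zero event. Because the quantizer is
strictly increasing, binarized codes are invariant to the steepness whenever
the quantizer bias is zero.

## Objective

Each training step samples triplets inside the minibatch: every element
with at least one same-class partner anchors one triplet; its positive is a
uniform same-class draw and its negative a uniform other-class draw
(uniform random mining; semi-hard mining is intentionally out of the
default path since the formulation specifies none). The loss is

    L_total = lambda * (L_focal(a) + L_focal(p) + L_focal(n)) + beta * L_triplet

with `lambda = 1/3` (making the classification term a mean over the three
members) and `beta = 1` (the top-level training loop of the formulation
adds the two losses with unit weights). Focal loss
`-(1 - p_y)^gamma * log(p_y)` with `gamma = 1.5` down-weights easy examples
so minority classes keep gradient share; at `gamma = 0` it reduces exactly
to cross-entropy (asserted to 1e-9 over a probability grid). The true-class
probability is floored at 1e-12 inside the log. The triplet term uses
Euclidean distance on the *continuous* codes: binarized codes would have
zero gradient almost everywhere; squared-Euclidean is available by flag.
Both terms reduce by batch mean so the loss scale is batch-size invariant.

Since no autodiff framework is available in this stack, all gradients are
derived and implemented by hand (im2col convolutions, both attention gates,
pooling argmax routing, the shared-bias quantizer where
`d pre / d b = alpha + 1`). The test suite validates every parameter tensor
against central finite differences to 1e-4 relative error.

## Training protocol

Defaults mirror the reference recipe: Adam, learning rate 1e-4, weight
decay 1e-4 (the "regularization rate", interpreted as L2 weight decay),
50 epochs, batch size 32 (the published setup states none; 32 is the
config-driven default), no learning-rate schedule. Validation runs after
every epoch: the query set is encoded, ranked against the encoded database
and scored as MAP@10 and MAP@1; the checkpoint with the best validation
MAP@10 is kept alongside the last one. MAP@10 is used as the selection
metric because it is the protocol's headline quantity.

**Small-problem step size.** The desk-scale experiments in this package
(200 synthetic images, ~5 steps per epoch, ≤10 epochs, so ~50 optimizer
steps in total) use learning rate 1e-3. The paper-scale default of 1e-4 is
calibrated for corpora three orders of magnitude larger with tens of
thousands of steps; at 50 steps it barely moves the parameters. This is a
problem-size adaptation, chosen once, not a tuned quantity; the package
default remains 1e-4.

Reproducibility: one user-facing seed fans out to weight initialization,
epoch shuffling, triplet draws, the synthetic generator and the split
through independent derived streams (`derive_seed(seed, tag)`), so any
stage can be re-run in isolation. Two identically seeded runs produce
bit-identical metric histories on one CPU thread; this is asserted
end-to-end.

## Retrieval and metrics

Codes are stored as bits ((b+1)/2), packed 8 per byte, and ranked by
popcount over XORed bytes. Ranking is ascending distance with ties broken
by ascending database index — deterministic across platforms, and
exhaustively checked against a brute-force stable sort.

Average precision follows the defining sum
`AP = (1/n_gt) * sum_k P(k) r(k)`; MAP averages it over queries, with
relevance defined as sharing the query's class label. For the truncated
MAP@k there is a genuine normalization ambiguity: with the full-corpus
`n_gt` in the denominator, a perfect top-k list can score below 1 whenever
`n_gt > k`. The package normalizes by `min(n_gt, k)` so a perfect
truncated list scores exactly 1 — the convention under which MAP@1 equals
top-1 retrieval accuracy, which is how MAP@1 is interpreted as a
classification-accuracy proxy; the raw normalization remains available
(`normalize = "gt"`). The MAP@1 confusion matrix row-normalizes, per query
class, the class of each query's rank-1 result; its label-weighted diagonal
mean reproduces MAP@1.

When the query and database sets overlap (they do not under the 8:2
protocol), candidates with the query's exact `source_id` are excluded;
otherwise a query's own stored copy would trivially rank first.

## Preprocessing decisions

* **IQR cleaning.** The cleaning criterion names mean, variance and
  quartiles without fixing the fenced statistic; the package fences
  per-image mean *and* per-image variance independently at
  `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (the conventional 1.5 factor; none is
  published) and removes an image if either fails. Cleaning is corpus-wide
  by default; applying it per collection is a config choice. With an
  infinite factor, or a degenerate corpus where IQR = 0 and all values
  coincide, nothing is removed.
* **Standardization.** Per-image min-max scaling to [0,1] (a constant image
  maps to zeros rather than dividing by zero), bilinear resampling to the
  working side (default 224), then 8-bit quantization so PNG serialization
  round-trips losslessly. Grayscale is stored single-channel and replicated
  to three channels only at model input.
* **Augmentation.** The union of both published op lists is implemented —
  noise, blur, brightness, rotation, scaling — with ranges
  sd ∈ [0, 0.05], blur ∈ [0, 1.5] px, delta ∈ [−0.2, 0.2], ±15°,
  scale ∈ [0.9, 1.1] (unstated in the source; conventional mild ranges,
  all exposed in config). Ops apply in a fixed order with seeded parameter
  draws, so augmentation is bit-reproducible.
* **Split rounding.** Per class, `round(0.8 * n_c)` with round-half-to-even;
  shortfalls land on the query side. Every class needs at least 2 images.
* **DICOM.** A minimal reader for single-frame uncompressed little-endian
  files (explicit and implicit VR) covers the pixel-module tags and rescale
  slope/intercept. Compressed syntaxes, sequences and 3-D volumes are out
  of scope.

## The synthetic generator

Each class's signature is an oriented grating (class-specific frequency,
orientation, base phase) plus 2–4 Gaussian blobs at class-seeded positions;
images within a class vary by a small seeded phase jitter (±0.5 rad) and
blob jitter (±2 px), and optional Gaussian pixel noise. At zero noise the
classes are separable by a nearest-centroid rule on raw pixels (asserted),
so end-to-end retrieval quality is a meaningful learnability signal rather
than an artifact of chance.

What it does **not** emulate: anatomical structure, inter-patient
variability, modality physics (CT windowing, MR intensity
non-standardization), label noise, and the extreme class imbalance of real
oncology archives. Passing the end-to-end bar on these fixtures shows the
optimization and retrieval machinery is correct and can learn separable
structure; it says nothing about clinical-scale accuracy, which in the
reference setting requires GPU-scale training on hundreds of thousands of
slices. For the chance-floor check the generator is run in a
noise-dominated regime (noise sd 1.0 against a ~0.2-amplitude signal):
with recoverable class signal even a random-weight encoder sits above
chance, so the 50% floor is only well-defined when the images carry none.

## Problem sizes used in the shipped checks

Unit tests run on 16–32 px images with a reduced tiny backbone; the
end-to-end learnability check trains 16-bit codes on 200 noiseless 64 px
images for 10 epochs (~1 minute); the determinism check trains twice for 2
epochs on 36 images. `scripts/acceptance.R` reruns the 200-image study and
reports MAP@10, MAP@1, first/final losses, the final steepness and the
untrained chance floor. These sizes were chosen as the smallest instances
at which every claimed property is non-trivially exercised.

## Known limitations

* The tiny backbone is not a compound-scaled pretrained network; absolute
  retrieval numbers on real corpora will differ accordingly. Any stronger
  backbone can be plugged in through the `(f_backbone, f_tap)` interface.
* Linear-scan retrieval is the contract; no multi-index hashing or LSH.
* Focal loss omits the per-class alpha-balancing factor, matching the
  formulation used here.
* The trainer is single-threaded CPU; there is no mixed precision or
  distributed path.
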