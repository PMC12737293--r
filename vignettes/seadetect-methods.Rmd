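---
title: "seadetect: model, design decisions and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seadetect: model, design decisions and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detector

`seadetect` implements a single-stage anchor-based detector for four marine
organism classes (echinus, starfish, holothurian, scallop). The baseline is
the familiar small-width cross-stage-partial architecture: a backbone of
strided convolutions and C3 blocks ending in fast spatial pyramid pooling
(SPPF), an FPN-PAN neck fusing strides 8/16/32, and a detection head that
predicts, per grid cell and per anchor, box offsets, objectness and class
logits. Widths are scaled by 0.50 (rounded up to multiples of 8) and C3
repeat counts by 0.33. Two structural edits define the variants:

* `use_scsa`: one spatial-channel synergistic attention block inserted
  immediately after SPPF, at the SPPF output width (512 channels at width
  multiple 0.50).
* `use_c3k2_psconv`: the C3 blocks named in `psconv_positions` are replaced
  by the dual-path pinwheel-convolution block.

All computation runs on a package-internal reverse-mode autodiff core over
plain R arrays. That choice makes every operation (convolution via
im2col/col2im, batch/group normalization, pooling, attention) and its
gradient inspectable and testable with finite differences; the price is
speed, which is why the shipped training problems are small (see
"Problem sizes" below).

## Attention block

SMSA assumes the informative spatial structure of a feature map survives
averaging along one axis at a time: the map is pooled along H and along W,
each pooled sequence is split into four channel groups, and each group
passes through a depthwise 1-D convolution of kernel 3, 5, 7 or 9 — four
receptive-field "semantics" at negligible cost. The convolutions are shared
between the two directions (this is what "shared" refers to); each direction
has its own 4-group GroupNorm (learnable affine, eps 1e-5), and a sigmoid
turns the responses into gates in (0,1) applied multiplicatively along both
axes. Because both gates are strictly inside (0,1), SMSA can only attenuate:
`|SMSA(X)| <= |X|` elementwise, which the tests assert.

PCSA compresses the gated map by adaptive average pooling to a 7×7 token
grid (clamped to the input size when the map is smaller — the deepest maps
of a 640-px model are 20×20, but the block must also run on smaller ones).
Q/K/V are per-channel depthwise projections of kernel 1 (a scale and shift
per channel); attention is the row-softmaxed `QKᵀ/√C`, a C×C channel-channel
matrix, applied to V; the (7,7)→(1,1)-pooled attention output is
sigmoid-squashed into one gate per channel. Single-head attention with the
√C denominator is used: the printed formula is ambiguous between `/C` and
`/√C`, so the denominator is a config enum (`scale_denominator`) defaulting
to the standard scaled dot product. Note that even with a single pooled
token the attention matrix is C×C, so it mixes channels; the package follows
this channel-attention definition consistently.

## Pinwheel convolution

PSConv extracts directional structure with four parallel branches. Each
branch asymmetrically zero-pads the input and applies a 1×3 or 3×1
convolution (+BN+SiLU) with c2/4 output channels. The printed pad/kernel
pairs are mutually inconsistent with the stated branch output size
`h' = h/s + 1`; the package pairs them so the 3-pixel pad lies along each
kernel's long axis and the 1-pixel pad along the short axis, one branch per
pinwheel direction, which satisfies the size equation exactly for strides 1
and 2 (the constructor asserts it). The literal printed tuples remain
available as `pairing = "printed"` for comparison. The four branch maps are
concatenated to c2 channels and fused by an unpadded 2×2 convolution with
**4 channel groups** — one group per direction. The grouped fusion is the
reading of "the four feature maps undergo grouped convolution" that makes
the block genuinely lighter: with a full 2×2 fusion the block would cost
more parameters than the C3 blocks it replaces and no replacement list could
reduce the model size, contradicting the published ablation.

C3k2-PSConv wires PSConv into a dual-path block: entry 1×1 conv to the
hidden width (= c2), channel split into two halves, one half kept as an
identity path, the other passed through **two sequential** PSConv modules,
concat, exit 1×1 conv. The sequential (rather than parallel) reading keeps a
shortcut path as in the C3 family and is the wiring that reconciles the
published parameter budget.

## Parameter accounting

`count_parameters()` reports per-layer and total counts in two conventions:

* **raw**: every trainable array; each Conv+BN pair contributes
  `c1·c2·k² + 2·c2`;
* **BN-fused**: each Conv+BN pair folded into a biased convolution
  (`c1·c2·k² + c2`), the deployment convention.

At four classes the baseline counts 7,030,417 raw and 7,020,913 fused
parameters. Only the fused value reproduces the published "7.02 M", so the
fused convention is used for the published-size comparisons (the raw integer
is always reported alongside). The SCSA block adds 17·C parameters
(C = 512: 8,704), giving 7.03 M. The replacement list
`psconv_positions = c("c3b", "neck_c3_p3", "neck_c3_p5")` — the second
backbone C3 stage plus the neck P3 and P5 blocks, touching both backbone and
neck — removes 187,776 fused parameters, giving exactly 6.83 M. The list is
configuration, not code, so alternative placements are testable.

These two edits touch disjoint layers, so their deltas are additive, and the
combined variant necessarily lands at 6,841,841 fused = **6.84 M**. The
published table prints 6.85 M; it also prints an SCSA delta of +0.01 M and a
combined-minus-PSConv delta of +0.02 M, which no additive accounting can
produce simultaneously. An exhaustive search over all subsets of the eight
replaceable C3 positions confirms that no list reproduces both 6.83 and 6.85
under one convention. The package therefore reproduces 7.02/7.03/6.83
exactly, reports the honestly computed 6.84 for the combined variant, and
the relative reduction (baseline → combined) computes to 2.55 %, against
"approximately 2.4 %" published.

## Losses and training

Targets are assigned per scale to anchors passing a w/h ratio gate
(`max(r, 1/r) < 4` on both axes) at the center cell plus the two nearest
neighbor cells. The box term is the mean complete-IoU loss
(`1 − IoU + ρ²/c² + αv`, α detached) over assigned cells on decoded offsets
(`2σ(t) − 0.5` centers, `(2σ(t))²·anchor` sizes); objectness and class terms
are mean BCE-with-logits (objectness target 1 at assigned cells, one-hot
classes). Component weights default to 0.05/1.0/0.5 (box/obj/cls),
detector-conventional since none are published. The optimizer is Adam with
β₁ = 0.937 — the published sheet lists "Adam" with "momentum 0.937", which
only makes sense as β₁ — lr 0.01, weight decay 5e-4, 3 warm-up epochs of
linear ramp then cosine decay to 1 % of lr0. Training aborts with a
diagnostic on a non-finite loss. With a fixed seed and a single BLAS thread
the loss history is bit-reproducible, which a test asserts.

Gradient correctness is tested end to end: backprop through the full tiny
model and loss agrees with central finite differences to 1e-3 relative on
sampled weights in every stage of the network.

## Evaluation

Matching is greedy one-to-one within image and class by descending
confidence (ties broken by input order) at IoU ≥ 0.5 — the conventional
threshold; it is a flag since the publication leaves it unstated. AP is the
all-points area under the monotone-envelope PR curve (the integral
definition, not 11-point sampling); mAP is the arithmetic mean over classes
with ground truth; classes without ground truth are excluded with a warning.
NMS is greedy per class. The implementations are tested against brute-force
oracles (O(n²) NMS, direct-definition AP integration) and property checks
(idempotence, count conservation, invariance of AP to monotone confidence
rescaling).

## Synthetic scenes

The generator emulates the statistical structure the method targets, not
photometric realism: a green-blue tinted background with a vertical
brightness gradient, soft low-frequency blobs and a bottom sediment band;
four parametric shapes — spiked disc (echinus), five-armed star (starfish),
elongated low-contrast blob placed in the lower half near the sediment it
resembles (holothurian), fan/half-disc (scallop); Gaussian blur (σ = 1 px)
and additive Gaussian noise (σ = 0.03) applied after label extraction.
Labels are tight bounding boxes of the drawn masks, recorded pre-blur, in
normalized YOLO form; placement rejects box overlap unless an occlusion draw
(probability 0.2) allows it. Defaults (256-px scenes, radii 9–22 px, up to
three echinus and one each of the others) keep targets small relative to
the image, as in the motivating imagery. What passing tests on these scenes
shows is that the pipeline — assignment, losses, optimization, decoding,
matching, metrics — is internally correct; it says nothing about accuracy on
real underwater photographs, which have texture, lighting and class
imbalance the generator does not model.

Mosaic augmentation composes four scenes around a random center, each
quadrant taking the matching corner crop of its source, with labels
remapped, clipped, and dropped below 1 px².

## Problem sizes

The shipped tests and the end-to-end smoke run use deliberately small
instances — 64-px scenes, width multiple 0.25, ~10 training epochs on 10
scenes — chosen so the whole suite exercises every code path, including full
training steps, in well under a minute of CPU. The acceptance computation
(parameter accounting) builds the full-width 640-px variants; it involves no
data and runs in seconds.

## Known limitations

* No GPU or C acceleration; training beyond toy scale is impractical.
* Anchor auto-tuning (k-means + genetic evolution) is out of scope; the
  conventional 9-anchor set is fixed.
* mAP is reported at IoU 0.5 only (no COCO-style 0.5:0.95 sweep).
* BN running statistics use biased batch variance; EMA weights and mixed
  precision are not implemented.
* The combined-variant parameter budget differs from the published figure by
  one printed unit for the structural reasons documented above.
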