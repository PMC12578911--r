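---
title: "Hyper-scale shifted aggregation networks: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyper-scale shifted aggregation networks: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hssamnet)
```

## The problem

Colorectal polyps are precancerous mucosal growths whose early removal during
colonoscopy measurably reduces cancer incidence; automatic pixel-level
segmentation of polyps in endoscopic frames is therefore a core
computer-aided-diagnosis task. It is hard for reasons that are structural
rather than incidental: polyps vary enormously in size and shape, their
colour contrast against surrounding mucosa is often poor, and wet tissue
produces saturated specular highlights that confound appearance cues.
Encoder-decoder networks dominate this task, but the standard transitions --
max pooling down, bilinear interpolation up -- discard three of four features
per 2x2 window on the way down and fill space by smooth approximation on the
way up, degrading exactly the fine boundary information that clinical use
requires.

This package implements a family of operators that attack those losses, and
assembles them into a lightweight five-stage encoder-decoder:

* **Max-diagonal pooling (Max-DP)** and **max-diagonal unpooling
  (Max-DUP)** -- parameter-free dual-branch sampling layers,
* **Hyper-scale shifted aggregation (HSSAM)** -- a skip-connection
  aggregation combining multi-stage encoding aggregation (MSEA) with
  shifted-submap aggregation (SSAM),
* **Progressive reusing attention (PRA)** -- channel attention with weights
  in $[0,2]$ (PGCA) and multiscale reusing spatial attention (MRSA),
* a metric suite (Dice, HD95, mIoU, MAE, ACC, PPV, TPR, TNR), a seeded
  synthetic-data generator, and training/evaluation/protocol harnesses.

Everything runs on the CPU through a compact Rcpp tensor backend with
reverse-mode differentiation written for this package; gradient correctness
of every operator is established against central finite differences in the
test suite.

## Dual-branch sampling

### Max-diagonal pooling

For each non-overlapping 2x2 window, Max-DP retains the maximum $m$ *and*
the value $d$ in the diagonally opposite cell, with both absolute positions.
Retaining the diagonal partner reduces the maximum sampling interval from
three cells to one and doubles the number of input cells that receive
gradient (2 of 4 instead of 1 of 4 -- asserted by finite differences in the
tests). Ties resolve to the first maximal cell in row-major order, which
makes the operator deterministic. Odd inputs are reflect-padded on the
bottom/right and the padding recorded so unpooling can crop back.

An optional window normalisation divides each retained value by the
stabilised window sum $c = A_m + A_d + A_{l1} + A_{l2} + \varepsilon$
(default $\varepsilon = 10^{-6}$: small enough not to perturb the weights,
large enough to keep all-zero windows finite). The normalisation is exposed
both as a standalone operation (`window_normalize()`) and as a network
configuration switch (`normalize_windows`), applied to the pooled maps that
feed the M2D fusion; where exactly the division sits inside the layer is not
prescribed by the architecture, so it is a documented configuration choice
(default off).

```{r}
x <- matrix(c(5, 1, 2, 3), 2, 2, byrow = TRUE)
p <- max_diagonal_pool(x)
c(max = p$max_map, diag = p$diag_map)
```

### Max-diagonal unpooling

Max-DUP combines the two classical upsampling philosophies: a dense
"many-to-many" bilinear interpolation of the max-branch input provides a
spatially continuous base, and a sparse "one-to-one" index-guided scatter
writes the max- and diagonal-branch values back to the exact cells they came
from, overwriting the interpolated base there. Round-trip exactness --
`unpool(pool(x))` equals `x` at every indexed cell, i.e. half of all cells
-- is a tested invariant. Scatter collisions are impossible by construction
(the two indices of a window are distinct diagonal partners and windows are
disjoint) and asserted at runtime. The bilinear base uses half-pixel-centre
coordinates, so a 1x1 input fills its 2x2 output with a constant.

In the network, the max/diagonal encoder outputs are concatenated and fused
by a 1x1 bottleneck before entering the next stage. The architecture names
this the M2D block but never defines it; the 1x1 fusion is the minimal
reading that exploits the joint information of the two branches, and it is
flagged here as an interpretation.

## Hyper-scale shifted aggregation

Skip connections carry encoder detail to the decoder, but summing
down-scaled feature maps from several stages risks spatial discontinuity and
scale degradation. HSSAM aggregates two complementary views at stage $i$:

* **MSEA** adaptively max-pools the stage feature $f_i$ and its deeper
  neighbour $f_{i+1}$ (projected to $f_i$'s width by a 1x1 bottleneck) to a
  common size and sums them. The contributing set $\{f_i, f_{i+1}\}$ is the
  only concrete enumeration the architecture description gives, and is the
  one implemented.
* **SSAM** collects five shifted submaps of the relatively high-resolution
  feature -- four corner-anchored crops and one centred crop of side
  $\mathrm{round}((1-\theta)\,\mathrm{dim})$ -- average-pools each to the
  target size and sums them. The shift ratio is structural, not learned:
  $\theta = 1/2^z$ with $z \ge 1$. For $\theta \le 1/2$ the five crops
  jointly cover every cell of the source (a tested coverage invariant), so
  no spatial information is dropped.

The two pre-bottleneck sums are added and passed once through a single
shared bottleneck (1x1 convolution, batch normalisation, ReLU). The fusion
operator is not fixed by the original description of the architecture; the elementwise sum with
one shared bottleneck is chosen for parameter thrift, consistent with the
architecture's lightweight budget, and means that disabling SSAM reduces the
module exactly to its MSEA path (a tested ablation identity).

Shift feasibility is governed by
$r^n\,L / (2^{z+1}\Psi) \ge L_{rm}/L$, where $r^n$ is the receptive-field
span of the first decoder kernel, $L$ the larger side of the source map and
$L_{rm}$ the missing-margin length. $\Psi$ is not given a definition in the original
description and defaults to 1 (configurable); $L_{rm}$ defaults to $\theta L$, the
margin lost to a single shift. An infeasible specification degrades to the
centre submap with a warning. The receptive field itself is computed by the
standard recursion (span grows by $(k-1)\cdot\mathrm{dilation}\cdot$
cumulative stride) and is validated against a brute-force impulse-influence
oracle over random stacks; an alternative literal form of the recursion, which
multiplies the whole bracket by the cumulative stride, disagrees with the
impulse count whenever strides exceed 1 and is retained only behind
`receptive_field(..., literal = TRUE)` for comparison.

## Progressive reusing attention

### Channel path (PGCA)

Global average pooling produces a length-$C$ channel descriptor. Instead of
a fully connected interaction (parameter-heavy) or a 1-d convolution
(locally blinkered), the descriptor is zero-padded to the smallest perfect
square $S^2 \ge C$, reshaped to an $S \times S$ grid -- shortening the
interaction distance between any two channels to at most $S\sqrt2$ -- and
processed by a progressive stack of dilated 3x3 convolutions (dilations
1, 2, 4 by default, configurable), moving from partial to global
interaction. The padded entries are dropped and the result mapped through
$2\sigma(\cdot)$, so every channel weight lies in $[0,2]$: weights above 1
enhance a channel, below 1 suppress it, and a zero-initialised stack emits
exactly 1 for every channel (identity scaling) -- both tested invariants.
The original description also mentions a "grouping map" produced by
"incrementally dividing the representations with a specific factor"; no
operator definition is given, and this implementation realises the
partial-to-global progression through the dilation schedule alone, which is
the configurable knob.

### Spatial path (MRSA)

The channel-scaled feature is compressed by a 1x1 convolution and passed
through five parallel branches with perceptible ranges 1 (pointwise), 3, 7,
15 (3x3 kernels with dilations 1, 3, 7) and global (pooled context,
broadcast). The stated ranges are the per-branch kernel spans $2d+1$,
verified by a single-impulse response oracle; because each branch *reuses*
the previous branch's output (added to the compressed input), the cumulative
receptive fields after reuse are larger -- the branch-4 path composes spans
3, 7 and 15 into a cumulative span of 23. The five outputs are concatenated,
fused by a 1x1 convolution and mapped through a sigmoid to $[0,1]$;
`mrsa_module(..., activation = "sigmoid2")` switches to the $[0,2]$ map,
which is also what makes the zero-initialised combined attention an exact
identity. No batch normalisation is used inside MRSA. The weight map is a
single spatial map broadcast across channels (the per-pixel-per-channel
variant is not implemented; the original description is silent and the broadcast is the
CBAM-style convention).

`pra_apply()` composes the two: channels first, then pixels.

## The five-stage network

Each encoder stage is a local-aware block (when enabled) followed by two
residual blocks; stages 1-4 end in a Max-DP transition fused by the M2D
bottleneck. The local-aware block is named but never defined in the original description;
it is realised as 3x3 convolution + batch normalisation + ReLU followed by a
3x3 depthwise convolution whose sigmoid output gates the features locally,
with a residual add -- a minimal local-gating reading, configurable. Skip
connections form $af_i$ through HSSAM and PRA, combine it with $f_i$ by
elementwise addition (concatenation + 1x1 fusion available by flag) and pass
through an additive attention gate driven by the deeper decoder state. The
deepest feature $f_5$ feeds the decoder directly. Each decoder stage holds
two residual blocks and two parallel 1x1 bottlenecks producing the max- and
diagonal-branch inputs of Max-DUP, which consumes the indices of the
matching encoder stage. The head is a 1x1 convolution and sigmoid;
predictions are binarised at a configurable threshold, default 0.5.

Ablation variants mirror the architecture's feature flags: `M1` (plain max
pooling + bilinear, no local-aware block, no attention aggregation), `M2`
(+Max-DP, +LAB), `M3` (+Max-DUP), `M4` = `full` (+HSSAM/PRA). Parameter
counts are monotone across the variants (tested).

### Stage widths

The published per-layer parameter table is internally inconsistent: its rows
sum to roughly 1.7 M against a stated total of ~0.9 M, and several rows
match a single convolution rather than the stated pair. Exact intended
widths are therefore unrecoverable. This package defaults to stage widths
$(6, 12, 24, 48, 96)$, which put the full variant at

```{r}
param_count(build_network(network_config()))
```

learnable parameters -- matching the ~0.9 M headline while remaining freely
configurable; `param_breakdown()` reports per-module counts transparently
instead of attempting to match irreconcilable rows.

## Evaluation suite

Dice, mIoU, MAE, ACC, PPV, TPR and TNR are pure set-arithmetic functions
over binary masks; all are cross-checked to $10^{-12}$ against an
independent coordinate-list reimplementation, and Dice is verified against
the algebraic identity $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$.
HD95 is the symmetric 95th-percentile Hausdorff distance over 8-connected
boundary point sets (the standard medical-segmentation convention; full-mask
point sets available by flag), with linear-interpolation percentiles.
Empty-mask conventions are explicit: both masks empty gives Dice 1 and HD95
0; exactly one empty gives the configured HD95 penalty (image diagonal by
default). Ratios with empty reference sets return 1.

## Synthetic data generator

The generator emulates the stated segmentation challenges with controllable,
testable parameters: a mucosa-like background (smooth low-frequency reddish
field plus fine Gaussian noise), polyps as radially perturbed ellipses
(random harmonics of orders 2-8 scaled by `boundary_irregularity`) filled
with contrast-shifted tissue texture, and saturated specular blobs placed on
and off the polyp. The mask is the exact polyp support, star-convex in the
ellipse frame and hence a single 4-connected component per polyp. Defaults:
64x64 resolution, one polyp covering 5-30% of the image, irregularity 0.3,
luminance contrast offset 0.18 (deliberately low -- "poor contrast" is part
of the emulated difficulty), three highlights, noise 0.03. Every sample is a
pure function of its seed.

What the generator does *not* emulate: perspective and lumen geometry,
instrument artefacts, motion blur, mucosal folds, colour calibration drift
between scopes, and -- critically -- polyps whose texture statistics match
the background so closely that shape context is the only cue. Passing the
desk-scale training smoke therefore shows that the training loop, gradients
and architecture wiring work end to end; it does not certify clinical
segmentation quality on real endoscopy.

## Training harness

Training uses binary cross-entropy plus soft Dice, equally weighted (the
de-facto standard for polyp segmentation; the source never states its loss),
Adam or SGD, a linear warmup over the first 5% of steps (the learning rate
at 0-based step $s$ is $\mathrm{lr}\cdot(s+1)/\mathrm{warmup\ steps}$,
reaching the configured rate exactly at the end of warmup), and early
stopping on validation Dice with patience 10 and minimum improvement
$10^{-4}$ by default; the checkpoint kept is the best validation epoch, not
the last. Data splits follow the explicit three-way 80/10/10 protocol, with
the training split absorbing rounding remainders. Protocol harnesses cover
repeated seeded runs (mean +/- sd), seeded disjoint k-fold partitions and
cross-dataset transfer (train on A, evaluate on all of B). All randomness
flows from the run seed; two runs with the same configuration are
bit-identical.

### The desk-scale smoke study and its limits

The acceptance suite trains the full variant on 64 synthetic 64x64 samples
for up to 15 epochs (batch 8, Adam at $10^{-3}$, early-stopping patience 5)
-- sizes chosen so the whole study runs on one CPU in minutes. Under this
protocol the full variant reaches a median held-out Dice above 0.93 across
seeds, comfortably clearing the 0.85 smoke threshold.

The companion ablation comparison -- full variant `M4` versus plain baseline
`M1`, five seeds each -- does **not** reproduce the qualitative ordering
observed on real benchmark data at this scale, and the corresponding test is
deliberately left failing rather than adjusted. The measured medians are
0.956 (`M1`) versus 0.931 (`M4`) at 15 epochs; at 30 epochs both variants
saturate within half a Dice point of each other (0.971 vs 0.970 test Dice on
the first seed). The reason is visible in the convergence curves: the
synthetic task is nearly solvable from colour contrast alone, so the plain
baseline -- fewer parameters, no attention bottlenecks between gradient and
pixels -- converges fastest, while the advantages the dual-branch sampling
and attention machinery were designed for (ambiguous boundaries, confounding
artefacts, scale diversity) are barely exercised. A generator hard enough to
reward that machinery would have to starve the colour cue deliberately;
the generator's conditions were fixed before the comparison was run and are
not tuned to its outcome.

## Numerical choices and degenerate inputs

* Tie-breaks in all max operations: first maximal cell in row-major order.
* Bilinear coordinates: half-pixel centres, clamped at borders; adaptive
  pooling windows are `floor(i*H/out)` to `ceil((i+1)*H/out)`.
* Crop arithmetic: `round((1-theta)*dim)` sides, 0-based half-open windows,
  centre offset `floor(theta*dim/2)`.
* Batch normalisation: full backward through the batch statistics in
  training mode, running statistics (momentum 0.1) in inference;
  $\varepsilon = 10^{-5}$.
* Parameter initialisation: He-normal from the R RNG, so a single seed fixes
  every parameter; zero-initialised variants exist for the identity-weight
  configurations used in tests.
* Degenerate inputs are errors, not silent repairs: empty feature maps,
  non-positive $\varepsilon$, out-of-bounds sampling indices, mismatched
  mask shapes, empty dataset splits, more folds than samples, and a
  non-finite loss all abort with diagnostics.

## Known limitations

* CPU-only; practical for desk-scale experiments and operator research, not
  for training on full-resolution clinical benchmarks.
* The M2D block, local-aware block and PGCA grouping are minimal readings of
  under-specified components, flagged as interpretations and configurable.
* HD95 on very small masks is sensitive to the boundary-extraction
  convention; the full-mask variant is provided for comparison.
* The ablation ordering of the published architecture is a property of hard
  real data; it is not reproduced (and should not be expected) on the easy
  synthetic task, as analysed above.
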