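---
title: "Edge-attention segmentation of fuzzy-boundary lesions: models and methods"
author: "edgeseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-attention segmentation of fuzzy-boundary lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(edgeseg)
```

## The problem

Malignant bone lesions in MRI sit in cluttered anatomical backgrounds, and
their rims are *fuzzy*: intensity falls off gradually across the boundary,
so the true contour is ambiguous even though the lesion interior is bright
and compact. A plain instance-segmentation network localizes such a lesion
well but blurs or truncates exactly the boundary band a clinician cares
about. `edgeseg` implements a supervised edge-attention pipeline built
around three ideas:

1. **Sub-pixel pooling.** Region-of-interest features are pooled with RoI
   Align — bilinear sampling at continuous coordinates, averaged over a
   regular sub-grid per output bin — instead of quantized or max pooling,
   so weakly-brighter key pixels near the fuzzy rim survive pooling.
2. **Mixed attention.** The head-mask features are enhanced by a channel
   self-attention branch and a position (spatial) self-attention branch
   running *in parallel* on the same input, each in residual form with a
   zero-initialized learning factor, and summed.
3. **Supervised edge attention.** A multi-branch dilated-convolution head
   (boundary points proposal, BPP) predicts a sigmoid edge-candidate map
   that residually re-weights the tumor features,
   $F_{edge} = F_{tumor}\,(1 + F_{points})$. Its supervision target is not
   a hand-drawn edge map but the output of a randomized *boundary key
   points selection* (BKPS) search: among candidate edge pixels, repeatedly
   draw $n$ points, join them into a polygon, and keep the draw whose
   region boundary minimizes the 95th-percentile Hausdorff distance (HD95)
   to the ground-truth contour.

## Model components and their contracts

**Bilinear sampling and RoI Align.** Coordinates are continuous and
0-based with pixel centers at integers. The interpolated value at $(x, y)$
is the separable blend of the four enclosing grid values; out-of-range
queries clamp to the edge so behavior near borders is exact and testable.
RoI Align divides a box into $h \times w$ bins and averages
`samples_per_bin` bilinear samples placed on a centered sub-grid (default
4, arranged 2×2). Averaging, never max: a max would discard the faint
discriminative pixels at the rim. The ablation flag `RA = FALSE` switches
to quantized sampling (coordinates rounded) to measure what alignment buys.

**Channel attention.** With the head features flattened to
$M \in \mathbb{R}^{N \times C}$, the weight of channel $k$ on channel $j$
is the softmax over $k$ of the dot products $M_{\cdot k} \cdot M_{\cdot j}$,
and the branch output is $B_j = \omega \sum_k a_{jk} M_{\cdot k} + M_{\cdot j}$.
Dot products are used unscaled, as defined. $\omega$ starts at 0 and is
learned, so a fresh module is exactly the identity — attention can only
*add* discriminative weighting, never erase pretrained signal.

**Spatial attention.** Three learned 1×1 projections reduce $C$ channels
to $\lfloor C/8 \rfloor$ (queries $Q$, keys $S$, values $V$); position
weights $e_{jk} = \mathrm{softmax}_k(Q_k \cdot S_j)$ form an $N \times N$
grid ($N = H W$, materialized, hence meant for head-size maps, $N \le 4096$);
the weighted values are projected back to $C$ channels by a fourth 1×1
projection and added residually with factor $\varphi$ (zero-initialized).

**Mixed attention wiring.** The default integrates the branches in
parallel, $Z = B + U$ (each branch carries its own copy of the residual
input, so at $\omega = \varphi = 0$, $Z = 2\,O_f$ — a fixed scaling that
downstream convolutions absorb). The two serial orders are provided purely
as the ablation wirings.

**BPP head.** One pure 1×1-reduction branch plus one branch per dilation
rate (default rates {1, 2, 4} with 64 reduced channels at reference scale;
{1, 2} with 8 channels in the tiny preset). Each 3×3 convolution uses
padding = dilation so spatial size is preserved; every convolution is
followed by batch normalization and ReLU; the concatenated branches are
projected to one channel and sigmoid-activated. The branch count and rates
are not fixed by the method description, so they are configuration, and
the defaults were chosen once as a standard small dilation pyramid.

**Edge fusion.** The expression "multiply by one-plus-attention" is
implemented as $F_{tumor} \otimes (1 \oplus F_{points})$. This grouping is
the only one under which the method's own limiting argument holds: as
$F_{points} \to 0$ the fused features reduce to $F_{tumor}$.

**BKPS.** Candidate pixels come from Canny edges of the intensity image
(Gaussian $\sigma = 1$; hysteresis thresholds from Otsu's criterion on the
non-max-suppressed gradient magnitude, low = 0.4·high — the edge detector
is implemented in-package since no installed R package provides Canny)
restricted to a ±5 px band around the ground-truth contour; if fewer than
$3n$ candidates remain the ground-truth contour itself is the pool — this
also resolves the ambiguity of whether detection runs on the image or the
annotation: image first, annotation as fallback. "Connecting the points"
is made precise as ordering by polar angle about the centroid (ties broken
by radius) and filling the resulting simple polygon, pixel centers on the
boundary included. This ordering deliberately reproduces the known failure
mode of large $n$ on non-convex lesions — angular sorting can sever narrow
necks — which is why more points are not automatically better.
HD95 retains the 95th percentile (linear-interpolation convention, R type
7) of the directed nearest-neighbour distances *per direction* and takes
the maximum of the two directions — the standard HD95 reading; pooling
before the percentile is the other defensible reading and was not chosen.
Degenerate draws (collinear points) are skipped but still consume
iteration budget, keeping runs comparable across seeds. Pixel spacing
defaults to 1 mm/px and simply scales distances.

**Losses.** $l_{seg} = l_{cls} + l_{box} + l_{mask}$ and
$l_{total} = l_{seg} + l_{edge} + l_{reg}$, all terms unweighted. The
classification loss is focal, $-\alpha(1-\rho)^\gamma\log\rho$ with
defaults $\alpha = 0.25, \gamma = 2$ (the exponents are described only as
tunable, so the standard focal defaults are used and exposed). The box
loss is $1 - \mathrm{IoU} + (d/c)^p$ with $d$ the center distance and $c$
the enclosing-box diagonal; the typeset form of the penalty is read as the
ratio $(d/c)^p$ — both quantities are lengths and $p$ (default 2) is the
control exponent, recovering the distance-IoU family. Mask, edge and
region losses are mean binary cross-entropies (probabilities clamped at
$10^{-7}$); mask and region targets are the ground-truth mask RoI-aligned
to the 14×14 head grid, and the edge target is the BKPS key points mapped
into the head grid and stamped as radius-1 disks. The classification
probability $\rho$ is per-RoI (the classification head), matching the
task decomposition of the segmentation loss.

## The network and its compute engine

No deep-learning framework is available to R in this package's dependency
footprint, so `edgeseg` carries a compact reverse-mode layer engine:
im2col convolutions, batch normalization, linear layers, bilinear
resizing, max pooling, RoI Align, both attention branches, the BPP head
and the fusion — each with a hand-derived backward pass validated against
central-difference numerical gradients in the test suite (relative error
around $10^{-10}$). Batches are formed by accumulating gradients over
single-image steps; batch normalization therefore normalizes over the
spatial extent per image during training and uses running moments at
evaluation.

The graph follows the reference layer table: a stem plus four residual
stages (C1–C5, strides 2/4/8/16/32), lateral 1×1 + top-down FPN producing
P2–P6 at a common width, per-level RPN heads (3 aspect-ratio anchors per
cell, base size 4× the level stride), RoI-aligned 7×7 features through a
shared fully connected layer into class/box heads, and a mask branch:
14×14 RoI-aligned features → two conv-BN-ReLU blocks (the head mask
features) → mixed attention → BPP → edge fusion → mask and region
predictors. The region predictor is a separate 1×1 sigmoid head on the
fused features: it is the term the region-supervision loss trains, while
the mask head remains the output path, so the two supervision signals stay
distinguishable. At inference the top-objectness proposal is decoded,
refined by the box head, and the head-resolution mask/boundary maps are
bilinearly pasted into the refined box on a full-resolution canvas.

Two deliberate simplifications, chosen for the desk-scale regime of a
single lesion per image: the RoI heads read P2 (the finest pyramid level)
rather than a size-dependent level — lesions at 64×64 all fall in the
fine-level regime anyway — and RPN heads are per-level rather than
weight-shared, which keeps the backward bookkeeping simple at a negligible
parameter cost. During training the positive RoI alternates between a
jittered ground-truth box and the network's own current top proposal (when
it overlaps the lesion at IoU ≥ 0.3), so the heads see the same RoI
distribution they will face at inference; per-step stochastic choices come
from a per-sample substream, which makes a frozen model's loss trace
exactly constant across epochs and fixed-seed runs bitwise reproducible.

Reference-scale defaults (512×512, ResNet-50-style stage widths,
256-channel FPN, 1024-d FC, 182 epochs, batch 16, initial learning rate
0.02, momentum 0.9, weight decay $10^{-4}$) are retained in the
configuration objects but are not CPU-feasible; the tested path is the
tiny preset: 64×64 inputs, one residual block per stage with widths
16/24/32/40, 24-channel FPN, batch 4, AdamW at $2\times10^{-3}$. The
optimizer description in the source material mixes Adam with
momentum-plus-weight-decay language; the package defaults to
decoupled-weight-decay Adam and provides plain SGD with momentum as an
alternative rather than resolving the contradiction silently.

## What the phantom generator emulates — and what it does not

Each phantom is a single bright star-convex blob (low-order radial Fourier
perturbation of a disk, relative perturbation capped at 0.25 so the
boundary stays simple and closed) on a darker background with distractor
ellipses whose intensities overlap the lesion's, placed outside the lesion
support. Only the lesion's intensity step is Gaussian-blurred (kernel
truncated at 3σ, so the blur is provably local to the rim); the mask
records the crisp pre-blur support. Gaussian intensity noise and salt
impulses are applied last. Tiny-preset study conditions, chosen once:
radius 10–18 px at 64×64 (lesion fills a realistic 5–25% of the image),
rim blur σ = 1.5 px (a rim band comparable to the lesion radius's
ambiguity in clinical imagery), 3 distractors, 2% Gaussian noise, 0.2%
salt.

What this shows and does not show: passing the end-to-end study
demonstrates that the pipeline — localization, attention, edge supervision
and optimization — works as specified on images whose ground truth is
exact and whose ambiguity is purely intensity-driven. It does not
demonstrate clinical performance: phantoms have no anatomy, no
inter-annotator ambiguity, single lesions only, and an intensity
distribution chosen by this package, not measured from MRI.

## Numerical choices and degenerate inputs

* Probability clamp $10^{-7}$ in all log-losses; saturated predictions get
  (effectively) zero gradient rather than infinities.
* Box-delta decoding clamps shifts to ±2 anchor sizes and log-scales to
  ±3 before exponentiation; boxes degenerate after clamping are errors in
  the functional API and skipped-with-budget in the randomized search.
* The box-loss gradient with respect to the four regression deltas is
  computed by central differences (8 cheap closed-form evaluations); the
  IoU/enclosing-box terms are piecewise smooth and this avoids a long
  hand derivation in rarely-hot code. All other gradients are analytic.
* Empty masks are rejected loudly (`mask_bbox`, `extract_edge_pixels`);
  augmentation that empties a mask is retried up to 3 times, then the
  sample passes through untransformed.
* The 95th percentile uses R's default type-7 (linear interpolation)
  quantile; stated because percentile conventions differ across packages.

## Problem sizes used by the tests and the acceptance script

The study sizes are the package's chosen desk-scale conditions: the
end-to-end run trains on 200 phantoms for 14 epochs and evaluates 50
held-out phantoms (about 5 minutes on one CPU core, reaching mean DSC
≈ 0.95); the flag-ablation comparison runs 60/20 phantoms for 6 epochs
over 3 seeds per row; the key-point search study uses an exact
radius-30 px disk at 128×128 with T = 500 (and T = 200 for the $n$
comparison over 10 seeds). Per-image BKPS supervision targets during
training use n = 20, T = 30: the targets only need to mark the boundary
band at head-grid resolution (14×14), where the benefit of a longer search
is below the rasterization quantum.

## Known limitations

* One lesion per image, one foreground class; no 3D volumes.
* The $N \times N$ spatial-attention grid is materialized; the module is
  intended for head-size maps, not full-resolution ones.
* The engine is single-threaded R; reference-scale (512×512, ResNet-50
  widths) configurations construct and validate but are not practical to
  train here.
* Checkpoints are R serializations of parameter arrays — portable across
  sessions, not across incompatible configuration changes.
* Augmentation transports cached key points through the sample's affine
  map instead of re-running the search per epoch; exact only because the
  transforms are affine and boundary maps to boundary.
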