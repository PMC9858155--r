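# edgeseg

Supervised edge-attention segmentation of single lesions with **fuzzy
(intensity-blurred) boundaries** in grayscale 2D images — the regime of
malignant bone tumors in MRI, where the lesion interior is bright and
compact but the rim fades gradually into tissue, making the true contour
ambiguous. The package is aimed at people studying boundary-aware
instance segmentation who need a fully testable, CPU-scale implementation
with exact ground truth.

The pipeline:

* **RoI Align** — continuous-coordinate pooling of proposal boxes
  (bilinear samples averaged on a sub-grid per bin; no rounding), so
  weakly discriminative pixels near the fuzzy rim survive pooling;
* **Mixed attention** — parallel channel and spatial self-attention in
  residual form: `B_j = ω Σ_k a_jk O_k + O_j` with
  `a_jk = softmax_k(O_k · O_j)`, and the positional analogue
  `U_j = φ Σ_k e_jk V_k + O_j` at reduced width C/8; outputs summed,
  `Z = B + U`; learning factors ω, φ start at 0 (identity);
* **Boundary points proposal (BPP)** — a parallel multi-branch
  dilated-convolution head emitting a sigmoid edge-candidate map
  `F_points`, fused residually: `F_edge = F_tumor ⊗ (1 ⊕ F_points)`;
* **Boundary key points selection (BKPS)** — randomized search: draw n
  candidate edge pixels, join them into a polygon (angular sort), and
  keep the draw minimizing the 95th-percentile Hausdorff distance
  `HD95(X, Y) = max(d_XY, d_YX)`, `d_XY = P95 over x of min_y ‖x − y‖`,
  to the ground-truth contour; the selected points, rasterized, supervise
  the BPP head;
* **Losses** — focal classification `−α(1−ρ)^γ log ρ`, distance-IoU box
  loss `(1 − IoU) + (d/c)^p`, and mean binary cross-entropies for mask,
  edge and region supervision: `l_total = l_cls + l_box + l_mask + l_edge + l_reg`;
* **Metrics** — Acc / Pre / Re / F1 / IOU / DSC from pixel confusion
  counts, with `DSC = 2·IOU/(1 + IOU)` checked on every evaluation;
* a **synthetic phantom generator** (star-convex blob, blurred rim, exact
  pre-blur mask, distractors, noise) standing in for clinical data, and a
  tiny (64×64) network preset so the whole method trains on one CPU core
  in minutes — no deep-learning framework required (the package carries
  its own gradient-checked layer engine).

## Worked example

```r
library(edgeseg)

# 250 synthetic fuzzy-boundary phantoms: 200 train, 50 held out
dat <- make_phantom_set(250, base_seed = 1)
fit <- ean_train(dat[1:200],
                  net_config = ean_config(tiny = TRUE, seed = 1),
                  config = train_config(tiny_mode = TRUE, epochs = 14, seed = 1),
                  verbose = FALSE)
print(fit)
#> edge-attention segmentation model: 64x64 input, 202799 parameters, 14 epoch(s)
#>   final loss 0.8399
#>   modules: RA=TRUE CA=TRUE SA=TRUE EA=TRUE ES=TRUE RS=TRUE (parallel attention)

ev <- ean_evaluate(fit, dat[201:250])
round(ev$mean, 4)
#>    Acc    Pre     Re     F1    IOU    DSC
#> 0.9846 0.9817 0.9318 0.9551 0.9153 0.9551
```

The printed means are per-image averages over the 50 held-out phantoms at
threshold 0.5: the model recovers the lesion with mean Dice overlap 0.955
(intersection-over-union 0.915), and pixel accuracy 0.985 — accuracy is
dominated by the large true-negative background, which is why DSC/IOU are
the informative numbers. `predict(fit, sample)` returns a binary mask for
a new image; `plot(fit)` shows the loss and validation-DSC curves.

The boundary key-point machinery is usable on its own:

```r
s   <- generate_phantom(phantom_config(image_size = 64,
                                       lesion_radius_range = c(10, 18),
                                       boundary_blur_sigma = 1.5, seed = 7))
run <- select_boundary_keypoints(s$image, s$mask, n = 20, T = 500, seed = 1)
print(run)
#> bkps_run: n = 20, T = 500, HD_min = 1.000 mm (0 degenerate draws)
D_GT <- rasterize_keypoints(run$P_select, dim(s$mask), radius = 1)
```

A thin command-line wrapper is installed as `exec/edgeseg` with
subcommands `simulate`, `bkps`, `train`, `evaluate`.

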