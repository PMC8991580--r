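---
title: "Methods: radial DP active contours and staged-tooth classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial DP active contours and staged-tooth classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem and scope

`toothstage` implements a semi-automated workflow for staging mandibular
premolar development from grayscale radiograph crops, using the Demirjian
system restricted to stages C through H (the earliest stages A and B are
excluded: by the ages at which premolar crops are typically acquired,
development has passed them). The workflow has three phases:

1. **Preprocessing** — a user-placed seed point defines a 250 × 250 crop;
   intensities are percentile-stretched; a 7 × 7 median filter removes
   impulse noise while preserving edges; CLAHE can be applied on the
   segmentation path.
2. **Segmentation** — a radial active contour optimized *globally* by
   dynamic programming, rather than by gradient descent, so no contour
   initialization is needed beyond the seed point.
3. **Classification** — a compact convolutional network mapping the
   (masked, resized) crop to one of six stages, with the standard
   evaluation battery: confusion matrix, per-stage recall, overall
   accuracy and Cohen's kappa.

Because clinical radiographs cannot be redistributed, the package ships a
star-convex tooth *phantom* generator that stands in for the private data
in every test. The phantoms are labelled synthetic data and are documented
as such throughout.

## The radial DP active contour

A grid of $M$ radial lines leaves the seed point at uniformly spaced
angles; each line carries $N$ discrete candidate positions ("graduations")
at radii $s, 2s, \dots, Ns$ (spacing $s = 1$ px by default, so $N$ equals
the radius length in pixels). A contour picks one graduation $v_i$ per
line. Its energy is cyclic and additive,

$$E(v_1,\dots,v_M) \;=\; \sum_{i=1}^{M} E_i(v_i, v_{i+1}), \qquad
  v_{M+1} \equiv v_1,$$

with the stage cost

$$E_i(v_i, v_{i+1}) \;=\;
  \begin{cases} -\,g(v_i) & \text{if } D(v_i, v_{i+1}) \le \delta,\\
  \infty & \text{otherwise,}\end{cases}$$

where $g(v)$ is the image gradient at $v$ projected on the ray's outward
unit vector and $D$ is Euclidean distance. Minimizing $E$ yields the
closed contour of greatest directional gradient strength whose consecutive
points (wrap pair included) stay within the user-set distance bound
$\delta$ — the smoothness control.

Numerical choices, all configurable:

* **Polarity.** For a bright tooth on a darker surround the outward
  derivative at the boundary is negative; with `bright_object = TRUE`
  (default) the field is negated so the boundary attracts the contour.
* **$\delta$ default** is $3s$: it permits jumps of up to three
  graduations between neighboring lines, ample for the boundary slopes the
  phantom family and premolar silhouettes exhibit, while excluding
  radial leaps to background clutter.
* **Finite infinity.** The $\infty$ in the stage cost is a sentinel
  $2(M{+}1)(\max|g|+1)$, strictly larger than any feasible cycle's energy
  magnitude, so arithmetic stays finite; any cycle containing a sentinel
  edge is detectable by its energy and reported `feasible = FALSE`
  (the least-bad selection is still returned).
* **Cyclic closure.** The wrap term couples $v_M$ to $v_1$, which plain
  chain DP cannot handle. With `closure = "exact"` the open-chain DP is
  solved once per candidate first point and the best cycle kept — globally
  optimal at $O(M N^3)$ — and this is the default while $N \le 256$.
  Beyond that, `"two_pass"` solves the free chain once, fixes the first
  point at its optimum and re-solves that single cycle: a documented
  approximation whose energy can only be $\ge$ the exact optimum.
  Because the lines are uniformly spaced, inter-line distances depend
  only on the two radii; feasibility is one $N \times N$ relation with
  contiguous feasible bands, which keeps the DP fast.
* **Tie-breaks** go to the smallest candidate index at every stage and
  the smallest first point, making results deterministic.
* **Sampling.** The gradient is sampled with bilinear interpolation and
  central differences, edge-replicated outside the frame.

The contour polygon is rasterized with a pixel-center even-odd test,
boundary-inclusive, and the mask is superimposed on the crop to suppress
background structures. Masks are compared with Dice and Jaccard scores
(identity $J = D/(2-D)$ is asserted in tests), and graded
under-/well-/over-segmented by thresholding the missing and spurious area
fractions at `tol = 0.2` — a reproducible stand-in for the visual judgement
such tables usually encode. `sweep_parameters()` reproduces the standard
two-parameter accuracy table over radius length × number of lines.

## The classifier

The reference network (built by `reference_architecture()`) is fixed by
its published layer accounting: input 90 × 90 × 1; four stages of 64
3 × 3 filters with strides 1, 3, 1, 3 and 2 × 2 max pools after stages 2
and 4 — feature-map sides 90, 30, 15, 15, 5, 2 — then flatten (256),
dense 30, dense 6 with softmax: 119,320 trainable parameters
(640 + 3 × 36,928 + 7,710 + 186). Strided "same"-padding convolutions are
the only parsimonious reading that reproduces both every printed shape
and every parameter count; input resizing to 90 px uses bilinear
interpolation.

The loss is categorical cross-entropy (the standard choice for a softmax
head). Four optimizers are provided — Adam ($\beta_1 = 0.9$,
$\beta_2 = 0.999$), SGD, RMSProp, AdaGrad — at learning rate $10^{-3}$;
the quoted $\varepsilon = 10^{-3}$ of the protocol is read as the learning
rate, as its own description says, not Adam's stability epsilon. Default
protocol: 10 epochs, batch size 8, an 80/20 stratified train/test split,
and a further stratified 80/20 train/validation split inside the training
partition (the validation fraction is not pinned by the protocol; 20% is
the conventional choice). Dropout, when enabled, acts on the 30-unit
dense layer. All randomness — He-normal initialization, shuffling,
dropout masks — derives from integer seeds, and training twice with one
seed reproduces bit-identical histories.

The engine itself is a compact single-precision implementation (im2col +
BLAS gemm convolutions) living in the package's compiled code; no
external deep-learning runtime is involved, which keeps runs reproducible
and dependencies minimal.

Model selection utilities mirror the usual protocol: a 27-point grid
search over dense layers {0, 1, 2} × layer sizes {16, 32, 64} ×
convolution stages {1, 2, 3} ranked by final validation loss
(`grid_search_models()`; the family places a 2 × 2 pool after every
convolution stage); an optimizer comparison over 50 epochs from shared
initial weights (`compare_optimizers()`); and a dropout study over rates
{none, 0.1, 0.5, 0.7, 0.9} (`dropout_study()`).

## Evaluation battery

`agreement_report()` computes the 6 × 6 confusion matrix in fixed stage
order, row-normalized proportions (displayed to two decimals, the
conventional format), overall accuracy (trace/total), per-stage recall
and unweighted Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$. Degenerate margins ($p_e = 1$) return
$\kappa = 1$ under perfect agreement and are an error otherwise.
`summarize_history()` reports the best epoch, minimum validation loss and
an overfitting onset: the first epoch at which validation loss exceeds
its running minimum for at least two consecutive epochs.

## The phantom generator

The generator emulates the *geometry* of staged premolar crops, not their
radiographic physics. A phantom is a star-convex silhouette about the
image center: an elliptical crown (64 × 48 px nominal) plus a root prong
modelled as a Gaussian angular bump about straight-down whose length is
`root_length_fraction × crown height`, minus a narrow apex notch while
the apex is open; the notch carves the root bump only, never below the
crown ellipse, so early stages with short roots simply show a blunted
apex. The stage mapping is monotone, mirroring the
qualitative staging criteria (root grows, apex closes):

| stage | root length fraction | apex gap (px) |
|-------|----------------------|---------------|
| C     | 0.10                 | 12            |
| D     | 0.30                 | 10            |
| E     | 0.55                 | 8             |
| F     | 0.80                 | 6             |
| G     | 1.00                 | 4             |
| H     | 1.10                 | 0             |

Two geometry-scale cohorts (0.90 and 1.00) emulate the two-sex design;
20 cases per stage per cohort reproduce the 240-case study size. Each
case carries 3% multiplicative jitter on all geometric fields. The tooth
is brighter than the background by `contrast = 0.45` over a 0.25 base
level, with smooth low-frequency cosine clutter (amplitude 0.08) and 2%
salt-and-pepper impulses — the latter included precisely so the 7 × 7
median-filter stage is observable end to end. Ground truth is the
rasterized generating polygon.

These values were fixed once, as a plausible emulation of cropped
premolar ROIs, before any evaluation: the root-to-crown proportion is the
dominant, scale-invariant stage cue; the apex notch is a secondary cue;
cohort scale is a nuisance factor the classifier must ignore. What
phantoms do **not** model: neighboring teeth and bone texture, beam
physics, blur gradients, patient positioning. Passing tests therefore
demonstrate that the algorithms are implemented correctly and that the
pipeline can extract a known geometric signal — not clinical-grade
accuracy on radiographs.

## Problem sizes used in the tests

The test-suite operating points are the package's own choices: DP oracle
equivalence is checked on 100 random lattices with $M \le 5$, $N \le 4$
against exhaustive enumeration; segmentation recovery on 60 noise-free
phantoms at the recommended 1200 lines × 100 px radius (mean Dice
≥ 0.98); the classifier end to end on 240 phantoms augmented ×10 within
the training partition (1,920 training items), 10 epochs, batch 8, Adam.
Model-selection mechanics are exercised at reduced scale (12–30 px
inputs, shortened runs), since the logic is scale-free.

## Known limitations

* The contour is star-convex by construction: one graduation per ray.
  Teeth with strongly re-entrant outlines (two separated root prongs seen
  at wide angles) are approximated by their radial envelope.
* Exact cyclic closure costs $O(M N^3)$; past $N = 256$ the two-pass
  approximation is used unless forced.
* The rasterizer is boundary-inclusive; masks are biased outward by up to
  half a pixel relative to an area-weighted rule — negligible at the
  object sizes used, and consistent between prediction and ground truth.
* Augmentation defaults (rotation ±15°, flip p = 0.5, crop 90–100%,
  brightness ±0.1, blur σ ∈ [0, 1], zoom 90–110%, resampling 70–100%)
  are label-preserving for this anatomy but are not a learned policy.
* The CNN engine is single-threaded and CPU-only by design; it is sized
  for the 119k-parameter reference family, not for large networks.
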