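# toothstage

Semi-automated dental developmental staging from radiograph crops, in R.

`toothstage` is for researchers in forensic odontology and dental imaging
who need a reproducible pipeline from a cropped premolar region of
interest to a Demirjian stage (C–H): preprocessing, globally optimal
radial active-contour segmentation, six-class convolutional network
classification, and the full evaluation battery. Because clinical
radiographs are private, the package also ships a star-convex tooth
*phantom* generator producing images, ground-truth masks and stage
labels, so the entire pipeline runs and is tested without patient data.

## The method

**Segmentation.** From a user-placed seed point, M radial lines are cast
at uniform angles, each carrying N discrete candidate positions. A closed
contour picks one candidate v_i per line and is scored by the cyclic
additive energy

```
E(v_1, …, v_M) = Σ_i E_i(v_i, v_{i+1}),          v_{M+1} ≡ v_1
E_i(v_i, v_{i+1}) = −g(v_i)   if D(v_i, v_{i+1}) ≤ δ
                  = ∞          otherwise
```

where g(v) is the outward directional image gradient at v, D is
Euclidean distance and δ a user-set smoothness bound. Dynamic
programming minimizes E exactly over all N^M contours (the cyclic wrap
term is closed exactly by solving the open chain once per candidate
first point), yielding the contour of greatest directional gradient
strength — no gradient-descent evolution, no contour initialization.
The polygon is rasterized (pixel-center even-odd, boundary-inclusive)
and the mask superimposed on the crop. Dice and Jaccard scores, a
qualitative under/well/over grade and a radius × line-count parameter
sweep (`sweep_parameters()`) evaluate segmentation quality; the
recommended operating point is 1200 lines × 100 px radius.

**Classification.** A compact CNN (90×90×1 input; four stages of 64 3×3
filters with strides 1, 3, 1, 3; 2×2 pools after stages 2 and 4; flatten
to 256; dense 30; softmax over 6 stages; 119,320 parameters) trained
with Adam (β₁ = 0.9, β₂ = 0.999, lr = 10⁻³), 10 epochs, batch 8, on an
80/20 stratified split with ×10 label-preserving augmentation of the
training partition. Architecture grid search (27 candidates ranked by
validation loss), optimizer comparison and a dropout study are included,
as are confusion matrices, per-stage recall, overall accuracy, Cohen's
kappa and learning-curve summaries.

## Worked example

```r
library(toothstage)

# the reference network reproduces its published layer accounting
model <- build_model(reference_architecture())
count_parameters(model)
#>    layer           type    output_shape  side channels n_param
#>  1 conv2d_1        conv    (90, 90, 64)    90       64     640
#>  2 activation_1    relu    (90, 90, 64)    90       64       0
#>  3 conv2d_2        conv    (30, 30, 64)    30       64   36928
#>  ...
#> 11 flatten         flatten (256)           NA       NA       0
#> 12 dense_1         dense   (30)            NA       NA    7710
#> 13 dense_output    dense   (6)             NA       NA     186
# total 119,320 parameters; flattened feature length 256

# phantoms -> split -> augment -> train -> evaluate
set   <- generate_phantom_set(20, seed = 11)            # 240 labeled cases
parts <- split_dataset(set, 0.8, seed = 12)             # 192 / 48
aug   <- expand_dataset(parts$train, augment_plan(factor = 10), seed = 13)
fit   <- train_stage_cnn(build_model(reference_architecture(), seed = 14),
                         aug, train_config(epochs = 10, batch_size = 8,
                                           seed = 15))
evaluate_model(fit, parts$test)
#> Agreement over 48 cases
#>          predicted
#> reference C D E    F    G    H
#>         C 1 0 0 0.00 0.00 0.00
#>         D 0 1 0 0.00 0.00 0.00
#>         E 0 0 1 0.00 0.00 0.00
#>         F 0 0 0 0.75 0.25 0.00
#>         G 0 0 0 0.00 1.00 0.00
#>         H 0 0 0 0.00 0.25 0.75
#> Overall accuracy: 0.92   Kappa index: 0.90
```

Held-out accuracy is 0.92 on this run and every misclassification lands
on a neighbouring stage — the phantom geometry makes adjacent stages the
only plausible confusions, mirroring how staging errors behave.

Segmenting one crop:

```r
case <- generate_phantom(phantom_spec("F", seed = 3))
seg  <- segment_tooth(case$image, n_lines = 1200, radius_length = 100)
dice(seg$mask, case$mask)        # 0.993 on this (noisy) phantom
autoplot(seg)                    # crop with the optimal contour overlaid
```

A thin command-line front end is installed with the package
(`exec/toothstage`): `toothstage synth|preprocess|segment|sweep|run`.

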