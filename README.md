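# shoalcount

Estimating the number of fish in a shoal from a single underwater image,
for aquaculture monitoring and biomass estimation. The package
implements the full counting-by-regression workflow in R: underwater
image enhancement, geometry-adaptive density-map supervision built from
point annotations, a hybrid convolutional counting network (multi-column
front end + dilated back end), a batch-size-one Adam training loop, the
standard counting evaluation suite, and a seeded synthetic shoal-scene
generator that stands in for proprietary footage.

## The method

Counting works by density-map regression rather than detection. An image
with `N` annotated fish centers `x_i` is represented as
`H(x) = Σ δ(x − x_i)` and smoothed with per-point Gaussian kernels,

    F = H * G_{σ_i},   σ_i = β · d̄_i   (β = 0.3),

where `d̄_i` is the mean distance from `x_i` to its `k` nearest
annotations — crowded regions get narrow kernels, compensating
perspective-induced size variation. The integral of `F` equals `N`, and
the network is trained (MSE loss, Adam, batch size 1) to regress `F`
from the image; at test time the count is the grid sum of the predicted
map.

The network front end is three convolutional columns with kernel
ladders 9-7-7-7 / 7-5-5-5 / 5-3-3-3 (three 2×2 max-pools each, so the
fused map is at 1/8 resolution); the back end is six dilated 3×3
convolutions (dilation 2 — effective receptive field `kr − r + 1 = 5`
per side through only 9 taps), followed by a 1×1 convolutional head, so
any input size is accepted. Enhancement remaps each color channel to
mean 128 by a piecewise-linear grey-world stretch (depleted channels
are shifted instead) and blends the result with its
histogram-equalized reference by minimizing a Sobolev-norm functional,
whose minimizer is the pointwise blend `α·S0 + (1−α)·Sr`. Evaluation
reports MAE, RMSE, MAPE, accuracy = 100 − MAPE, Pearson correlation,
range-stratified accuracy and error histograms.

The convolution engine (dilated im2col forward/backward, max-pooling,
Adam) is implemented inside the package with RcppArmadillo; no external
deep-learning framework is used.

## Worked example

```r
library(shoalcount)

# a seeded synthetic shoal scene with point labels
sc <- generateScene(SceneConfig(width = 128L, height = 128L), seed = 7)
sc$annotations
#> AnnotationSet 'scene_000007': 112 point(s) on a 128 x 128 image

# geometry-adaptive density supervision: mass equals the count
map <- renderDensityMap(sc$annotations)
countFromDensity(map)
#> [1] 112
dim(densityGrid(blockSumDownsample(map, 8)))   # at the network's scale
#> [1] 16 16

# enhancement pulls the attenuated red channel towards mid-grey
enh <- enhanceImage(sc$image)
channelStats(sc$image, "R")$mean; channelStats(enh, "R")$mean
#> [1] 53.51069
#> [1] 124.4304

# counting metrics
evaluateCounts(c(110, 90), c(100, 100))
#> MetricsReport (n = 2)
#>   MAE 10.0000  RMSE 10.0000  MAPE 10.0000%  accuracy 90.0000%  Pearson NA
```

The annotation count (112) is recovered exactly by integrating the
rendered density map; the enhanced red mean moves from 53.5 to 124.4
(128 exactly before 8-bit quantization and blending). In the metrics
report, symmetric ±10 errors around a true count of 100 give MAE = RMSE
= 10 and 90% accuracy; Pearson is undefined (NA) because the truths are
constant.

Model training follows the same pattern: `buildModel()` +
`trainModel()` on images and downsampled ground-truth maps, then
`predictDensity()` and `countFromDensity()` on held-out images. A
command-line wrapper covering the whole workflow (synth / enhance /
density / train / predict / evaluate) is installed at
`system.file("scripts", "shoalcount", package = "shoalcount")`.

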