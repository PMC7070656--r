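#' @useDynLib shoalcount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif sd cor dist
NULL

## ---------------------------------------------------------------------------
## Enhancement parameters
## ---------------------------------------------------------------------------

#' Parameters of the underwater enhancement pipeline
#'
#' Bundles the tunables of the grey-world color correction and the
#' Sobolev-norm contrast blend: `lambdaShift` controls how far a
#' red-depleted channel is shifted towards mid-grey, `alpha` weighs the
#' color-corrected image against the contrast-expanded reference,
#' `lowValueCutoff` / `lowFractionTrigger` decide when a channel counts as
#' depleted (fraction of pixels at or below the cutoff exceeding the
#' trigger).
#'
#' @slot lambdaShift positive scalar, shift-branch strength.
#' @slot alpha scalar in \[0, 1\], fidelity weight of the contrast blend.
#' @slot lowValueCutoff intensity in \[0, 255\].
#' @slot lowFractionTrigger fraction in \[0, 1\].
#' @exportClass EnhancementParams
setClass("EnhancementParams",
  representation(lambdaShift = "numeric", alpha = "numeric",
                 lowValueCutoff = "numeric", lowFractionTrigger = "numeric"),
  prototype(lambdaShift = 0.5, alpha = 0.5, lowValueCutoff = 40,
            lowFractionTrigger = 0.7),
  validity = function(object) {
    if (length(object@lambdaShift) != 1L || object@lambdaShift <= 0)
      return("lambdaShift must be a single positive number")
    if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
      return("alpha must lie in [0, 1]")
    if (object@lowValueCutoff < 0 || object@lowValueCutoff > 255)
      return("lowValueCutoff must lie in [0, 255]")
    if (object@lowFractionTrigger < 0 || object@lowFractionTrigger > 1)
      return("lowFractionTrigger must lie in [0, 1]")
    TRUE
  })

#' @param lambdaShift,alpha,lowValueCutoff,lowFractionTrigger see slots.
#' @rdname EnhancementParams-class
#' @export
EnhancementParams <- function(lambdaShift = 0.5, alpha = 0.5,
                              lowValueCutoff = 40, lowFractionTrigger = 0.7) {
  new("EnhancementParams", lambdaShift = lambdaShift, alpha = alpha,
      lowValueCutoff = lowValueCutoff, lowFractionTrigger = lowFractionTrigger)
}

## ---------------------------------------------------------------------------
## Point annotations
## ---------------------------------------------------------------------------

#' Point annotations of one image
#'
#' One `(x, y)` point per fish center, 0-based pixel coordinates
#' (`x` = column, `y` = row), tied to the dimensions of the annotated
#' image. The number of points is the ground-truth count.
#'
#' @slot imageId character identifier of the annotated image.
#' @slot points numeric matrix with columns `x` and `y`.
#' @slot width,height image dimensions in pixels.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(imageId = "character", points = "matrix",
                 width = "integer", height = "integer"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2L) return("points must have two columns (x, y)")
    if (nrow(p) > 0L) {
      if (!all(is.finite(p))) return("points must be finite")
      if (any(p[, 1L] < 0 | p[, 1L] >= object@width))
        return("x coordinates must lie in [0, width)")
      if (any(p[, 2L] < 0 | p[, 2L] >= object@height))
        return("y coordinates must lie in [0, height)")
    }
    if (object@width < 1L || object@height < 1L)
      return("image dimensions must be positive")
    TRUE
  })

#' @param points numeric matrix (or two-column data.frame) of 0-based
#'   `(x, y)` fish centers.
#' @param width,height dimensions of the annotated image in pixels.
#' @param imageId identifier tying the set to an image.
#' @rdname AnnotationSet-class
#' @export
AnnotationSet <- function(points, width, height, imageId = "image") {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 2L)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  new("AnnotationSet", imageId = imageId, points = points,
      width = as.integer(width), height = as.integer(height))
}

## ---------------------------------------------------------------------------
## Density maps
## ---------------------------------------------------------------------------

#' Kernel parameters of geometry-adaptive density rendering
#'
#' Each annotation is rendered as an isotropic Gaussian whose bandwidth
#' adapts to local crowding: `sigma_i = beta * dbar_i`, with `dbar_i` the
#' mean distance from point i to its `kNeighbors` nearest annotations.
#' Kernels are truncated at `truncationSigmas * sigma` and renormalized so
#' every point deposits total mass one, including at image borders.
#' Isolated points (no neighbour to measure) fall back to `fallbackSigma`.
#'
#' @slot beta bandwidth-to-spacing ratio (default 0.3).
#' @slot kNeighbors number of nearest annotations entering the mean
#'   spacing (default 3).
#' @slot truncationSigmas kernel support radius in sigmas (default 4).
#' @slot fallbackSigma bandwidth in pixels for isolated points (default 15).
#' @exportClass KernelParams
setClass("KernelParams",
  representation(beta = "numeric", kNeighbors = "integer",
                 truncationSigmas = "numeric", fallbackSigma = "numeric"),
  prototype(beta = 0.3, kNeighbors = 3L, truncationSigmas = 4,
            fallbackSigma = 15),
  validity = function(object) {
    if (object@beta <= 0) return("beta must be positive")
    if (object@kNeighbors < 1L) return("kNeighbors must be >= 1")
    if (object@truncationSigmas <= 0)
      return("truncationSigmas must be positive")
    if (object@fallbackSigma <= 0) return("fallbackSigma must be positive")
    TRUE
  })

#' @param beta,kNeighbors,truncationSigmas,fallbackSigma see slots.
#' @rdname KernelParams-class
#' @export
KernelParams <- function(beta = 0.3, kNeighbors = 3L, truncationSigmas = 4,
                         fallbackSigma = 15) {
  new("KernelParams", beta = beta, kNeighbors = as.integer(kNeighbors),
      truncationSigmas = truncationSigmas, fallbackSigma = fallbackSigma)
}

#' Object density map
#'
#' A nonnegative grid whose sum is the (expected) object count; `scale`
#' records the grid resolution relative to the source image (1 for
#' full-resolution maps, 1/8 for network outputs).
#'
#' @slot grid numeric matrix (rows = y, columns = x), entries >= 0.
#' @slot scale grid-to-image resolution ratio.
#' @exportClass DensityMap
setClass("DensityMap",
  representation(grid = "matrix", scale = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@grid)) return("grid must be numeric")
    if (any(object@grid < -1e-9)) return("grid entries must be nonnegative")
    if (length(object@scale) != 1L || object@scale <= 0)
      return("scale must be a single positive number")
    TRUE
  })

#' @param grid numeric matrix of nonnegative densities.
#' @param scale resolution ratio relative to the source image.
#' @rdname DensityMap-class
#' @export
DensityMap <- function(grid, scale = 1) {
  new("DensityMap", grid = grid, scale = scale)
}

## ---------------------------------------------------------------------------
## Network configuration and model
## ---------------------------------------------------------------------------

#' Structural description of the hybrid counting network
#'
#' Three parallel convolutional columns with distinct kernel-size ladders
#' (large/medium/small receptive fields), each interleaved with three 2x2
#' stride-2 max-pooling steps, fused by channel concatenation and followed
#' by a dilated convolutional back end (all 3x3 kernels, dilation 2) and a
#' 1x1 convolutional head producing the single-channel density map. All
#' convolutions are stride 1 with "same" padding and ReLU activations.
#'
#' @slot columnKernels list of three integer vectors of per-layer kernel
#'   sizes.
#' @slot columnFilters list of three integer vectors of per-layer filter
#'   counts.
#' @slot poolAfter list of three integer vectors: layer indices followed
#'   by max pooling (exactly three per column).
#' @slot backendFilters integer vector of back-end filter counts.
#' @slot backendKernel,backendDilation back-end kernel size and dilation.
#' @slot inputChannels number of image channels (3 for RGB).
#' @exportClass HybridConfig
setClass("HybridConfig",
  representation(columnKernels = "list", columnFilters = "list",
                 poolAfter = "list", backendFilters = "integer",
                 backendKernel = "integer", backendDilation = "integer",
                 inputChannels = "integer"),
  validity = function(object) {
    if (length(object@columnKernels) != 3L ||
        length(object@columnFilters) != 3L || length(object@poolAfter) != 3L)
      return("exactly three columns are required")
    for (i in 1:3) {
      ks <- object@columnKernels[[i]]
      fs <- object@columnFilters[[i]]
      if (length(ks) != length(fs))
        return("kernel and filter ladders must have equal length")
      if (any(ks %% 2L == 0L) || any(ks < 1L))
        return("column kernel sizes must be odd and >= 1")
      if (any(fs < 1L)) return("filter counts must be >= 1")
      pa <- object@poolAfter[[i]]
      if (length(pa) != 3L)
        return("each column must contain exactly three pooling operations")
      if (any(pa < 1L) || any(pa > length(ks)))
        return("poolAfter indices out of range")
    }
    if (object@backendKernel != 3L || object@backendDilation != 2L)
      return("back end is fixed at 3x3 kernels with dilation 2")
    if (any(object@backendFilters < 1L))
      return("backend filter counts must be >= 1")
    TRUE
  })

#' Trained or untrained hybrid counting model
#'
#' Opaque weight container produced by [buildModel()]. Maps an RGB image
#' (sides divisible by 8; smaller images are zero-padded) to a
#' nonnegative density map at 1/8 the input resolution.
#'
#' @slot config the [HybridConfig-class] the model realizes.
#' @slot weights list of per-layer weight matrices and bias vectors.
#' @slot downsampleFactor resolution reduction of the output (8).
#' @exportClass HybridModel
setClass("HybridModel",
  representation(config = "HybridConfig", weights = "list",
                 downsampleFactor = "integer"),
  prototype(downsampleFactor = 8L))

## ---------------------------------------------------------------------------
## Training
## ---------------------------------------------------------------------------

#' Training recipe of the counting network
#'
#' Adam optimization of the mean-squared error between predicted and
#' ground-truth density maps, batch size one (online learning), with a
#' fixed fraction of the training set held out for validation.
#'
#' @slot learningRate Adam step size (default 1e-5).
#' @slot epochs number of passes over the training set (default 100).
#' @slot batchSize fixed at 1.
#' @slot validationFraction fraction of the training set used for
#'   validation (default 0.10).
#' @slot seed integer seed driving shuffling and any stochastic step.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", validationFraction = "numeric",
                 seed = "integer"),
  prototype(learningRate = 1e-5, epochs = 100L, batchSize = 1L,
            validationFraction = 0.10, seed = 1L),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize != 1L) return("batchSize is fixed at 1")
    if (object@validationFraction < 0 || object@validationFraction >= 1)
      return("validationFraction must lie in [0, 1)")
    TRUE
  })

#' @param learningRate,epochs,batchSize,validationFraction,seed see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(learningRate = 1e-5, epochs = 100L, batchSize = 1L,
                        validationFraction = 0.10, seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      validationFraction = validationFraction, seed = as.integer(seed))
}

#' Per-epoch training history
#'
#' @slot loss per-epoch mean training loss.
#' @slot valMAE,valRMSE,valMAPE per-epoch validation metrics (NA when no
#'   validation split was held out).
#' @exportClass TrainHistory
setClass("TrainHistory",
  representation(loss = "numeric", valMAE = "numeric", valRMSE = "numeric",
                 valMAPE = "numeric"))

## ---------------------------------------------------------------------------
## Evaluation
## ---------------------------------------------------------------------------

#' Counting performance report
#'
#' MAE, RMSE, MAPE (percent), accuracy (100 - MAPE, percent) and the
#' Pearson correlation between estimated and true per-image counts.
#'
#' @slot mae,rmse count units.
#' @slot mape,accuracy percent; `accuracy = 100 - mape` by construction.
#' @slot pearson correlation in \[-1, 1\].
#' @slot n number of (estimate, truth) pairs.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(mae = "numeric", rmse = "numeric", mape = "numeric",
                 accuracy = "numeric", pearson = "numeric", n = "integer"),
  validity = function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (object@mae < 0 || object@rmse < -1e-12)
      return("errors must be nonnegative")
    if (object@rmse < object@mae - 1e-9)
      return("RMSE cannot be smaller than MAE")
    if (abs(object@accuracy - (100 - object@mape)) > 1e-9)
      return("accuracy must equal 100 - MAPE")
    if (!is.na(object@pearson) && abs(object@pearson) > 1 + 1e-12)
      return("pearson must lie in [-1, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## Synthetic scenes
## ---------------------------------------------------------------------------

#' Configuration of the synthetic fish-shoal scene generator
#'
#' Describes an underwater scene photographed from below: overlapping
#' elliptical fish silhouettes over a blue-green background with an
#' attenuated red channel, a vertical size gradient emulating perspective
#' (fish near the top of the frame are farther away, hence smaller), and
#' a final Gaussian blur emulating water turbidity.
#'
#' @slot width,height scene size in pixels.
#' @slot countRange inclusive integer range the per-scene fish count is
#'   drawn from (default 30--214, the range observed in shoal imagery
#'   this generator emulates).
#' @slot fishLength range of fish body half-lengths in pixels at the
#'   bottom (near side) of the frame.
#' @slot aspectRatio range of ellipse width-to-length ratios.
#' @slot sizeGradient far-side shrink factor in (0, 1\]; fish at the top
#'   edge are drawn at this fraction of their near-side size.
#' @slot baseColor background RGB triple (0--255), bluish green.
#' @slot redAttenuation multiplicative attenuation of the red channel of
#'   fish bodies, emulating red absorption under water.
#' @slot blurSigma Gaussian blur bandwidth in pixels.
#' @slot overlapAllowed whether fish may occlude each other.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(width = "integer", height = "integer",
                 countRange = "integer", fishLength = "numeric",
                 aspectRatio = "numeric", sizeGradient = "numeric",
                 baseColor = "numeric", redAttenuation = "numeric",
                 blurSigma = "numeric", overlapAllowed = "logical"),
  prototype(width = 256L, height = 256L, countRange = c(30L, 214L),
            fishLength = c(5, 10), aspectRatio = c(0.3, 0.5),
            sizeGradient = 0.5, baseColor = c(35, 95, 115),
            redAttenuation = 0.55, blurSigma = 1.0, overlapAllowed = TRUE),
  validity = function(object) {
    if (object@width < 8L || object@height < 8L)
      return("scene must be at least 8x8 pixels")
    if (length(object@countRange) != 2L || any(object@countRange < 0L) ||
        object@countRange[1L] > object@countRange[2L])
      return("countRange must be an ordered nonnegative pair")
    if (any(object@fishLength <= 0)) return("fish sizes must be positive")
    if (object@sizeGradient <= 0 || object@sizeGradient > 1)
      return("sizeGradient must lie in (0, 1]")
    if (2 * max(object@fishLength) >= min(object@width, object@height))
      return("fish larger than the image")
    TRUE
  })

#' @param width,height,countRange,fishLength,aspectRatio,sizeGradient see
#'   slots.
#' @param baseColor,redAttenuation,blurSigma,overlapAllowed see slots.
#' @rdname SceneConfig-class
#' @export
SceneConfig <- function(width = 256L, height = 256L,
                        countRange = c(30L, 214L), fishLength = c(5, 10),
                        aspectRatio = c(0.3, 0.5), sizeGradient = 0.5,
                        baseColor = c(35, 95, 115), redAttenuation = 0.55,
                        blurSigma = 1.0, overlapAllowed = TRUE) {
  new("SceneConfig", width = as.integer(width), height = as.integer(height),
      countRange = as.integer(countRange), fishLength = fishLength,
      aspectRatio = aspectRatio, sizeGradient = sizeGradient,
      baseColor = baseColor, redAttenuation = redAttenuation,
      blurSigma = blurSigma, overlapAllowed = overlapAllowed)
}

#' Noise augmentation parameters
#'
#' @slot gaussianVariance variance of additive zero-mean Gaussian noise
#'   on the \[0, 1\] intensity scale (default 0.001).
#' @slot saltPepperAmount fraction of pixels replaced by impulse noise
#'   (default 0.001).
#' @exportClass NoiseConfig
setClass("NoiseConfig",
  representation(gaussianVariance = "numeric", saltPepperAmount = "numeric"),
  prototype(gaussianVariance = 0.001, saltPepperAmount = 0.001),
  validity = function(object) {
    if (object@gaussianVariance <= 0 || object@gaussianVariance >= 1)
      return("gaussianVariance must lie in (0, 1)")
    if (object@saltPepperAmount <= 0 || object@saltPepperAmount >= 1)
      return("saltPepperAmount must lie in (0, 1)")
    TRUE
  })

#' @param gaussianVariance,saltPepperAmount see slots.
#' @rdname NoiseConfig-class
#' @export
NoiseConfig <- function(gaussianVariance = 0.001, saltPepperAmount = 0.001) {
  new("NoiseConfig", gaussianVariance = gaussianVariance,
      saltPepperAmount = saltPepperAmount)
}
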