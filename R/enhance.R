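#' Per-channel intensity statistics
#'
#' Mean, maximum and minimum of one channel; these drive the piecewise
#' linear color-correction stretch.
#'
#' @param image numeric `H x W x 3` array in \[0, 255\].
#' @param channel `"R"`, `"G"`, `"B"` or an index 1--3.
#' @return named list with `mean`, `max`, `min` and `channel`.
#' @export
channelStats <- function(image, channel) {
  assertRGB(image)
  idx <- channelIndex(channel)
  ch <- image[, , idx]
  list(mean = mean(ch), max = max(ch), min = min(ch),
       channel = c("R", "G", "B")[idx])
}

#' Fraction of low-intensity pixels in a channel
#'
#' The fraction of pixels at or below `cutoff`; a channel where this
#' exceeds the trigger fraction (0.7 by default) is considered depleted —
#' typical of the red channel under water — and is shifted rather than
#' stretched during color correction.
#'
#' @inheritParams channelStats
#' @param cutoff intensity threshold in \[0, 255\] (default 40).
#' @return fraction in \[0, 1\].
#' @export
lowValueFraction <- function(image, channel, cutoff = 40) {
  assertRGB(image)
  if (cutoff < 0 || cutoff > 255) stop("cutoff must lie in [0, 255]")
  mean(image[, , channelIndex(channel)] <= cutoff)
}

#' Grey-world piecewise-linear color correction
#'
#' Under the grey-world hypothesis the average color of a natural scene
#' is achromatic, so each channel is independently remapped to mean 128.
#' Channels whose mean lies at or below 128 are stretched about the
#' minimum, channels above 128 about the maximum; the affine map fixes
#' `Smin` (resp. `Smax`) and sends the channel mean to 128. A depleted
#' channel (low-value fraction above the trigger) is instead shifted by
#' `lambda * (mean - 128)` to avoid overcorrection. Outputs are clamped
#' to \[0, 255\] after the transform; arithmetic stays in floating point
#' (no 8-bit quantization), so the mean-128 property is exact whenever no
#' pixel clips.
#'
#' @param image numeric `H x W x 3` array in \[0, 255\].
#' @param params an [EnhancementParams-class] object.
#' @return corrected image, same dimensions, floating point in \[0, 255\].
#' @export
colorCorrect <- function(image, params = EnhancementParams()) {
  assertRGB(image)
  validObject(params)
  out <- image
  for (idx in 1:3) {
    ch <- array(image[, , idx], dim(image)[1:2])
    m <- mean(ch)
    pLow <- mean(ch <= params@lowValueCutoff)
    if (pLow > params@lowFractionTrigger) {
      res <- ch - params@lambdaShift * (m - 128)
    } else if (m <= 128) {
      smin <- min(ch)
      if (smin == m) {                      # constant channel
        res <- array(128, dim(ch))
      } else {
        res <- (ch - m) * (smin - 128) / (smin - m) + 128
      }
    } else {
      smax <- max(ch)
      if (smax == m) {
        res <- array(128, dim(ch))
      } else {
        res <- (ch - m) * (smax - 128) / (smax - m) + 128
      }
    }
    out[, , idx] <- pmin(pmax(res, 0), 255)
  }
  out
}

#' Contrast-expanded reference image
#'
#' Builds the reference image for the contrast-enhancement blend by
#' per-channel global histogram equalization (256 bins, CDF remapped so
#' the lowest occupied bin maps to 0 and the highest to 255). A constant
#' channel is returned unchanged, and an already full-range two-valued
#' channel is a fixed point up to quantization.
#'
#' @inheritParams colorCorrect
#' @return equalized image, same dimensions, values in \[0, 255\].
#' @export
buildReference <- function(image) {
  assertRGB(image)
  out <- image
  for (idx in 1:3) {
    ch <- image[, , idx]
    v <- pmin(pmax(as.integer(floor(ch + 0.5)), 0L), 255L)
    h <- tabulate(v + 1L, nbins = 256L)
    cdf <- cumsum(h) / length(v)
    cdfMin <- cdf[which(h > 0L)[1L]]
    if (cdfMin >= 1) next                  # constant channel: unchanged
    lut <- (cdf - cdfMin) / (1 - cdfMin) * 255
    out[, , idx] <- array(lut[v + 1L], dim(ch))
  }
  out
}

#' Sobolev-norm contrast enhancement
#'
#' Finds the image `E` minimizing
#' `alpha * ||E - S0||^2_W12 + (1 - alpha) * ||E - Sr||^2_W12`, where the
#' squared Sobolev W(1,2) norm is the squared intensity difference plus
#' the squared forward-difference gradient. Both terms share the same
#' positive-definite quadratic operator, so the unique minimizer is the
#' pointwise convex blend `alpha * S0 + (1 - alpha) * Sr`; the package
#' test suite verifies this closed form against a numerical minimizer of
#' the discretized functional.
#'
#' @param s0 fidelity image (typically the color-corrected image).
#' @param sr reference image (typically [buildReference()] of `s0`).
#' @param alpha blend weight in \[0, 1\]; 1 returns `s0`, 0 returns `sr`.
#' @return the blended image, same dimensions.
#' @export
contrastEnhance <- function(s0, sr, alpha = 0.5) {
  assertRGB(s0)
  assertRGB(sr)
  if (!identical(dim(s0), dim(sr)))
    stop("s0 and sr must have identical dimensions")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * s0 + (1 - alpha) * sr
}

#' Full underwater enhancement pipeline
#'
#' Applies grey-world color correction, builds the equalized reference,
#' and blends the two by the Sobolev-norm criterion. The result is
#' quantized to the 8-bit grid (round half up) unless `quantize = FALSE`,
#' in which case the floating-point image is returned.
#'
#' @inheritParams colorCorrect
#' @param quantize quantize the result to integers in \[0, 255\]?
#' @return enhanced image, same dimensions as the input.
#' @export
enhanceImage <- function(image, params = EnhancementParams(),
                         quantize = TRUE) {
  corrected <- colorCorrect(image, params)
  reference <- buildReference(corrected)
  out <- contrastEnhance(corrected, reference, params@alpha)
  if (quantize) quantize8(out) else out
}
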