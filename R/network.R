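#' Effective receptive-field side of a dilated convolution
#'
#' A `k x k` kernel with dilation rate `r` spaces its taps `r` pixels
#' apart, so a single layer sees a `(k*r - r + 1)`-pixel-wide window
#' while keeping only `k^2` parameters: dilation enlarges the receptive
#' field without extra parameters or resolution loss.
#'
#' @param k kernel size (odd, >= 1).
#' @param r dilation rate (>= 1).
#' @return the side length, `k*r - r + 1`.
#' @examples
#' effectiveKernelSize(3, 1)  # 3: identical to a standard convolution
#' effectiveKernelSize(3, 2)  # 5
#' @export
effectiveKernelSize <- function(k, r) {
  k <- as.integer(k)
  r <- as.integer(r)
  if (is.na(k) || k < 1L || k %% 2L == 0L)
    stop("k must be an odd integer >= 1")
  if (is.na(r) || r < 1L) stop("r must be an integer >= 1")
  k * r - r + 1L
}

#' Tap positions of a dilated convolution kernel
#'
#' The `k^2` input offsets (relative to the top-left tap) that carry
#' nonzero weight: `{(i*r, j*r) : i, j = 0..k-1}`. Their bounding box
#' side equals [effectiveKernelSize()]; all other positions inside the
#' receptive field are skipped.
#'
#' @inheritParams effectiveKernelSize
#' @return integer matrix with columns `dy`, `dx`, one row per tap.
#' @export
dilatedKernelFootprint <- function(k, r) {
  effectiveKernelSize(k, r)            # validates k, r
  k <- as.integer(k)
  r <- as.integer(r)
  off <- (0:(k - 1L)) * r
  cbind(dy = rep(off, times = k), dx = rep(off, each = k))
}

#' Default architecture of the hybrid counting network
#'
#' Front end: three columns with kernel ladders 9-7-7-7, 7-5-5-5 and
#' 5-3-3-3 and filter ladders 16-32-16-8, 20-40-20-10 and 24-48-24-12
#' (the multi-column design this model builds on), each with three 2x2
#' max-pooling steps, so the fused feature map is at 1/8 resolution.
#' Back end: six dilated 3x3 layers (dilation 2) with filters
#' 64-64-64-32-32-16 — deeper and wider than the columns but narrower
#' than VGG-16 — then a 1x1 convolutional head to one channel, keeping
#' the model fully convolutional so any input size is accepted.
#'
#' `widthScale` shrinks every filter count proportionally (minimum 1),
#' giving the reduced-width models used for desk-scale training
#' experiments.
#'
#' @param widthScale multiplier on all filter counts (default 1).
#' @return a [HybridConfig-class].
#' @export
defaultHybridConfig <- function(widthScale = 1) {
  if (widthScale <= 0) stop("widthScale must be positive")
  sc <- function(v) pmax(1L, as.integer(round(v * widthScale)))
  new("HybridConfig",
      columnKernels = list(c(9L, 7L, 7L, 7L), c(7L, 5L, 5L, 5L),
                           c(5L, 3L, 3L, 3L)),
      columnFilters = list(sc(c(16, 32, 16, 8)), sc(c(20, 40, 20, 10)),
                           sc(c(24, 48, 24, 12))),
      poolAfter = list(1:3, 1:3, 1:3),
      backendFilters = sc(c(64, 64, 64, 32, 32, 16)),
      backendKernel = 3L, backendDilation = 2L, inputChannels = 3L)
}

# Flatten a HybridConfig into the ordered layer list the engine runs:
# each element list(k, d, nin, nout, relu, column, pool) where pool says
# whether a 2x2 max pool follows, and column is 1:3 or "backend"/"head".
layerPlan <- function(config) {
  plan <- list()
  for (col in 1:3) {
    ks <- config@columnKernels[[col]]
    fs <- config@columnFilters[[col]]
    nin <- config@inputChannels
    for (l in seq_along(ks)) {
      plan[[length(plan) + 1L]] <-
        list(k = ks[l], d = 1L, nin = nin, nout = fs[l], relu = TRUE,
             column = col, pool = l %in% config@poolAfter[[col]])
      nin <- fs[l]
    }
  }
  fused <- sum(vapply(config@columnFilters, function(f) f[length(f)],
                      numeric(1)))
  nin <- as.integer(fused)
  for (f in config@backendFilters) {
    plan[[length(plan) + 1L]] <-
      list(k = config@backendKernel, d = config@backendDilation,
           nin = nin, nout = f, relu = TRUE, column = "backend",
           pool = FALSE)
    nin <- f
  }
  plan[[length(plan) + 1L]] <-
    list(k = 1L, d = 1L, nin = nin, nout = 1L, relu = TRUE,
         column = "head", pool = FALSE)
  plan
}
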