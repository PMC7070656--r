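# Weight container layout: one entry per layer of layerPlan(), each a
# list(W, b) with W of shape n_out x (n_in * k * k) in im2col tap order.

#' Build a hybrid counting model
#'
#' Instantiates the network described by a [HybridConfig-class]. By
#' default all convolution weights are drawn from a zero-mean Gaussian
#' with standard deviation 0.01 (the full-scale training recipe);
#' `initSd = "he"` instead scales each layer's standard deviation as
#' `sqrt(2 / fan_in)`, which keeps activations input-dependent from the
#' first forward pass and is the appropriate choice for the short
#' desk-scale training schedules used in the package's experiments.
#' Biases start at zero; construction is deterministic for a given seed.
#'
#' @param config a [HybridConfig-class] (default [defaultHybridConfig()]).
#' @param seed integer seed for weight initialization.
#' @param initSd weight standard deviation: a positive number (default
#'   0.01) or `"he"` for per-layer variance scaling.
#' @return an untrained [HybridModel-class].
#' @export
buildModel <- function(config = defaultHybridConfig(), seed = 1L,
                       initSd = 0.01) {
  validObject(config)
  plan <- layerPlan(config)
  weights <- withSeed(as.integer(seed), {
    lapply(plan, function(l) {
      nw <- l$nout * l$nin * l$k * l$k
      sd <- if (identical(initSd, "he"))
        sqrt(2 / (l$nin * l$k * l$k)) else as.numeric(initSd)
      list(W = matrix(rnorm(nw, mean = 0, sd = sd), nrow = l$nout),
           b = numeric(l$nout))
    })
  })
  new("HybridModel", config = config, weights = weights,
      downsampleFactor = 8L)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Forward pass over the [0,1]-scaled input cube x (H x W x 3, H and W
# divisible by 8). Returns the 1-channel output and, when train = TRUE,
# the per-layer caches the backward pass needs.
forwardPass <- function(weights, config, x, train = FALSE) {
  plan <- layerPlan(config)
  caches <- if (train) vector("list", length(plan)) else NULL
  colOut <- vector("list", 3L)
  fused <- NULL
  for (li in seq_along(plan)) {
    l <- plan[[li]]
    z <- if (identical(l$column, "backend") || identical(l$column, "head")) {
      if (is.null(fused)) fused <- do.call(abind3, colOut)
      fused
    } else if (isColumnStart(plan, li)) {
      x
    } else {
      colOut[[l$column]]
    }
    fw <- cpp_conv_forward(z, weights[[li]]$W, weights[[li]]$b,
                           l$k, l$d, TRUE, train)
    out <- fw$out
    cache <- if (train)
      list(cols = fw$cols, y = out, inDim = dim(z), poolIdx = NULL,
           preDim = NULL)
    if (l$pool) {
      if (train) cache$preDim <- dim(out)
      mp <- cpp_maxpool2_forward(out)
      if (train) cache$poolIdx <- mp$idx
      out <- mp$out
    }
    if (train) caches[[li]] <- cache
    if (identical(l$column, "backend") || identical(l$column, "head")) {
      fused <- out
    } else {
      colOut[[l$column]] <- out
    }
  }
  list(out = fused, caches = caches)
}

isColumnStart <- function(plan, li) {
  l <- plan[[li]]
  if (!is.numeric(l$column)) return(FALSE)
  li == 1L || !identical(plan[[li - 1L]]$column, l$column)
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  nc <- sum(vapply(parts, function(p) dim(p)[3L], numeric(1)))
  out <- array(0, c(d[1L], d[2L], nc))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[3L]
    out[, , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

# Backward pass: given dLoss/dOutput, returns per-layer list(dW, db).
backwardPass <- function(weights, config, caches, dOut) {
  plan <- layerPlan(config)
  grads <- vector("list", length(plan))
  nL <- length(plan)
  # head and backend run last and are stored contiguously at the end
  backIdx <- which(vapply(plan, function(l) !is.numeric(l$column),
                          logical(1)))
  dy <- dOut
  for (li in rev(backIdx)) {
    l <- plan[[li]]
    bk <- cpp_conv_backward(dy, caches[[li]]$y, caches[[li]]$cols,
                            weights[[li]]$W, l$k, l$d, l$nin, TRUE, TRUE)
    grads[[li]] <- list(dW = bk$dW, db = as.numeric(bk$db))
    dy <- bk$dx
  }
  # split the fused gradient back into the three column tails
  splits <- vapply(config@columnFilters, function(f) f[length(f)],
                   numeric(1))
  at <- 0L
  for (col in 1:3) {
    dcol <- dy[, , at + seq_len(splits[col]), drop = FALSE]
    at <- at + splits[col]
    colIdx <- which(vapply(plan, function(l) identical(l$column, col),
                           logical(1)))
    dz <- dcol
    for (li in rev(colIdx)) {
      l <- plan[[li]]
      if (l$pool)
        dz <- cpp_maxpool2_backward(dz, caches[[li]]$poolIdx,
                                    caches[[li]]$preDim[1L],
                                    caches[[li]]$preDim[2L])
      needDx <- li != colIdx[1L]
      bk <- cpp_conv_backward(dz, caches[[li]]$y, caches[[li]]$cols,
                              weights[[li]]$W, l$k, l$d, l$nin, TRUE,
                              needDx)
      grads[[li]] <- list(dW = bk$dW, db = as.numeric(bk$db))
      if (needDx) dz <- bk$dx
    }
  }
  grads
}

#' Predict a density map for one image
#'
#' Scales the image to \[0, 1\], zero-pads the bottom/right edges to the
#' next multiple of 8 if needed, runs the fully convolutional model and
#' returns the nonnegative density map at 1/8 the (padded) input
#' resolution. The ReLU head guarantees nonnegative output, so the grid
#' sum is directly usable as the count estimate.
#'
#' @param model a [HybridModel-class].
#' @param image numeric `H x W x 3` array in \[0, 255\].
#' @return a [DensityMap-class] with `scale = 1/8`.
#' @export
predictDensity <- function(model, image) {
  stopifnot(is(model, "HybridModel"))
  assertRGB(image)
  x <- padToMultiple(image / 255, model@downsampleFactor)
  out <- forwardPass(model@weights, model@config, x, train = FALSE)$out
  DensityMap(out[, , 1L], scale = 1 / model@downsampleFactor)
}

padToMultiple <- function(x, m) {
  d <- dim(x)
  hp <- m * ceiling(d[1L] / m)
  wp <- m * ceiling(d[2L] / m)
  if (hp == d[1L] && wp == d[2L]) return(x)
  out <- array(0, c(hp, wp, d[3L]))
  out[seq_len(d[1L]), seq_len(d[2L]), ] <- x
  out
}

#' Input-gradient map of one dilated convolution layer
#'
#' Builds a single randomly weighted `k x k` convolution layer with
#' dilation `r` (linear, "same" padding), forwards a random input, and
#' backpropagates from the central output unit. The set of input pixels
#' with nonzero gradient is exactly the dilated tap pattern, so this
#' measures the true receptive-field geometry of the layer rather than
#' the closed-form arithmetic.
#'
#' @inheritParams effectiveKernelSize
#' @param size side of the square test input (odd sizes keep the center
#'   unambiguous; default 31).
#' @param seed seed for the random weights.
#' @return `size x size` matrix of gradients w.r.t. the input.
#' @export
inputGradient <- function(k, r, size = 31L, seed = 1L) {
  effectiveKernelSize(k, r)            # validates
  size <- as.integer(size)
  if (size < effectiveKernelSize(k, r))
    stop("test input smaller than the receptive field")
  withSeed(as.integer(seed), {
    x <- array(rnorm(size * size), c(size, size, 1L))
    W <- matrix(runif(k * k, min = 0.5, max = 1.5), nrow = 1L)
    fw <- cpp_conv_forward(x, W, 0, k, r, FALSE, TRUE)
    dy <- array(0, c(size, size, 1L))
    ctr <- (size + 1L) %/% 2L
    dy[ctr, ctr, 1L] <- 1
    bk <- cpp_conv_backward(dy, fw$out, fw$cols, W, k, r, 1L, FALSE, TRUE)
    bk$dx[, , 1L]
  })
}

#' Save and load a hybrid model
#'
#' The checkpoint stores the architecture and all weights in R's native
#' serialization; [writeHybridConfig()] / [readHybridConfig()] serialize
#' the architecture alone as YAML.
#'
#' @param model a [HybridModel-class].
#' @param path checkpoint path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "HybridModel"))
  saveRDS(list(config = configToList(model@config), weights = model@weights,
               downsampleFactor = model@downsampleFactor), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  new("HybridModel", config = configFromList(obj$config),
      weights = obj$weights,
      downsampleFactor = as.integer(obj$downsampleFactor))
}

configToList <- function(config) {
  list(columnKernels = config@columnKernels,
       columnFilters = config@columnFilters,
       poolAfter = config@poolAfter,
       backendFilters = config@backendFilters,
       backendKernel = config@backendKernel,
       backendDilation = config@backendDilation,
       inputChannels = config@inputChannels)
}

configFromList <- function(x) {
  asIntList <- function(l) lapply(l, as.integer)
  new("HybridConfig",
      columnKernels = asIntList(x$columnKernels),
      columnFilters = asIntList(x$columnFilters),
      poolAfter = asIntList(x$poolAfter),
      backendFilters = as.integer(x$backendFilters),
      backendKernel = as.integer(x$backendKernel),
      backendDilation = as.integer(x$backendDilation),
      inputChannels = as.integer(x$inputChannels))
}

#' @param config a [HybridConfig-class].
#' @rdname saveModel
#' @export
writeHybridConfig <- function(config, path) {
  stopifnot(is(config, "HybridConfig"))
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
readHybridConfig <- function(path) {
  configFromList(yaml::read_yaml(path))
}
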