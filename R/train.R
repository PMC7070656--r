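#' Train the hybrid counting network
#'
#' Batch-size-one ("online") Adam optimization of the mean squared error
#' between predicted and ground-truth density maps. The sample order is
#' reshuffled every epoch by a seeded generator; the validation split is
#' the last `validationFraction` of a seeded shuffle of the dataset, so
#' the whole run is deterministic for a given `TrainConfig` seed.
#' Validation counting metrics (MAE, RMSE, MAPE of integrated counts)
#' are recorded after every epoch, and the weights with the best
#' validation MAE are kept alongside the final ones.
#'
#' @param model an untrained (or warm-started) [HybridModel-class].
#' @param images list of `H x W x 3` arrays in \[0, 255\]; all sides must
#'   be divisible by the model's downsampling factor.
#' @param gtMaps list of ground-truth [DensityMap-class] objects at the
#'   model's output resolution (render at full resolution, then
#'   [blockSumDownsample()] by 8).
#' @param config a [TrainConfig-class].
#' @return list with `model` (final weights), `best` (best-validation
#'   weights; equal to `model` when no validation split), and `history`
#'   (a [TrainHistory-class]).
#' @export
trainModel <- function(model, images, gtMaps, config = TrainConfig()) {
  stopifnot(is(model, "HybridModel"))
  validObject(config)
  n <- length(images)
  if (n == 0L || length(gtMaps) != n)
    stop("images and gtMaps must be nonempty lists of equal length")
  f <- model@downsampleFactor
  for (i in seq_len(n)) {
    d <- dim(images[[i]])
    g <- if (is(gtMaps[[i]], "DensityMap")) gtMaps[[i]]@grid else
      stop("gtMaps must contain DensityMap objects")
    if (d[1L] %% f != 0L || d[2L] %% f != 0L)
      stop("training image sides must be divisible by the model's factor")
    if (nrow(g) != d[1L] / f || ncol(g) != d[2L] / f)
      stop(sprintf(
        "ground-truth map %d is %d x %d but the model outputs %d x %d",
        i, nrow(g), ncol(g), d[1L] / f, d[2L] / f))
  }
  weights <- model@weights
  cfg <- model@config
  adam <- lapply(weights, function(l)
    list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b))
  lr <- config@learningRate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  history <- withSeed(config@seed, {
    perm <- sample.int(n)
    nVal <- floor(config@validationFraction * n)
    valIdx <- if (nVal > 0L) perm[(n - nVal + 1L):n] else integer(0)
    trainIdx <- setdiff(perm, valIdx)
    loss <- valMAE <- valRMSE <- valMAPE <- rep(NA_real_, config@epochs)
    bestWeights <- weights
    bestMAE <- Inf
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(trainIdx)
      epochLoss <- 0
      for (i in ord) {
        x <- images[[i]] / 255
        gt <- gtMaps[[i]]@grid
        fw <- forwardPass(weights, cfg, x, train = TRUE)
        pred <- fw$out[, , 1L]
        diff <- pred - gt
        epochLoss <- epochLoss + mean(diff^2)
        dOut <- array(2 * diff / length(diff), c(dim(diff), 1L))
        grads <- backwardPass(weights, cfg, fw$caches, dOut)
        step <- step + 1L
        c1 <- 1 - b1^step
        c2 <- 1 - b2^step
        for (li in seq_along(weights)) {
          g <- grads[[li]]
          st <- adam[[li]]
          st$mW <- b1 * st$mW + (1 - b1) * g$dW
          st$vW <- b2 * st$vW + (1 - b2) * g$dW^2
          st$mb <- b1 * st$mb + (1 - b1) * g$db
          st$vb <- b2 * st$vb + (1 - b2) * g$db^2
          weights[[li]]$W <- weights[[li]]$W -
            lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
          weights[[li]]$b <- weights[[li]]$b -
            lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
          adam[[li]] <- st
        }
      }
      loss[epoch] <- epochLoss / length(ord)
      if (length(valIdx) > 0L) {
        est <- tru <- numeric(length(valIdx))
        for (j in seq_along(valIdx)) {
          i <- valIdx[j]
          out <- forwardPass(weights, cfg, images[[i]] / 255,
                             train = FALSE)$out
          est[j] <- sum(out)
          tru[j] <- sum(gtMaps[[i]]@grid)
        }
        err <- est - tru
        valMAE[epoch] <- mean(abs(err))
        valRMSE[epoch] <- sqrt(mean(err^2))
        valMAPE[epoch] <- if (all(tru > 0))
          mean(100 * abs(err) / tru) else NA_real_
        if (valMAE[epoch] < bestMAE) {
          bestMAE <- valMAE[epoch]
          bestWeights <- weights
        }
      }
    }
    list(loss = loss, valMAE = valMAE, valRMSE = valRMSE,
         valMAPE = valMAPE, bestWeights = bestWeights)
  })

  trained <- new("HybridModel", config = cfg, weights = weights,
                 downsampleFactor = f)
  best <- new("HybridModel", config = cfg,
              weights = if (is.finite(min(history$valMAE, Inf)) &&
                            any(!is.na(history$valMAE)))
                history$bestWeights else weights,
              downsampleFactor = f)
  list(model = trained, best = best,
       history = new("TrainHistory", loss = history$loss,
                     valMAE = history$valMAE, valRMSE = history$valRMSE,
                     valMAPE = history$valMAPE))
}
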