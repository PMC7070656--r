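# Shared fixture builders and independent oracles.

# Grey image with one channel replaced by the given matrix/values.
grayImage <- function(h, w, value = 128) {
  array(value, c(h, w, 3L))
}

# Image whose three channels are independent uniforms in [lo, hi].
uniformImage <- function(h, w, lo, hi, seed = 1L) {
  withr::with_seed(seed, array(runif(h * w * 3L, lo, hi), c(h, w, 3L)))
}

# Set one channel of an image from a vector/matrix of values.
setChannel <- function(image, channel, values) {
  image[, , channel] <- values
  image
}

# O(n^2) brute-force oracle for the mean k-nearest-neighbour distance.
knnOracle <- function(points, k) {
  n <- nrow(points)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(i) {
    if (n == 1L) return(NA_real_)
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- c(d, sqrt(sum((points[i, ] - points[j, ])^2)))
    }
    mean(sort(d)[seq_len(min(k, length(d)))])
  }, numeric(1))
}

# Naive loop-based oracle for the counting metrics.
metricsOracle <- function(est, tru) {
  n <- length(tru)
  sae <- sse <- sape <- 0
  for (i in seq_len(n)) {
    e <- est[i] - tru[i]
    sae <- sae + abs(e)
    sse <- sse + e^2
    sape <- sape + abs(e) / tru[i]
  }
  list(mae = sae / n, rmse = sqrt(sse / n), mape = 100 * sape / n,
       accuracy = 100 - 100 * sape / n)
}

# Numerical minimizer of the discretized Sobolev contrast functional
#   F(E) = a * ||E - S0||^2_W12 + (1 - a) * ||E - Sr||^2_W12
# with forward-difference gradients, via L-BFGS with the analytic
# gradient of the discretized functional (independent of the pointwise
# blend used by the implementation).
sobolevMinimizer <- function(s0, sr, alpha) {
  n <- nrow(s0); m <- ncol(s0)
  dx <- function(u) u[, -1, drop = FALSE] - u[, -m, drop = FALSE]
  dy <- function(u) u[-1, , drop = FALSE] - u[-n, , drop = FALSE]
  dxT <- function(v) {            # adjoint of dx
    out <- matrix(0, n, m)
    out[, -m] <- out[, -m] - v
    out[, -1] <- out[, -1] + v
    out
  }
  dyT <- function(v) {
    out <- matrix(0, n, m)
    out[-n, ] <- out[-n, ] - v
    out[-1, ] <- out[-1, ] + v
    out
  }
  term <- function(u) sum(u^2) + sum(dx(u)^2) + sum(dy(u)^2)
  fn <- function(e) {
    e <- matrix(e, n, m)
    alpha * term(e - s0) + (1 - alpha) * term(e - sr)
  }
  gr <- function(e) {
    e <- matrix(e, n, m)
    g <- function(u) 2 * (u + dxT(dx(u)) + dyT(dy(u)))
    as.numeric(alpha * g(e - s0) + (1 - alpha) * g(e - sr))
  }
  res <- stats::optim(as.numeric((s0 + sr) / 2), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = 2000, factr = 1e1))
  matrix(res$par, n, m)
}

listImagesInDir <- function(dir) {
  list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
}

# A small annotated scene plus its density supervision, for reuse.
smallTrainingSet <- function(nScenes, size = 64L, seed = 1L,
                             countRange = c(5L, 15L)) {
  cfg <- SceneConfig(width = size, height = size, countRange = countRange,
                     fishLength = c(3, 6))
  imgs <- list(); gts <- list(); counts <- integer(0)
  for (i in seq_len(nScenes)) {
    sc <- generateScene(cfg, seed = seed + i)
    imgs[[i]] <- sc$image
    gts[[i]] <- blockSumDownsample(renderDensityMap(sc$annotations), 8L)
    counts[i] <- nPoints(sc$annotations)
  }
  list(images = imgs, gt = gts, counts = counts)
}
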