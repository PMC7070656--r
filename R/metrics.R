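#' Mean squared error between two density maps
#'
#' The training loss: the mean over grid cells of squared differences
#' between the predicted and ground-truth maps.
#'
#' @param pred,truth [DensityMap-class] objects (or bare matrices) of
#'   identical dimensions.
#' @return nonnegative scalar.
#' @export
densityMSE <- function(pred, truth) {
  p <- if (is(pred, "DensityMap")) pred@grid else as.matrix(pred)
  t_ <- if (is(truth, "DensityMap")) truth@grid else as.matrix(truth)
  if (!identical(dim(p), dim(t_)))
    stop("density maps must have identical dimensions")
  mean((p - t_)^2)
}

#' Counting performance metrics
#'
#' Computes, over paired per-image counts, the mean absolute error
#' \deqn{MAE = \frac{1}{N}\sum |z_i - z_i^{GT}|,}
#' the root mean square error, the mean absolute percentage error
#' \deqn{MAPE = \frac{100}{N}\sum |z_i - z_i^{GT}| / z_i^{GT},}
#' the accuracy `100 - MAPE`, and the Pearson correlation between
#' estimates and truths.
#'
#' @param estimates,truths equal-length numeric vectors of per-image
#'   counts; truths must be strictly positive (MAPE divides by them).
#' @return a [MetricsReport-class].
#' @export
evaluateCounts <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length")
  n <- length(truths)
  if (n == 0L) stop("empty input")
  if (any(truths <= 0))
    stop("truths must be positive (MAPE divides by the true count)")
  err <- estimates - truths
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  mape <- mean(100 * abs(err) / truths)
  pear <- if (n >= 2L && sd(estimates) > 0 && sd(truths) > 0)
    cor(estimates, truths) else NA_real_
  if (n >= 2L && sd(truths) > 0 && sd(estimates) == 0) pear <- 0
  if (is.na(pear) && all(estimates == truths)) pear <- 1
  new("MetricsReport", mae = mae, rmse = rmse, mape = mape,
      accuracy = 100 - mape, pearson = pear, n = n)
}

#' Accuracy stratified by true count
#'
#' Buckets test images by their true count into half-open ranges
#' (default edges 60, 100, 140, 180, giving the five strata
#' fewer/few/medium/many/large) and reports the per-bucket sample size
#' and counting accuracy.
#'
#' @inheritParams evaluateCounts
#' @param edges increasing interior bucket edges; a truth `t` falls in
#'   the bucket with `lower <= t < upper`.
#' @return data.frame with columns `name`, `lower`, `upper`, `n`,
#'   `accuracy` (percent; `NA` for empty buckets).
#' @export
rangeReport <- function(estimates, truths,
                        edges = c(60, 100, 140, 180)) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length")
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  lower <- c(0, edges)
  upper <- c(edges, Inf)
  name <- if (length(edges) == 4L)
    c("Fewer", "Few", "Medium", "Many", "Large")
  else paste0("[", lower, ", ", ifelse(is.finite(upper), upper, "Inf"), ")")
  idx <- findInterval(truths, lower)     # 1-based bucket index
  acc <- n <- numeric(length(lower))
  for (b in seq_along(lower)) {
    sel <- idx == b
    n[b] <- sum(sel)
    acc[b] <- if (n[b] > 0L)
      evaluateCounts(estimates[sel], truths[sel])@accuracy else NA_real_
  }
  data.frame(name = name, lower = lower, upper = upper, n = as.integer(n),
             accuracy = acc, stringsAsFactors = FALSE)
}

#' Per-image signed errors and their histogram
#'
#' Errors are `estimate - truth` in input order, summarizing where the
#' model over- or under-counts; the histogram uses fixed-width bins
#' covering the whole error range.
#'
#' @inheritParams evaluateCounts
#' @param binWidth histogram bin width in count units.
#' @return list with `errors` (numeric vector), `breaks` and `counts`
#'   (histogram; `sum(counts) == length(errors)`).
#' @export
errorSeries <- function(estimates, truths, binWidth = 5) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length")
  if (binWidth <= 0) stop("binWidth must be positive")
  errors <- estimates - truths
  lo <- binWidth * floor(min(errors) / binWidth)
  hi <- binWidth * ceiling(max(errors) / binWidth)
  if (hi == lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  counts <- graphics::hist(errors, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  list(errors = errors, breaks = breaks, counts = counts)
}
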