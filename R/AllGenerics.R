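#' Count objects by integrating a density map
#'
#' The defining property of a density map is that its integral over a
#' region equals the expected object count there; summing the whole grid
#' therefore estimates the per-image count.
#'
#' @param x a [DensityMap-class] (or an object holding one).
#' @return the (real-valued) object count.
#' @export
setGeneric("countFromDensity", function(x) standardGeneric("countFromDensity"))

#' @describeIn countFromDensity grid sum of the map.
setMethod("countFromDensity", "DensityMap", function(x) {
  if (any(x@grid < 0)) stop("density map has negative entries")
  sum(x@grid)
})

#' @rdname accessors
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

#' @rdname accessors
#' @export
setGeneric("densityScale", function(x) standardGeneric("densityScale"))

#' @rdname accessors
#' @export
setGeneric("annotationPoints", function(x) standardGeneric("annotationPoints"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' Accessors for shoalcount objects
#'
#' @param x the object.
#' @return `densityGrid`: the numeric matrix; `densityScale`: the
#'   resolution ratio; `annotationPoints`: the n x 2 matrix of 0-based
#'   `(x, y)` centers; `nPoints`: the annotation count; `imageId`: the
#'   image identifier.
#' @name accessors
#' @rdname accessors
#' @export
setMethod("densityGrid", "DensityMap", function(x) x@grid)

#' @rdname accessors
setMethod("densityScale", "DensityMap", function(x) x@scale)

#' @rdname accessors
setMethod("annotationPoints", "AnnotationSet", function(x) x@points)

#' @rdname accessors
setMethod("nPoints", "AnnotationSet", function(x) nrow(x@points))

#' @rdname accessors
setMethod("imageId", "AnnotationSet", function(x) x@imageId)

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet '%s': %d point(s) on a %d x %d image\n",
              object@imageId, nrow(object@points), object@width,
              object@height))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap %d x %d (scale %s): count %.4f\n",
              nrow(object@grid), ncol(object@grid),
              format(object@scale), sum(object@grid)))
})

setMethod("show", "HybridConfig", function(object) {
  cat("HybridConfig: 3-column front end + dilated back end\n")
  for (i in 1:3)
    cat(sprintf("  column %d: kernels %s, filters %s, pools after %s\n", i,
                paste(object@columnKernels[[i]], collapse = "-"),
                paste(object@columnFilters[[i]], collapse = "-"),
                paste(object@poolAfter[[i]], collapse = ",")))
  cat(sprintf("  back end: %s (3x3, dilation 2) + 1x1 head\n",
              paste(object@backendFilters, collapse = "-")))
})

setMethod("show", "HybridModel", function(object) {
  np <- sum(vapply(object@weights,
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("HybridModel: %d layers, %d parameters, output 1/%d scale\n",
              length(object@weights), np, object@downsampleFactor))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport (n = %d)\n  MAE %.4f  RMSE %.4f  ",
                     "MAPE %.4f%%  accuracy %.4f%%  Pearson %.4f\n"),
              object@n, object@mae, object@rmse, object@mape,
              object@accuracy, object@pearson))
})

setMethod("show", "TrainHistory", function(object) {
  n <- length(object@loss)
  cat(sprintf("TrainHistory: %d epoch(s), final loss %.6g", n,
              object@loss[n]))
  if (!is.na(object@valMAE[n]))
    cat(sprintf(", final validation MAE %.4f", object@valMAE[n]))
  cat("\n")
})

#' Coerce a metrics report to a list or data.frame
#'
#' @param x a [MetricsReport-class].
#' @param ... ignored.
#' @return `as.list`: named list of the five metrics and `n`.
#' @export
setMethod("as.list", "MetricsReport", function(x, ...) {
  list(mae = x@mae, rmse = x@rmse, mape = x@mape, accuracy = x@accuracy,
       pearson = x@pearson, n = x@n)
})
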