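#' Mean distance to the k nearest annotations
#'
#' For every annotated point, the mean Euclidean distance to its `k`
#' nearest other points — the local crowding measure that sets the
#' geometry-adaptive kernel bandwidth. When a point has fewer than `k`
#' neighbours the mean is taken over all available ones; a point with no
#' neighbour at all yields `NA`, the sentinel that later triggers the
#' fallback bandwidth.
#'
#' @param points numeric `n x 2` matrix of `(x, y)` coordinates (or an
#'   [AnnotationSet-class]).
#' @param k number of nearest neighbours (>= 1).
#' @return numeric vector of length `n` (empty for empty input).
#' @export
knnMeanDistance <- function(points, k = 3L) {
  if (is(points, "AnnotationSet")) points <- annotationPoints(points)
  points <- as.matrix(points)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(points)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(NA_real_)
  dm <- as.matrix(dist(points))
  vapply(seq_len(n), function(i) {
    d <- sort(dm[i, -i])
    mean(d[seq_len(min(k, length(d)))])
  }, numeric(1))
}

#' Geometry-adaptive kernel bandwidths
#'
#' Converts mean neighbour spacings to Gaussian bandwidths,
#' `sigma_i = beta * dbar_i`; in crowded regions the annotations sit
#' close together and receive narrow kernels, compensating the
#' perspective-induced size variation. Sentinel (`NA`) spacings map to
#' the fallback bandwidth.
#'
#' @param meanDistances vector of mean spacings in pixels (`NA` =
#'   isolated point).
#' @param params a [KernelParams-class] object.
#' @return vector of bandwidths in pixels.
#' @export
adaptiveSigmas <- function(meanDistances, params = KernelParams()) {
  validObject(params)
  if (any(meanDistances < 0, na.rm = TRUE))
    stop("distances must be nonnegative")
  ifelse(is.na(meanDistances), params@fallbackSigma,
         params@beta * meanDistances)
}

#' Render a geometry-adaptive Gaussian density map
#'
#' Each annotated point contributes an isotropic 2-D Gaussian centered at
#' its `(x, y)` position with its adaptive bandwidth, truncated at
#' `truncationSigmas * sigma` and renormalized over the in-frame support
#' so every point deposits total mass exactly one — also at image
#' borders. The grid sum therefore equals the annotation count.
#'
#' Kernels are evaluated at pixel centers; annotation coordinates are
#' 0-based with `x` indexing columns and `y` rows.
#'
#' @param annotations an [AnnotationSet-class].
#' @param params a [KernelParams-class] object.
#' @return a [DensityMap-class] at full resolution (`scale = 1`).
#' @export
renderDensityMap <- function(annotations, params = KernelParams()) {
  stopifnot(is(annotations, "AnnotationSet"))
  validObject(annotations)
  validObject(params)
  h <- annotations@height
  w <- annotations@width
  pts <- annotations@points
  grid <- matrix(0, nrow = h, ncol = w)
  if (nrow(pts) == 0L) return(DensityMap(grid, scale = 1))
  oob <- pts[, 1L] < 0 | pts[, 1L] >= w | pts[, 2L] < 0 | pts[, 2L] >= h
  if (any(oob)) {
    i <- which(oob)[1L]
    stop(sprintf("point %d at (%.2f, %.2f) lies outside the %d x %d image",
                 i, pts[i, 1L], pts[i, 2L], w, h))
  }
  sigmas <- adaptiveSigmas(knnMeanDistance(pts, params@kNeighbors), params)
  for (i in seq_len(nrow(pts))) {
    s <- max(sigmas[i], 1e-6)
    r <- params@truncationSigmas * s
    x0 <- pts[i, 1L]
    y0 <- pts[i, 2L]
    xs <- max(0L, floor(x0 - r)):min(w - 1L, ceiling(x0 + r))
    ys <- max(0L, floor(y0 - r)):min(h - 1L, ceiling(y0 + r))
    gx <- exp(-((xs - x0)^2) / (2 * s^2))
    gy <- exp(-((ys - y0)^2) / (2 * s^2))
    patch <- outer(gy, gx)
    patch[outer((ys - y0)^2, (xs - x0)^2, "+") > r^2] <- 0
    total <- sum(patch)
    if (total <= 0) {                      # pathological: all mass truncated
      patch <- matrix(0, length(ys), length(xs))
      patch[which.min(abs(ys - y0)), which.min(abs(xs - x0))] <- 1
      total <- 1
    }
    grid[ys + 1L, xs + 1L] <- grid[ys + 1L, xs + 1L] + patch / total
  }
  DensityMap(grid, scale = 1)
}

#' Count-preserving block-sum downsampling
#'
#' Sums non-overlapping `factor x factor` blocks, reducing resolution
#' while preserving the grid sum exactly; dimensions not divisible by the
#' factor are zero-padded bottom/right first. Used to bring ground-truth
#' maps to the 1/8-resolution output of the counting network.
#'
#' @param map a [DensityMap-class].
#' @param factor integer >= 1.
#' @return downsampled [DensityMap-class]; `scale` divided by `factor`.
#' @export
blockSumDownsample <- function(map, factor = 8L) {
  stopifnot(is(map, "DensityMap"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(map)
  g <- map@grid
  h <- nrow(g)
  w <- ncol(g)
  hp <- factor * ceiling(h / factor)
  wp <- factor * ceiling(w / factor)
  if (hp != h || wp != w) {
    gp <- matrix(0, hp, wp)
    gp[seq_len(h), seq_len(w)] <- g
    g <- gp
  }
  h2 <- hp / factor
  w2 <- wp / factor
  # fold rows then columns
  g <- rowsum(g, rep(seq_len(h2), each = factor))
  g <- t(rowsum(t(g), rep(seq_len(w2), each = factor)))
  dimnames(g) <- NULL
  DensityMap(g, scale = map@scale / factor)
}

#' Read and write point annotations
#'
#' CSV with columns `image_id`, `x`, `y` (0-based pixel coordinates) or
#' JSON with fields `image_id`, `width`, `height` and a `points` array;
#' the CSV reader takes the image dimensions as arguments since CSV rows
#' carry none. Round-trips are lossless.
#'
#' @param path file path (`.csv` or `.json`).
#' @param width,height image dimensions (CSV only).
#' @return an [AnnotationSet-class] (lists of them, keyed by `image_id`,
#'   when the CSV holds several images).
#' @export
readAnnotations <- function(path, width = NULL, height = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- obj$points
    if (is.null(pts) || length(pts) == 0L)
      pts <- matrix(numeric(0), ncol = 2L)
    return(AnnotationSet(as.matrix(pts), width = obj$width,
                         height = obj$height, imageId = obj$image_id))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns image_id, x, y")
  if (is.null(width) || is.null(height))
    stop("width and height are required when reading CSV annotations")
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | df$x < 0 | df$y < 0 |
                 df$x >= width | df$y >= height)
  if (length(bad) > 0L)
    stop(sprintf("invalid annotation at line %d of %s",
                 bad[1L] + 1L, path))   # +1 for the header line
  sets <- lapply(split(df, df$image_id), function(d)
    AnnotationSet(cbind(x = d$x, y = d$y), width = width, height = height,
                  imageId = d$image_id[1L]))
  if (length(sets) == 1L) sets[[1L]] else sets
}

#' @param set an [AnnotationSet-class].
#' @rdname readAnnotations
#' @export
writeAnnotations <- function(set, path) {
  stopifnot(is(set, "AnnotationSet"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(image_id = set@imageId, width = set@width, height = set@height,
           points = unname(set@points)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    pts <- set@points
    df <- data.frame(image_id = rep(set@imageId, nrow(pts)),
                     x = pts[, 1L], y = pts[, 2L])
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Save and load density maps
#'
#' Stores the numeric grid in R's native serialization alongside a JSON
#' sidecar recording the image id, resolution scale and integrated count.
#'
#' @param map a [DensityMap-class].
#' @param path output path for the grid (`.rds`); the sidecar is written
#'   next to it with extension `.json`.
#' @param imageId identifier recorded in the sidecar.
#' @export
writeDensityMap <- function(map, path, imageId = "image") {
  stopifnot(is(map, "DensityMap"))
  saveRDS(map@grid, path, compress = "gzip")
  jsonlite::write_json(
    list(image_id = imageId, scale = map@scale, count = sum(map@grid),
         height = nrow(map@grid), width = ncol(map@grid)),
    sub("\\.rds$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDensityMap
#' @export
readDensityMap <- function(path) {
  grid <- readRDS(path)
  side <- sub("\\.rds$", ".json", path)
  scale <- 1
  if (file.exists(side))
    scale <- jsonlite::read_json(side, simplifyVector = TRUE)$scale
  DensityMap(grid, scale = scale)
}
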