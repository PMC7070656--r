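#' Generate a synthetic underwater fish-shoal scene
#'
#' Renders a seeded stand-in for an underwater shoal photograph taken
#' from below: a blue-green background with a mild vertical illumination
#' gradient, overlapping elliptical fish silhouettes in silvery tones
#' with an attenuated red channel, fish sizes shrinking towards the top
#' of the frame (farther from the camera), and a final Gaussian blur for
#' turbidity. The fish count is drawn uniformly from the configured
#' range, and the annotation set holds each fish's true center.
#'
#' Fish are composited bottom-up (near fish paint over far ones), so
#' occlusions resemble the overlap patterns of real shoal imagery;
#' labels stay at the true centers regardless of occlusion.
#'
#' @param config a [SceneConfig-class].
#' @param seed integer seed; the same seed reproduces the scene and its
#'   labels exactly.
#' @return list with `image` (`H x W x 3` array in \[0, 255\]) and
#'   `annotations` (an [AnnotationSet-class]).
#' @export
generateScene <- function(config = SceneConfig(), seed = 1L) {
  validObject(config)
  withSeed(as.integer(seed), {
    h <- config@height
    w <- config@width
    img <- array(0, c(h, w, 3L))
    light <- 1 + 0.15 * (seq_len(h) - 1) / max(1, h - 1)  # brighter below
    for (c in 1:3)
      img[, , c] <- config@baseColor[c] * light +
        matrix(runif(h * w, -5, 5), h, w)

    n <- if (config@countRange[1L] == config@countRange[2L])
      config@countRange[1L]
    else sample(config@countRange[1L]:config@countRange[2L], 1L)

    cx <- runif(n, 0, w - 1)
    cy <- runif(n, 0, h - 1)
    if (!config@overlapAllowed && n > 1L) {
      minSep <- 2 * mean(config@fishLength)
      for (i in 2:n) {
        tries <- 0L
        while (tries < 200L &&
               min(sqrt((cx[i] - cx[1:(i - 1)])^2 +
                        (cy[i] - cy[1:(i - 1)])^2)) < minSep) {
          cx[i] <- runif(1, 0, w - 1)
          cy[i] <- runif(1, 0, h - 1)
          tries <- tries + 1L
        }
      }
    }
    a0 <- runif(n, config@fishLength[1L], config@fishLength[2L])
    ar <- runif(n, config@aspectRatio[1L], config@aspectRatio[2L])
    theta <- runif(n, 0, pi)
    bright <- runif(n, 150, 220)
    # perspective: top of frame is far, fish shrink by sizeGradient there
    depth <- cy / max(1, h - 1)
    sizeFac <- config@sizeGradient + (1 - config@sizeGradient) * depth

    for (i in order(cy)) {                 # far (small) fish first
      a <- a0[i] * sizeFac[i]
      b <- max(0.8, a * ar[i])
      r <- ceiling(a) + 1L
      xs <- max(0L, floor(cx[i] - r)):min(w - 1L, ceiling(cx[i] + r))
      ys <- max(0L, floor(cy[i] - r)):min(h - 1L, ceiling(cy[i] + r))
      dx <- outer(rep(1, length(ys)), xs - cx[i])
      dy <- outer(ys - cy[i], rep(1, length(xs)))
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      mask <- (u / a)^2 + (v / b)^2 <= 1
      col <- bright[i] * c(config@redAttenuation, 1.0, 1.05)
      for (c in 1:3) {
        patch <- img[ys + 1L, xs + 1L, c]
        patch[mask] <- col[c]
        img[ys + 1L, xs + 1L, c] <- patch
      }
    }

    if (config@blurSigma > 0) {
      dat <- aperm(pmin(pmax(img, 0), 255) / 255, c(2L, 1L, 3L))
      blurred <- EBImage::gblur(EBImage::Image(dat, colormode = "Color"),
                                sigma = config@blurSigma)
      img <- aperm(EBImage::imageData(blurred), c(2L, 1L, 3L)) * 255
    }
    img <- pmin(pmax(img, 0), 255)
    list(image = img,
         annotations = AnnotationSet(cbind(x = cx, y = cy), width = w,
                                     height = h, imageId = sprintf(
                                       "scene_%06d", as.integer(seed))))
  })
}

#' Additive Gaussian noise augmentation
#'
#' Adds zero-mean Gaussian noise with the configured variance on the
#' \[0, 1\] intensity scale (so variance 0.001 corresponds to a standard
#' deviation of about 8 grey levels), then clamps to \[0, 255\] and
#' quantizes to the 8-bit grid.
#'
#' @param image numeric `H x W x 3` array in \[0, 255\].
#' @param config a [NoiseConfig-class].
#' @param seed integer seed.
#' @return noisy image, same dimensions.
#' @export
addGaussianNoise <- function(image, config = NoiseConfig(), seed = 1L) {
  assertRGB(image)
  validObject(config)
  withSeed(as.integer(seed), {
    noise <- rnorm(length(image), 0, sqrt(config@gaussianVariance)) * 255
    quantize8(pmin(pmax(image + noise, 0), 255))
  })
}

#' Salt-and-pepper noise augmentation
#'
#' Replaces a seeded fraction of pixel locations by impulse noise: each
#' corrupted pixel becomes pure black (0) or pure white (255) across all
#' channels with equal probability; all other pixels are untouched.
#'
#' @inheritParams addGaussianNoise
#' @export
addSaltPepper <- function(image, config = NoiseConfig(), seed = 1L) {
  assertRGB(image)
  validObject(config)
  withSeed(as.integer(seed), {
    d <- dim(image)
    nPix <- d[1L] * d[2L]
    hit <- which(runif(nPix) < config@saltPepperAmount)
    if (length(hit) > 0L) {
      val <- ifelse(runif(length(hit)) < 0.5, 0, 255)
      for (c in 1:3) {
        ch <- image[, , c]
        ch[hit] <- val
        image[, , c] <- ch
      }
    }
    image
  })
}

#' Build a synthetic counting dataset on disk
#'
#' Generates `nScenes` seeded scenes and, for each, the four variants of
#' the augmentation scheme — original, enhanced, Gaussian-noise and
#' salt-and-pepper — all sharing one annotation set. Scenes (with all
#' four variants) are assigned wholesale to the train/validation/test
#' splits, so no fish distribution can leak across splits. Images are
#' written as PNG, annotations as JSON, and one manifest JSON per split
#' lists the image paths and annotation references.
#'
#' @param nScenes number of scenes.
#' @param outDir output directory (created if missing).
#' @param sceneConfig a [SceneConfig-class].
#' @param noiseConfig a [NoiseConfig-class].
#' @param split named fractions summing to 1 (default train 0.7,
#'   val 0.1, test 0.2).
#' @param seed master seed; per-scene seeds are derived from it.
#' @param enhanceParams an [EnhancementParams-class] for the enhanced
#'   variant.
#' @return named list of manifests (one data.frame per split), invisibly;
#'   manifests are also written to `<outDir>/manifest_<split>.json`.
#' @export
makeDataset <- function(nScenes, outDir, sceneConfig = SceneConfig(),
                        noiseConfig = NoiseConfig(),
                        split = c(train = 0.7, val = 0.1, test = 0.2),
                        seed = 1L,
                        enhanceParams = EnhancementParams()) {
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (is.null(names(split)) || any(!nzchar(names(split))))
    stop("split fractions must be named")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sceneSeeds <- withSeed(as.integer(seed),
                         sample.int(.Machine$integer.max, nScenes))
  rows <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    sc <- generateScene(sceneConfig, seed = sceneSeeds[i])
    id <- sprintf("scene_%04d", i)
    paths <- c(original = file.path(outDir, paste0(id, "_orig.png")),
               enhanced = file.path(outDir, paste0(id, "_enh.png")),
               gaussian = file.path(outDir, paste0(id, "_gauss.png")),
               salt_pepper = file.path(outDir, paste0(id, "_sp.png")))
    writeRGB(sc$image, paths["original"])
    writeRGB(enhanceImage(sc$image, enhanceParams), paths["enhanced"])
    writeRGB(addGaussianNoise(sc$image, noiseConfig,
                              seed = sceneSeeds[i]), paths["gaussian"])
    writeRGB(addSaltPepper(sc$image, noiseConfig,
                           seed = sceneSeeds[i]), paths["salt_pepper"])
    annPath <- file.path(outDir, paste0(id, "_annotations.json"))
    ann <- sc$annotations
    ann@imageId <- id
    writeAnnotations(ann, annPath)
    rows[[i]] <- data.frame(scene_id = id, count = nPoints(ann),
                            annotations = annPath,
                            t(paths), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  perm <- withSeed(as.integer(seed) + 1L, sample.int(nScenes))
  sizes <- floor(split * nScenes)
  sizes[1L] <- nScenes - sum(sizes[-1L])
  manifests <- list()
  at <- 0L
  for (s in names(split)) {
    idx <- perm[at + seq_len(sizes[[s]])]
    at <- at + sizes[[s]]
    m <- df[sort(idx), , drop = FALSE]
    rownames(m) <- NULL
    manifests[[s]] <- m
    jsonlite::write_json(m, file.path(outDir,
                                      paste0("manifest_", s, ".json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(manifests)
}
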