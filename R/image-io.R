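#' Read and write 8-bit RGB images
#'
#' Images are represented throughout the package as numeric
#' `height x width x 3` arrays with values in \[0, 255\] (channel order
#' R, G, B; rows are image rows). `readRGB` accepts PNG and JPEG files;
#' greyscale files are expanded to three identical channels.
#'
#' @param path file path.
#' @return `readRGB`: a numeric `H x W x 3` array in \[0, 255\].
#' @export
readRGB <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(dat, c(dim(dat), 3L))
  if (dim(dat)[3L] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  x <- aperm(dat, c(2L, 1L, 3L)) * 255
  assertRGB(x)
  x
}

#' @param image numeric `H x W x 3` array in \[0, 255\].
#' @rdname readRGB
#' @return `writeRGB`: the path, invisibly.
#' @export
writeRGB <- function(image, path) {
  assertRGB(image)
  dat <- aperm(pmin(pmax(image, 0), 255) / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}

# Shared contract of every image-consuming operation.
assertRGB <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be a height x width x 3 array")
  d <- dim(image)
  if (d[1L] < 1L || d[2L] < 1L) stop("image is empty")
  if (any(image < -1e-9) || any(image > 255 + 1e-9))
    stop("image values must lie in [0, 255]")
  invisible(TRUE)
}

# Map a channel identifier ("R"/"G"/"B" or 1:3) to a slice index.
channelIndex <- function(channel) {
  if (is.character(channel)) {
    idx <- match(toupper(channel), c("R", "G", "B"))
    if (is.na(idx)) stop("channel must be one of 'R', 'G', 'B'")
    return(idx)
  }
  channel <- as.integer(channel)
  if (channel < 1L || channel > 3L) stop("channel index out of range")
  channel
}

# Round-half-up quantization to the 8-bit grid (R's round() would tie to
# even, which breaks the x.5 cases deliberately exercised in tests).
quantize8 <- function(image) {
  pmin(pmax(floor(image + 0.5), 0), 255)
}
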