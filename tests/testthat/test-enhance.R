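test_that("channel statistics are exact", {
  img <- grayImage(2, 2, 100)
  s <- channelStats(img, "R")
  expect_equal(s$mean, 100)
  expect_equal(s$max, 100)
  expect_equal(s$min, 100)

  img <- setChannel(grayImage(1, 2), 2, matrix(c(0, 255), 1, 2))
  s <- channelStats(img, 2)
  expect_equal(s$mean, 127.5)
  expect_equal(s$max, 255)
  expect_equal(s$min, 0)

  img <- setChannel(grayImage(2, 2), 3, matrix(c(0, 100, 200, 100), 2, 2))
  s <- channelStats(img, "B")
  expect_equal(s$mean, 100)
  expect_equal(s$max, 200)
  expect_equal(s$min, 0)

  expect_error(channelStats(array(0, c(2, 2, 2)), "R"), "3 array")
  expect_error(channelStats(grayImage(2, 2), "X"), "channel")
})

test_that("low-value fraction counts pixels at or below the cutoff", {
  expect_equal(lowValueFraction(grayImage(3, 3, 0), "R", 40), 1.0)
  expect_equal(lowValueFraction(grayImage(3, 3, 255), "R", 40), 0.0)
  img <- setChannel(grayImage(2, 2), 1, matrix(c(10, 40, 41, 200), 2, 2))
  expect_equal(lowValueFraction(img, "R", 40), 0.5)   # <= is inclusive
  expect_error(lowValueFraction(grayImage(2, 2), "R", 300), "cutoff")
})

test_that("color correction stretch branch matches hand evaluation", {
  # mean exactly 128 with Smin < 128: the affine map is the identity
  ch <- matrix(c(56, 200, 120, 136), 2, 2)
  stopifnot(mean(ch) == 128)
  out <- colorCorrect(setChannel(grayImage(2, 2), 1, ch))
  expect_equal(out[, , 1], ch, tolerance = 1e-12)

  # channel {0, 100}: 0 -> 0 and 100 -> 256 clamped to 255
  img <- setChannel(grayImage(1, 2, 100), 1, matrix(c(0, 100), 1, 2))
  out <- colorCorrect(img)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[1, 2, 1], 255)
})

test_that("depleted channels take the shift branch", {
  # 80% of pixels <= 40, mean 30, lambda 0.5: every pixel moves by +49
  vals <- c(rep(20, 8), 70, 70)
  stopifnot(mean(vals) == 30)
  img <- setChannel(grayImage(2, 5, 128), 1, matrix(vals, 2, 5))
  out <- colorCorrect(img, EnhancementParams(lambdaShift = 0.5))
  expect_equal(out[, , 1], matrix(vals + 49, 2, 5), tolerance = 1e-12)
})

test_that("stretch branch restores an exact mean of 128 without clipping", {
  for (seed in 1:5) {
    img <- uniformImage(16, 16, 60, 200, seed = seed)
    out <- colorCorrect(img)
    for (c in 1:3)
      expect_equal(mean(out[, , c]), 128, tolerance = 1e-9)
  }
})

test_that("stretch branch fixes its anchor points and preserves order", {
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, runif(63, 5, 120))
    vals <- c(vals, mean(vals))          # appending the mean keeps it
    img <- setChannel(grayImage(8, 8, 128), 1, matrix(vals, 8, 8))
    m <- mean(vals)
    out <- colorCorrect(img)[, , 1]
    # Smin is a fixed point on the mean <= 128 branch
    expect_equal(out[which.min(vals)], min(vals), tolerance = 1e-9)
    # the pixel sitting at the channel mean maps to 128
    expect_equal(out[64], 128, tolerance = 1e-9)
    # affine with positive slope: order preserved
    expect_equal(order(out), order(vals))

    # mean > 128 branch: Smax is the fixed point
    vals2 <- withr::with_seed(seed + 100, runif(64, 140, 250))
    img2 <- setChannel(grayImage(8, 8, 128), 1, matrix(vals2, 8, 8))
    out2 <- colorCorrect(img2)[, , 1]
    expect_equal(out2[which.max(vals2)], max(vals2), tolerance = 1e-9)
    # order preserved among pixels the clamp left untouched
    sel <- out2 > 0 & out2 < 255
    expect_equal(order(out2[sel]), order(vals2[sel]))
  }
})

test_that("constant channels degrade to mid-grey", {
  out <- colorCorrect(grayImage(4, 4, 77))
  expect_true(all(out == 128))
})

test_that("histogram-equalized reference behaves at its fixed points", {
  img <- grayImage(4, 4, 90)
  expect_equal(buildReference(img), img)   # single-bin histogram

  ch <- matrix(rep(c(0, 255), each = 8), 4, 4)
  img <- setChannel(grayImage(4, 4, 90), 1, ch)
  ref <- buildReference(img)
  expect_equal(ref[, , 1], ch)             # already full range
  expect_equal(dim(ref), dim(img))
})

test_that("contrast blend obeys its endpoint and midpoint contracts", {
  s0 <- uniformImage(6, 6, 0, 255, seed = 3)
  sr <- uniformImage(6, 6, 0, 255, seed = 4)
  expect_equal(contrastEnhance(s0, sr, 1), s0)
  expect_equal(contrastEnhance(s0, sr, 0), sr)
  e <- contrastEnhance(grayImage(3, 3, 100), grayImage(3, 3, 200), 0.5)
  expect_true(all(e == 150))
  expect_error(contrastEnhance(s0, grayImage(3, 3), 0.5), "dimensions")
})

test_that("pointwise blend equals the Sobolev functional minimizer", {
  for (seed in 1:3) {
    s0 <- withr::with_seed(seed, matrix(runif(64, 0, 255), 8, 8))
    sr <- withr::with_seed(seed + 50, matrix(runif(64, 0, 255), 8, 8))
    for (alpha in c(0.25, 0.5, 0.8)) {
      blend <- alpha * s0 + (1 - alpha) * sr
      oracle <- sobolevMinimizer(s0, sr, alpha)
      expect_lt(max(abs(blend - oracle)), 1e-4)
    }
  }
})

test_that("full enhancement pipeline composes its stages", {
  img <- uniformImage(16, 24, 20, 230, seed = 7)
  out <- enhanceImage(img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))
  expect_true(all(out == floor(out)))      # 8-bit quantized

  # alpha = 1: the blend degenerates to the color-corrected image
  p1 <- EnhancementParams(alpha = 1)
  expect_equal(enhanceImage(img, p1, quantize = FALSE), colorCorrect(img, p1))

  # constant mid-grey: correction fills 128, reference unchanged
  out <- enhanceImage(grayImage(8, 8, 128))
  expect_true(all(out == 128))
})
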