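test_that("dilated receptive-field arithmetic follows k*r - r + 1", {
  expect_identical(effectiveKernelSize(3, 1), 3L)
  expect_identical(effectiveKernelSize(3, 2), 5L)
  expect_identical(effectiveKernelSize(5, 3), 13L)
  expect_error(effectiveKernelSize(4, 2), "odd")
  expect_error(effectiveKernelSize(3, 0), ">= 1")
})

test_that("dilated kernel footprints enumerate the tap grid", {
  fp <- dilatedKernelFootprint(3, 2)
  expect_equal(nrow(fp), 9L)
  expect_equal(max(fp[, "dy"]) + 1L, 5L)
  expect_equal(max(fp[, "dx"]) + 1L, 5L)

  fp1 <- dilatedKernelFootprint(1, 7)
  expect_equal(nrow(fp1), 1L)

  fp3 <- dilatedKernelFootprint(3, 1)
  expect_setequal(paste(fp3[, 1], fp3[, 2]),
                  paste(rep(0:2, times = 3), rep(0:2, each = 3)))
})

test_that("input gradients of a real dilated layer match the footprint", {
  for (case in list(c(3, 1), c(3, 2), c(5, 3))) {
    k <- case[1]; r <- case[2]
    g <- inputGradient(k, r, size = 31)
    nz <- which(abs(g) > 1e-12, arr.ind = TRUE)
    expect_equal(nrow(nz), k^2)
    side <- effectiveKernelSize(k, r)
    expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1L, side)
    expect_equal(max(nz[, 2]) - min(nz[, 2]) + 1L, side)
    # positions are exactly the dilated tap grid
    fp <- dilatedKernelFootprint(k, r)
    got <- cbind(nz[, 1] - min(nz[, 1]), nz[, 2] - min(nz[, 2]))
    expect_setequal(paste(got[, 1], got[, 2]), paste(fp[, 1], fp[, 2]))
  }
})

test_that("the default architecture matches its structural contract", {
  cfg <- defaultHybridConfig()
  expect_length(cfg@columnKernels, 3L)
  expect_true(all(vapply(cfg@poolAfter, length, integer(1)) == 3L))
  expect_identical(cfg@backendKernel, 3L)
  expect_identical(cfg@backendDilation, 2L)
  plan <- shoalcount:::layerPlan(cfg)
  head <- plan[[length(plan)]]
  expect_identical(head$column, "head")
  expect_identical(head$nout, 1L)      # density maps are scalar-valued
  expect_identical(head$k, 1L)         # convolutional, not fully connected
  # width scaling shrinks every ladder proportionally
  half <- defaultHybridConfig(0.5)
  expect_equal(half@columnFilters[[1]], c(8L, 16L, 8L, 4L))
})

test_that("weight initialization is seeded Gaussian with sd 0.01", {
  m1 <- buildModel(defaultHybridConfig(0.25), seed = 11)
  m2 <- buildModel(defaultHybridConfig(0.25), seed = 11)
  expect_identical(m1@weights, m2@weights)
  m3 <- buildModel(defaultHybridConfig(0.25), seed = 12)
  expect_false(identical(m1@weights, m3@weights))

  w <- unlist(lapply(buildModel(seed = 1)@weights, function(l) l$W))
  expect_gt(length(w), 1e4)
  expect_gt(sd(w), 0.008)
  expect_lt(sd(w), 0.012)
  expect_lt(abs(mean(w)), 0.001)
})

test_that("prediction obeys the 1/8 law and nonnegativity", {
  model <- buildModel(defaultHybridConfig(0.125), seed = 3)
  x <- uniformImage(64, 64, 0, 255, seed = 1)
  dm <- predictDensity(model, x)
  expect_equal(dim(densityGrid(dm)), c(8, 8))
  expect_equal(densityScale(dm), 1 / 8)

  x <- uniformImage(256, 192, 0, 255, seed = 2)
  dm <- predictDensity(model, x)
  expect_equal(dim(densityGrid(dm)), c(32, 24))
  expect_true(all(densityGrid(dm) >= 0))
})

test_that("any input with sides divisible by 8 is accepted", {
  model <- buildModel(defaultHybridConfig(0.125), seed = 3)
  for (side in c(32, 48, 104, 512)) {
    dm <- predictDensity(model, uniformImage(side, 32, 0, 255, seed = side))
    expect_equal(dim(densityGrid(dm)), c(side / 8, 4))
  }
  # non-multiples are zero-padded to the next multiple
  dm <- predictDensity(model, uniformImage(30, 42, 0, 255, seed = 9))
  expect_equal(dim(densityGrid(dm)), c(4, 6))
})

test_that("a dilated layer preserves the size a pool-conv-upsample loses", {
  x <- withr::with_seed(1, array(runif(24 * 24), c(24, 24, 1)))
  W <- matrix(rnorm(9, sd = 0.1), 1)
  dil <- shoalcount:::cpp_conv_forward(x, W, 0, 3L, 2L, FALSE, FALSE)$out
  expect_equal(dim(dil)[1:2], c(24, 24))   # same size, no resolution loss

  pooled <- shoalcount:::cpp_maxpool2_forward(x)$out
  conv <- shoalcount:::cpp_conv_forward(pooled, W, 0, 3L, 1L, FALSE,
                                        FALSE)$out
  expect_equal(dim(conv)[1:2], c(12, 12))  # halved: must be upsampled
  up <- conv[rep(1:12, each = 2), rep(1:12, each = 2), 1]
  expect_equal(dim(up), c(24, 24))         # only then sizes agree again
})

test_that("the fully convolutional model is translation covariant", {
  model <- buildModel(defaultHybridConfig(0.125), seed = 5)
  h <- 384
  x <- uniformImage(h, 96, 0, 255, seed = 2)
  xs <- x
  xs[9:h, , ] <- x[1:(h - 8), , ]          # shift content down 8 pixels
  a <- densityGrid(predictDensity(model, x))
  b <- densityGrid(predictDensity(model, xs))
  # interior cells (a receptive-field margin away from any border)
  rows <- 20:28
  expect_equal(b[rows + 1, 6], a[rows, 6], tolerance = 1e-8)
})

test_that("models and configs survive save/load round-trips", {
  cfg <- defaultHybridConfig(0.25)
  model <- buildModel(cfg, seed = 8)
  ck <- tempfile(fileext = ".ckpt")
  saveModel(model, ck)
  back <- loadModel(ck)
  expect_identical(back@weights, model@weights)
  x <- uniformImage(32, 32, 0, 255, seed = 1)
  expect_equal(densityGrid(predictDensity(back, x)),
               densityGrid(predictDensity(model, x)))

  yml <- tempfile(fileext = ".yaml")
  writeHybridConfig(cfg, yml)
  cfg2 <- readHybridConfig(yml)
  expect_equal(cfg2@columnFilters, cfg@columnFilters)
  expect_equal(cfg2@backendFilters, cfg@backendFilters)
})
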