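test_that("knn mean distances match hand-worked cases", {
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(knnMeanDistance(two, k = 1), c(5, 5))

  collinear <- cbind(c(0, 1, 3), 0)
  expect_equal(knnMeanDistance(collinear, k = 2), c(2.0, 1.5, 2.5))

  expect_equal(knnMeanDistance(rbind(c(1, 1)), k = 3), NA_real_)
  expect_equal(knnMeanDistance(matrix(numeric(0), ncol = 2), 1), numeric(0))
  # fewer than k neighbours: average over all available
  expect_equal(knnMeanDistance(two, k = 5), c(5, 5))
})

test_that("knn mean distances agree with the brute-force oracle", {
  for (seed in 1:4) {
    n <- c(7, 23, 101, 200)[seed]
    pts <- withr::with_seed(seed, cbind(runif(n, 0, 500), runif(n, 0, 300)))
    for (k in c(1, 3, 6))
      expect_equal(knnMeanDistance(pts, k), knnOracle(pts, k),
                   tolerance = 1e-12)
  }
})

test_that("adaptive bandwidths scale spacing by beta", {
  expect_equal(adaptiveSigmas(10, KernelParams(beta = 0.3)), 3.0)
  p <- KernelParams()
  expect_equal(adaptiveSigmas(NA_real_, p), p@fallbackSigma)
  d <- c(1, 5, 12.5)
  expect_equal(adaptiveSigmas(2 * d, p), 2 * adaptiveSigmas(d, p))
  expect_error(adaptiveSigmas(-1, p), "nonnegative")
})

test_that("bandwidths are homothety-covariant", {
  pts <- withr::with_seed(9, cbind(runif(40, 0, 100), runif(40, 0, 100)))
  s1 <- adaptiveSigmas(knnMeanDistance(pts, 3))
  s2 <- adaptiveSigmas(knnMeanDistance(pts * 2.5, 3))
  expect_equal(s2, 2.5 * s1, tolerance = 1e-12)
})

test_that("rendered density maps conserve mass", {
  # single centered point
  ann <- AnnotationSet(rbind(c(16, 16)), width = 33, height = 33)
  expect_equal(countFromDensity(renderDensityMap(ann)), 1, tolerance = 1e-9)

  # several random in-bounds points
  pts <- withr::with_seed(2, cbind(runif(5, 0, 63), runif(5, 0, 47)))
  ann <- AnnotationSet(pts, width = 64, height = 48)
  expect_equal(countFromDensity(renderDensityMap(ann)), 5, tolerance = 1e-6)

  # a point in the extreme corner: without renormalization its kernel
  # would keep only about a quarter of its mass in frame
  ann <- AnnotationSet(rbind(c(0, 0), c(20, 20)), width = 40, height = 40)
  map <- renderDensityMap(ann)
  expect_equal(countFromDensity(map), 2, tolerance = 1e-6)
  s <- adaptiveSigmas(knnMeanDistance(ann@points, 3))[1]
  xs <- 0:39
  inFrame <- sum(outer(stats::dnorm(xs, 0, s), stats::dnorm(xs, 0, s)))
  expect_lt(inFrame, 0.5)  # truncated analytic mass, before renormalization
})

test_that("mass conservation holds across random scenes with borders", {
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(1:60, 1))
    pts <- withr::with_seed(seed + 10,
                            cbind(runif(n, 0, 79.999), runif(n, 0, 59.999)))
    pts[1, ] <- c(0, 0)                 # force a border point
    ann <- AnnotationSet(pts, width = 80, height = 60)
    expect_equal(countFromDensity(renderDensityMap(ann)), n,
                 tolerance = 1e-6)
  }
})

test_that("rendering is invariant to point order", {
  pts <- withr::with_seed(5, cbind(runif(12, 0, 31), runif(12, 0, 31)))
  a <- renderDensityMap(AnnotationSet(pts, 32, 32))
  b <- renderDensityMap(AnnotationSet(pts[sample(12), ], 32, 32))
  expect_equal(densityGrid(a), densityGrid(b), tolerance = 1e-12)
})

test_that("out-of-bounds annotations are rejected by name", {
  expect_error(AnnotationSet(rbind(c(-1, 5)), 10, 10), "x coordinates")
  expect_error(AnnotationSet(rbind(c(5, 10)), 10, 10), "y coordinates")
})

test_that("block-sum downsampling preserves counts exactly", {
  g <- matrix(1, 4, 4)
  m <- DensityMap(g)
  expect_equal(densityGrid(blockSumDownsample(m, 1)), g)
  d2 <- blockSumDownsample(m, 2)
  expect_equal(densityGrid(d2), matrix(4, 2, 2))
  expect_equal(densityScale(d2), 0.5)

  r <- DensityMap(withr::with_seed(3, matrix(runif(64 * 48), 48, 64)))
  d8 <- blockSumDownsample(r, 8)
  expect_equal(dim(densityGrid(d8)), c(6, 8))
  expect_equal(countFromDensity(d8), countFromDensity(r), tolerance = 1e-12)

  # non-divisible dimensions: zero-padded bottom/right
  odd <- DensityMap(matrix(1, 5, 7))
  d <- blockSumDownsample(odd, 4)
  expect_equal(dim(densityGrid(d)), c(2, 2))
  expect_equal(countFromDensity(d), 35, tolerance = 1e-12)
  expect_error(blockSumDownsample(odd, 0), "factor")
})

test_that("counting by integration composes with rendering", {
  expect_equal(countFromDensity(DensityMap(matrix(0, 4, 4))), 0)
  pts <- withr::with_seed(11, cbind(runif(9, 0, 39), runif(9, 0, 39)))
  full <- renderDensityMap(AnnotationSet(pts, 40, 40))
  expect_equal(countFromDensity(full), 9, tolerance = 1e-6)
  expect_equal(countFromDensity(blockSumDownsample(full, 8)),
               countFromDensity(full), tolerance = 1e-12)
  expect_error(DensityMap(matrix(c(-0.5, 1, 1, 1), 2, 2)), "nonnegative")
})

test_that("annotation files round-trip losslessly", {
  pts <- withr::with_seed(4, cbind(x = runif(10, 0, 99), y = runif(10, 0, 49)))
  ann <- AnnotationSet(pts, width = 100, height = 50, imageId = "img_07")

  csv <- tempfile(fileext = ".csv")
  writeAnnotations(ann, csv)
  back <- readAnnotations(csv, width = 100, height = 50)
  expect_equal(annotationPoints(back), annotationPoints(ann))
  expect_equal(imageId(back), "img_07")

  js <- tempfile(fileext = ".json")
  writeAnnotations(ann, js)
  back <- readAnnotations(js)
  expect_equal(annotationPoints(back), annotationPoints(ann))
  expect_equal(back@width, 100L)

  # empty set round-trips
  empty <- AnnotationSet(matrix(numeric(0), ncol = 2), 10, 10)
  writeAnnotations(empty, js)
  expect_equal(nPoints(readAnnotations(js)), 0L)

  # invalid rows are rejected with their line number
  writeLines(c("image_id,x,y", "a,5,5", "a,-1,3"), csv)
  expect_error(readAnnotations(csv, width = 10, height = 10), "line 3")
})

test_that("density maps round-trip with their sidecar metadata", {
  map <- blockSumDownsample(
    renderDensityMap(AnnotationSet(rbind(c(10, 12)), 32, 32)), 8)
  path <- tempfile(fileext = ".rds")
  writeDensityMap(map, path, imageId = "scene_1")
  back <- readDensityMap(path)
  expect_equal(densityGrid(back), densityGrid(map))
  expect_equal(densityScale(back), 0.125)
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(side$count, 1, tolerance = 1e-6)
})
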