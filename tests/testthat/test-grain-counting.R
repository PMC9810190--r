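test_that("region labeling honors the requested connectivity", {
  m <- matrix(FALSE, 7, 7)
  m[2:3, 2:3] <- TRUE
  m[5:6, 5:6] <- TRUE
  expect_equal(nrow(labelRegions(m)$table), 2L)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- TRUE
  diag2[3, 3] <- TRUE
  expect_equal(nrow(labelRegions(diag2, 8L)$table), 1L)
  expect_equal(nrow(labelRegions(diag2, 4L)$table), 2L)

  expect_equal(nrow(labelRegions(matrix(FALSE, 3, 3))$table), 0L)
})

test_that("labeled areas always sum to the foreground pixel count", {
  set.seed(61)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.35, 30, 30)
    lab <- labelRegions(m)
    expect_equal(sum(lab$table$area), sum(m))
    expect_true(all(lab$table$area >= 1))
    # labels partition the foreground
    expect_identical(lab$labels > 0L, m)
  }
})

test_that("the area curve smooths, differentiates and sorts correctly", {
  cfg <- pipelineConfig()
  curve <- buildAreaCurve(rep(50, 6), cfg)
  expect_equal(curve@laplacian[2:5], rep(0, 4))
  expect_equal(curve@smoothed, rep(50, 6))

  curve <- buildAreaCurve(c(1, 1, 1, 10), cfg)
  expect_gt(curve@laplacian[3], 0)  # convex corner at the jump

  expect_equal(buildAreaCurve(c(9, 9, 9), cfg)@smoothed, rep(9, 3))

  # unsorted input is sorted and the permutation retained
  curve <- buildAreaCurve(c(30, 10, 20), cfg)
  expect_equal(curve@areas, c(10, 20, 30))
  expect_equal(curve@ordering, c(2L, 3L, 1L))
})

test_that("point A lands after the noise run and matches the brute scan", {
  cfg <- pipelineConfig()
  # constant curve: no structure, fall back to the first index
  expect_equal(findPointA(buildAreaCurve(rep(100, 8), cfg)), 1L)
  expect_equal(findPointA(buildAreaCurve(42, cfg)), 1L)

  set.seed(67)
  for (i in 1:20) {
    nNoise <- sample(3:8, 1)
    nPlateau <- sample(10:40, 1)
    areas <- c(sort(sample(2:15, nNoise, replace = TRUE)),
               sort(round(500 * (1 + runif(nPlateau, -0.1, 0.1)))))
    curve <- buildAreaCurve(areas, cfg)
    A <- findPointA(curve)
    expect_equal(A, brutePointA(areas))
    expect_equal(A, nNoise + 1L)  # first plateau region
  }
})

test_that("the bare sign-pattern scan is exposed via a zero guard", {
  cfg <- pipelineConfig()
  # gentle convex tail after a dip: the literal 4-clause pattern fires
  areas <- c(2, 2, 3, 400, 405, 408, 412, 418, 426, 436)
  curve <- buildAreaCurve(areas, cfg)
  g <- curve@laplacian
  literal <- NA
  for (i in 2:(length(g) - 1)) {
    if (g[i - 1] < 0 && g[i - 1] < g[i] && g[i + 1] > 0 && g[i + 1] > g[i]) {
      literal <- i
      break
    }
  }
  expect_equal(findPointA(curve, minDipFraction = 0), literal)
})

test_that("point B fires at the first plateau-jump ratio violation", {
  cfg <- pipelineConfig()
  curve <- buildAreaCurve(c(100, 100, 100, 100, 130), cfg)
  expect_equal(findPointB(curve, A = 1L, cfg), 2L)

  # equal areas: every region holds one grain, B falls back to the end
  curve <- buildAreaCurve(rep(250, 7), cfg)
  expect_equal(findPointB(curve, A = 1L, cfg), 7L)

  curve <- buildAreaCurve(c(100, 500), cfg)
  expect_equal(findPointB(curve, A = 1L, cfg), 2L)

  # post-jump convention includes the offset
  cfg2 <- pipelineConfig(pointBConvention = "post-jump")
  curve <- buildAreaCurve(c(100, 100, 100, 100, 130), cfg2)
  expect_equal(findPointB(curve, A = 1L, cfg2), 5L)
})

test_that("optimal area minimizes total relative deviation", {
  expect_equal(optimalGrainArea(c(100, 110, 120)), 110)
  expect_equal(optimalGrainArea(777), 777)
  expect_error(optimalGrainArea(numeric(0)), "candidate")

  set.seed(71)
  for (i in 1:20) {
    s <- sample(50:5000, sample(2:30, 1), replace = TRUE)
    expect_equal(optimalGrainArea(s), exhaustiveOptimalArea(s))
  }
})

test_that("per-region counts apply the 0.4 fractional rule", {
  expect_identical(countRegion(100, 100), 1L)
  expect_identical(countRegion(250, 100), 3L)
  expect_identical(countRegion(139, 100), 1L)
  expect_identical(countRegion(141, 100), 2L)
  expect_identical(countRegion(c(40, 41, 240), 100), c(0L, 1L, 2L))

  # monotone in the area for fixed s_opt
  s <- seq(1, 1000, by = 7)
  expect_false(is.unsorted(countRegion(s, 137)))
})

test_that("total grain count sums regions and skips noise", {
  cfg <- pipelineConfig()
  tab <- data.frame(label = 1:3, area = c(500, 1000, 1500))
  curve <- buildAreaCurve(tab, cfg)
  out <- countGrains(curve, tab, 500, cfg)
  expect_equal(out$nGrain, 6L)
  expect_equal(out$regions$count, c(1L, 2L, 3L))

  # noise regions below A contribute nothing
  tab <- data.frame(label = 1:6, area = c(3, 4, 5, 480, 500, 520))
  curve <- buildAreaCurve(tab, cfg)
  expect_equal(curve@indexA, 4L)
  out <- countGrains(curve, tab, 500, cfg)
  expect_equal(out$nGrain, 3L)
  expect_identical(out$regions$isNoise, c(rep(TRUE, 3), rep(FALSE, 3)))
})

test_that("grain recovery is exact on touching-pair scenes", {
  scene <- generateScene(sceneSpec(seed = 77, nGrains = 40,
                                   adhesionFraction = 0.25,
                                   clusterSizes = 2L,
                                   germinationFraction = 0))
  expect_equal(sum(scene$truth@clusters$multiplicity), 40L)
  rep <- runPipeline(scene$image)
  expect_equal(nGrain(rep), 40L)
})

test_that("grain count is invariant under doubling the linear resolution", {
  spec1 <- sceneSpec(seed = 83, nGrains = 20, germinationFraction = 0.5)
  spec2 <- sceneSpec(seed = 83, nGrains = 20, germinationFraction = 0.5,
                     scale = 2)
  r1 <- runPipeline(generateScene(spec1)$image)
  r2 <- runPipeline(generateScene(spec2)$image)
  expect_equal(nGrain(r2), nGrain(r1))
  expect_gt(sOpt(r2) / sOpt(r1), 3.4)
  expect_lt(sOpt(r2) / sOpt(r1), 4.6)
})
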