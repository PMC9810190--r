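test_that("red histogram tallies foreground pixels by red value", {
  img <- solidImage(2, 5, c(85, 0, 0))
  mask <- matrix(TRUE, 2, 5)
  h <- redHistogram(img, mask)
  expect_equal(h[86], 10)
  expect_equal(sum(h), 10)

  img[, , 1][1, ] <- 234L
  h <- redHistogram(img, mask)
  expect_equal(h[86], 5)
  expect_equal(h[235], 5)

  expect_error(redHistogram(img, matrix(FALSE, 2, 5)), "foreground")
})

test_that("histogram smoothing preserves constants and total mass", {
  u <- rep(4, 256)
  expect_equal(gaussianSmoothHistogram(u), u)

  set.seed(41)
  for (i in 1:10) {
    h <- runif(256, 0, 100)
    hs <- gaussianSmoothHistogram(h)
    expect_equal(sum(hs), sum(h), tolerance = 1e-6)
    expect_true(all(hs >= 0))
  }
})

test_that("smoothing a delta reproduces the discretized Gaussian kernel", {
  h <- numeric(256)
  h[129] <- 1  # red value 128
  hs <- gaussianSmoothHistogram(h)
  x <- -50:50
  kern <- exp(-x^2 / (2 * 7.5^2))
  kern <- kern / sum(kern)
  expect_equal(hs[129 + x], kern, tolerance = 1e-12)
  expect_equal(hs[1:70], rep(0, 70))
})

test_that("quintic fit recovers exact polynomial histograms", {
  x <- 0:255
  true <- c(a = 2e-9, b = -1e-6, c = 1e-4, d = -0.01, e = 0.5, f = 3)
  h <- true["a"] * x^5 + true["b"] * x^4 + true["c"] * x^3 +
       true["d"] * x^2 + true["e"] * x + true["f"]
  fit <- fitQuintic(h)
  expect_equal(fit$coefficients, true, tolerance = 1e-6)
  expect_equal(fit$trend, h, tolerance = 1e-8)

  fit <- fitQuintic(rep(7, 256))
  expect_equal(unname(fit$coefficients["f"]), 7, tolerance = 1e-8)
  expect_equal(max(abs(fit$trend - 7)), 0, tolerance = 1e-8)
})

test_that("the quintic residual never exceeds the nested quartic residual", {
  set.seed(43)
  x <- 0:255
  for (i in 1:5) {
    h <- runif(256, 0, 50)
    rss5 <- sum((fitQuintic(h)$trend - h)^2)
    q4 <- lm(h ~ x + I(x^2) + I(x^3) + I(x^4))
    expect_lte(rss5, sum(resid(q4)^2) + 1e-6)
  }
})

test_that("valley threshold lies between the two dominant peaks", {
  # bimodal trend shaped like the border/core histogram
  x <- 0:255
  h <- 120 * exp(-(x - 85)^2 / (2 * 20^2)) +
       200 * exp(-(x - 234)^2 / (2 * 15^2))
  res <- findValleyThreshold(fitQuintic(gaussianSmoothHistogram(h)))
  expect_false(is.na(thresholdD(res)))
  expect_gt(thresholdD(res), res@peakA)
  expect_lt(thresholdD(res), res@peakB)
  expect_gt(res@peakA, 40)
  expect_lt(res@peakB, 256)

  # monotone trend: no bimodal structure, refinement skipped
  res <- findValleyThreshold(fitQuintic(as.numeric(x)))
  expect_true(is.na(thresholdD(res)))
})

test_that("valley index equals brute-force search on synthetic bimodal curves", {
  set.seed(47)
  for (i in 1:20) {
    c1 <- runif(1, 40, 110); c2 <- runif(1, 160, 230)
    h <- runif(1, 50, 200) * exp(-(0:255 - c1)^2 / (2 * runif(1, 10, 30)^2)) +
         runif(1, 50, 200) * exp(-(0:255 - c2)^2 / (2 * runif(1, 10, 30)^2))
    fit <- fitQuintic(gaussianSmoothHistogram(h))
    res <- findValleyThreshold(fit)
    expect_equal(thresholdD(res), bruteValley(fit$trend))
  }
})

test_that("refinement is anti-extensive and respects the threshold", {
  set.seed(53)
  img <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), dim = c(20, 20, 3))
  storage.mode(img) <- "integer"
  mask <- matrix(runif(400) < 0.6, 20, 20)

  expect_identical(refineMask(img, mask, 0), mask)
  expect_false(any(refineMask(img, mask, 256)))

  for (d in c(40, 128, 200)) {
    out <- refineMask(img, mask, d)
    expect_true(all(mask[out]))            # anti-extensive
    expect_false(any(img[, , 1][out] < d)) # all survivors at or above d
  }

  noRes <- findValleyThreshold(fitQuintic(as.numeric(0:255)))
  expect_identical(refineMask(img, mask, noRes), mask)
})

test_that("refinement strips the dark border band from a synthetic grain", {
  scene <- generateScene(benignSpec(seed = 8, nGrains = 6,
                                    germinationFraction = 0))
  cfg <- pipelineConfig()
  coarse <- coarseSegment(scene$image, cfg)
  ref <- refineSegmentation(scene$image, coarse, cfg)
  d <- thresholdD(ref$result)
  expect_gt(d, 110)   # above the border peak (~85)
  expect_lt(d, 180)   # below the core level (>= 180)
  red <- scene$image[, , 1]
  expect_false(any(red[ref$mask] < d))
  # the removed pixels are exactly the coarse-foreground pixels below d
  expect_identical(ref$mask, coarse & !(red < d))
})
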