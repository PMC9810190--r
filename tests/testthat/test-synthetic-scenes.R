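test_that("scene generation is bit-identical for a fixed seed", {
  spec <- benignSpec(seed = 123, nGrains = 8)
  s1 <- generateScene(spec)
  s2 <- generateScene(spec)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth@grainLabels, s2$truth@grainLabels)

  s3 <- generateScene(benignSpec(seed = 124, nGrains = 8))
  expect_false(identical(s1$image, s3$image))
})

test_that("a single clean grain yields one region and truth (1, 0)", {
  scene <- generateScene(sceneSpec(seed = 2, nGrains = 1,
                                   germinationFraction = 0,
                                   noiseReflections = 0L,
                                   noiseSpecks = 0L))
  expect_equal(nGrains(scene$truth), 1L)
  expect_equal(nGerminated(scene$truth), 0L)
  mask <- coarseSegment(scene$image)
  expect_equal(nrow(labelRegions(mask)$table), 1L)
})

test_that("ground truth records the requested composition", {
  scene <- generateScene(sceneSpec(seed = 9, nGrains = 40,
                                   adhesionFraction = 0.3,
                                   germinationFraction = 0.7))
  expect_equal(nGrains(scene$truth), 40L)
  expect_equal(nGerminated(scene$truth), 28L)
  expect_equal(sum(scene$truth@clusters$multiplicity), 40L)
  expect_true(any(scene$truth@clusters$multiplicity >= 2L))
  # germ ids refer to existing grains
  germIds <- setdiff(unique(as.vector(scene$truth@germLabels)), 0L)
  expect_equal(length(germIds), 28L)
  expect_true(all(germIds %in% seq_len(40L)))
})

test_that("grain cores sit in the clipped feature branch, rims below it", {
  scene <- generateScene(benignSpec(seed = 14, nGrains = 10))
  img <- scene$image
  feats <- computeColorFeatures(img)
  inGrain <- scene$truth@grainLabels > 0L
  core <- inGrain & img[, , 1] >= 180L
  rim <- inGrain & img[, , 1] <= 110L
  expect_gt(sum(core), 0)
  expect_gt(sum(rim), 0)
  expect_true(all(feats$rb[core] == 30L))
  expect_true(all(feats$gb[core] == 30L))
  # rims stay below the clip (a small noise-driven tail is tolerated)
  expect_gt(mean(feats$rb[rim] < 60L & feats$rb[rim] > 20L), 0.99)
})

test_that("an unplaceable request errors after the layout check", {
  expect_error(generateScene(sceneSpec(seed = 1, nGrains = 50,
                                       imageSize = c(100, 100))),
               "cannot place")
})

test_that("adversarial scenarios are named and validated", {
  expect_error(generateAdversarial("no-such-scene"), "unknown")
  for (k in c("droplet-on-edge", "intertwined-germs", "germ-under-grain",
              "overlapping-grains")) {
    adv <- generateAdversarial(k, seed = 11)
    expect_identical(adv$kind, k)
    expect_s4_class(adv$truth, "GroundTruth")
    expect_identical(dim(adv$image)[1:2], dim(adv$truth@grainLabels))
  }
})

test_that("antialiased rendering halves the supersampled canvas", {
  spec <- benignSpec(seed = 31, nGrains = 6)
  specAA <- benignSpec(seed = 31, nGrains = 6, antialias = TRUE)
  plain <- generateScene(spec)
  soft <- generateScene(specAA)
  expect_lt(max(abs(dim(soft$image)[1:2] - dim(plain$image)[1:2])), 10)
  expect_identical(soft$image, generateScene(specAA)$image)
})

test_that("written scenes round-trip through the truth sidecar", {
  dir <- tempfile("scenes")
  scene <- generateScene(benignSpec(seed = 4, nGrains = 6))
  writeScene(scene, dir, "demo")
  expect_true(file.exists(file.path(dir, "demo.png")))
  truth <- jsonlite::fromJSON(file.path(dir, "demo_truth.json"))
  expect_equal(truth$n_grains, nGrains(scene$truth))
  expect_equal(truth$n_germinated, nGerminated(scene$truth))
})
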