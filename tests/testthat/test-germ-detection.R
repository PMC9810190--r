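test_that("germ mask keeps only bright non-grain pixels", {
  img <- solidImage(4, 4, c(0, 0, 0))
  expect_false(any(germMask(img, matrix(FALSE, 4, 4))))

  img <- solidImage(4, 4, c(255, 255, 255))
  grain <- matrix(FALSE, 4, 4)
  grain[1:2, ] <- TRUE
  gm <- germMask(img, grain)
  expect_identical(gm, !grain)

  # gray exactly at the threshold is excluded (strict inequality)
  img160 <- solidImage(2, 2, c(160, 160, 160))
  expect_false(any(germMask(img160, matrix(FALSE, 2, 2))))
  img161 <- solidImage(2, 2, c(161, 161, 161))
  expect_true(all(germMask(img161, matrix(FALSE, 2, 2))))
})

test_that("contact measurement counts boundary and intersection pixels", {
  germ <- matrix(0L, 9, 9)
  germ[3:5, 3:5] <- 1L  # isolated 3x3 square
  grain <- matrix(0L, 9, 9)
  m <- measureContact(germ, grain)
  expect_equal(m$area, 9L)
  expect_equal(m$perimeter, 8L)
  expect_equal(m$intersection, 0L)

  # 1-pixel germ fully surrounded by grain: l = p = 1
  germ <- matrix(0L, 5, 5)
  germ[3, 3] <- 1L
  grain <- matrix(1L, 5, 5)
  grain[3, 3] <- 0L
  m <- measureContact(germ, grain)
  expect_equal(m$perimeter, 1L)
  expect_equal(m$intersection, 1L)
  expect_equal(m$lpRatio, 1)

  # candidate sharing exactly one edge pixel with a grain: a 1 x 3 germ
  # whose right end touches a grain pixel; only that end pixel has any
  # grain contact within its 8-neighborhood
  germ <- matrix(0L, 9, 9)
  germ[5, 2:4] <- 1L
  grain <- matrix(0L, 9, 9)
  grain[5, 5] <- 2L
  m <- measureContact(germ, grain)
  expect_equal(m$intersection, 1L)
  expect_equal(m$adjacentGrains[[1]], 2L)
  expect_true(m$intersection <= m$perimeter)
})

test_that("the area window is strictly open on both sides", {
  df <- data.frame(label = 1:5, area = c(59, 60, 500, 999, 1000))
  kept <- filterByArea(df, 3000)
  expect_identical(kept$label, c(3L, 4L))
  expect_identical(filterByArea(data.frame(label = integer(0),
                                           area = numeric(0)), 3000)$label,
                   integer(0))
  # a grain-sized blob is never a germ
  expect_equal(nrow(filterByArea(data.frame(label = 1L, area = 3000), 3000)),
               0L)
})

test_that("germinated counting needs adjacency and a small contact ratio", {
  cands <- data.frame(label = 1:4,
                      area = c(100, 100, 100, 100),
                      perimeter = c(40, 40, 40, 40),
                      intersection = c(0L, 8L, 20L, 15L))
  cands$lpRatio <- cands$intersection / cands$perimeter
  out <- countGerminated(cands, nGrain = 10L)
  # l = 0 detached; 8/40 = 0.2 accepted; 20/40 = 0.5 rejected;
  # 15/40 = 0.375 accepted
  expect_identical(out$accepted, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$nBud, 2L)
  expect_equal(out$germinationRate, 0.2)

  # removing any candidate never increases the count
  for (i in 1:4) {
    expect_lte(countGerminated(cands[-i, ], 10L)$nBud, out$nBud)
  }

  # undefined rate is flagged when no grains exist
  none <- countGerminated(cands, nGrain = 0L)
  expect_true(is.na(none$germinationRate))
  expect_false(none$rateDefined)
})

test_that("constructed germs pass the detector's own area and contact rules", {
  scene <- generateScene(benignSpec(seed = 19, nGrains = 20,
                                    germinationFraction = 0.6))
  rep <- runPipeline(scene$image)
  grainLab <- labelRegions(attr(rep, "masks")$grain)$labels
  m <- measureContact(scene$truth@germLabels, grainLab)
  expect_true(all(m$intersection >= 1L))
  expect_true(all(m$lpRatio < 0.4))
  expect_true(all(m$area > sOpt(rep) / 50))
  expect_true(all(m$area < sOpt(rep) / 3))
})

test_that("two germs merged into one component count as one at most", {
  adv <- generateAdversarial("intertwined-germs", seed = 3)
  rep <- runPipeline(adv$image)
  expect_lt(nBud(rep), nGerminated(adv$truth))
})
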