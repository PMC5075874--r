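# Worm masking, components, the single-worm area model and worm counting.

test_that("masking recovers live worm pixels almost exactly on clean scenes", {
  spec <- sceneSpec(imageHeightPx = 420L, imageWidthPx = 420L, nWorms = 5L,
                    seed = 8L, noiseSd = 0)
  sc <- renderScene(spec)
  mask <- maskWorms(sc$brightfield)
  lab <- labelImage(sc$truth)
  expect_gte(mean(mask[lab > 0L]), 0.99)  # >= 99% of worm pixels recovered
  comps <- extractComponents(mask, sc$brightfield)
  for (w in seq_len(5L)) {
    truthPx <- which(lab == w)
    iou <- max(vapply(comps, function(cp) {
      cpx <- nemasurv:::pxIndex(componentPixels(cp), dim(lab))
      length(intersect(cpx, truthPx)) / length(union(cpx, truthPx))
    }, 0))
    expect_gte(iou, 0.95)
  }
})

test_that("uniform background yields an empty mask and no components", {
  f <- frameFromDarkness(matrix(0.1, 80, 80))
  mask <- maskWorms(f)
  expect_false(any(mask))
  expect_length(extractComponents(mask, f), 0L)
})

test_that("fluorescence masking matches the deposited pixel set", {
  spec <- sceneSpec(imageHeightPx = 320L, imageWidthPx = 320L, nWorms = 1L,
                    seed = 12L, noiseSd = 0)
  sc <- renderScene(spec)
  mask <- maskWorms(sc$fluorescence, contrastFloor = 0.1)
  truth <- labelImage(sc$truth) > 0L
  expect_gte(sum(mask & truth) / sum(mask | truth), 0.95)
})

test_that("disjoint rods give two components with closed boundaries", {
  d <- matrix(0.1, 60, 120)
  d[11:20, 11:60] <- 0.7
  d[41:50, 51:100] <- 0.7
  f <- frameFromDarkness(d)
  comps <- extractComponents(maskWorms(f, bgRadius = 15L), f)
  expect_length(comps, 2L)
  expect_setequal(vapply(comps, function(x) x@areaPx, 0L), c(500L, 500L))
  for (cp in comps) {
    b <- componentBoundary(cp)
    expect_gte(nrow(b), 100)  # a closed loop around a 50x10 rod
    expect_lte(max(abs(b[1L, ] - b[nrow(b), ])), 1)  # closed traversal
    expect_gt(cp@meanDarkness, 0.6)
  }
})

test_that("a stricter darkness threshold yields a subset mask", {
  spec <- sceneSpec(imageHeightPx = 360L, imageWidthPx = 360L, nWorms = 4L,
                    seed = 33L)
  sc <- renderScene(spec)
  loose <- maskWorms(sc$brightfield, method = "fixed", fixedThreshold = 0.3,
                     fillHoles = FALSE, minObjectAreaPx = 0)
  strict <- maskWorms(sc$brightfield, method = "fixed", fixedThreshold = 0.5,
                      fillHoles = FALSE, minObjectAreaPx = 0)
  expect_true(all(loose[strict]))
})

test_that("the area model finds the degenerate and discrete modes exactly", {
  am <- fitAreaModel(c(100, 100, 100, 100, 100))
  expect_equal(singleWormArea(am), 100)
  am2 <- fitAreaModel(c(98, 100, 102, 201, 299))
  expect_gte(singleWormArea(am2), 98)
  expect_lte(singleWormArea(am2), 102)
  counts <- round(c(98, 100, 102, 201, 299) / singleWormArea(am2))
  expect_equal(counts, c(1, 1, 1, 2, 3))
  expect_error(fitAreaModel(c(100, 100)), "at least 5")
})

test_that("the area model recovers the true single-worm area on scenes", {
  # 30 worms with ~20% in touching clusters
  spec <- sceneSpec(imageHeightPx = 760L, imageWidthPx = 760L, nWorms = 30L,
                    clusterPlan = makeClusterPlan(c(3L, 3L), "mixed"),
                    seed = 101L)
  sc <- renderScene(spec)
  comps <- extractComponents(maskWorms(sc$brightfield), sc$brightfield)
  am <- fitAreaModel(comps)
  truthMean <- mean(wormTable(sc$truth)$area_px)
  expect_lt(abs(singleWormArea(am) - truthMean) / truthMean, 0.10)
  expect_gt(singleWormLength(am), 0)
  expect_lt(minObjectArea(am), singleWormArea(am))
})

test_that("worm counts round the area ratio and clamp debris to one", {
  am <- new("AreaModel", singleWormAreaPx = 100, singleWormLengthPx = 100,
            singleWormWidthPx = 10, minObjectAreaPx = 20)
  mk <- function(area) new("WormComponent", componentId = 1L,
    pixels = rectPixels(1:10, seq_len(area / 10)), areaPx = as.integer(area),
    boundary = matrix(0L, 0L, 2L), estimatedWormCount = 1L,
    meanDarkness = 0.5, lowConfidence = FALSE)
  expect_equal(as.integer(countWorms(mk(100), am)), 1L)
  expect_equal(as.integer(countWorms(mk(210), am)), 2L)
  n <- countWorms(mk(40), am)
  expect_equal(as.integer(n), 1L)
  expect_true(attr(n, "lowConfidence"))
  comps <- assignWormCounts(list(mk(210), mk(40)), am)
  expect_equal(vapply(comps, estimatedWormCount, 0L), c(2L, 1L))
  expect_equal(vapply(comps, function(x) x@lowConfidence, NA), c(FALSE, TRUE))
})

test_that("debris blobs below the size filter are removed from the mask", {
  spec <- sceneSpec(imageHeightPx = 560L, imageWidthPx = 560L, nWorms = 12L,
                    seed = 55L, debrisCount = 4L)
  sc <- renderScene(spec)
  mask <- maskWorms(sc$brightfield)
  comps <- extractComponents(mask, sc$brightfield)
  # only worm-scale components survive
  expect_length(comps, 12L)
  expect_true(all(vapply(comps, function(x) x@areaPx, 0L) > 300))
})
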