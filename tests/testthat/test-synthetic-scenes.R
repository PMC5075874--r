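# The synthetic scene generator: worm shapes, cluster geometry, rendering
# invariants, and the assay time lapse.

test_that("a straight 100x10 worm has the area of a rod with tapered caps", {
  set.seed(1)
  for (i in 1:3) {
    sh <- generateWormShape(100, 10, curvatureAmplitude = 0)
    expect_gte(nrow(sh$pixels), 850)
    expect_lte(nrow(sh$pixels), 1150)
  }
})

test_that("worm shapes are one connected component for any seed", {
  set.seed(7)
  for (i in 1:5) {
    sh <- generateWormShape(80 + 10 * i, 8, curvatureAmplitude = 0.9)
    m <- nemasurv:::pxToMask(sh$pixels, sh$dim)
    expect_equal(max(nemasurv:::label8(m)), 1L)
  }
})

test_that("curved worm area matches length x width x taper by pixel count", {
  set.seed(3)
  for (i in 1:4) {
    sh <- generateWormShape(120, 8, curvatureAmplitude = 0.8)
    ratio <- nrow(sh$pixels) / (120 * 8)
    expect_gte(ratio, 0.85)
    expect_lte(ratio, 1.15)
  }
})

test_that("shape generation rejects invalid geometry", {
  expect_error(generateWormShape(30, 10), "5")
  expect_error(generateWormShape(100, 10, curvatureAmplitude = 2), "1.3")
})

test_that("an empty scene is background, pillars and noise only", {
  spec <- sceneSpec(imageHeightPx = 200L, imageWidthPx = 200L, nWorms = 0L,
                    seed = 5L)
  sc <- renderScene(spec)
  expect_true(all(labelImage(sc$truth) == 0L))
  expect_equal(nrow(wormTable(sc$truth)), 0L)
  d <- frameDarkness(sc$brightfield)
  expect_lt(max(d), 0.5)  # nothing darker than a pillar plus noise
})

test_that("rendering is deterministic for an identical SceneSpec", {
  spec <- sceneSpec(imageHeightPx = 300L, imageWidthPx = 300L, nWorms = 4L,
                    seed = 21L)
  a <- renderScene(spec)
  b <- renderScene(spec)
  expect_identical(framePixels(a$brightfield), framePixels(b$brightfield))
  expect_identical(framePixels(a$fluorescence), framePixels(b$fluorescence))
  expect_identical(labelImage(a$truth), labelImage(b$truth))
})

test_that("label image pixel count equals the sum of per-worm areas", {
  spec <- sceneSpec(imageHeightPx = 420L, imageWidthPx = 420L, nWorms = 6L,
                    clusterPlan = makeClusterPlan(2, "side_touch"),
                    seed = 13L, debrisCount = 3L)
  sc <- renderScene(spec)
  expect_equal(sum(labelImage(sc$truth) > 0L),
               sum(wormTable(sc$truth)$area_px))
})

test_that("clustered worms touch and separate groups never overlap", {
  spec <- sceneSpec(imageHeightPx = 500L, imageWidthPx = 520L, nWorms = 6L,
                    clusterPlan = makeClusterPlan(c(2L, 2L),
                      c("side_touch", "end_touch")), seed = 42L)
  sc <- renderScene(spec)
  lab <- labelImage(sc$truth)
  dims <- dim(lab)
  # cluster mates share a boundary-adjacent pixel pair
  for (pair in list(1:2, 3:4)) {
    a <- lab == pair[1L]; b <- lab == pair[2L]
    expect_false(any(a & b))                          # never overlap
    expect_true(any(nemasurv:::adjacentTo8(a, b)))    # but touch
  }
  # the two unclustered worms touch nothing
  for (w in 5:6) {
    self <- lab == w
    others <- lab > 0L & !self
    expect_false(any(nemasurv:::adjacentTo8(self, others)))
  }
  # a side-touching pair is one connected component with two labels
  um <- lab %in% 1:2
  expect_equal(max(nemasurv:::label8(matrix(um, dims[1L], dims[2L]))), 1L)
})

test_that("thresholding a noiseless scene at the midpoint recovers live worms", {
  spec <- sceneSpec(imageHeightPx = 420L, imageWidthPx = 420L, nWorms = 5L,
                    seed = 8L, noiseSd = 0)
  sc <- renderScene(spec)
  d <- frameDarkness(sc$brightfield)
  mid <- (spec@backgroundLevel + spec@aliveDarkness) / 2
  wormPx <- labelImage(sc$truth) > 0L
  expect_gte(mean(d[wormPx] > mid), 0.99)
})

test_that("dead worms darken toward background along the decay curve", {
  spec <- sceneSpec(imageHeightPx = 300L, imageWidthPx = 300L, nWorms = 2L,
                    seed = 31L, noiseSd = 0)
  state <- list(alive = c(TRUE, FALSE), hoursSinceDeath = c(0, 6),
                shiftPx = matrix(0L, 2L, 2L))
  sc <- renderScene(spec, state = state)
  d <- frameDarkness(sc$brightfield)
  lab <- labelImage(sc$truth)
  expect_gt(mean(d[lab == 1L]), 0.6)             # alive: near aliveDarkness
  expect_lt(mean(d[lab == 2L]), mean(d[lab == 1L]))
  expect_lt(mean(d[lab == 2L]), 0.15)            # 6 h post mortem: faint
  # the default decay curve is monotone non-increasing
  dt <- seq(0, 10, by = 0.5)
  expect_true(all(diff(defaultDeadDarknessCurve(dt, 0.6)) <= 0))
})

test_that("time lapse: viability flags flip at the death hour and dead worms stop", {
  spec <- sceneSpec(imageHeightPx = 300L, imageWidthPx = 300L, nWorms = 3L,
                    seed = 77L, noiseSd = 0)
  tl <- generateAssayTimelapse(spec, deathTimes = c(Inf, 10, Inf),
                               durationH = 12, frameIntervalH = 1)
  expect_equal(tl$times, 0:12)
  aliveMat <- t(vapply(tl$frames,
    function(fr) wormTable(fr$truth0)$alive, logical(3L)))
  expect_true(all(aliveMat[, 1L]))
  expect_true(all(aliveMat[, 3L]))
  expect_equal(unname(aliveMat[, 2L]), c(rep(TRUE, 10), rep(FALSE, 3)))
  # every frame keeps the full worm census (worms cannot leave)
  for (fr in tl$frames)
    expect_equal(nrow(wormTable(fr$truth0)), 3L)
})

test_that("zero-speed worms give identical pair frames at worm pixels", {
  spec <- sceneSpec(imageHeightPx = 300L, imageWidthPx = 300L, nWorms = 3L,
                    seed = 19L, noiseSd = 0)
  tl <- generateAssayTimelapse(spec, deathTimes = Inf, durationH = 1,
                               speedsPxPerS = 0)
  fr <- tl$frames[[1L]]
  expect_identical(labelImage(fr$truth0), labelImage(fr$truth1))
})

test_that("moving worms displace between pair frames", {
  spec <- sceneSpec(imageHeightPx = 300L, imageWidthPx = 300L, nWorms = 2L,
                    seed = 19L, noiseSd = 0)
  tl <- generateAssayTimelapse(spec, deathTimes = Inf, durationH = 0,
                               speedsPxPerS = 6)
  fr <- tl$frames[[1L]]
  moved <- sum(labelImage(fr$truth0) != labelImage(fr$truth1))
  expect_gt(moved, 0)
})

test_that("SceneSpec validity enforces elongation and contrast", {
  expect_error(sceneSpec(wormWidthPx = c(30, 1)), "elongated")
  expect_error(sceneSpec(aliveDarkness = 0.05, backgroundLevel = 0.1),
               "darker")
})
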