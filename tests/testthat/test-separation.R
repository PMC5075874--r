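# The multi-worm separation cascade: body parts, junction prohibition and
# resolution, chain splitting, and the full separateComponent contract.

# deterministic fixture: a horizontal rod with a shallow-V worm touching
# its upper flank tangentially (two worms kissing side-on)
vKissScene <- function() {
  H <- 120L; W <- 160L
  stamp <- function(mask, mid, r = 5) {
    for (j in seq_len(nrow(mid))) {
      ri <- max(1L, floor(mid[j, 1] - r)):min(H, ceiling(mid[j, 1] + r))
      ci <- max(1L, floor(mid[j, 2] - r)):min(W, ceiling(mid[j, 2] + r))
      mask[ri, ci] <- mask[ri, ci] |
        outer((ri - mid[j, 1])^2, (ci - mid[j, 2])^2, "+") <= r^2
    }
    mask
  }
  s <- seq(0, 1, length.out = 241)
  midA <- cbind(rep(70, 241), 20 + s * 120)      # straight rod, length 120
  # gently bowed worm (parabolic midline, apex toward the rod)
  midB <- cbind(52 - 9 * (2 * s - 1)^2, 25 + s * 110)
  A <- stamp(matrix(FALSE, H, W), midA)
  # slide the bowed worm down until its apex just touches the rod's flank
  B <- NULL
  for (dr in 0:60) {
    cand <- stamp(matrix(FALSE, H, W), cbind(midB[, 1] + dr, midB[, 2]))
    if (any(A & cand)) break
    B <- cand
  }
  list(A = A, B = B, union = A | B)
}

areaModel100 <- function() {
  new("AreaModel", singleWormAreaPx = 1100, singleWormLengthPx = 110,
      singleWormWidthPx = 10, minObjectAreaPx = 200)
}

componentFromMask <- function(mask, darkness = 0.7, areaModel = NULL) {
  f <- frameFromDarkness(ifelse(mask, darkness, 0.1))
  comps <- extractComponents(
    maskWorms(f, method = "fixed", fixedThreshold = 0.4), f)
  stopifnot(length(comps) == 1L)
  if (!is.null(areaModel)) comps <- assignWormCounts(comps, areaModel)
  comps[[1L]]
}

test_that("a tangential side contact decomposes into parts joined at junctions", {
  sc <- vKissScene()
  cp <- componentFromMask(sc$union, areaModel = areaModel100())
  expect_equal(estimatedWormCount(cp), 2L)
  d <- extractBodyParts(cp, areaModel100())
  big <- Filter(function(p) p$lengthPx >= 10, d$parts)
  expect_gte(length(big), 4L)           # both halves of both worms
  withEp <- Filter(function(j) NROW(j$endpoints) >= 2L, d$junctions)
  expect_gte(length(withEp), 1L)        # the contact produced junction(s)
  # every attached endpoint belongs to a known part
  for (jn in withEp)
    expect_true(all(jn$endpoints$part %in% seq_along(d$parts)))
})

test_that("sharp-turn prohibition is symmetric and both worms are recovered", {
  sc <- vKissScene()
  am <- areaModel100()
  cp <- componentFromMask(sc$union, areaModel = am)
  d <- extractBodyParts(cp, am)
  bnd <- componentBoundary(cp)
  tp <- computeTurnAngles(bnd, 5L, 70)
  expect_gt(sum(tp$sharp), 0)           # the contact notches are sharp
  d <- prohibitPairings(d, bnd, tp)
  proh <- do.call(rbind, lapply(d$junctions, function(j) j$prohibited))
  expect_gt(NROW(proh), 0L)
  # symmetry: (a,b) prohibited iff (b,a) prohibited, per junction
  for (jn in d$junctions) {
    if (is.null(jn$prohibited)) next
    key <- paste(jn$prohibited[, 1L], jn$prohibited[, 2L])
    rev <- paste(jn$prohibited[, 2L], jn$prohibited[, 1L])
    expect_setequal(key, rev)
  }
  d <- resolveJunctions(d)
  expect_gte(sum(vapply(d$junctions, function(j) NROW(j$matches), 0L)), 1L)
  res <- separateComponent(cp, am)
  # each true worm is recovered almost exactly by one output instance
  for (truth in list(sc$A, sc$B)) {
    truthPx <- which(truth)
    best <- max(vapply(res$instances, function(inst) {
      ipx <- nemasurv:::pxIndex(instancePixels(inst), dim(truth))
      length(intersect(ipx, truthPx)) / length(union(ipx, truthPx))
    }, 0))
    expect_gte(best, 0.9)
  }
})

test_that("a junction with no sharp turns prohibits nothing", {
  sc <- vKissScene()
  cp <- componentFromMask(sc$union, areaModel = areaModel100())
  d <- extractBodyParts(cp, areaModel100())
  bnd <- componentBoundary(cp)
  tp <- computeTurnAngles(bnd, 5L, 70)
  tp$sharp[] <- FALSE  # silence every flag
  d <- prohibitPairings(d, bnd, tp)
  for (jn in d$junctions) expect_null(jn$prohibited)
})

test_that("an isolated worm passes through separation untouched", {
  set.seed(4)
  sh <- generateWormShape(100, 10, 0.6)
  mask <- nemasurv:::pxToMask(sh$pixels, sh$dim)
  cp <- componentFromMask(mask)
  res <- separateComponent(cp, areaModel100())
  expect_length(res$instances, 1L)
  expect_equal(instanceConfidence(res$instances[[1L]]), "isolated")
  expect_equal(
    nemasurv:::pxIndex(instancePixels(res$instances[[1L]]), sh$dim),
    nemasurv:::pxIndex(componentPixels(cp), sh$dim))
})

test_that("splitChains cuts by the length ruler into equal medial pieces", {
  am <- areaModel100()
  straight <- cbind(rep(5, 111), seq(0, 110, by = 1))  # length 110 = 1 ruler
  expect_length(splitChains(straight, am), 1L)
  long <- cbind(rep(5, 232), seq(0, 231, by = 1))      # 2.1 rulers
  pieces <- splitChains(long, am)
  expect_length(pieces, 2L)
  lens <- vapply(pieces, nemasurv:::polylineLength, 0)
  expect_lt(abs(lens[1L] - lens[2L]), 3)               # cut at the midpoint
})

test_that("an end-to-end pair splits near the true contact point", {
  am <- calibratedAreaModel()
  hits <- 0L; tries <- 0L
  for (seed in c(301, 302, 304)) {
    spec <- sceneSpec(imageHeightPx = 560L, imageWidthPx = 560L, nWorms = 2L,
                      clusterPlan = makeClusterPlan(2L, "end_touch"),
                      seed = seed)
    sc <- renderScene(spec)
    mask <- maskWorms(sc$brightfield)
    comps <- assignWormCounts(extractComponents(mask, sc$brightfield), am)
    lab <- labelImage(sc$truth)
    multi <- Filter(function(cp) estimatedWormCount(cp) > 1L, comps)
    if (!length(multi)) next
    res <- separateComponent(multi[[1L]], am)
    if (length(res$instances) != 2L) next
    tries <- tries + 1L
    ious <- vapply(1:2, function(w) {
      truthPx <- which(lab == w)
      max(vapply(res$instances, function(inst) {
        ipx <- nemasurv:::pxIndex(instancePixels(inst), dim(lab))
        length(intersect(ipx, truthPx)) / length(union(ipx, truthPx))
      }, 0))
    }, 0)
    if (all(ious >= 0.7)) hits <- hits + 1L
  }
  expect_gte(tries, 2L)
  expect_gte(hits, tries - 1L)
})

test_that("instances are disjoint, contained, and conserve counts when resolved", {
  am <- calibratedAreaModel()
  checked <- 0L
  conserved <- 0L
  resolvedChecked <- 0L
  for (seed in 401:412) {
    out <- clusterRecovery(seed, am)
    if (!out$generated) next
    for (cp in out$components) {
      res <- separateComponent(cp, am)
      allPx <- lapply(res$instances, function(i)
        nemasurv:::pxIndex(instancePixels(i), c(560L, 560L)))
      # pairwise disjoint
      expect_equal(anyDuplicated(unlist(allPx)), 0L)
      # contained in the component
      cpPx <- nemasurv:::pxIndex(componentPixels(cp), c(560L, 560L))
      expect_true(all(unlist(allPx) %in% cpPx))
      checked <- checked + 1L
      if (res$resolvedAll) {
        resolvedChecked <- resolvedChecked + 1L
        if (length(res$instances) == estimatedWormCount(cp))
          conserved <- conserved + 1L
      }
    }
  }
  expect_gt(checked, 10L)
  expect_gt(resolvedChecked, 0L)
  # a component only reports full resolution when the counts agree
  expect_equal(conserved, resolvedChecked)
})

test_that("a dense eight-worm clump is flagged rather than silently resolved", {
  am <- calibratedAreaModel()
  set.seed(50)
  spec <- sceneSpec(imageHeightPx = 640L, imageWidthPx = 640L, nWorms = 8L,
                    clusterPlan = makeClusterPlan(8L, "side_touch"),
                    seed = 50L)
  sc <- renderScene(spec)
  mask <- maskWorms(sc$brightfield)
  comps <- assignWormCounts(extractComponents(mask, sc$brightfield), am)
  big <- comps[[which.max(vapply(comps, function(x) x@areaPx, 0L))]]
  res <- separateComponent(big, am)
  lab <- labelImage(sc$truth)
  rec <- sum(vapply(1:8, function(w) {
    truthPx <- which(lab == w)
    best <- max(vapply(res$instances, function(inst) {
      ipx <- nemasurv:::pxIndex(instancePixels(inst), dim(lab))
      length(intersect(ipx, truthPx)) / length(union(ipx, truthPx))
    }, 0))
    best >= 0.7
  }, NA))
  # the dense clump defeats full resolution and says so
  expect_false(res$resolvedAll)
  expect_lt(rec / 8, 1)
})
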