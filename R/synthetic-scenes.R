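# Ground-truthed synthetic chamber scenes: dark curved worms on a light
# background with a hexagonal pillar lattice, touching-worm clusters built by
# sliding worms together until their silhouettes meet (never overlap: the
# chamber height forbids crossing), post-mortem opacity decay, and per-worm
# fluorescence deposition.

#' Default post-mortem darkness decay
#'
#' Darkness excess (over background) of a cadaver as a function of hours
#' since death: an immediate drop to 40% of the live excess as the gut
#' granules disperse, then exponential decay with a 1 h half-life, leaving
#' only a faint trace of the cuticle (~1.5% of the live excess) by 4 h.
#'
#' @param hoursSinceDeath non-negative hours.
#' @param aliveExcess live-worm darkness minus background darkness.
#' @return darkness excess of the cadaver.
#' @export
defaultDeadDarknessCurve <- function(hoursSinceDeath, aliveExcess) {
  aliveExcess * 0.4 * 2^(-hoursSinceDeath)
}

#' Construct a SceneSpec
#'
#' Defaults emulate one 2.5x bright-field field of view of a microfluidic
#' chamber: ~100 x 10 px worms of darkness 0.7 on a 0.1-darkness background,
#' a hexagonal lattice of slightly dark pillar disks, and mild additive
#' noise. See the package vignette for the reasoning behind each default.
#'
#' @param imageHeightPx,imageWidthPx scene size in pixels.
#' @param nWorms number of worms.
#' @param wormLengthPx,wormWidthPx `c(mean, sd)` of worm midline length and
#'   body width, pixels.
#' @param clusterPlan list of cluster descriptors `list(worms =, contact =)`;
#'   see [makeClusterPlan()].
#' @param aliveDarkness mean darkness of live worm pixels.
#' @param deadDarknessCurve function(hoursSinceDeath, aliveExcess).
#' @param backgroundLevel background darkness.
#' @param pillarSpec `list(pitch, radius, darkness)` or `list()` for none.
#' @param noiseSd additive Gaussian noise sd (darkness scale).
#' @param fluorPerWorm per-worm total fluorescence, recycled to `nWorms`.
#' @param debrisCount number of small progeny/debris blobs.
#' @param seed integer RNG seed.
#' @return a [SceneSpec-class] object.
#' @export
sceneSpec <- function(imageHeightPx = 600L, imageWidthPx = 600L, nWorms = 10L,
                      wormLengthPx = c(100, 15), wormWidthPx = c(10, 2),
                      clusterPlan = list(), aliveDarkness = 0.7,
                      deadDarknessCurve = defaultDeadDarknessCurve,
                      backgroundLevel = 0.1,
                      pillarSpec = list(pitch = 45, radius = 5, darkness = 0.25),
                      noiseSd = 0.02, fluorPerWorm = 200, debrisCount = 0L,
                      seed = 1L) {
  new("SceneSpec",
    imageHeightPx = as.integer(imageHeightPx),
    imageWidthPx = as.integer(imageWidthPx),
    nWorms = as.integer(nWorms),
    wormLengthPx = as.numeric(wormLengthPx),
    wormWidthPx = as.numeric(wormWidthPx),
    clusterPlan = clusterPlan,
    aliveDarkness = aliveDarkness,
    deadDarknessCurve = deadDarknessCurve,
    backgroundLevel = backgroundLevel,
    pillarSpec = pillarSpec,
    noiseSd = noiseSd,
    fluorPerWorm = as.numeric(fluorPerWorm),
    debrisCount = as.integer(debrisCount),
    seed = as.integer(seed)
  )
}

#' Build a cluster plan
#'
#' Assigns the first `sum(sizes)` worms of a scene to touching clusters.
#'
#' @param sizes integer vector of cluster sizes.
#' @param contacts contact type per cluster, recycled: `"side_touch"`,
#'   `"end_touch"` or `"mixed"`.
#' @return list of cluster descriptors for [sceneSpec()].
#' @export
makeClusterPlan <- function(sizes, contacts = "mixed") {
  contacts <- rep_len(contacts, length(sizes))
  plan <- vector("list", length(sizes))
  at <- 1L
  for (i in seq_along(sizes)) {
    plan[[i]] <- list(worms = seq.int(at, at + sizes[i] - 1L),
                      contact = contacts[i])
    at <- at + sizes[i]
  }
  plan
}

hexPillarMask <- function(dim, pillarSpec) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  if (!length(pillarSpec)) return(m)
  pitch <- pillarSpec$pitch
  r <- pillarSpec$radius
  rowstep <- pitch * sqrt(3) / 2
  rows <- seq(rowstep / 2, dim[1L], by = rowstep)
  for (i in seq_along(rows)) {
    xoff <- if (i %% 2 == 0) pitch / 2 else 0
    cols <- seq(pitch / 2 + xoff, dim[2L], by = pitch)
    for (cc in cols) {
      ri <- max(1L, floor(rows[i] - r)):min(dim[1L], ceiling(rows[i] + r))
      ci <- max(1L, floor(cc - r)):min(dim[2L], ceiling(cc + r))
      m[ri, ci] <- m[ri, ci] |
        outer((ri - rows[i])^2, (ci - cc)^2, "+") <= r^2
    }
  }
  m
}

tangentAt <- function(midline, idx, k = 8L) {
  n <- nrow(midline)
  i0 <- max(1L, idx - k); i1 <- min(n, idx + k)
  v <- midline[i1, ] - midline[i0, ]
  v / sqrt(sum(v^2))
}

# Slide shape B along unit vector u (1 px steps) until it first overlaps the
# occupied mask, then back off one step so the silhouettes touch without
# sharing pixels. Returns the placed shape or NULL.
slideUntilTouch <- function(maskA, shB, u, maxSteps = 600L) {
  dimA <- dim(maskA)
  base <- shB$pixels
  lastOk <- NULL
  for (step in 0:maxSteps) {
    dr <- round(step * u[1L]); dc <- round(step * u[2L])
    r <- base[, 1L] + dr; c <- base[, 2L] + dc
    if (min(r) < 1L || min(c) < 1L || max(r) > dimA[1L] || max(c) > dimA[2L])
      return(NULL)
    if (any(maskA[(c - 1L) * dimA[1L] + r])) {
      if (is.null(lastOk)) return(NULL)
      out <- shiftShape(shB, lastOk[1L], lastOk[2L])
      if (!masksTouch(pxToMask(out$pixels, dimA), maskA)) return(NULL)
      return(out)
    }
    lastOk <- c(dr, dc)
  }
  NULL
}

# Attach one worm to a growing cluster with the requested contact type.
attachWorm <- function(maskA, shapes, lenB, widB, type) {
  anchor <- shapes[[sample.int(length(shapes), 1L)]]
  n <- nrow(anchor$midline)
  if (type == "side_touch") {
    parallel <- runif(1) < 0.6
    idx <- max(1L, round(runif(1, 0.3, 0.7) * n))
    cpt <- anchor$midline[idx, ]
    tang <- tangentAt(anchor$midline, idx)
    sgn <- sample(c(-1, 1), 1L)
    perp <- c(-tang[2L], tang[1L]) * sgn
    if (parallel) {
      # same overall heading but an independent posture: bodies meet at
      # their convex flanks, not in full-length fusion
      shB <- generateWormShape(lenB, widB, 0.7,
        baseHeading = anchor$baseHeading + runif(1, -0.25, 0.25))
      d0 <- 35
      long <- runif(1, -0.25, 0.25) * lenB
    } else {
      shB <- generateWormShape(lenB, widB, 0.5,
        baseHeading = anchor$baseHeading + sample(c(-1, 1), 1L) * runif(1, 0.5, 1.1))
      d0 <- lenB / 2 + 20
      long <- 0
    }
    midIdx <- max(1L, round(nrow(shB$midline) / 2))
    target <- cpt + perp * d0 + tang * long
    delta <- target - shB$midline[midIdx, ]
    shB <- shiftShape(shB, delta[1L], delta[2L])
    slideUntilTouch(maskA, shB, -perp)
  } else {  # end_touch
    headEnd <- runif(1) < 0.5
    eIdx <- if (headEnd) n else 1L
    e <- anchor$midline[eIdx, ]
    te <- if (headEnd) tangentAt(anchor$midline, n) else -tangentAt(anchor$midline, 1L)
    ang <- atan2(te[1L], te[2L]) + runif(1, -0.35, 0.35)
    shB <- generateWormShape(lenB, widB, 0.6, baseHeading = ang)
    d0 <- widB + 15
    u <- c(sin(ang), cos(ang))
    target <- e + u * d0
    delta <- target - shB$midline[1L, ]
    shB <- shiftShape(shB, delta[1L], delta[2L])
    slideUntilTouch(maskA, shB, -u)
  }
}

# Build one touching cluster on a private canvas; returns shapes in
# cluster-local coordinates (cropped bounding box) or NULL on failure.
buildCluster <- function(lens, wids, contact, maxTries = 12L) {
  k <- length(lens)
  cw <- as.integer(2 * max(lens) + 320)
  for (try in seq_len(maxTries)) {
    h0 <- runif(1, 0, 2 * pi)
    sh1 <- generateWormShape(lens[1L], wids[1L], 0.7, baseHeading = h0)
    sh1$baseHeading <- h0
    mid <- c(cw / 2, cw / 2) - sh1$midline[max(1L, round(nrow(sh1$midline) / 2)), ]
    sh1 <- shiftShape(sh1, mid[1L], mid[2L])
    shapes <- list(sh1)
    occ <- pxToMask(sh1$pixels, c(cw, cw))
    ok <- TRUE
    for (j in seq_len(k - 1L)) {
      type <- switch(contact,
        mixed = sample(c("side_touch", "end_touch"), 1L),
        contact)
      placed <- NULL
      for (att in 1:8) {
        cand <- attachWorm(occ, shapes, lens[j + 1L], wids[j + 1L], type)
        if (!is.null(cand)) { placed <- cand; break }
      }
      if (is.null(placed)) { ok <- FALSE; break }
      placed$baseHeading <- if (is.null(placed$baseHeading))
        shapes[[1L]]$baseHeading else placed$baseHeading
      shapes <- c(shapes, list(placed))
      occ <- occ | pxToMask(placed$pixels, c(cw, cw))
    }
    if (!ok) next
    if (max(label8(occ)) != 1L) next  # all members must touch up
    # crop to bounding box
    allpx <- do.call(rbind, lapply(shapes, `[[`, "pixels"))
    r0 <- min(allpx[, 1L]) - 1L; c0 <- min(allpx[, 2L]) - 1L
    shapes <- lapply(shapes, shiftShape, dr = -r0, dc = -c0)
    return(list(
      shapes = shapes,
      dim = c(max(allpx[, 1L]) - r0, max(allpx[, 2L]) - c0)
    ))
  }
  NULL
}

sampleWormSizes <- function(n, lengthPx, widthPx) {
  lens <- pmin(pmax(rnorm(n, lengthPx[1L], lengthPx[2L]), 55), 170)
  wids <- pmin(pmax(rnorm(n, widthPx[1L], widthPx[2L]), 5), 16)
  wids <- pmin(wids, lens / 5.5)
  list(lens = lens, wids = wids)
}

# Lay out all worms of a scene: cluster construction, then random placement
# of clusters and singles without contact between separate groups.
planScene <- function(spec, .setSeed = TRUE) {
  if (.setSeed) set.seed(spec@seed)
  H <- spec@imageHeightPx; W <- spec@imageWidthPx
  n <- spec@nWorms
  sz <- sampleWormSizes(n, spec@wormLengthPx, spec@wormWidthPx)
  clusterId <- integer(n)
  shapes <- vector("list", n)
  occupancy <- matrix(FALSE, H, W)
  margin <- 4L
  placeGroup <- function(groupPx, groupDim, what) {
    if (groupDim[1L] + 2L * margin >= H || groupDim[2L] + 2L * margin >= W)
      stop("scene too small to place ", what)
    blocked <- dilateMask(occupancy, 2)
    for (try in 1:150) {
      r0 <- sample.int(H - groupDim[1L] - 2L * margin, 1L) + margin
      c0 <- sample.int(W - groupDim[2L] - 2L * margin, 1L) + margin
      idx <- (groupPx[, 2L] + c0 - 1L) * H + groupPx[, 1L] + r0
      if (!any(blocked[idx])) return(c(r0, c0))
    }
    stop("placement failed for ", what, " after 150 tries")
  }
  # clusters first (they need the most room)
  for (ci in seq_along(spec@clusterPlan)) {
    cl <- spec@clusterPlan[[ci]]
    idxs <- cl$worms
    if (cl$contact == "none") next
    built <- buildCluster(sz$lens[idxs], sz$wids[idxs], cl$contact)
    if (is.null(built))
      stop("could not assemble touching cluster ", ci,
           " (contact ", cl$contact, ")")
    allpx <- do.call(rbind, lapply(built$shapes, `[[`, "pixels"))
    off <- placeGroup(allpx, built$dim, paste0("cluster ", ci))
    for (j in seq_along(idxs)) {
      shapes[[idxs[j]]] <- shiftShape(built$shapes[[j]], off[1L], off[2L])
      clusterId[idxs[j]] <- ci
    }
    occupancy <- occupancy | pxToMask(
      do.call(rbind, lapply(idxs, function(i) shapes[[i]]$pixels)), c(H, W))
  }
  # then isolated worms
  for (i in seq_len(n)) {
    if (!is.null(shapes[[i]])) next
    sh <- generateWormShape(sz$lens[i], sz$wids[i], 0.7,
                            baseHeading = runif(1, 0, 2 * pi))
    off <- placeGroup(sh$pixels, sh$dim, paste0("worm ", i))
    shapes[[i]] <- shiftShape(sh, off[1L], off[2L])
    occupancy <- occupancy | pxToMask(shapes[[i]]$pixels, c(H, W))
  }
  # small debris blobs (progeny/eggs), below the size filter
  debris <- matrix(integer(), 0L, 2L)
  for (d in seq_len(spec@debrisCount)) {
    r <- runif(1, 2, 3.5)
    blob <- maskToPx(diskBrush(r) > 0)
    off <- tryCatch(placeGroup(blob, c(max(blob[, 1L]), max(blob[, 2L])),
                               paste0("debris ", d)),
                    error = function(e) NULL)
    if (is.null(off)) next
    blob[, 1L] <- blob[, 1L] + off[1L]; blob[, 2L] <- blob[, 2L] + off[2L]
    debris <- rbind(debris, blob)
    occupancy <- occupancy | pxToMask(blob, c(H, W))
  }
  fl <- rep_len(spec@fluorPerWorm, max(n, 1L))[seq_len(n)]
  list(shapes = shapes, clusterId = clusterId, debris = debris,
       fluorPerWorm = fl, dim = c(H, W))
}

defaultSceneState <- function(n) {
  list(alive = rep(TRUE, n), hoursSinceDeath = rep(0, n),
       shiftPx = matrix(0L, n, 2L))
}

#' Render a synthetic chamber scene
#'
#' Draws the bright-field and fluorescence frames of a scene and returns
#' them together with exact ground truth. Rendering is deterministic for a
#' given spec (the spec's seed drives layout and noise).
#'
#' @param spec a [SceneSpec-class].
#' @param state optional per-worm state: `list(alive, hoursSinceDeath,
#'   shiftPx)` (used by [generateAssayTimelapse()]).
#' @param plan optional precomputed layout from an earlier render (internal).
#' @param timeH,pairIndex,chamber metadata stamped on the returned frames.
#' @return `list(brightfield, fluorescence, truth)`: two [WormFrame-class]
#'   objects and a [SceneTruth-class].
#' @export
renderScene <- function(spec, state = NULL, plan = NULL, timeH = 0,
                        pairIndex = 0L, chamber = "sim") {
  if (is.null(plan)) plan <- planScene(spec)
  n <- spec@nWorms
  if (is.null(state)) state <- defaultSceneState(n)
  H <- plan$dim[1L]; W <- plan$dim[2L]
  dark <- matrix(spec@backgroundLevel, H, W)
  pil <- hexPillarMask(c(H, W), spec@pillarSpec)
  if (length(spec@pillarSpec)) dark[pil] <- spec@pillarSpec$darkness
  lab <- matrix(0L, H, W)
  fluor <- matrix(0.05, H, W)
  excess <- spec@aliveDarkness - spec@backgroundLevel
  # apply pair displacements, falling back to smaller shifts on collision;
  # base footprints of worms not yet placed stay reserved so no worm can
  # displace into another's fallback position
  px <- vector("list", n)
  occ <- matrix(FALSE, H, W)
  baseCount <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    idx <- pxIndex(plan$shapes[[i]]$pixels, c(H, W))
    baseCount[idx] <- baseCount[idx] + 1L
  }
  for (i in seq_len(n)) {
    base <- plan$shapes[[i]]$pixels
    bidx <- pxIndex(base, c(H, W))
    baseCount[bidx] <- baseCount[bidx] - 1L  # release own reservation
    shift <- state$shiftPx[i, ]
    placed <- base
    for (fac in c(1, 0.5, 0)) {
      p <- base
      p[, 1L] <- p[, 1L] + as.integer(round(shift[1L] * fac))
      p[, 2L] <- p[, 2L] + as.integer(round(shift[2L] * fac))
      if (min(p) < 1L || max(p[, 1L]) > H || max(p[, 2L]) > W) next
      pidx <- pxIndex(p, c(H, W))
      if (any(occ[pidx]) || any(baseCount[pidx] > 0L)) next
      placed <- p
      break
    }
    px[[i]] <- placed
    occ[pxIndex(placed, c(H, W))] <- TRUE
  }
  wormFl <- numeric(n)
  for (i in seq_len(n)) {
    idx <- pxIndex(px[[i]], c(H, W))
    d <- if (state$alive[i]) spec@aliveDarkness else
      spec@backgroundLevel + spec@deadDarknessCurve(state$hoursSinceDeath[i], excess)
    dark[idx] <- d
    lab[idx] <- i
    perPx <- plan$fluorPerWorm[i] / length(idx)
    fluor[idx] <- fluor[idx] + perPx
    wormFl[i] <- perPx * length(idx)
  }
  if (nrow(plan$debris)) {
    dark[pxIndex(plan$debris, c(H, W))] <- spec@aliveDarkness
  }
  if (spec@noiseSd > 0) {
    dark <- dark + matrix(rnorm(H * W, 0, spec@noiseSd), H, W)
    fluor <- fluor + matrix(rnorm(H * W, 0, spec@noiseSd), H, W)
  }
  dark <- pmin(pmax(dark, 0), 1)
  fluor <- pmin(pmax(fluor, 0), 1)
  worms <- data.frame(
    worm_id = seq_len(n),
    length_px = vapply(seq_len(n),
      function(i) polylineLength(plan$shapes[[i]]$midline), 0),
    area_px = vapply(px, NROW, 0L),
    alive = state$alive,
    fluorescence_total = wormFl,
    cluster_id = plan$clusterId
  )
  mids <- lapply(seq_len(n), function(i) {
    m <- plan$shapes[[i]]$midline
    m[, 1L] <- m[, 1L] + (px[[i]][1L, 1L] - plan$shapes[[i]]$pixels[1L, 1L])
    m[, 2L] <- m[, 2L] + (px[[i]][1L, 2L] - plan$shapes[[i]]$pixels[1L, 2L])
    m
  })
  truth <- new("SceneTruth", labelImage = lab, worms = worms, midlines = mids)
  bf <- new("WormFrame", pixels = 1 - dark, channel = "brightfield",
            chamberId = chamber, timeH = timeH, pairIndex = as.integer(pairIndex),
            path = "synthetic")
  fr <- new("WormFrame", pixels = fluor, channel = "fluorescence",
            chamberId = chamber, timeH = timeH, pairIndex = as.integer(pairIndex),
            path = "synthetic")
  list(brightfield = bf, fluorescence = fr, truth = truth)
}

#' Generate a synthetic hourly killing-assay time lapse
#'
#' Renders frame pairs (two bright-field frames ~1 s apart for motility, plus
#' a fluorescence frame) at each imaging time. Live worms displace between
#' the pair frames with per-worm speeds; after its death time a worm stops
#' moving and its darkness follows the spec's post-mortem decay curve.
#'
#' @param spec a [SceneSpec-class]; its seed drives all randomness.
#' @param deathTimes hours post infection at which each worm dies; `Inf` for
#'   worms that survive the assay. Recycled to `nWorms`.
#' @param frameIntervalH imaging interval, hours.
#' @param pairOffsetS offset between the two motility frames, seconds.
#' @param durationH assay duration; default covers the last death plus 4 h.
#' @param speedsPxPerS per-worm crawling speed, px/s; default drawn
#'   uniformly from \[0, 8\].
#' @param chamber chamber id stamped on the frames.
#' @return list with `times` and `frames`, a list with one entry per time
#'   point: `list(timeH, brightfield0, brightfield1, fluorescence1, truth0,
#'   truth1)`.
#' @export
generateAssayTimelapse <- function(spec, deathTimes, frameIntervalH = 1,
                                   pairOffsetS = 1.3, durationH = NULL,
                                   speedsPxPerS = NULL, chamber = "sim") {
  stopifnot(frameIntervalH > 0)
  n <- spec@nWorms
  deathTimes <- rep_len(deathTimes, n)
  if (any(deathTimes < 0)) stop("deathTimes must be >= 0 (or Inf)")
  if (is.null(durationH)) {
    fin <- deathTimes[is.finite(deathTimes)]
    durationH <- if (length(fin)) max(fin) + 4 else 12
  }
  set.seed(spec@seed)
  plan <- planScene(spec, .setSeed = FALSE)
  if (is.null(speedsPxPerS)) speedsPxPerS <- runif(n, 0, 8)
  speedsPxPerS <- rep_len(speedsPxPerS, n)
  times <- seq(0, durationH, by = frameIntervalH)
  frames <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    alive <- t < deathTimes
    hsd <- pmax(0, t - deathTimes)
    hsd[alive] <- 0
    st0 <- list(alive = alive, hoursSinceDeath = hsd,
                shiftPx = matrix(0L, n, 2L))
    ang <- runif(n, 0, 2 * pi)
    disp <- speedsPxPerS * pairOffsetS
    disp[!alive] <- 0
    st1 <- st0
    st1$shiftPx <- cbind(as.integer(round(disp * sin(ang))),
                         as.integer(round(disp * cos(ang))))
    r0 <- renderScene(spec, state = st0, plan = plan, timeH = t,
                      pairIndex = 0L, chamber = chamber)
    r1 <- renderScene(spec, state = st1, plan = plan, timeH = t,
                      pairIndex = 1L, chamber = chamber)
    frames[[k]] <- list(
      timeH = t,
      brightfield0 = r0$brightfield,
      brightfield1 = r1$brightfield,
      fluorescence1 = r1$fluorescence,
      truth0 = r0$truth,
      truth1 = r1$truth
    )
  }
  list(times = times, frames = frames)
}
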