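# Shared fixtures, all generated in code.

# a WormFrame from a darkness matrix (bright-field: intensity = 1 - darkness)
frameFromDarkness <- function(dark, channel = "brightfield", timeH = 0,
                              pairIndex = 0L, chamber = "test") {
  new("WormFrame", pixels = 1 - dark, channel = channel, chamberId = chamber,
      timeH = timeH, pairIndex = as.integer(pairIndex), path = "fixture")
}

# a WormInstance from a pixel matrix
instanceFromPixels <- function(px, id = 1L) {
  new("WormInstance", wormId = as.integer(id),
      pixels = px, componentId = 1L,
      medialPath = matrix(numeric(), 0L, 2L), lengthPx = 0,
      confidence = "isolated")
}

rectPixels <- function(rows, cols) {
  as.matrix(expand.grid(row = rows, col = cols))
}

# single-worm area model calibrated once from a 30-worm scene, shared
# across test files
calibratedAreaModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sceneSpec(imageHeightPx = 760L, imageWidthPx = 760L,
                        nWorms = 30L, seed = 999L)
      sc <- renderScene(spec)
      comps <- extractComponents(maskWorms(sc$brightfield), sc$brightfield)
      cache <<- fitAreaModel(comps)
    }
    cache
  }
})

# one random 2-5 worm touching cluster; returns recovered/total at the
# given IoU threshold plus diagnostics
clusterRecovery <- function(seed, areaModel, iouMin = 0.7) {
  set.seed(seed)
  k <- sample(2:5, 1)
  contact <- sample(c("side_touch", "end_touch", "mixed"), 1)
  spec <- sceneSpec(imageHeightPx = 560L, imageWidthPx = 560L, nWorms = k,
                    clusterPlan = list(list(worms = seq_len(k),
                                            contact = contact)),
                    seed = seed)
  sc <- tryCatch(renderScene(spec), error = function(e) NULL)
  if (is.null(sc))
    return(list(recovered = 0L, total = 0L, generated = FALSE))
  mask <- maskWorms(sc$brightfield)
  comps <- assignWormCounts(extractComponents(mask, sc$brightfield),
                            areaModel)
  lab <- labelImage(sc$truth)
  instances <- list()
  allResolved <- TRUE
  for (cp in comps) {
    out <- separateComponent(cp, areaModel)
    instances <- c(instances, out$instances)
    allResolved <- allResolved && out$resolvedAll
  }
  recovered <- 0L
  for (w in seq_len(k)) {
    truthPx <- which(lab == w)
    best <- 0
    for (inst in instances) {
      ipx <- nemasurv:::pxIndex(instancePixels(inst), dim(lab))
      iou <- length(intersect(ipx, truthPx)) / length(union(ipx, truthPx))
      best <- max(best, iou)
    }
    if (best >= iouMin) recovered <- recovered + 1L
  }
  list(recovered = recovered, total = k, generated = TRUE,
       instances = instances, components = comps,
       allResolved = allResolved, truth = sc$truth)
}
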