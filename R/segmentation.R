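# Worm-pixel masking, connected components, and the single-worm area model.

#' Mask worm-associated pixels in a frame
#'
#' Worms are much darker than background in bright-field frames (and
#' brighter in fluorescence frames), so worm pixels are found by comparing
#' each pixel's signal (darkness for bright-field, intensity for
#' fluorescence) against a background estimate. The default `"local"` method
#' estimates background with a large-window median filter (window well above
#' the worm width, so pillar shading and slow illumination gradients are
#' absorbed into the background), then keeps pixels exceeding background by
#' `max(kSigma * sigma_bg, contrastFloor)`, where `sigma_bg` is a robust
#' (MAD) noise estimate of the background residual. Holes are filled (the
#' gut interior can be brighter than the cuticle) and objects below the
#' debris cutoff are dropped.
#'
#' @param frame a [WormFrame-class].
#' @param method `"local"` (median-filter background), `"otsu"`, or
#'   `"fixed"`.
#' @param kSigma noise multiple for the local threshold (default 3).
#' @param contrastFloor minimum signal excess over background (default 0.2);
#'   keeps faint structures such as pillar disks out of the mask when the
#'   noise level is very low.
#' @param bgRadius median-filter radius in px; default 31 (about 3 worm
#'   widths at 2.5x scale).
#' @param fixedThreshold scalar threshold for `method = "fixed"`.
#' @param minObjectAreaPx debris cutoff; if `NULL`, bootstrapped as 0.2x the
#'   median first-pass component area.
#' @param fillHoles fill enclosed holes before component extraction.
#' @return logical matrix the shape of the frame, with attributes
#'   `method` and `threshold` (the spatial threshold actually applied).
#' @export
maskWorms <- function(frame, method = c("local", "otsu", "fixed"),
                      kSigma = 3, contrastFloor = 0.2, bgRadius = 31L,
                      fixedThreshold = NULL, minObjectAreaPx = NULL,
                      fillHoles = TRUE) {
  method <- match.arg(method)
  sig <- if (frameChannel(frame) == "brightfield") frameDarkness(frame)
         else framePixels(frame)
  if (method == "local") {
    bg <- EBImage::medianFilter(sig, bgRadius)
    resid <- sig - bg
    sigma <- stats::mad(resid)
    lift <- max(kSigma * sigma, contrastFloor)
    mask <- resid > lift
    thr <- bg + lift
  } else if (method == "otsu") {
    thr <- EBImage::otsu(sig)
    mask <- sig > thr
  } else {
    if (is.null(fixedThreshold))
      stop("method 'fixed' requires fixedThreshold")
    thr <- fixedThreshold
    mask <- sig > thr
  }
  if (fillHoles) mask <- EBImage::fillHull(mask * 1) > 0.5
  lab <- label8(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    if (is.null(minObjectAreaPx)) {
      # drop noise specks before bootstrapping the debris cutoff from the
      # first-pass median component area
      real <- areas[areas >= 9]
      cutoff <- if (length(real)) max(9, 0.2 * median(real)) else 9
    } else {
      cutoff <- minObjectAreaPx
    }
    drop <- which(areas < cutoff)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  attr(mask, "method") <- method
  attr(mask, "threshold") <- thr
  mask
}

#' Extract connected worm components from a mask
#'
#' Labels the mask with 8-connectivity; each component corresponds to a worm
#' or to several touching worms. Components carry their area, ordered outer
#' boundary contour and mean darkness in the source frame.
#'
#' @param mask logical matrix from [maskWorms()].
#' @param frame the source [WormFrame-class] (for mean darkness).
#' @return list of [WormComponent-class] objects (empty for an empty mask).
#' @export
extractComponents <- function(mask, frame = NULL) {
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  sig <- if (is.null(frame)) NULL
         else if (frameChannel(frame) == "brightfield") frameDarkness(frame)
         else framePixels(frame)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    px <- maskToPx(lab == k)
    sub <- componentSubmask(px)
    bnd <- traceBoundary(sub$mask)
    bnd[, 1L] <- bnd[, 1L] + sub$off[1L]
    bnd[, 2L] <- bnd[, 2L] + sub$off[2L]
    md <- if (is.null(sig)) NA_real_ else mean(sig[pxIndex(px, dim(mask))])
    out[[k]] <- new("WormComponent",
      componentId = k, pixels = px, areaPx = nrow(px), boundary = bnd,
      estimatedWormCount = 1L, meanDarkness = md, lowConfidence = FALSE)
  }
  out
}

# Crop a pixel set to its padded bounding-box mask; returns mask and offset
# such that full-image coords = submask coords + off.
componentSubmask <- function(px, pad = 2L) {
  r0 <- min(px[, 1L]) - pad; c0 <- min(px[, 2L]) - pad
  nr <- max(px[, 1L]) - r0 + pad; nc <- max(px[, 2L]) - c0 + pad
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1L] - r0, px[, 2L] - c0)] <- TRUE
  list(mask = m, off = c(r0, c0), dim = c(nr, nc))
}

# Skeleton length and width of one component (in px), via thinning and the
# distance transform.
componentSkeletonStats <- function(component) {
  sub <- componentSubmask(componentPixels(component))
  sk <- thinMask(sub$mask)
  if (!any(sk)) return(list(length = 0, width = 2))
  path <- orderPathPixels(maskToPx(sk))
  dm <- EBImage::distmap(sub$mask * 1)
  # trunk width, not mean width: the taper toward the tips would bias a
  # median low, so take an upper quantile of the medial half-width
  list(length = polylineLength(path),
       width = 2 * as.numeric(quantile(dm[sk], 0.85)))
}

#' Fit the single-worm area model
#'
#' Single-worm components are the most abundant in a chamber, so the
#' single-worm area is estimated as the dominant mode of the component-area
#' distribution: a histogram with bin width 0.25x the median component area
#' is built over areas below 1.6x the median, the highest bin is taken, and
#' the estimate is the mean of the areas within that bin plus/minus one bin.
#' Components whose area is within 30% of the estimate then calibrate the
#' single-worm skeleton length and body width.
#'
#' @param components list of [WormComponent-class] objects (possibly pooled
#'   over several frames), or a bare numeric vector of component areas (then
#'   length and width are filled from a nominal 10:1 aspect ratio).
#' @param minComponents minimum number of components required (default 5).
#' @param minObjectAreaFrac debris cutoff as a fraction of the single-worm
#'   area (default 0.2).
#' @return an [AreaModel-class].
#' @export
fitAreaModel <- function(components, minComponents = 5L,
                         minObjectAreaFrac = 0.2) {
  bare <- is.numeric(components)
  areas <- if (bare) as.numeric(components)
           else vapply(components, function(x) as.numeric(x@areaPx), 0)
  if (length(areas) < minComponents)
    stop("only ", length(areas), " components observed; at least ",
         minComponents, " are needed - analyze more frames")
  est <- dominantModeArea(areas)
  # the mode locates the single-worm population; an iterated windowed mean
  # around it then estimates the mean single-worm area without the downward
  # bias a pure mode has when worm sizes vary
  for (it in 1:3) {
    win <- areas[areas >= 0.5 * est & areas <= 1.55 * est]
    if (!length(win)) break
    est <- mean(win)
  }
  nearSingle <- which(abs(areas - est) <= 0.3 * est)
  if (bare) {
    wid <- sqrt(est / 10)
    len <- 10 * wid
  } else {
    stats <- lapply(components[nearSingle], componentSkeletonStats)
    len <- mean(vapply(stats, `[[`, 0, "length"))
    wid <- median(vapply(stats, `[[`, 0, "width"))
    if (!is.finite(len) || len <= 0) len <- est / max(wid, 1)
  }
  new("AreaModel",
    singleWormAreaPx = est,
    singleWormLengthPx = len,
    singleWormWidthPx = wid,
    minObjectAreaPx = minObjectAreaFrac * est)
}

# Highest histogram bin (bin width 0.25 x median) among areas below 1.6 x
# median; returns the mean of areas within that bin +/- one bin width.
dominantModeArea <- function(areas) {
  med <- median(areas)
  bw <- 0.25 * med
  cand <- areas[areas < 1.6 * med]
  bins <- floor(cand / bw)
  tab <- table(bins)
  top <- as.numeric(names(tab)[which.max(tab)])
  lo <- (top - 1) * bw
  hi <- (top + 2) * bw
  mean(cand[cand >= lo & cand < hi])
}

#' Estimate the number of worms in a component
#'
#' The component area divided by the single-worm area, rounded to the
#' nearest integer and clamped to at least 1. Components well below one worm
#' area (surviving debris) are clamped to 1 and flagged low-confidence.
#'
#' @param component a [WormComponent-class].
#' @param areaModel an [AreaModel-class].
#' @return positive integer worm count (with attribute `lowConfidence`).
#' @export
countWorms <- function(component, areaModel) {
  ratio <- component@areaPx / singleWormArea(areaModel)
  n <- max(1L, as.integer(round(ratio)))
  attr(n, "lowConfidence") <- ratio < 0.5
  n
}

#' Fill estimated worm counts into a component list
#'
#' @param components list of [WormComponent-class].
#' @param areaModel an [AreaModel-class].
#' @return the component list with `estimatedWormCount` and `lowConfidence`
#'   slots set.
#' @export
assignWormCounts <- function(components, areaModel) {
  lapply(components, function(cp) {
    n <- countWorms(cp, areaModel)
    cp@estimatedWormCount <- as.integer(n)
    cp@lowConfidence <- attr(n, "lowConfidence")
    cp
  })
}
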