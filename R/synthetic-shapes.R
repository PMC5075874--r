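# Synthetic worm body geometry: smooth midlines swept with a tapered width
# profile, rasterized by stamping disks along the midline.

#' Generate a synthetic worm body shape
#'
#' Builds a smooth midline whose heading follows a damped sinusoid (random
#' phase; amplitude up to `curvatureAmplitude`), sweeps it with a tapered
#' width profile, and rasterizes the swept band to a pixel set. Emulates the
#' crawling postures of C. elegans between micro-pillars without any
#' biomechanical model. Shapes whose midline would self-intersect are
#' rejected and re-drawn (bounded retries).
#'
#' @param lengthPx midline length in pixels; must be at least 5x `widthPx`.
#' @param widthPx maximal body width in pixels.
#' @param curvatureAmplitude maximal heading swing of the sinusoid, radians.
#'   0 gives a straight rod. Values above ~1.3 are rejected (a worm's
#'   silhouette cannot bend back on itself over one body length).
#' @param baseHeading overall direction of the body, radians (0 = along
#'   increasing column).
#' @param shapeParams optional list(amp, phase, waves, damp) to reuse the
#'   posture of a previously generated worm (used for side-lying pairs).
#' @param maxTries retries before giving up on a non-self-intersecting shape.
#'
#' @return list with `pixels` (integer (row, col) matrix, 1-based in its own
#'   bounding box), `midline` (numeric matrix, same coordinates), `lengthPx`,
#'   `shapeParams`, and `dim` (bounding box size).
#'
#' @details Pixel area is approximately `lengthPx * widthPx * 0.95` (the
#'   taper removes a little, the rounded caps add a little back). The pixel
#'   set is one simply connected 8-component by construction (dense disk
#'   stamping along a connected midline, hull-filled).
#'
#' @export
generateWormShape <- function(lengthPx, widthPx, curvatureAmplitude = 0.6,
                              baseHeading = 0, shapeParams = NULL,
                              maxTries = 25L) {
  if (lengthPx < 5 * widthPx)
    stop("worm shapes require lengthPx >= 5 * widthPx")
  if (curvatureAmplitude < 0 || curvatureAmplitude > 1.3)
    stop("curvatureAmplitude must lie in [0, 1.3]")
  for (try in seq_len(maxTries)) {
    sp <- shapeParams
    if (is.null(sp)) {
      sp <- list(
        amp = runif(1, 0.25, 1) * curvatureAmplitude,
        phase = runif(1, 0, 2 * pi),
        waves = runif(1, 0.8, 1.6),
        damp = runif(1, 0, 0.6)
      )
      if (curvatureAmplitude == 0) sp$amp <- 0
    }
    ds <- 0.5
    s <- seq(0, lengthPx, by = ds)
    theta <- baseHeading +
      sp$amp * exp(-sp$damp * s / lengthPx) *
        sin(2 * pi * sp$waves * s / lengthPx + sp$phase)
    # midline in continuous (row, col) coordinates
    row <- cumsum(c(0, ds * sin(theta[-1])))
    col <- cumsum(c(0, ds * cos(theta[-1])))
    mid <- cbind(row, col)
    if (selfIntersects(mid, widthPx)) {
      shapeParams <- NULL  # re-draw posture
      next
    }
    out <- rasterizeWorm(mid, widthPx, lengthPx, sp)
    out$baseHeading <- baseHeading
    return(out)
  }
  stop("could not generate a non-self-intersecting worm shape in ", maxTries,
       " tries")
}

# TRUE when non-adjacent midline stretches come closer than one body width
selfIntersects <- function(mid, widthPx) {
  n <- nrow(mid)
  sub <- mid[seq(1L, n, by = 4L), , drop = FALSE]  # ~2 px spacing
  m <- nrow(sub)
  if (m < 6L) return(FALSE)
  d2 <- as.matrix(stats::dist(sub))^2
  sep <- abs(outer(seq_len(m), seq_len(m), "-"))
  any(d2[sep > ceiling(widthPx)] < widthPx^2)
}

# Tapered width profile: full width over the trunk, cosine taper to a
# rounded tip over the outer 15% of each end.
taperProfile <- function(s, lengthPx, widthPx) {
  edge <- 0.15 * lengthPx
  f <- pmin(s, lengthPx - s) / edge
  w <- widthPx * ifelse(f >= 1, 1, 0.35 + 0.65 * sin(pmin(f, 1) * pi / 2))
  pmax(w, 1.5)
}

rasterizeWorm <- function(mid, widthPx, lengthPx, shapeParams) {
  s <- seq(0, lengthPx, length.out = nrow(mid))
  rad <- taperProfile(s, lengthPx, widthPx) / 2
  pad <- ceiling(max(rad)) + 1L
  rmin <- floor(min(mid[, 1L])) - pad
  cmin <- floor(min(mid[, 2L])) - pad
  mid[, 1L] <- mid[, 1L] - rmin + 1
  mid[, 2L] <- mid[, 2L] - cmin + 1
  nr <- ceiling(max(mid[, 1L])) + pad
  nc <- ceiling(max(mid[, 2L])) + pad
  canvas <- matrix(FALSE, nr, nc)
  # stamp disks: vectorized over the local window of each sample
  for (j in seq_len(nrow(mid))) {
    r <- rad[j]
    ri <- max(1L, floor(mid[j, 1L] - r)):min(nr, ceiling(mid[j, 1L] + r))
    ci <- max(1L, floor(mid[j, 2L] - r)):min(nc, ceiling(mid[j, 2L] + r))
    dr2 <- (ri - mid[j, 1L])^2
    dc2 <- (ci - mid[j, 2L])^2
    canvas[ri, ci] <- canvas[ri, ci] | outer(dr2, dc2, "+") <= r^2
  }
  canvas <- EBImage::fillHull(canvas * 1) > 0.5
  list(
    pixels = maskToPx(canvas),
    midline = mid,
    lengthPx = lengthPx,
    shapeParams = shapeParams,
    dim = c(nr, nc)
  )
}

# Translate a shape's pixel/midline coordinates by (dr, dc).
shiftShape <- function(shape, dr, dc) {
  shape$pixels[, 1L] <- shape$pixels[, 1L] + as.integer(round(dr))
  shape$pixels[, 2L] <- shape$pixels[, 2L] + as.integer(round(dc))
  shape$midline[, 1L] <- shape$midline[, 1L] + dr
  shape$midline[, 2L] <- shape$midline[, 2L] + dc
  shape
}
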