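#' @import methods
#' @importFrom stats median sd quantile rnorm runif rexp setNames ks.test isoreg ecdf
#' @importFrom utils write.csv read.csv head tail
NULL

#' WormFrame: one grayscale microscopy frame with acquisition metadata
#'
#' The unit of ingestion for the analysis pipeline: a single normalized
#' grayscale image together with the metadata needed to place it in a
#' time-lapse killing assay (chamber, channel, hours post infection, and the
#' index within the ~1 s motility frame pair).
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\] (rows x cols).
#' @slot channel character, `"brightfield"` or `"fluorescence"`.
#' @slot chamberId character chamber identifier.
#' @slot timeH numeric, hours post infection (>= 0).
#' @slot pairIndex integer, 0 or 1: position within the motility frame pair.
#' @slot path character source identifier (file path or `"synthetic"`).
#'
#' @export
setClass("WormFrame",
  representation(
    pixels = "matrix",
    channel = "character",
    chamberId = "character",
    timeH = "numeric",
    pairIndex = "integer",
    path = "character"
  ),
  prototype(
    channel = "brightfield", chamberId = "chamber", timeH = 0,
    pairIndex = 0L, path = "synthetic"
  )
)

setValidity("WormFrame", function(object) {
  msg <- character()
  px <- object@pixels
  if (length(px) == 0L || nrow(px) < 1L || ncol(px) < 1L)
    msg <- c(msg, "pixels must be a nonempty matrix")
  if (length(px) > 0 && (anyNA(px) || min(px) < 0 || max(px) > 1))
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (!object@channel %in% c("brightfield", "fluorescence"))
    msg <- c(msg, "channel must be 'brightfield' or 'fluorescence'")
  if (length(object@timeH) != 1L || object@timeH < 0)
    msg <- c(msg, "timeH must be a single non-negative number")
  if (!object@pairIndex %in% c(0L, 1L))
    msg <- c(msg, "pairIndex must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' SceneSpec: parameters of a synthetic chamber scene
#'
#' Describes one synthetic microfluidic-chamber image: geometry of the worm
#' population, contrast model (darkness = 1 - intensity, so "darker" is
#' larger), pillar lattice, noise, and per-worm fluorescence. The generator's
#' defaults emulate a 2.5x bright-field view of a chamber: dark curved worms
#' (~100 x 10 px) on a light background with slightly dark pillar disks.
#'
#' @slot imageHeightPx,imageWidthPx positive integers.
#' @slot nWorms non-negative integer.
#' @slot wormLengthPx,wormWidthPx numeric length-2 `c(mean, sd)` in pixels.
#' @slot clusterPlan list of cluster descriptors, each a list with `worms`
#'   (integer indices) and `contact` (one of `"none"`, `"side_touch"`,
#'   `"end_touch"`, `"mixed"`).
#' @slot aliveDarkness mean darkness of live worm pixels, in \[0, 1\].
#' @slot deadDarknessCurve function(hoursSinceDeath, aliveExcess) returning
#'   the darkness excess over background of a cadaver.
#' @slot backgroundLevel background darkness in \[0, 1\].
#' @slot pillarSpec list with `pitch`, `radius`, `darkness`, or empty list
#'   for no pillars.
#' @slot noiseSd additive Gaussian noise sd on the darkness scale.
#' @slot fluorPerWorm numeric vector of per-worm total fluorescence
#'   (recycled to nWorms).
#' @slot debrisCount integer, number of small debris blobs (< 20% of a
#'   single-worm area) to scatter, emulating progeny/eggs.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SceneSpec",
  representation(
    imageHeightPx = "integer",
    imageWidthPx = "integer",
    nWorms = "integer",
    wormLengthPx = "numeric",
    wormWidthPx = "numeric",
    clusterPlan = "list",
    aliveDarkness = "numeric",
    deadDarknessCurve = "function",
    backgroundLevel = "numeric",
    pillarSpec = "list",
    noiseSd = "numeric",
    fluorPerWorm = "numeric",
    debrisCount = "integer",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@imageHeightPx < 1L || object@imageWidthPx < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@nWorms < 0L) msg <- c(msg, "nWorms must be non-negative")
  if (length(object@wormLengthPx) != 2L || length(object@wormWidthPx) != 2L)
    msg <- c(msg, "wormLengthPx and wormWidthPx must be c(mean, sd)")
  else if (object@wormWidthPx[1] >= object@wormLengthPx[1] / 5)
    msg <- c(msg, "worms must be elongated: mean width < mean length / 5")
  if (object@aliveDarkness <= object@backgroundLevel)
    msg <- c(msg, "aliveDarkness must exceed backgroundLevel (worms darker than background)")
  if (object@aliveDarkness > 1 || object@backgroundLevel < 0)
    msg <- c(msg, "darkness levels must lie in [0, 1]")
  for (cl in object@clusterPlan) {
    if (!is.list(cl) || is.null(cl$worms) || is.null(cl$contact) ||
        !cl$contact %in% c("none", "side_touch", "end_touch", "mixed"))
      msg <- c(msg, "each cluster descriptor needs $worms and $contact in {none, side_touch, end_touch, mixed}")
  }
  if (length(msg)) msg else TRUE
})

#' SceneTruth: exact ground truth for a synthetic scene
#'
#' @slot labelImage integer matrix; 0 = background, k = pixels of worm k.
#' @slot worms data.frame with one row per worm: `worm_id`, `length_px`,
#'   `area_px`, `alive`, `fluorescence_total`, `cluster_id` (0 = unclustered).
#' @slot midlines list of per-worm midline polylines (n x 2 matrices,
#'   (row, col)).
#'
#' @export
setClass("SceneTruth",
  representation(labelImage = "matrix", worms = "data.frame", midlines = "list")
)

setValidity("SceneTruth", function(object) {
  msg <- character()
  nlab <- sum(object@labelImage > 0L)
  if (nrow(object@worms) > 0 && nlab != sum(object@worms$area_px))
    msg <- c(msg, "label image pixel count must equal the sum of per-worm areas")
  if (length(msg)) msg else TRUE
})

#' AreaModel: single-worm size calibration
#'
#' Size reference fitted from the distribution of connected-component areas:
#' the dominant mode of that distribution is the single-worm area (single-worm
#' components being the most abundant in a chamber), and components near the
#' mode calibrate the single-worm skeleton length and body width.
#'
#' @slot singleWormAreaPx positive numeric, area of one worm in pixels.
#' @slot singleWormLengthPx positive numeric, skeleton length of one worm.
#' @slot singleWormWidthPx positive numeric, body width (2x distance
#'   transform at the skeleton).
#' @slot minObjectAreaPx debris cutoff: components below this are dropped.
#'
#' @export
setClass("AreaModel",
  representation(
    singleWormAreaPx = "numeric",
    singleWormLengthPx = "numeric",
    singleWormWidthPx = "numeric",
    minObjectAreaPx = "numeric"
  )
)

setValidity("AreaModel", function(object) {
  msg <- character()
  if (object@singleWormAreaPx <= 0) msg <- c(msg, "singleWormAreaPx must be positive")
  if (object@singleWormLengthPx <= 0) msg <- c(msg, "singleWormLengthPx must be positive")
  if (object@minObjectAreaPx >= object@singleWormAreaPx)
    msg <- c(msg, "minObjectAreaPx must be below singleWormAreaPx")
  if (length(msg)) msg else TRUE
})

#' WormComponent: a connected set of worm pixels
#'
#' One 8-connected component of the worm mask — a single worm or several
#' touching worms — with its ordered boundary contour and the worm count
#' estimated from the area model.
#'
#' @slot componentId integer.
#' @slot pixels integer matrix (n x 2), 1-based (row, col) pixel coordinates.
#' @slot areaPx integer pixel count.
#' @slot boundary integer matrix (m x 2): closed, ordered outer contour.
#' @slot estimatedWormCount positive integer.
#' @slot meanDarkness numeric in \[0, 1\].
#' @slot lowConfidence logical: TRUE when the count came from clamping a
#'   sub-worm-sized component to 1.
#'
#' @export
setClass("WormComponent",
  representation(
    componentId = "integer",
    pixels = "matrix",
    areaPx = "integer",
    boundary = "matrix",
    estimatedWormCount = "integer",
    meanDarkness = "numeric",
    lowConfidence = "logical"
  ),
  prototype(estimatedWormCount = 1L, lowConfidence = FALSE)
)

setValidity("WormComponent", function(object) {
  msg <- character()
  if (object@areaPx != nrow(object@pixels))
    msg <- c(msg, "areaPx must equal nrow(pixels)")
  if (object@estimatedWormCount < 1L)
    msg <- c(msg, "estimatedWormCount must be >= 1")
  if (length(msg)) msg else TRUE
})

#' WormInstance: one individual worm within a frame
#'
#' @slot wormId integer, per-frame identifier.
#' @slot pixels integer matrix (n x 2) of (row, col) coordinates.
#' @slot componentId integer, the parent component.
#' @slot medialPath numeric matrix (m x 2), the assembled medial path.
#' @slot lengthPx numeric medial length.
#' @slot confidence character, one of `"isolated"`, `"resolved"`,
#'   `"chain_split"`, `"unresolved"`.
#'
#' @export
setClass("WormInstance",
  representation(
    wormId = "integer",
    pixels = "matrix",
    componentId = "integer",
    medialPath = "matrix",
    lengthPx = "numeric",
    confidence = "character"
  )
)

setValidity("WormInstance", function(object) {
  if (!object@confidence %in% c("isolated", "resolved", "chain_split", "unresolved"))
    "confidence must be one of isolated/resolved/chain_split/unresolved"
  else TRUE
})

#' SurvivalCurve: a survival probability time course
#'
#' @slot timeH numeric time grid, hours.
#' @slot surv survival probability S(t) in \[0, 1\], non-increasing.
#' @slot se standard error per point (binomial for chamber assays,
#'   Greenwood for Kaplan-Meier).
#' @slot nAtRisk numeric, subjects at risk at each point.
#' @slot method `"empirical_chip"` or `"kaplan_meier"`.
#'
#' @export
setClass("SurvivalCurve",
  representation(
    timeH = "numeric",
    surv = "numeric",
    se = "numeric",
    nAtRisk = "numeric",
    method = "character"
  )
)

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  n <- length(object@timeH)
  if (length(object@surv) != n || length(object@se) != n || length(object@nAtRisk) != n)
    msg <- c(msg, "timeH, surv, se, nAtRisk must have equal length")
  if (n > 0) {
    if (min(object@surv) < -1e-12 || max(object@surv) > 1 + 1e-12)
      msg <- c(msg, "surv must lie in [0, 1]")
    if (any(diff(object@surv) > 1e-9))
      msg <- c(msg, "surv must be non-increasing")
    if (any(object@se < 0)) msg <- c(msg, "se must be non-negative")
  }
  if (!object@method %in% c("empirical_chip", "kaplan_meier"))
    msg <- c(msg, "method must be 'empirical_chip' or 'kaplan_meier'")
  if (length(msg)) msg else TRUE
})
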