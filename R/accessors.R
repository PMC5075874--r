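# Accessors and show() methods for the core S4 classes.

#' @rdname WormFrame-class
#' @param object a WormFrame
#' @export
setGeneric("framePixels", function(object) standardGeneric("framePixels"))
#' @rdname WormFrame-class
#' @export
setMethod("framePixels", "WormFrame", function(object) object@pixels)

#' @rdname WormFrame-class
#' @export
setGeneric("frameChannel", function(object) standardGeneric("frameChannel"))
#' @rdname WormFrame-class
#' @export
setMethod("frameChannel", "WormFrame", function(object) object@channel)

#' @rdname WormFrame-class
#' @export
setGeneric("chamberId", function(object) standardGeneric("chamberId"))
#' @rdname WormFrame-class
#' @export
setMethod("chamberId", "WormFrame", function(object) object@chamberId)

#' @rdname WormFrame-class
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname WormFrame-class
#' @export
setMethod("frameTime", "WormFrame", function(object) object@timeH)

#' @rdname WormFrame-class
#' @export
setGeneric("pairIndex", function(object) standardGeneric("pairIndex"))
#' @rdname WormFrame-class
#' @export
setMethod("pairIndex", "WormFrame", function(object) object@pairIndex)

#' Darkness of a frame
#'
#' Darkness is defined as `1 - intensity` throughout: worms are darker
#' (larger darkness) than background in bright-field images.
#'
#' @param object a WormFrame
#' @return numeric matrix of darkness values in \[0, 1\]
#' @export
setGeneric("frameDarkness", function(object) standardGeneric("frameDarkness"))
#' @rdname frameDarkness
#' @export
setMethod("frameDarkness", "WormFrame", function(object) 1 - object@pixels)

setMethod("show", "WormFrame", function(object) {
  cat(sprintf(
    "WormFrame %dx%d px | channel=%s chamber=%s t=%gh pair=%d\n",
    nrow(object@pixels), ncol(object@pixels), object@channel,
    object@chamberId, object@timeH, object@pairIndex
  ))
})

#' @rdname SceneTruth-class
#' @param object a SceneTruth
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))
#' @rdname SceneTruth-class
#' @export
setMethod("labelImage", "SceneTruth", function(object) object@labelImage)

#' @rdname SceneTruth-class
#' @export
setGeneric("wormTable", function(object) standardGeneric("wormTable"))
#' @rdname SceneTruth-class
#' @export
setMethod("wormTable", "SceneTruth", function(object) object@worms)

#' @rdname SceneTruth-class
#' @export
setGeneric("wormMidlines", function(object) standardGeneric("wormMidlines"))
#' @rdname SceneTruth-class
#' @export
setMethod("wormMidlines", "SceneTruth", function(object) object@midlines)

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth: %d worms, %d labeled px, %d cluster(s)\n",
    nrow(object@worms), sum(object@labelImage > 0),
    length(unique(setdiff(object@worms$cluster_id, 0L)))
  ))
})

#' @rdname AreaModel-class
#' @param object an AreaModel
#' @export
setGeneric("singleWormArea", function(object) standardGeneric("singleWormArea"))
#' @rdname AreaModel-class
#' @export
setMethod("singleWormArea", "AreaModel", function(object) object@singleWormAreaPx)

#' @rdname AreaModel-class
#' @export
setGeneric("singleWormLength", function(object) standardGeneric("singleWormLength"))
#' @rdname AreaModel-class
#' @export
setMethod("singleWormLength", "AreaModel", function(object) object@singleWormLengthPx)

#' @rdname AreaModel-class
#' @export
setGeneric("singleWormWidth", function(object) standardGeneric("singleWormWidth"))
#' @rdname AreaModel-class
#' @export
setMethod("singleWormWidth", "AreaModel", function(object) object@singleWormWidthPx)

#' @rdname AreaModel-class
#' @export
setGeneric("minObjectArea", function(object) standardGeneric("minObjectArea"))
#' @rdname AreaModel-class
#' @export
setMethod("minObjectArea", "AreaModel", function(object) object@minObjectAreaPx)

setMethod("show", "AreaModel", function(object) {
  cat(sprintf(
    "AreaModel: single worm %.0f px^2, length %.0f px, width %.1f px (debris cutoff %.0f px^2)\n",
    object@singleWormAreaPx, object@singleWormLengthPx,
    object@singleWormWidthPx, object@minObjectAreaPx
  ))
})

#' @rdname WormComponent-class
#' @param object a WormComponent
#' @export
setGeneric("componentPixels", function(object) standardGeneric("componentPixels"))
#' @rdname WormComponent-class
#' @export
setMethod("componentPixels", "WormComponent", function(object) object@pixels)

#' @rdname WormComponent-class
#' @export
setGeneric("componentBoundary", function(object) standardGeneric("componentBoundary"))
#' @rdname WormComponent-class
#' @export
setMethod("componentBoundary", "WormComponent", function(object) object@boundary)

#' @rdname WormComponent-class
#' @export
setGeneric("estimatedWormCount", function(object) standardGeneric("estimatedWormCount"))
#' @rdname WormComponent-class
#' @export
setMethod("estimatedWormCount", "WormComponent", function(object) object@estimatedWormCount)

setMethod("show", "WormComponent", function(object) {
  cat(sprintf(
    "WormComponent #%d: %d px, ~%d worm(s), mean darkness %.2f\n",
    object@componentId, object@areaPx, object@estimatedWormCount,
    object@meanDarkness
  ))
})

#' @rdname WormInstance-class
#' @param object a WormInstance
#' @export
setGeneric("instancePixels", function(object) standardGeneric("instancePixels"))
#' @rdname WormInstance-class
#' @export
setMethod("instancePixels", "WormInstance", function(object) object@pixels)

#' @rdname WormInstance-class
#' @export
setGeneric("instanceConfidence", function(object) standardGeneric("instanceConfidence"))
#' @rdname WormInstance-class
#' @export
setMethod("instanceConfidence", "WormInstance", function(object) object@confidence)

setMethod("show", "WormInstance", function(object) {
  cat(sprintf(
    "WormInstance #%d: %d px, length %.0f px, %s\n",
    object@wormId, nrow(object@pixels), object@lengthPx, object@confidence
  ))
})

#' @rdname SurvivalCurve-class
#' @param object a SurvivalCurve
#' @export
setGeneric("survTime", function(object) standardGeneric("survTime"))
#' @rdname SurvivalCurve-class
#' @export
setMethod("survTime", "SurvivalCurve", function(object) object@timeH)

#' @rdname SurvivalCurve-class
#' @export
setGeneric("survProb", function(object) standardGeneric("survProb"))
#' @rdname SurvivalCurve-class
#' @export
setMethod("survProb", "SurvivalCurve", function(object) object@surv)

#' @rdname SurvivalCurve-class
#' @export
setGeneric("survSE", function(object) standardGeneric("survSE"))
#' @rdname SurvivalCurve-class
#' @export
setMethod("survSE", "SurvivalCurve", function(object) object@se)

#' @rdname SurvivalCurve-class
#' @export
setGeneric("survNAtRisk", function(object) standardGeneric("survNAtRisk"))
#' @rdname SurvivalCurve-class
#' @export
setMethod("survNAtRisk", "SurvivalCurve", function(object) object@nAtRisk)

#' @rdname SurvivalCurve-class
#' @export
setGeneric("survMethod", function(object) standardGeneric("survMethod"))
#' @rdname SurvivalCurve-class
#' @export
setMethod("survMethod", "SurvivalCurve", function(object) object@method)

#' Convert a SurvivalCurve to a data.frame
#'
#' @param x a SurvivalCurve
#' @param row.names,optional,... passed for generic compatibility, unused
#' @return data.frame with columns t, S, SE, n_at_risk
#' @export
as.data.frame.SurvivalCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(t = x@timeH, S = x@surv, SE = x@se, n_at_risk = x@nAtRisk)
}

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf(
    "SurvivalCurve (%s): %d time points over [%g, %g] h, final S = %.3f\n",
    object@method, length(object@timeH),
    if (length(object@timeH)) min(object@timeH) else NA,
    if (length(object@timeH)) max(object@timeH) else NA,
    if (length(object@surv)) tail(object@surv, 1) else NA
  ))
})
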