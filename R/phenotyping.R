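# Per-worm viability classification and quantitative phenotypes:
# opacity, fluorescence, motility, and time-of-death estimation.

#' Classify a worm as dead or alive from its bright-field opacity
#'
#' A worm's opacity is its mean darkness; live worms are opaque (dark gut
#' granules), while cadavers degrade within hours to a faint trace. In the
#' default adaptive mode the threshold is the mean darkness of a ring-shaped
#' neighborhood around the worm (excluding all worm pixels) plus the
#' standard deviation of the darkness of the whole frame, optionally scaled
#' by `sdMultiplier`. A fixed scalar threshold is available behind
#' `mode = "fixed"`. The choice of threshold is deliberately uncritical: the
#' post-mortem opacity drop is rapid, so shifting the threshold moves the
#' estimated time of death by little.
#'
#' @param instance a [WormInstance-class].
#' @param frame the bright-field [WormFrame-class].
#' @param wormMask logical matrix marking all worm pixels in the frame (so
#'   neighboring worms do not contaminate the background ring); defaults to
#'   just the instance's own pixels.
#' @param mode `"adaptive"` (neighborhood mean + frame sd) or `"fixed"`.
#' @param fixedThreshold darkness threshold for `mode = "fixed"`.
#' @param sdMultiplier scales the sd term of the adaptive threshold
#'   (default 1). Sensible values lie in \[0.75, 2\]: below that the
#'   threshold approaches the residual darkness of a cadaver a couple of
#'   hours post mortem (death calls drift beyond the assay's 1 h
#'   resolution), above it the live-worm opacity itself.
#' @param referenceSd optional fixed darkness standard deviation to use for
#'   the sd term instead of this frame's own sd. Passing the sd of the
#'   assay's first frame keeps the threshold fixed over the whole assay
#'   (the per-frame sd collapses as the cohort dies and fades, which would
#'   drag the threshold down late in the assay); the pipeline does this by
#'   default (`viability$sd_scope = "assay"`).
#' @param ringWidthPx width of the neighborhood ring; default one worm
#'   width (10 px nominal).
#' @return list with `viability` (`"alive"`/`"dead"`), `opacity`,
#'   `threshold`, and `fallback` (TRUE when the ring was fully occupied by
#'   other worms and the frame background mean was used instead).
#'
#' @details Boundary convention: a worm exactly at threshold is dead
#'   (opacity <= threshold), making the dead set closed.
#' @export
classifyViability <- function(instance, frame, wormMask = NULL,
                              mode = c("adaptive", "fixed"),
                              fixedThreshold = NULL, sdMultiplier = 1,
                              referenceSd = NULL, ringWidthPx = 10L) {
  mode <- match.arg(mode)
  dark <- frameDarkness(frame)
  dims <- dim(dark)
  px <- instancePixels(instance)
  idx <- pxIndex(px, dims)
  opacity <- mean(dark[idx])
  fallback <- FALSE
  if (mode == "fixed") {
    if (is.null(fixedThreshold)) stop("mode 'fixed' requires fixedThreshold")
    thr <- fixedThreshold
  } else {
    if (is.null(wormMask)) wormMask <- pxToMask(px, dims)
    self <- pxToMask(px, dims)
    ring <- dilateMask(self, ringWidthPx) & !wormMask
    if (!any(ring)) {
      fallback <- TRUE
      bg <- dark[!wormMask]
      ringMean <- if (length(bg)) mean(bg) else 0
    } else {
      ringMean <- mean(dark[ring])
    }
    sdTerm <- if (is.null(referenceSd)) sd(dark) else referenceSd
    thr <- ringMean + sdMultiplier * sdTerm
  }
  list(
    viability = if (opacity > thr) "alive" else "dead",
    opacity = opacity,
    threshold = thr,
    fallback = fallback
  )
}

#' Estimate time of death from a viability time series
#'
#' The time of death is the first observation at which the worm is dead and
#' stays dead for every later observation (persistence rule). A worm that is
#' alive at the last observation never died (`Inf`). A dead call followed by
#' re-emergence (alive again) is a segmentation anomaly: it is logged and
#' the time is taken from the last alive-to-dead transition.
#'
#' @param timesH numeric observation times, hours.
#' @param viability character vector (`"alive"`/`"dead"`) or logical
#'   (TRUE = alive), same length.
#' @return time of death in hours (`Inf` if never), with attribute
#'   `anomaly` = TRUE when re-emergence was seen.
#' @export
estimateTimeOfDeath <- function(timesH, viability) {
  if (length(timesH) < 2L) stop("need at least 2 time points")
  if (length(timesH) != length(viability))
    stop("timesH and viability lengths differ")
  o <- order(timesH)
  timesH <- timesH[o]
  alive <- if (is.logical(viability)) viability[o]
           else viability[o] == "alive"
  n <- length(alive)
  anomaly <- any(diff(alive) > 0)  # dead -> alive re-emergence
  if (alive[n]) {
    out <- Inf
  } else {
    # last alive -> dead transition, persisting to the end
    i <- n
    while (i > 1L && !alive[i - 1L]) i <- i - 1L
    out <- timesH[i]
  }
  if (anomaly)
    message("viability re-emergence seen; using last alive->dead transition")
  attr(out, "anomaly") <- anomaly
  out
}

#' Total background-subtracted fluorescence of a worm
#'
#' Sums `max(0, intensity - background)` over the instance's pixels. The
#' background estimate defaults to the median intensity of all non-worm
#' pixels of the frame.
#'
#' @param instance a [WormInstance-class].
#' @param frame the fluorescence [WormFrame-class] (registered to the same
#'   grid as the bright-field frame).
#' @param wormMask logical matrix of all worm pixels (for the background
#'   estimate); defaults to the instance's pixels.
#' @param background `"median"` (default) or a numeric scalar.
#' @return total fluorescence (arbitrary units, additive over pixel sets).
#' @export
measureFluorescence <- function(instance, frame, wormMask = NULL,
                                background = "median") {
  px <- framePixels(frame)
  idx <- pxIndex(instancePixels(instance), dim(px))
  bg <- if (is.numeric(background)) {
    background
  } else {
    if (is.null(wormMask)) wormMask <- pxToMask(instancePixels(instance), dim(px))
    median(px[!wormMask])
  }
  sum(pmax(0, px[idx] - bg))
}

#' Motility as the newly covered pixel fraction
#'
#' Two bright-field frames are taken about a second apart; a worm's motility
#' is the fraction of its pixels in the later frame that were not covered by
#' worm pixels in the earlier frame. A still worm scores 0, a worm that
#' moved entirely clear of its previous silhouette scores 1.
#'
#' @param instance a [WormInstance-class] segmented in the later frame.
#' @param earlierMask logical worm mask of the earlier frame (computed with
#'   the same masking parameters), or `NULL` if the earlier frame is
#'   missing.
#' @return fraction in \[0, 1\], or `NA_real_` when `earlierMask` is `NULL`.
#' @export
measureMotility <- function(instance, earlierMask) {
  if (is.null(earlierMask)) return(NA_real_)
  idx <- pxIndex(instancePixels(instance), dim(earlierMask))
  mean(!earlierMask[idx])
}

#' Population summaries of per-worm measurements
#'
#' For each time point and each quantity (fluorescence, opacity, motility)
#' computes the empirical CDF over worms, the mean and standard deviation,
#' and two-sample Kolmogorov-Smirnov comparisons between all pairs of time
#' points. Population inhomogeneity that the mean hides (broadening,
#' bimodality) shows in the CDFs and in the KS statistics.
#'
#' @param measurements data.frame with columns `time_h`, `worm_id` and the
#'   measured quantities (see [measureWorms()]).
#' @param quantities character vector of measurement columns to summarize.
#' @param minN time points with fewer worms than this are flagged low-n
#'   (default 3).
#' @return list with `stats` (data.frame: time_h, quantity, n, mean, sd,
#'   low_n), `cdfs` (nested list of `ecdf` functions by quantity and time)
#'   and `ks` (data.frame of pairwise KS statistics and p-values per
#'   quantity).
#' @export
populationSummaries <- function(measurements,
                                quantities = c("fluorescence_total",
                                               "opacity", "motility"),
                                minN = 3L) {
  stopifnot(nrow(measurements) > 0L)
  quantities <- intersect(quantities, names(measurements))
  times <- sort(unique(measurements$time_h))
  statRows <- list()
  cdfs <- list()
  ksRows <- list()
  for (q in quantities) {
    cdfs[[q]] <- list()
    vals <- list()
    for (t in times) {
      v <- measurements[[q]][measurements$time_h == t]
      v <- v[is.finite(v)]
      vals[[as.character(t)]] <- v
      cdfs[[q]][[as.character(t)]] <- if (length(v)) ecdf(v) else NULL
      statRows[[length(statRows) + 1L]] <- data.frame(
        time_h = t, quantity = q, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else NA_real_,
        low_n = length(v) < minN)
    }
    for (i in seq_along(times)) {
      for (j in seq_along(times)) {
        if (j <= i) next
        vi <- vals[[as.character(times[i])]]
        vj <- vals[[as.character(times[j])]]
        if (length(vi) < 1L || length(vj) < 1L) next
        kt <- suppressWarnings(ks.test(vi, vj))
        ksRows[[length(ksRows) + 1L]] <- data.frame(
          quantity = q, time_a = times[i], time_b = times[j],
          statistic = unname(kt$statistic), p_value = kt$p.value)
      }
    }
  }
  list(
    stats = do.call(rbind, statRows),
    cdfs = cdfs,
    ks = if (length(ksRows)) do.call(rbind, ksRows) else
      data.frame(quantity = character(), time_a = numeric(),
                 time_b = numeric(), statistic = numeric(),
                 p_value = numeric())
  )
}

#' Measure all worm instances of one frame pair
#'
#' Convenience wrapper producing one measurement row per worm: area,
#' opacity and viability from the bright-field frame, total fluorescence
#' from the fluorescence frame (if given), and motility against the earlier
#' pair frame's worm mask (if given).
#'
#' @param instances list of [WormInstance-class].
#' @param brightfield bright-field [WormFrame-class].
#' @param fluorescence optional fluorescence [WormFrame-class].
#' @param earlierMask optional worm mask of the earlier pair frame.
#' @param wormMask logical mask of all worm pixels in `brightfield`.
#' @param ... passed to [classifyViability()].
#' @return data.frame with one row per worm: chamber_id, time_h, worm_id,
#'   area_px, fluorescence_total, opacity, motility, viability, confidence.
#' @export
measureWorms <- function(instances, brightfield, fluorescence = NULL,
                         earlierMask = NULL, wormMask = NULL, ...) {
  if (is.null(wormMask) && length(instances)) {
    allpx <- do.call(rbind, lapply(instances, instancePixels))
    wormMask <- pxToMask(allpx, dim(framePixels(brightfield)))
  }
  rows <- lapply(instances, function(inst) {
    vit <- classifyViability(inst, brightfield, wormMask = wormMask, ...)
    data.frame(
      chamber_id = chamberId(brightfield),
      time_h = frameTime(brightfield),
      worm_id = inst@wormId,
      area_px = nrow(instancePixels(inst)),
      fluorescence_total = if (is.null(fluorescence)) NA_real_ else
        measureFluorescence(inst, fluorescence, wormMask = wormMask),
      opacity = vit$opacity,
      motility = measureMotility(inst, earlierMask),
      viability = vit$viability,
      confidence = instanceConfidence(inst)
    )
  })
  if (!length(rows))
    return(data.frame(
      chamber_id = character(), time_h = numeric(), worm_id = integer(),
      area_px = integer(), fluorescence_total = numeric(),
      opacity = numeric(), motility = numeric(), viability = character(),
      confidence = character()))
  out <- do.call(rbind, rows)
  out$worm_id <- seq_len(nrow(out))
  out
}
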