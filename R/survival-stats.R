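# Survival curves: the censoring-free chamber estimator (worms cannot
# escape a sealed chamber, so S(t) is a plain alive fraction) and the
# Kaplan-Meier product-limit estimator for plate-style records where lost
# worms must be censored.

#' Survival curve from per-frame alive counts (chamber assay)
#'
#' In a sealed microfluidic chamber no worm is ever lost, so the survival
#' probability is simply `alive(t) / initialN` — no censoring, no
#' product-limit machinery. Standard errors are binomial,
#' `sqrt(S (1-S) / n)` (Greenwood's formula reduces to this without
#' censoring). Segmentation jitter can make raw alive counts rise between
#' frames; a pool-adjacent-violators (isotonic) correction restores
#' monotonicity and is logged.
#'
#' @param timesH frame times, hours.
#' @param aliveCounts alive worms per frame.
#' @param initialN number of worms loaded; defaults to the first count.
#' @return a [SurvivalCurve-class] with `method = "empirical_chip"`.
#' @export
chipSurvival <- function(timesH, aliveCounts, initialN = NULL) {
  stopifnot(length(timesH) == length(aliveCounts), length(timesH) >= 1L)
  o <- order(timesH)
  timesH <- timesH[o]
  counts <- as.numeric(aliveCounts[o])
  if (is.null(initialN)) initialN <- counts[1L]
  stopifnot(initialN >= 1)
  if (any(diff(counts) > 0)) {
    message("alive counts increase between frames; applying isotonic correction")
    counts <- round(-isoreg(timesH, -counts)$yf)
  }
  s <- pmin(1, pmax(0, counts / initialN))
  se <- sqrt(s * (1 - s) / initialN)
  new("SurvivalCurve", timeH = timesH, surv = s, se = se,
      nAtRisk = rep(initialN, length(s)), method = "empirical_chip")
}

#' Kaplan-Meier survival curve from event records
#'
#' Product-limit estimator for plate-style records where escaped or
#' otherwise lost worms leave the risk set without counting as deaths:
#' S(t) is the product over death times up to t of (1 - deaths/at-risk),
#' with Greenwood standard errors. Subjects alive when the assay stops are
#' censored at the final observation time.
#'
#' @param records data.frame with columns `subject_id`, `event_time_h`, and
#'   `status` in `c("died", "censored", "alive_at_end")` (`"lost"` is
#'   accepted as a synonym for `"censored"`).
#' @return a [SurvivalCurve-class] with `method = "kaplan_meier"`; the time
#'   grid holds t = 0 plus every distinct event time.
#' @export
kaplanMeier <- function(records) {
  stopifnot(nrow(records) >= 1L)
  status <- as.character(records$status)
  status[status == "lost"] <- "censored"
  bad <- setdiff(unique(status), c("died", "censored", "alive_at_end"))
  if (length(bad)) stop("unknown status values: ", paste(bad, collapse = ", "))
  if (any(records$event_time_h < 0)) stop("event_time_h must be >= 0")
  event <- as.integer(status == "died")
  if (!any(event == 1L))
    warning("all records censored; survival curve is identically 1")
  fit <- survival::survfit(
    survival::Surv(records$event_time_h, event) ~ 1, conf.type = "none")
  sm <- summary(fit)
  t <- c(0, sm$time)
  s <- c(1, sm$surv)
  se <- c(0, ifelse(is.na(sm$std.err), 0, sm$std.err))
  nr <- c(nrow(records), sm$n.risk)
  new("SurvivalCurve", timeH = t, surv = s, se = se, nAtRisk = nr,
      method = "kaplan_meier")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Step-function evaluation (right-continuous).
#'
#' @param curve a [SurvivalCurve-class].
#' @param timesH times to evaluate at.
#' @return survival probabilities.
#' @export
survivalAt <- function(curve, timesH) {
  i <- findInterval(timesH, survTime(curve))
  out <- rep(1, length(timesH))
  out[i > 0] <- survProb(curve)[i[i > 0]]
  out
}

#' Cumulative fraction of lost (censored) worms over time
#'
#' Plate assays lose worms (they crawl up the walls and desiccate); chamber
#' assays lose none, so the chip course is identically zero.
#'
#' @param records plate-style records as in [kaplanMeier()], or `NULL`.
#' @param timesH evaluation time grid; defaults to the distinct event times.
#' @param initialN denominator; defaults to `nrow(records)`.
#' @param chip when TRUE, return a zero course over `timesH` (a sealed
#'   chamber loses no worms).
#' @return data.frame with `time_h` and `lost_fraction` (non-decreasing).
#' @export
lostFractionCourse <- function(records = NULL, timesH = NULL,
                               initialN = NULL, chip = is.null(records)) {
  if (chip) {
    if (is.null(timesH)) timesH <- 0
    return(data.frame(time_h = timesH, lost_fraction = rep(0, length(timesH))))
  }
  status <- as.character(records$status)
  status[status == "lost"] <- "censored"
  if (is.null(timesH)) timesH <- sort(unique(c(0, records$event_time_h)))
  if (is.null(initialN)) initialN <- nrow(records)
  lostTimes <- records$event_time_h[status == "censored"]
  frac <- vapply(timesH, function(t) sum(lostTimes <= t) / initialN, 0)
  data.frame(time_h = timesH, lost_fraction = frac)
}

#' Compare two survival curves
#'
#' Reports the median survival time of each curve (first time S drops to
#' 0.5, linearly interpolated within the bracketing step; `Inf` when the
#' curve never reaches 0.5), their difference, pointwise differences on the
#' union time grid, and — when the underlying event records are supplied —
#' the log-rank test.
#'
#' @param curveA,curveB [SurvivalCurve-class] objects.
#' @param recordsA,recordsB optional event records (as in [kaplanMeier()])
#'   for the log-rank test.
#' @return list with `medianA`, `medianB` (hours; `Inf` = beyond the
#'   observed range), `medianDiff`, `pointwise` (data.frame time_h, sA, sB,
#'   diff), and `logrank` (list with `chisq`, `df`, `p_value`) or `NULL`.
#' @export
compareCurves <- function(curveA, curveB, recordsA = NULL, recordsB = NULL) {
  medA <- medianSurvival(curveA)
  medB <- medianSurvival(curveB)
  grid <- sort(unique(c(survTime(curveA), survTime(curveB))))
  pw <- data.frame(
    time_h = grid,
    sA = survivalAt(curveA, grid),
    sB = survivalAt(curveB, grid))
  pw$diff <- pw$sA - pw$sB
  lr <- NULL
  if (!is.null(recordsA) && !is.null(recordsB)) {
    recs <- rbind(
      data.frame(time = recordsA$event_time_h,
                 event = as.integer(as.character(recordsA$status) == "died"),
                 arm = "A"),
      data.frame(time = recordsB$event_time_h,
                 event = as.integer(as.character(recordsB$status) == "died"),
                 arm = "B"))
    sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = recs)
    lr <- list(chisq = unname(sd$chisq), df = length(sd$n) - 1L,
               p_value = stats::pchisq(sd$chisq, length(sd$n) - 1L,
                                       lower.tail = FALSE))
  }
  list(medianA = medA, medianB = medB,
       medianDiff = medA - medB, pointwise = pw, logrank = lr)
}

#' Median survival time of a curve
#'
#' @param curve a [SurvivalCurve-class].
#' @return hours; `Inf` when S never drops to 0.5 within the observed range.
#' @export
medianSurvival <- function(curve) {
  t <- survTime(curve); s <- survProb(curve)
  below <- which(s <= 0.5)
  if (!length(below)) return(Inf)
  i <- below[1L]
  if (i == 1L || s[i] == 0.5) return(t[i])
  # linear interpolation between the last point above 0.5 and this one
  t[i - 1L] + (s[i - 1L] - 0.5) / (s[i - 1L] - s[i]) * (t[i] - t[i - 1L])
}
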