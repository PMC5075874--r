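# Separation of multi-worm components into individual worms: narrow regions
# of the mask are single-worm body parts; thicker regions are worm-worm
# junctions; junctions are resolved by prohibiting part connections whose
# boundary arc turns too sharply to be one worm's silhouette; end-to-end
# chains that no junction can split are cut with the average single-worm
# length as a ruler.

#' Signed turn angles along a closed boundary contour
#'
#' At contour pixel i the turn angle is the signed angle (degrees) between
#' the chords (i-window -> i) and (i -> i+window), indices cyclic. Turns
#' sharper than `sharpTurnDeg` cannot come from the silhouette of a single
#' worm (its bending radius is bounded by body stiffness) and mark contact
#' points between worms.
#'
#' @param boundary ordered closed contour, n x 2 (row, col) matrix.
#' @param windowPx chord half-window in pixels (default 5).
#' @param sharpTurnDeg sharp-turn threshold in degrees (default 70).
#' @return list with `angleDeg` (signed, in (-180, 180]), `sharp` (logical),
#'   `windowPx`, `sharpTurnDeg`.
#' @export
computeTurnAngles <- function(boundary, windowPx = 5L, sharpTurnDeg = 70) {
  n <- nrow(boundary)
  if (n < 3L * windowPx)
    stop("contour of length ", n, " is shorter than 3x the turn window")
  idx <- seq_len(n)
  im <- ((idx - 1L - windowPx) %% n) + 1L
  ip <- ((idx - 1L + windowPx) %% n) + 1L
  v1r <- boundary[idx, 1L] - boundary[im, 1L]
  v1c <- boundary[idx, 2L] - boundary[im, 2L]
  v2r <- boundary[ip, 1L] - boundary[idx, 1L]
  v2c <- boundary[ip, 2L] - boundary[idx, 2L]
  ang <- atan2(v1c * v2r - v1r * v2c, v1r * v2r + v1c * v2c) * 180 / pi
  list(angleDeg = ang, sharp = abs(ang) > sharpTurnDeg,
       windowPx = windowPx, sharpTurnDeg = sharpTurnDeg)
}

#' Default separation configuration
#'
#' Tunables of the multi-worm separation cascade. All lengths are in pixels
#' at the nominal 2.5x scale (worm width ~10 px); see the package vignette
#' for how each default was chosen.
#'
#' @return list with:
#' \describe{
#'   \item{widthFactor}{narrowness criterion: skeleton stretches whose local
#'     half-width is at most `widthFactor` x the single-worm half-width are
#'     body parts (default 1.6, tolerating posture- and worm-to-worm width
#'     variation; contacts still register as junctions via skeleton branch
#'     points).}
#'   \item{turnWindowPx}{chord half-window of the boundary turn-angle
#'     profile (default 5).}
#'   \item{sharpTurnDeg}{turns sharper than this flag worm-worm contacts
#'     (default 70; a worm silhouette rarely exceeds ~60 degrees over a
#'     10 px chord).}
#'   \item{minPartLenPx}{skeleton fragments shorter than this are folded
#'     into junctions (default 3).}
#'   \item{spurLenPx}{free-ending skeleton spurs up to this length are
#'     pruned before part extraction (default 8).}
#'   \item{tangentKPx}{steps over which a part's endpoint tangent is
#'     averaged (default 6).}
#'   \item{minChainFrac}{assembled chains below this fraction of the
#'     single-worm length are treated as skeleton residue (default 0).}
#'   \item{rescueContinuity}{when every pairing at a junction is prohibited
#'     (crowded contacts can pollute all boundary arcs with sharp turns),
#'     pairs whose geometric continuity score exceeds this are still
#'     admitted; `NA` disables the fallback (default 0.5).}
#'   \item{tangentWeight}{weight of tangent continuity vs positional
#'     alignment in the junction matching score (default 0.3).}
#' }
#' @export
separationConfig <- function() {
  list(widthFactor = 1.6, turnWindowPx = 5L, sharpTurnDeg = 70,
       minPartLenPx = 3L, spurLenPx = 8L, tangentKPx = 6L,
       minChainFrac = 0, rescueContinuity = 0.5, tangentWeight = 0.3)
}

#' Decompose a multi-worm component into body parts and junctions
#'
#' Computes the skeleton (Zhang-Suen thinning) and distance transform of the
#' component, keeps skeleton stretches whose local width is consistent with
#' a single worm as body parts (split at skeleton branch points), and groups
#' the remaining thick/branch skeleton pixels into junctions. Each part
#' endpoint lying next to a junction is attached to it.
#'
#' @param component a [WormComponent-class].
#' @param areaModel an [AreaModel-class] (supplies the single-worm width).
#' @param config list from [separationConfig()].
#' @return list with `parts` (each: `id`, `path` ordered submask
#'   coordinates, `lengthPx`, `junction` attached per end, endpoint
#'   positions/tangents), `junctions` (each: `id`, skeleton pixels,
#'   endpoint table), plus the submask geometry used downstream.
#' @export
extractBodyParts <- function(component, areaModel, config = separationConfig()) {
  sub <- componentSubmask(componentPixels(component), pad = 2L)
  sk <- thinMask(sub$mask)
  dm <- EBImage::distmap(sub$mask * 1)
  halfw <- singleWormWidth(areaModel) / 2
  if (!any(sk)) {
    # degenerate (everything thinner than 2 px): whole component is one part
    sk <- sub$mask
  }
  sk <- pruneSpurs(sk, maxLen = config$spurLenPx)
  narrow <- sk & dm <= config$widthFactor * pmax(halfw, 1)
  branch <- sk & neighborCount8(sk) >= 3L
  partMask <- narrow & !branch
  partLab <- label8(partMask)
  nraw <- max(partLab)
  parts <- list()
  junPool <- sk & !partMask
  for (k in seq_len(nraw)) {
    px <- maskToPx(partLab == k)
    if (nrow(px) < config$minPartLenPx) {
      junPool[pxIndex(px, dim(junPool))] <- TRUE
      next
    }
    path <- orderPathPixels(px)
    parts[[length(parts) + 1L]] <- list(
      id = length(parts) + 1L, path = path, lengthPx = polylineLength(path))
  }
  junLab <- label8(junPool)
  nj <- max(junLab)
  junctions <- lapply(seq_len(nj), function(j) {
    list(id = j, skpx = maskToPx(junLab == j),
         endpoints = NULL, prohibited = NULL, matches = NULL,
         unresolved = FALSE)
  })
  # attach part endpoints to junctions within a 5x5 neighborhood
  epRows <- list()
  for (p in seq_along(parts)) {
    path <- parts[[p]]$path
    n <- nrow(path)
    for (e in 1:2) {
      pos <- if (e == 1L) path[1L, ] else path[n, ]
      tang <- pathEndTangent(path, if (e == 1L) "head" else "tail",
                             k = config$tangentKPx)
      j <- nearestJunction(pos, junLab)
      parts[[p]]$junction[e] <- j
      if (j > 0L)
        epRows[[length(epRows) + 1L]] <- data.frame(
          part = p, end = e, row = pos[1L], col = pos[2L],
          tr = tang[1L], tc = tang[2L], junction = j)
    }
  }
  ep <- if (length(epRows)) do.call(rbind, epRows) else
    data.frame(part = integer(), end = integer(), row = integer(),
               col = integer(), tr = numeric(), tc = numeric(),
               junction = integer())
  for (j in seq_len(nj))
    junctions[[j]]$endpoints <- ep[ep$junction == j, , drop = FALSE]
  list(parts = parts, junctions = junctions, sub = sub, skeleton = sk,
       distmap = dm, junLab = junLab, config = config)
}

nearestJunction <- function(pos, junLab, radius = 2L) {
  nr <- nrow(junLab); nc <- ncol(junLab)
  ri <- max(1L, pos[1L] - radius):min(nr, pos[1L] + radius)
  ci <- max(1L, pos[2L] - radius):min(nc, pos[2L] + radius)
  w <- junLab[ri, ci, drop = FALSE]
  if (!any(w > 0L)) return(0L)
  hits <- which(w > 0L, arr.ind = TRUE)
  d <- pmax(abs(ri[hits[, 1L]] - pos[1L]), abs(ci[hits[, 2L]] - pos[2L]))
  as.integer(w[hits[which.min(d), , drop = FALSE]])
}

#' Prohibit junction pairings whose boundary arc turns too sharply
#'
#' Maps every boundary pixel of the component to its nearest body part or
#' junction (geodesic assignment within the mask), reads off the boundary
#' arcs connecting consecutive part runs, and prohibits the endpoint pairing
#' across any arc that contains a sharp turn: such a turn marks a worm-worm
#' contact point, so the two flanking parts cannot belong to the same worm.
#' Prohibition is symmetric by construction.
#'
#' @param decomposition output of [extractBodyParts()].
#' @param boundary the component's ordered boundary (full-image coords).
#' @param turnProfile output of [computeTurnAngles()] on that boundary.
#' @return the decomposition with each junction's `prohibited` (2-column
#'   endpoint-pair matrix) and `arcs` filled.
#' @export
prohibitPairings <- function(decomposition, boundary, turnProfile) {
  d <- decomposition
  P <- length(d$parts)
  if (P == 0L || length(d$junctions) == 0L) return(d)
  sub <- d$sub
  seeds <- matrix(0L, sub$dim[1L], sub$dim[2L])
  for (p in seq_len(P))
    seeds[pxIndex(d$parts[[p]]$path, sub$dim)] <- p
  for (j in seq_along(d$junctions))
    seeds[pxIndex(d$junctions[[j]]$skpx, sub$dim)] <- P + j
  assign <- bfsAssign(sub$mask, seeds)
  b <- boundary
  b[, 1L] <- b[, 1L] - sub$off[1L]
  b[, 2L] <- b[, 2L] - sub$off[2L]
  keep <- b[, 1L] >= 1L & b[, 1L] <= sub$dim[1L] &
          b[, 2L] >= 1L & b[, 2L] <= sub$dim[2L]
  cs <- integer(nrow(b))
  cs[keep] <- assign[pxIndex(b[keep, , drop = FALSE], sub$dim)]
  sharp <- turnProfile$sharp
  N <- length(cs)
  # rotate so index 1 starts a run
  brk <- which(cs != c(cs[N], cs[-N]))
  if (length(brk)) {
    rot <- brk[1L] - 1L
    if (rot > 0L) {
      ord <- c((rot + 1L):N, seq_len(rot))
      cs <- cs[ord]; sharp <- sharp[ord]; b <- b[ord, , drop = FALSE]
    }
  }
  r <- rle(cs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  partRuns <- which(r$values >= 1L & r$values <= P)
  if (length(partRuns) < 2L) return(d)
  arcs <- list()
  for (m in seq_along(partRuns)) {
    cur <- partRuns[m]
    nxt <- partRuns[if (m == length(partRuns)) 1L else m + 1L]
    a <- r$values[cur]; bb <- r$values[nxt]
    if (a == bb) next
    gap <- gapIndices(ends[cur], starts[nxt], N, expand = 2L)
    jset <- setdiff(unique(cs[gap]), c(0L, seq_len(P))) - P
    sharpGap <- any(sharp[gap])
    centerIdx <- gap[ceiling(length(gap) / 2)]
    center <- b[centerIdx, ]
    if (!length(jset)) {
      ja <- d$parts[[a]]$junction; jb <- d$parts[[bb]]$junction
      jset <- intersect(ja[ja > 0L], jb[jb > 0L])
    }
    for (j in jset)
      arcs[[length(arcs) + 1L]] <- list(a = a, b = bb, junction = j,
                                        sharp = sharpGap, center = center)
  }
  for (arc in arcs) {
    j <- arc$junction
    if (j < 1L || j > length(d$junctions)) next
    epj <- d$junctions[[j]]$endpoints
    ea <- pickEndpoint(epj, arc$a, arc$center)
    eb <- pickEndpoint(epj, arc$b, arc$center)
    if (is.null(ea) || is.null(eb)) next
    d$junctions[[j]]$arcs <- c(d$junctions[[j]]$arcs,
                               list(list(ea = ea, eb = eb, sharp = arc$sharp)))
    if (arc$sharp)
      d$junctions[[j]]$prohibited <- rbind(d$junctions[[j]]$prohibited,
                                           c(ea, eb), c(eb, ea))
  }
  d
}

gapIndices <- function(from, to, N, expand = 0L) {
  from <- from - expand; to <- to + expand
  if (to >= from) span <- from:to else span <- c(from:N, 1L:to)
  ((span - 1L) %% N) + 1L
}

# endpoint row index (within the junction's endpoint table) of part `p`
# closest to a reference boundary position
pickEndpoint <- function(epj, p, center) {
  rows <- which(epj$part == p)
  if (!length(rows)) return(NULL)
  if (length(rows) == 1L) return(rows)
  dd <- (epj$row[rows] - center[1L])^2 + (epj$col[rows] - center[2L])^2
  rows[which.min(dd)]
}

#' Resolve junctions by maximum-compatibility matching
#'
#' At every junction, non-prohibited endpoint pairs are matched to maximize
#' total tangent continuity (the cosine of the angle between one part's
#' incoming medial tangent and the reversed tangent of the other, with a
#' positional alignment term that disambiguates parallel-lying worms).
#' Endpoints may stay unmatched; pairs with non-positive compatibility are
#' never forced. A junction with two or more attached endpoints where no
#' pair can be matched is flagged unresolved.
#'
#' @param decomposition output of [prohibitPairings()].
#' @return the decomposition with each junction's `matches` (endpoint-pair
#'   matrix, rows of endpoint table indices) and `unresolved` flag filled.
#' @export
resolveJunctions <- function(decomposition) {
  d <- decomposition
  for (j in seq_along(d$junctions)) {
    jn <- d$junctions[[j]]
    ep <- jn$endpoints
    k <- NROW(ep)
    if (k < 2L) next
    score <- matrix(-Inf, k, k)
    for (a in seq_len(k - 1L)) for (bb in (a + 1L):k) {
      if (ep$part[a] == ep$part[bb]) next
      if (!is.null(jn$prohibited) &&
          any(jn$prohibited[, 1L] == a & jn$prohibited[, 2L] == bb)) next
      ta <- c(ep$tr[a], ep$tc[a]); tb <- c(ep$tr[bb], ep$tc[bb])
      dv <- c(ep$row[bb] - ep$row[a], ep$col[bb] - ep$col[a])
      nd <- sqrt(sum(dv^2))
      posTerm <- if (nd < 1e-9) 1 else
        0.5 * (sum(ta * dv) / nd + sum(tb * -dv) / nd)
      tw <- if (is.null(d$config$tangentWeight)) 0.5 else d$config$tangentWeight
      s <- tw * sum(ta * -tb) + (1 - tw) * posTerm
      score[a, bb] <- score[bb, a] <- s
    }
    if (k > 10L) {  # combinatorial blow-up: give up on this junction
      d$junctions[[j]]$unresolved <- TRUE
      next
    }
    mt <- bestMatching(score)
    rescue <- d$config$rescueContinuity
    if (nrow(mt) == 0L && is.numeric(rescue) && !is.na(rescue)) {
      # over-constrained junction: crowded contacts can pollute every arc
      # with sharp turns; admit only near-straight continuations
      score2 <- matrix(-Inf, k, k)
      for (a in seq_len(k - 1L)) for (bb in (a + 1L):k) {
        if (ep$part[a] == ep$part[bb]) next
        ta <- c(ep$tr[a], ep$tc[a]); tb <- c(ep$tr[bb], ep$tc[bb])
        dv <- c(ep$row[bb] - ep$row[a], ep$col[bb] - ep$col[a])
        nd <- sqrt(sum(dv^2))
        posTerm <- if (nd < 1e-9) 1 else
          0.5 * (sum(ta * dv) / nd + sum(tb * -dv) / nd)
        s <- 0.5 * sum(ta * -tb) + 0.5 * posTerm
        if (s > rescue) score2[a, bb] <- score2[bb, a] <- s
      }
      mt <- bestMatching(score2)
    }
    d$junctions[[j]]$matches <- mt
    d$junctions[[j]]$unresolved <- (nrow(mt) == 0L)
  }
  d
}

# exhaustive maximum-weight matching over a small score matrix; pairs with
# score <= 0 are left unmatched
bestMatching <- function(score) {
  k <- nrow(score)
  best <- list(score = 0, pairs = matrix(integer(), 0L, 2L))
  recurse <- function(remaining, pairs, total) {
    if (total > best$score + 1e-12) {
      best$score <<- total
      best$pairs <<- pairs
    }
    if (length(remaining) < 2L) return()
    i <- remaining[1L]
    rest <- remaining[-1L]
    recurse(rest, pairs, total)  # leave i unmatched
    for (j in rest) {
      if (is.finite(score[i, j]) && score[i, j] > 0)
        recurse(setdiff(rest, j), rbind(pairs, c(i, j)),
                total + score[i, j])
    }
  }
  recurse(seq_len(k), best$pairs, 0)
  best$pairs
}

#' Split an assembled medial path into worms with the length ruler
#'
#' An end-to-end chain of worms yields one long medial path that no junction
#' can split; it is cut into `round(length / singleWormLength)` contiguous
#' pieces of equal medial length (clamped to at least one).
#'
#' @param path ordered medial path (n x 2 matrix).
#' @param areaModel an [AreaModel-class] (supplies the length ruler).
#' @return list of sub-paths (each an m x 2 matrix), one per worm.
#' @export
splitChains <- function(path, areaModel) {
  n <- max(1L, as.integer(round(polylineLength(path) /
                                  singleWormLength(areaModel))))
  splitPathInto(path, n)
}

# cut an ordered path into n contiguous pieces of equal medial length
splitPathInto <- function(path, n) {
  if (n <= 1L || nrow(path) < 2L * n) return(list(path))
  L <- polylineLength(path)
  steps <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  cutAt <- findInterval(steps, seq(0, L, length.out = n + 1L),
                        rightmost.closed = TRUE, all.inside = TRUE)
  lapply(seq_len(n), function(i) path[cutAt == i, , drop = FALSE])
}


#' Separate a component into individual worms
#'
#' Runs the full cascade: single-worm components pass through unchanged
#' (confidence `"isolated"`); multi-worm components are decomposed into
#' narrow body parts and junctions, junction pairings are prohibited across
#' sharp boundary turns and resolved by maximum-compatibility matching,
#' assembled chains are cut with the single-worm length ruler, and finally
#' every component pixel is assigned to the nearest worm medial path by
#' geodesic (within-mask) distance, so no pixel leaks across a worm lying in
#' between. Failures are flags, never errors.
#'
#' @param component a [WormComponent-class] with `estimatedWormCount` set
#'   (see [assignWormCounts()]).
#' @param areaModel an [AreaModel-class].
#' @param config list from [separationConfig()].
#' @return list with `instances` (list of [WormInstance-class], pixel sets
#'   pairwise disjoint and contained in the component), `resolvedAll`
#'   (logical: every junction either matched or trivially empty), and
#'   `nUnresolved` (junctions left unresolved).
#' @export
separateComponent <- function(component, areaModel, config = separationConfig()) {
  nEst <- estimatedWormCount(component)
  if (nEst <= 1L) {
    st <- componentSkeletonStats(component)
    inst <- new("WormInstance",
      wormId = 1L, pixels = componentPixels(component),
      componentId = component@componentId,
      medialPath = matrix(numeric(), 0L, 2L),
      lengthPx = st$length, confidence = "isolated")
    return(list(instances = list(inst), resolvedAll = TRUE, nUnresolved = 0L))
  }
  d <- extractBodyParts(component, areaModel, config)
  bnd <- componentBoundary(component)
  tp <- tryCatch(
    computeTurnAngles(bnd, config$turnWindowPx, config$sharpTurnDeg),
    error = function(e) NULL)
  if (!is.null(tp)) d <- prohibitPairings(d, bnd, tp)
  d <- resolveJunctions(d)
  chains <- assembleChains(d)
  unresolvedParts <- unresolvedPartSet(d)
  # a large junction that no pairing traverses can be a worm buried in the
  # clump (e.g. the middle animal of a parallel bundle): its skeleton
  # becomes a low-confidence worm candidate of its own
  for (jn in d$junctions) {
    if (!is.null(jn$matches) && nrow(jn$matches) > 0L) next
    if (nrow(jn$skpx) >= 0.5 * singleWormLength(areaModel)) {
      chains <- c(chains, list(list(path = orderPathPixels(jn$skpx),
                                    parts = integer(), rescued = TRUE)))
    }
  }
  # cut chains with the length ruler, gather final medial paths
  sub <- d$sub
  pieces <- list()
  # chains far below half a worm length are skeleton residue, not worms:
  # they are not seeded, so their pixels flow to the nearest real worm
  chLens <- vapply(chains, function(ch) polylineLength(ch$path), 0)
  keep <- chLens >= config$minChainFrac * singleWormLength(areaModel)
  if (!any(keep) && length(chains)) keep[which.max(chLens)] <- TRUE
  chains <- chains[keep]
  chLens <- chLens[keep]
  R <- singleWormLength(areaModel)
  plans <- lapply(chains, function(ch) chainCutPlan(ch$path, d$distmap, R))
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    subpaths <- applyCutPlan(ch$path, plans[[ci]])
    conf <- if (isTRUE(ch$rescued) || any(ch$parts %in% unresolvedParts))
              "unresolved"
            else if (length(subpaths) > 1L) "chain_split"
            else "resolved"
    for (sp in subpaths)
      pieces[[length(pieces) + 1L]] <- list(path = sp, confidence = conf)
  }
  if (!length(pieces))
    pieces <- list(list(path = maskToPx(d$skeleton), confidence = "unresolved"))
  seeds <- matrix(0L, sub$dim[1L], sub$dim[2L])
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]$path
    p <- p[p[, 1L] >= 1L & p[, 1L] <= sub$dim[1L] &
           p[, 2L] >= 1L & p[, 2L] <= sub$dim[2L], , drop = FALSE]
    seeds[pxIndex(round(p), sub$dim)] <- i
  }
  assign <- bfsAssign(sub$mask, seeds)
  instances <- list()
  for (i in seq_along(pieces)) {
    m <- assign == i & sub$mask
    if (!any(m)) next
    px <- maskToPx(m)
    px[, 1L] <- px[, 1L] + sub$off[1L]
    px[, 2L] <- px[, 2L] + sub$off[2L]
    mp <- pieces[[i]]$path
    mp[, 1L] <- mp[, 1L] + sub$off[1L]
    mp[, 2L] <- mp[, 2L] + sub$off[2L]
    instances[[length(instances) + 1L]] <- new("WormInstance",
      wormId = length(instances) + 1L, pixels = px,
      componentId = component@componentId, medialPath = mp,
      lengthPx = polylineLength(pieces[[i]]$path),
      confidence = pieces[[i]]$confidence)
  }
  nUn <- sum(vapply(d$junctions, function(j) isTRUE(j$unresolved), NA))
  # a component is fully resolved only when every junction was matched AND
  # the worm tally from the assembled chains agrees with the area-based
  # count: disagreement between the two independent counts marks the
  # component low-confidence even if each junction looked consistent
  list(instances = instances,
       resolvedAll = nUn == 0L && length(instances) == nEst,
       nUnresolved = nUn)
}

unresolvedPartSet <- function(d) {
  out <- integer()
  for (jn in d$junctions)
    if (isTRUE(jn$unresolved) && NROW(jn$endpoints))
      out <- c(out, jn$endpoints$part)
  unique(out)
}

# Merge matched parts into chains: endpoints matched at a junction join two
# parts; traversal starts at unmatched endpoints; cycles are broken at an
# arbitrary match edge.
assembleChains <- function(d) {
  P <- length(d$parts)
  if (P == 0L) return(list())
  # match partner per endpoint key "part.end"
  partner <- list()
  for (jn in d$junctions) {
    if (is.null(jn$matches) || nrow(jn$matches) == 0L) next
    ep <- jn$endpoints
    for (r in seq_len(nrow(jn$matches))) {
      a <- jn$matches[r, 1L]; bb <- jn$matches[r, 2L]
      ka <- paste0(ep$part[a], ".", ep$end[a])
      kb <- paste0(ep$part[bb], ".", ep$end[bb])
      partner[[ka]] <- c(ep$part[bb], ep$end[bb])
      partner[[kb]] <- c(ep$part[a], ep$end[a])
    }
  }
  visited <- logical(P)
  chains <- list()
  walk <- function(p, startEnd) {
    pathList <- list()
    partsIn <- integer()
    repeat {
      visited[p] <<- TRUE
      partsIn <- c(partsIn, p)
      pp <- d$parts[[p]]$path
      if (startEnd == 2L) pp <- pp[rev(seq_len(nrow(pp))), , drop = FALSE]
      if (length(pathList)) {
        prev <- pathList[[length(pathList)]]
        pathList[[length(pathList) + 1L]] <-
          pixelBridge(prev[nrow(prev), ], pp[1L, ])
      }
      pathList[[length(pathList) + 1L]] <- pp
      exitEnd <- if (startEnd == 1L) 2L else 1L
      nxt <- partner[[paste0(p, ".", exitEnd)]]
      if (is.null(nxt) || visited[nxt[1L]]) break
      p <- nxt[1L]; startEnd <- nxt[2L]
    }
    list(path = do.call(rbind, pathList), parts = partsIn)
  }
  # chain starts: endpoints without a partner
  for (p in seq_len(P)) {
    if (visited[p]) next
    for (e in 1:2) {
      if (is.null(partner[[paste0(p, ".", e)]])) {
        chains[[length(chains) + 1L]] <- walk(p, e)
        break
      }
    }
  }
  # remaining parts sit on cycles; break at an arbitrary edge
  for (p in seq_len(P)) {
    if (!visited[p]) chains[[length(chains) + 1L]] <- walk(p, 1L)
  }
  chains
}

# Split one assembled chain into worms. The primary count comes from the
# length ruler (round(L / R)); where the body-width profile along the chain
# shows pronounced interior dips -- the tapered tips of two worms meeting
# end to end -- the dips both refine the cut positions and can justify one
# more worm than the ruler alone would grant (worm length varies, the ruler
# is a population average).
splitChainWithDips <- function(path, dm, R) {
  applyCutPlan(path, chainCutPlan(path, dm, R))
}

# cut positions (arc-length) and worm count for one chain
chainCutPlan <- function(path, dm, R) {
  L <- polylineLength(path)
  n <- nrow(path)
  if (n < 8L) return(list(n = 1L, cuts = NULL))
  steps <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  rp <- round(path)
  rp[, 1L] <- pmin(pmax(rp[, 1L], 1L), nrow(dm))
  rp[, 2L] <- pmin(pmax(rp[, 2L], 1L), ncol(dm))
  prof <- dm[(rp[, 2L] - 1L) * nrow(dm) + rp[, 1L]]
  w <- min(9L, n - (n + 1L) %% 2L)
  sm <- stats::filter(prof, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- stats::median(prof)
  medp <- stats::median(sm)
  interior <- steps > 0.35 * R & steps < L - 0.35 * R
  low <- as.logical(sm <= 0.6 * medp) & interior
  dips <- numeric()
  r <- rle(low)
  stop_ <- cumsum(r$lengths)
  start_ <- stop_ - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    seg <- start_[i]:stop_[i]
    dips <- c(dips, steps[seg[which.min(sm[seg])]])
  }
  if (length(dips) > 1L) {
    # enforce a minimum piece length of 0.5 R between dips
    keep <- dips[1L]
    for (dd in dips[-1L]) if (dd - tail(keep, 1L) >= 0.5 * R) keep <- c(keep, dd)
    dips <- keep
  }
  nLen <- max(1L, as.integer(round(L / R)))
  nDip <- length(dips) + 1L
  if (length(dips) && nDip >= nLen && L >= 0.55 * R * nDip) {
    list(n = nDip, cuts = dips)
  } else {
    list(n = nLen, cuts = NULL)
  }
}

# split a path at planned arc-length cuts (NULL cuts: equal lengths)
applyCutPlan <- function(path, plan) {
  n <- plan$n
  if (n <= 1L || nrow(path) < 2L * n) return(list(path))
  L <- polylineLength(path)
  steps <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  cuts <- if (is.null(plan$cuts) || length(plan$cuts) != n - 1L)
    seq(0, L, length.out = n + 1L)[2:n] else plan$cuts
  grp <- findInterval(steps, c(-Inf, cuts, Inf))
  lapply(sort(unique(grp)), function(g) path[grp == g, , drop = FALSE])
}

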