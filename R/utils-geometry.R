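# Pixel-set and binary-morphology helpers shared by the generator,
# segmentation and separation code. Pixel sets are integer (row, col)
# matrices, 1-based; masks are logical matrices.

pxIndex <- function(px, dim) (px[, 2L] - 1L) * dim[1L] + px[, 1L]

pxToMask <- function(px, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  if (NROW(px)) m[pxIndex(px, dim)] <- TRUE
  m
}

maskToPx <- function(mask) {
  w <- which(mask)
  cbind(
    row = as.integer((w - 1L) %% nrow(mask) + 1L),
    col = as.integer((w - 1L) %/% nrow(mask) + 1L)
  )
}

# result[i, j] = m[i + dr, j + dc], out-of-range filled with `fill`
shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# number of TRUE 8-neighbors per pixel
neighborCount8 <- function(mask) {
  s <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + shiftMat(mask, dr, dc)
  }
  s
}

# crossing number: 0->1 transitions in the circular 8-neighbor sequence.
# 1 = line end, 2 = interior of a simple path, >= 3 = branch point. Robust
# to thinning staircase artifacts that inflate the raw neighbor count.
crossingNumber8 <- function(mask) {
  p2 <- shiftMat(mask, -1L, 0L); p3 <- shiftMat(mask, -1L, 1L)
  p4 <- shiftMat(mask, 0L, 1L);  p5 <- shiftMat(mask, 1L, 1L)
  p6 <- shiftMat(mask, 1L, 0L);  p7 <- shiftMat(mask, 1L, -1L)
  p8 <- shiftMat(mask, 0L, -1L); p9 <- shiftMat(mask, -1L, -1L)
  (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
}

# TRUE where mask has any TRUE 8-neighbor in `other`
adjacentTo8 <- function(mask, other) {
  s <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s | shiftMat(other, dr, dc)
  }
  mask & s
}

masksTouch <- function(a, b) any(adjacentTo8(a, b)) || any(a & b)

diskBrush <- function(r) {
  sz <- 2L * floor(r) + 1L
  if (sz < 3L) return(matrix(1, 1L, 1L))
  EBImage::makeBrush(sz, shape = "disc")
}

dilateMask <- function(mask, r) {
  if (r < 1) return(mask)
  EBImage::dilate(mask * 1, diskBrush(r)) > 0.5
}

# Zhang-Suen morphological thinning; returns the 1-px skeleton of a mask.
# Vectorized over whole-matrix shifts; converges in O(object width) passes.
thinMask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shiftMat(m, -1L, 0L); p3 <- shiftMat(m, -1L, 1L)
      p4 <- shiftMat(m, 0L, 1L);  p5 <- shiftMat(m, 1L, 1L)
      p6 <- shiftMat(m, 1L, 0L);  p7 <- shiftMat(m, 1L, -1L)
      p8 <- shiftMat(m, 0L, -1L); p9 <- shiftMat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m <- m & !cond
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Order the pixels of a simple (branchless) 8-connected skeleton segment
# into a path, starting from an endpoint (or an arbitrary pixel for loops).
orderPathPixels <- function(px) {
  n <- NROW(px)
  if (n <= 1L) return(px)
  key <- paste(px[, 1L], px[, 2L])
  idx <- seq_len(n)
  names(idx) <- key
  nbrs <- function(p) {
    dr <- rep(-1:1, times = 3L); dc <- rep(-1:1, each = 3L)
    k <- paste(p[1L] + dr, p[2L] + dc)
    unname(idx[k[!is.na(idx[k]) & !(dr == 0L & dc == 0L)]])
  }
  deg <- vapply(idx, function(i) length(nbrs(px[i, ])), 0L)
  start <- if (any(deg == 1L)) which(deg == 1L)[1L] else 1L
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    path[k] <- cur
    visited[cur] <- TRUE
    cand <- nbrs(px[cur, ])
    cand <- cand[!visited[cand]]
    if (!length(cand)) {
      path <- path[seq_len(k)]
      break
    }
    # prefer 4-neighbors to avoid skipping across diagonals
    d4 <- abs(px[cand, 1L] - px[cur, 1L]) + abs(px[cand, 2L] - px[cur, 2L])
    cur <- cand[order(d4)][1L]
  }
  px[path, , drop = FALSE]
}

polylineLength <- function(path) {
  if (NROW(path) < 2L) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

# Unit tangent at one end of an ordered path, averaged over up to k steps,
# pointing outward from the path (i.e. away from its interior).
pathEndTangent <- function(path, end = c("head", "tail"), k = 6L) {
  end <- match.arg(end)
  n <- NROW(path)
  if (n < 2L) return(c(0, 0))
  k <- min(k, n - 1L)
  v <- if (end == "head") path[1L, ] - path[1L + k, ] else path[n, ] - path[n - k, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(0, 0) else v / nv
}

# Straight-line pixel bridge between two points (inclusive), rounded.
pixelBridge <- function(p, q) {
  n <- max(abs(q - p)) + 1L
  if (n <= 1L) return(rbind(p))
  t <- seq(0, 1, length.out = max(2L, n))
  cbind(round(p[1L] + t * (q[1L] - p[1L])), round(p[2L] + t * (q[2L] - p[2L])))
}

# Multi-source BFS label propagation within a mask: every mask pixel gets the
# label of the nearest seed set, distance measured inside the mask (geodesic).
# seeds: integer matrix of labels aligned with mask (0 = unseeded).
bfsAssign <- function(mask, seeds) {
  lab <- seeds
  lab[!mask] <- 0L
  active <- any(lab > 0L)
  if (!active) return(lab)
  # alternate 4- then 8-neighborhood passes to approximate Euclidean growth
  offs4 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  offs8 <- c(offs4, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  repeat {
    grew <- FALSE
    for (offs in list(offs4, offs8)) {
      frontier <- matrix(0L, nrow(mask), ncol(mask))
      for (o in offs) {
        nb <- shiftMat(lab, o[1L], o[2L], fill = 0L)
        take <- mask & lab == 0L & frontier == 0L & nb > 0L
        frontier[take] <- nb[take]
      }
      if (any(frontier > 0L)) {
        lab[frontier > 0L] <- frontier[frontier > 0L]
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  lab
}

# Remove short free-ending skeleton branches (spurs): boundary bumps create
# tiny side twigs at thinning branch points that would otherwise fragment
# the medial path. Walks back from each skeleton endpoint; runs shorter than
# maxLen that terminate at a branch point are erased.
pruneSpurs <- function(sk, maxLen = 8L) {
  for (pass in 1:3) {
    nb <- neighborCount8(sk)
    endpts <- maskToPx(sk & nb == 1L)
    if (!nrow(endpts)) break
    removedAny <- FALSE
    for (i in seq_len(nrow(endpts))) {
      cur <- endpts[i, ]
      if (!sk[cur[1L], cur[2L]]) next
      trail <- matrix(cur, 1L, 2L)
      hitBranch <- FALSE
      while (nrow(trail) <= maxLen) {
        nbrs <- skNeighbors(sk, cur)
        keep <- !(paste(nbrs[, 1L], nbrs[, 2L]) %in%
                    paste(trail[, 1L], trail[, 2L]))
        nbrs <- nbrs[keep, , drop = FALSE]
        if (nrow(nbrs) == 0L) break
        if (nrow(nbrs) > 1L) { hitBranch <- TRUE; break }
        nxt <- nbrs[1L, ]
        if (nrow(skNeighbors(sk, nxt)) >= 3L) { hitBranch <- TRUE; break }
        trail <- rbind(trail, nxt)
        cur <- nxt
      }
      if (hitBranch && nrow(trail) <= maxLen) {
        sk[trail] <- FALSE
        removedAny <- TRUE
      }
    }
    if (!removedAny) break
  }
  sk
}

skNeighbors <- function(sk, p) {
  rs <- max(1L, p[1L] - 1L):min(nrow(sk), p[1L] + 1L)
  cs <- max(1L, p[2L] - 1L):min(ncol(sk), p[2L] + 1L)
  w <- which(sk[rs, cs, drop = FALSE], arr.ind = TRUE)
  out <- cbind(rs[w[, 1L]], cs[w[, 2L]])
  out[!(out[, 1L] == p[1L] & out[, 2L] == p[2L]), , drop = FALSE]
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (sh in list(c(-1L, -1L), c(-1L, 1L))) {
    b <- shiftMat(lab, sh[1L], sh[2L], fill = 0L)
    sel <- lab > 0L & b > 0L & lab != b
    if (any(sel)) {
      prs <- unique(cbind(lab[sel], b[sel]))
      for (r in seq_len(nrow(prs))) {
        ra <- findRoot(prs[r, 1L]); rb <- findRoot(prs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), findRoot, 0L)
  newid <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- newid[lab[lab > 0L]]
  out
}

# Ordered outer boundary (Moore tracing via EBImage::ocontour), 1-based.
traceBoundary <- function(mask) {
  oc <- EBImage::ocontour(mask * 1)
  if (!length(oc)) return(matrix(integer(), 0L, 2L))
  b <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1L
  colnames(b) <- c("row", "col")
  b
}
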