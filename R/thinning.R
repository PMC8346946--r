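# Internal binary morphology on logical matrices indexed [x, y].
# All functions treat out-of-canvas as background.

.shift <- function(m, dx, dy) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  xs <- seq_len(nr) - dx
  ys <- seq_len(nc) - dy
  okx <- xs >= 1L & xs <= nr
  oky <- ys >= 1L & ys <= nc
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# Dilation with a square (box) structuring element of half-width r:
# output stroke thickness 2r + 1. Separable (rows then columns) and
# confined to the foreground bounding box.
.boxDilate <- function(m, r) {
  if (r <= 0L || !any(m)) return(m)
  xr <- range(which(rowSums(m) > 0))
  yr <- range(which(colSums(m) > 0))
  xs <- max(1L, xr[1L] - r):min(nrow(m), xr[2L] + r)
  ys <- max(1L, yr[1L] - r):min(ncol(m), yr[2L] + r)
  sub <- m[xs, ys, drop = FALSE]
  acc <- sub
  for (dx in seq_len(r)) acc <- acc | .shift(sub, dx, 0L) | .shift(sub, -dx, 0L)
  sub <- acc
  for (dy in seq_len(r)) acc <- acc | .shift(sub, 0L, dy) | .shift(sub, 0L, -dy)
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[xs, ys] <- acc
  out
}

.boxErode <- function(m, r) {
  if (r <= 0L) return(m)
  out <- m
  for (dx in -r:r) {
    for (dy in -r:r) {
      if (dx == 0L && dy == 0L) next
      out <- out & .shift(m, dx, dy)
    }
  }
  out
}

# Chessboard distance to background, by iterated erosion. Cheap for the
# thin shapes this package produces; only used for diagnostics/tests.
.chessboardDistance <- function(m, max_iter = 64L) {
  d <- matrix(0L, nrow(m), ncol(m))
  cur <- m
  for (i in seq_len(max_iter)) {
    if (!any(cur)) break
    d[cur] <- d[cur] + 1L
    cur <- .boxErode(cur, 1L)
  }
  d
}

# Zhang-Suen thinning: iteratively peels the mask down to an 8-connected,
# mostly one-pixel-wide skeleton approximating the medial axis.
# Work is confined to the foreground bounding box (plus a 1-px border).
.thin <- function(m) {
  if (!any(m)) return(m)
  xr <- range(which(rowSums(m) > 0))
  yr <- range(which(colSums(m) > 0))
  xs <- max(1L, xr[1L] - 1L):min(nrow(m), xr[2L] + 1L)
  ys <- max(1L, yr[1L] - 1L):min(ncol(m), yr[2L] + 1L)
  sub <- .thinCore(m[xs, ys, drop = FALSE])
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[xs, ys] <- sub
  out
}

.thinCore <- function(m) {
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- .shift(m, 0L, -1L)  # north (y - 1)
      p3 <- .shift(m, 1L, -1L)
      p4 <- .shift(m, 1L, 0L)   # east
      p5 <- .shift(m, 1L, 1L)
      p6 <- .shift(m, 0L, 1L)   # south
      p7 <- .shift(m, -1L, 1L)
      p8 <- .shift(m, -1L, 0L)  # west
      p9 <- .shift(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Skeleton graph helpers -------------------------------------------------

.neighborCount <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  for (dx in -1:1) {
    for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      n <- n + .shift(m, dx, dy)
    }
  }
  n * m
}

# Crossing number: 0->1 transitions in the circular 8-neighborhood.
# 1 = endpoint, 2 = path pixel, >= 3 = junction. Raw neighbor counts
# misclassify diagonal contacts along thin paths; transitions do not.
.crossingNumber <- function(m) {
  p2 <- .shift(m, 0L, -1L)
  p3 <- .shift(m, 1L, -1L)
  p4 <- .shift(m, 1L, 0L)
  p5 <- .shift(m, 1L, 1L)
  p6 <- .shift(m, 0L, 1L)
  p7 <- .shift(m, -1L, 1L)
  p8 <- .shift(m, -1L, 0L)
  p9 <- .shift(m, -1L, -1L)
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  a * m
}

.OFFSETS <- cbind(
  dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
  dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
)

# Trace a branch from an endpoint until reaching a junction pixel
# (crossing number >= 3), another endpoint, or running out. Junction
# termination is checked across all neighbors of the current pixel
# before stepping, so diagonal shortcuts cannot walk past a junction.
# Returns the path (matrix of x, y; junction excluded), its Euclidean
# length, and whether it ended at a junction.
.traceBranch <- function(m, cross, x0, y0) {
  path <- matrix(c(x0, y0), 1L, 2L)
  len <- 0
  x <- x0
  y <- y0
  repeat {
    nxt <- NULL
    for (k in seq_len(nrow(.OFFSETS))) {
      nx <- x + .OFFSETS[k, 1L]
      ny <- y + .OFFSETS[k, 2L]
      if (nx < 1L || ny < 1L || nx > nrow(m) || ny > ncol(m)) next
      if (!m[nx, ny]) next
      if (any(path[, 1L] == nx & path[, 2L] == ny)) next
      step <- sqrt((nx - x)^2 + (ny - y)^2)
      if (cross[nx, ny] >= 3L) {
        return(list(path = path, length = len + step, at_junction = TRUE))
      }
      if (is.null(nxt)) nxt <- c(nx, ny)
    }
    if (is.null(nxt)) {
      return(list(path = path, length = len, at_junction = FALSE))
    }
    len <- len + sqrt(sum((nxt - c(x, y))^2))
    x <- nxt[1L]
    y <- nxt[2L]
    path <- rbind(path, nxt)
    if (cross[x, y] == 1L) {
      # reached the opposite endpoint: whole component is one open path
      return(list(path = path, length = len, at_junction = FALSE))
    }
  }
}

# Remove skeleton branches (endpoint-to-junction paths) strictly shorter
# than prune_len, iterating until stable. Whole components without a
# junction are kept regardless of length: they are genuine marks, not
# thinning artifacts.
.pruneBranches <- function(m, prune_len) {
  repeat {
    # one sweep works from a crossing-number snapshot; removals make it
    # stale only near junctions, which the next sweep revisits
    cross <- .crossingNumber(m)
    ends <- which(m & cross == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed <- FALSE
    for (i in seq_len(nrow(ends))) {
      x0 <- ends[i, 1L]
      y0 <- ends[i, 2L]
      if (!m[x0, y0]) next
      br <- .traceBranch(m, cross, x0, y0)
      if (br$at_junction && br$length < prune_len) {
        m[br$path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}
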