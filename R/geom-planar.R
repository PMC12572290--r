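# Planar polygon primitives. All functions take rings as 2-column matrices
# (x, y) in a metric frame, open (last vertex != first); orientation handled
# explicitly. These back the metric-frame geometry work: circularity,
# overlap ratios, buffering, cell coverage.

#' Signed area of a ring (shoelace)
#'
#' Positive for counter-clockwise rings.
#'
#' @param xy two-column numeric matrix of vertices (open ring).
#' @return Signed area in squared input units.
#' @keywords internal
ring_signed_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ring_area <- function(xy) abs(ring_signed_area(xy))

ring_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  d <- xy - xy[c(2:n, 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

ring_centroid <- function(xy) {
  n <- nrow(xy)
  a <- ring_signed_area(xy)
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  x <- xy[, 1]; y <- xy[, 2]
  xn <- x[c(2:n, 1L)]; yn <- y[c(2:n, 1L)]
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ensure_ccw <- function(xy) {
  if (ring_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

ring_is_convex <- function(xy, tol = 1e-9) {
  xy <- ensure_ccw(xy)
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  nxt <- c(2:n, 1L)
  d <- xy[nxt, , drop = FALSE] - xy
  d2 <- d[c(2:n, 1L), , drop = FALSE]
  cr <- d[, 1] * d2[, 2] - d[, 2] * d2[, 1]
  scale <- max(abs(cr), 1)
  all(cr >= -tol * scale)
}

#' Even-odd point-in-polygon test, vectorized over points
#' @keywords internal
points_in_ring <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  x <- xy[, 1]; y <- xy[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xi <- x[i] + (py[crosses] - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xi)
    }
    j <- i
  }
  inside
}

# Proper/improper intersection of segments p1-p2 and p3-p4, excluding shared
# endpoints. Used by the self-intersection (validity) check.
segs_cross <- function(p1, p2, p3, p4, tol = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  dp <- p3 - p1
  if (abs(den) < tol) {
    # parallel: overlap test on collinear segments
    if (abs(dp[1] * d1[2] - dp[2] * d1[1]) > tol * max(1, sum(abs(d1)))) return(FALSE)
    l2 <- sum(d1^2)
    if (l2 < tol) return(FALSE)
    t3 <- sum((p3 - p1) * d1) / l2
    t4 <- sum((p4 - p1) * d1) / l2
    lo <- min(t3, t4); hi <- max(t3, t4)
    return(max(lo, 0) < min(hi, 1) - 1e-9)
  }
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / den
  u <- (dp[1] * d1[2] - dp[2] * d1[1]) / den
  eps <- 1e-9
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

#' Is a ring a simple (non-self-intersecting) polygon with positive area?
#' @keywords internal
ring_is_simple <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(FALSE)
  if (any(!is.finite(xy))) return(FALSE)
  # drop exact duplicate closing vertex if present
  if (all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  if (n < 3) return(FALSE)
  # scale-invariant thinness cutoff also catches collinear "polygons" whose
  # shoelace area is only nonzero through projection round-off
  if (ring_area(xy) <= 1e-10 * max(1, ring_perimeter(xy)^2)) return(FALSE)
  # a strictly convex ring with positive area cannot self-intersect
  if (ring_is_convex(xy)) return(TRUE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      if (k == i || nxt[i] == k || nxt[k] == i) next
      if (segs_cross(xy[i, ], xy[nxt[i], ], xy[k, ], xy[nxt[k], ])) return(FALSE)
    }
  }
  TRUE
}

#' Clip a polygon against one half-plane (inside = left of a->b)
#' @keywords internal
clip_halfplane <- function(subj, a, b) {
  n <- nrow(subj)
  if (is.null(n) || n == 0) return(subj)
  ex <- b[1] - a[1]; ey <- b[2] - a[2]
  side <- ex * (subj[, 2] - a[2]) - ey * (subj[, 1] - a[1])
  inside <- side >= 0
  if (all(inside)) return(subj)
  if (!any(inside)) return(subj[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  prev <- n
  for (i in seq_len(n)) {
    if (inside[prev] && inside[i]) {
      out <- rbind(out, subj[i, ])
    } else if (inside[prev] != inside[i]) {
      t <- side[prev] / (side[prev] - side[i])
      ip <- subj[prev, ] + t * (subj[i, ] - subj[prev, ])
      out <- rbind(out, ip)
      if (inside[i]) out <- rbind(out, subj[i, ])
    }
    prev <- i
  }
  out
}

#' Sutherland-Hodgman clip: subject ring against a convex clip ring
#'
#' Correct intersection area for any simple subject polygon when the clip
#' ring is convex.
#' @keywords internal
clip_polygon_convex <- function(subj, clip) {
  clip <- ensure_ccw(clip)
  out <- subj
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) break
    out <- clip_halfplane(out, clip[i, ], clip[if (i == n) 1L else i + 1L, ])
  }
  out
}

bbox_of <- function(xy) c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))

bboxes_overlap <- function(b1, b2, tol = 0) {
  b1[1] <= b2[3] + tol && b2[1] <= b1[3] + tol &&
    b1[2] <= b2[4] + tol && b2[2] <= b1[4] + tol
}

#' Intersection area of two simple rings
#'
#' Exact via half-plane clipping when either ring is convex; otherwise a
#' deterministic dense-grid estimate over the shared bounding box.
#' @keywords internal
ring_intersection_area <- function(a, b, grid_n = 256L) {
  if (!bboxes_overlap(bbox_of(a), bbox_of(b))) return(0)
  if (ring_is_convex(b)) return(ring_area(clip_polygon_convex(a, b)))
  if (ring_is_convex(a)) return(ring_area(clip_polygon_convex(b, a)))
  ba <- bbox_of(a); bb <- bbox_of(b)
  lo <- pmax(ba[1:2], bb[1:2]); hi <- pmin(ba[3:4], bb[3:4])
  if (any(hi <= lo)) return(0)
  gx <- seq(lo[1], hi[1], length.out = grid_n)
  gy <- seq(lo[2], hi[2], length.out = grid_n)
  px <- rep(gx, times = grid_n); py <- rep(gy, each = grid_n)
  frac <- mean(points_in_ring(px, py, a) & points_in_ring(px, py, b))
  frac * (hi[1] - lo[1]) * (hi[2] - lo[2])
}

#' Regular polygon approximating a disc
#' @keywords internal
disc_ring <- function(center, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Outward Minkowski buffer of a convex ring by radius r
#'
#' Offsets each edge outward and joins them with circular arcs at the
#' vertices. Exact (up to arc discretization) for convex input; non-convex
#' rings are buffered via their convex hull with a warning.
#' @keywords internal
buffer_convex_ring <- function(xy, r, pts_per_arc = 24L) {
  stopifnot(r > 0)
  if (!ring_is_convex(xy)) {
    warning("non-convex ring: buffering its convex hull", call. = FALSE)
    xy <- xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE]
  }
  xy <- ensure_ccw(xy)
  # collapse consecutive duplicate vertices
  keep <- c(TRUE, rowSums(abs(diff(xy)))[] > 1e-9)
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy)
  out <- list()
  for (i in seq_len(n)) {
    p_prev <- xy[if (i == 1L) n else i - 1L, ]
    p <- xy[i, ]
    p_next <- xy[if (i == n) 1L else i + 1L, ]
    d1 <- p - p_prev; d2 <- p_next - p
    # outward normals of a CCW ring point right of the direction of travel
    a1 <- atan2(-d1[1], d1[2])  # angle of outward normal (d1y, -d1x)
    a2 <- atan2(-d2[1], d2[2])
    sweep <- (a2 - a1) %% (2 * pi)
    k <- max(2L, ceiling(sweep / (2 * pi) * pts_per_arc) + 1L)
    th <- a1 + seq(0, sweep, length.out = k)
    out[[i]] <- cbind(p[1] + r * cos(th), p[2] + r * sin(th))
  }
  do.call(rbind, out)
}

#' Clip a segment to a convex ring (Cyrus-Beck)
#'
#' @return NULL if outside, else a 2x2 matrix with the clipped endpoints.
#' @keywords internal
clip_segment_convex <- function(p0, p1, clip) {
  clip <- ensure_ccw(clip)
  n <- nrow(clip)
  d <- p1 - p0
  tmin <- 0; tmax <- 1
  for (i in seq_len(n)) {
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    e <- b - a
    nrm <- c(e[2], -e[1])                 # outward normal
    den <- sum(nrm * d)
    num <- sum(nrm * (p0 - a))            # >0 means outside this edge
    if (abs(den) < 1e-15) {
      if (num > 0) return(NULL)
    } else {
      t <- -num / den
      if (den > 0) tmax <- min(tmax, t) else tmin <- max(tmin, t)
      if (tmin > tmax) return(NULL)
    }
  }
  rbind(p0 + tmin * d, p0 + tmax * d)
}
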