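# Internal planar computational geometry for the grid overlay.
# Rings are n x 2 matrices of vertices (not necessarily closed); all
# predicates treat the boundary as part of the polygon, so a touch counts
# as an intersection.

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("polygon ring needs at least 3 vertices")
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

.ring_area <- function(ring) {
  ring <- .close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

.ring_valid <- function(ring) {
  ring <- as.matrix(ring)
  nrow(ring) >= 3L && all(is.finite(ring)) && .ring_area(ring) > 0
}

# point in polygon, boundary counts as inside
.point_in_ring <- function(px, py, ring, eps = 1e-9) {
  ring <- .close_ring(ring)
  n <- nrow(ring) - 1L
  x <- ring[, 1]; y <- ring[, 2]
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
    # on-segment check
    d <- abs((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1))
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (d * d <= eps * eps * max(seglen2, 1) &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

.segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - eps <= c[1] && c[1] <= max(a[1], b[1]) + eps &&
      min(a[2], b[2]) - eps <= c[2] && c[2] <= max(a[2], b[2]) + eps
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (abs(d1) <= eps && on_seg(p3, p4, p1)) ||
    (abs(d2) <= eps && on_seg(p3, p4, p2)) ||
    (abs(d3) <= eps && on_seg(p1, p2, p3)) ||
    (abs(d4) <= eps && on_seg(p1, p2, p4))
}

# does a polygon intersect an axis-aligned rectangle (boundary touch counts)?
.ring_rect_intersects <- function(ring, xmin, xmax, ymin, ymax) {
  ring <- .close_ring(ring)
  # quick bbox reject
  if (max(ring[, 1]) < xmin || min(ring[, 1]) > xmax ||
      max(ring[, 2]) < ymin || min(ring[, 2]) > ymax) return(FALSE)
  # any vertex inside the rectangle
  if (any(ring[, 1] >= xmin & ring[, 1] <= xmax &
          ring[, 2] >= ymin & ring[, 2] <= ymax)) return(TRUE)
  # any rectangle corner inside the polygon
  corners <- rbind(c(xmin, ymin), c(xmin, ymax), c(xmax, ymin), c(xmax, ymax))
  for (i in 1:4)
    if (.point_in_ring(corners[i, 1], corners[i, 2], ring)) return(TRUE)
  # any edge crossing
  rect <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax), c(xmin, ymin))
  n <- nrow(ring)
  for (i in seq_len(n - 1L)) {
    for (j in 1:4) {
      if (.segments_intersect(ring[i, ], ring[i + 1L, ], rect[j, ], rect[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

# Sutherland-Hodgman clip of a polygon by a rectangle; returns the clipped
# ring (possibly with zero area) as a matrix, or NULL when empty.
.clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  ring <- .close_ring(ring)
  pts <- ring[-nrow(ring), , drop = FALSE]
  clip_half <- function(pts, inside, intersect) {
    if (nrow(pts) == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(a, b, t) a + t * (b - a)
  pts <- clip_half(pts, function(p) p[1] >= xmin, function(a, b)
    ix(a, b, (xmin - a[1]) / (b[1] - a[1])))
  pts <- clip_half(pts, function(p) p[1] <= xmax, function(a, b)
    ix(a, b, (xmax - a[1]) / (b[1] - a[1])))
  pts <- clip_half(pts, function(p) p[2] >= ymin, function(a, b)
    ix(a, b, (ymin - a[2]) / (b[2] - a[2])))
  pts <- clip_half(pts, function(p) p[2] <= ymax, function(a, b)
    ix(a, b, (ymax - a[2]) / (b[2] - a[2])))
  if (nrow(pts) < 3L) NULL else pts
}

# regular polygon approximating a disc, used for synthetic language ranges
.disc_ring <- function(cx, cy, r, n_vertices = 32L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
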