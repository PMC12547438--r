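# Minimal planar polygon routines on lon/lat rings. Overlay membership is a
# cell-centre point-in-polygon test; distances are small enough on the
# polygon scale that the planar treatment of lon/lat is the documented
# convention, matching how the overlay is defined.

# signed area of a closed ring (shoelace); positive = counter-clockwise
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# TRUE if p = (px, py) lies on segment a-b (within eps)
point_on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-12) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  scale <- max(abs(bx - ax), abs(by - ay), 1)
  if (abs(cross) > eps * scale) return(FALSE)
  dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  len2 <- (bx - ax)^2 + (by - ay)^2
  dot >= -eps && dot <= len2 + eps
}

# ray-casting point-in-polygon; points on the boundary count as inside
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring) - 1  # last vertex repeats the first
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (point_on_segment(px, py, xi, yi, xj, yj)) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, ring) {
  vapply(seq_along(px), function(i) point_in_polygon(px[i], py[i], ring),
         logical(1))
}

# proper-intersection test of segments p1-p2 and p3-p4 (shared endpoints of
# adjacent ring edges do not count)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# a ring is simple if no two non-adjacent edges properly intersect
ring_is_simple <- function(ring) {
  n <- nrow(ring) - 1
  if (n < 3) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (segments_cross(ring[i, ], ring[i + 1, ], ring[j, ], ring[j + 1, ]))
        return(FALSE)
    }
  }
  TRUE
}

# orient a closed ring counter-clockwise (GeoJSON exterior-ring convention)
ring_ccw <- function(ring) {
  if (ring_signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}
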