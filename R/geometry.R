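# Internal planar geometry helpers. Polygons are n x 2 matrices of
# (x, y) vertices, implicitly closed. Boundary points count as inside.

points_in_polygon <- function(x, y, vertices) {
  as.logical(pracma::inpolygon(x, y, vertices[, 1], vertices[, 2],
                               boundary = TRUE))
}

polygon_area <- function(vertices) {
  abs(pracma::polyarea(vertices[, 1], vertices[, 2]))
}

# strict ("proper") crossing of segments p1-p2 and q1-q2: they intersect
# at a point interior to both. Collinear overlap and endpoint touches do
# not count, so a rectangle lying exactly on a polygon edge is still
# contained.
orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

segments_cross <- function(p1, p2, q1x, q1y, q2x, q2y) {
  d1 <- orient(q1x, q1y, q2x, q2y, p1[1], p1[2])
  d2 <- orient(q1x, q1y, q2x, q2y, p2[1], p2[2])
  d3 <- orient(p1[1], p1[2], p2[1], p2[2], q1x, q1y)
  d4 <- orient(p1[1], p1[2], p2[1], p2[2], q2x, q2y)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# is the closed axis-aligned rectangle [x0, x1] x [y0, y1] fully inside
# the polygon? Sufficient for simple polygons: a probe grid of corners,
# edge midpoints and center all inside, and no rectangle edge properly
# crossing a polygon edge.
rect_in_polygon <- function(x0, y0, x1, y1, vertices) {
  xm <- (x0 + x1) / 2
  ym <- (y0 + y1) / 2
  px <- c(x0, x1, x1, x0, xm, x1, xm, x0, xm)
  py <- c(y0, y0, y1, y1, y0, ym, y1, ym, ym)
  if (!all(points_in_polygon(px, py, vertices))) {
    return(FALSE)
  }
  n <- nrow(vertices)
  vx1 <- vertices[, 1]
  vy1 <- vertices[, 2]
  vx2 <- vertices[c(2:n, 1), 1]
  vy2 <- vertices[c(2:n, 1), 2]
  rect <- list(
    list(c(x0, y0), c(x1, y0)),
    list(c(x1, y0), c(x1, y1)),
    list(c(x1, y1), c(x0, y1)),
    list(c(x0, y1), c(x0, y0))
  )
  for (e in rect) {
    if (any(segments_cross(e[[1]], e[[2]], vx1, vy1, vx2, vy2))) {
      return(FALSE)
    }
  }
  TRUE
}

# overlap of two collinear segments a1-a2 and b1-b2 (each 2-vectors).
# Returns NULL or the overlapping sub-segment endpoints as a 2 x 2
# matrix (rows = points). tol is in pixels.
collinear_overlap <- function(a1, a2, b1, b2, tol = 1e-6) {
  d <- a2 - a1
  len <- sqrt(sum(d^2))
  if (len < tol) return(NULL)
  u <- d / len
  # both b endpoints must lie on the infinite line through a1-a2
  perp <- function(p) abs((p[1] - a1[1]) * u[2] - (p[2] - a1[2]) * u[1])
  if (perp(b1) > tol || perp(b2) > tol) return(NULL)
  proj <- function(p) sum((p - a1) * u)
  ta <- sort(c(0, len))
  tb <- sort(c(proj(b1), proj(b2)))
  lo <- max(ta[1], tb[1])
  hi <- min(ta[2], tb[2])
  if (hi - lo < tol) return(NULL)
  rbind(a1 + lo * u, a1 + hi * u)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
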