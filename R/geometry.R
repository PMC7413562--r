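# Planar polygon primitives.
#
# All geometry in the package is planar, in arbitrary length units. A *ring*
# is an n x 2 numeric matrix of vertices (not closed: the first vertex is not
# repeated at the end). A *polygon* is a list of rings, the first being the
# outer boundary and any further rings holes. A *multipolygon* is a list of
# polygons. Only areas, intersection areas and point containment are needed
# by the pipeline, so that is all that is implemented.

#' Construct a rectangular ring
#'
#' @param xmin,ymin,xmax,ymax rectangle corners.
#' @return A 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Construct a polygon from rings
#'
#' @param ... rings (n x 2 matrices); the first is the outer boundary,
#'   the rest are holes.
#' @return A polygon (list of rings).
#' @export
hm_polygon <- function(...) {
  rings <- list(...)
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
      stop("each ring must be an n x 2 matrix with n >= 3")
    if (any(!is.finite(r))) stop("non-finite ring coordinate")
  }
  rings
}

# signed area of a ring (positive if counter-clockwise)
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(ring) {
  if (ring_signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Area of a polygon (outer ring minus holes)
#'
#' @param poly a polygon (list of rings).
#' @return Non-negative area.
#' @export
poly_area <- function(poly) {
  a <- abs(ring_signed_area(poly[[1]]))
  if (length(poly) > 1)
    a <- a - sum(vapply(poly[-1], function(r) abs(ring_signed_area(r)), 0))
  max(a, 0)
}

# Sutherland-Hodgman: clip an arbitrary subject ring against one convex
# counter-clockwise clip ring. Output may carry zero-width bridges for
# non-convex subjects; its shoelace area is nevertheless the area of the
# intersection, which is all the callers use.
clip_ring_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance-ish: >= 0 means inside (left of directed edge)
    s <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      cur_in <- s[j] >= 0; nxt_in <- s[k] >= 0
      if (cur_in) {
        keep_x <- c(keep_x, out[j, 1]); keep_y <- c(keep_y, out[j, 2])
      }
      if (xor(cur_in, nxt_in)) {
        t <- s[j] / (s[j] - s[k])
        keep_x <- c(keep_x, out[j, 1] + t * (out[k, 1] - out[j, 1]))
        keep_y <- c(keep_y, out[j, 2] + t * (out[k, 2] - out[j, 2]))
      }
    }
    out <- cbind(keep_x, keep_y)
  }
  out
}

# Ear-clipping triangulation of a simple ring. Returns a list of 3 x 2
# matrices. Degenerate (collinear) vertices are dropped.
triangulate_ring <- function(ring) {
  ring <- ensure_ccw(ring)
  idx <- seq_len(nrow(ring))
  tris <- list()
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  guard <- 0L
  while (length(idx) > 3) {
    guard <- guard + 1L
    if (guard > 10000L) stop("triangulation failed to converge (degenerate ring?)")
    n <- length(idx)
    found <- FALSE
    for (j in seq_len(n)) {
      ip <- idx[if (j == 1) n else j - 1]
      ic <- idx[j]
      inx <- idx[if (j == n) 1 else j + 1]
      p <- ring[ip, ]; c0 <- ring[ic, ]; q <- ring[inx, ]
      cr <- cross2(p, c0, q)
      if (abs(cr) < 1e-12) { # collinear vertex: drop it
        idx <- idx[-j]; found <- TRUE; break
      }
      if (cr < 0) next # reflex
      # ear test: no other vertex strictly inside triangle p-c0-q
      others <- setdiff(idx, c(ip, ic, inx))
      ok <- TRUE
      for (o in others) {
        v <- ring[o, ]
        d1 <- cross2(p, c0, v); d2 <- cross2(c0, q, v); d3 <- cross2(q, p, v)
        if (d1 > 1e-12 && d2 > 1e-12 && d3 > 1e-12) { ok <- FALSE; break }
      }
      if (ok) {
        tris[[length(tris) + 1L]] <- ring[c(ip, ic, inx), , drop = FALSE]
        idx <- idx[-j]
        found <- TRUE
        break
      }
    }
    if (!found) stop("triangulation failed: no ear found (self-intersecting ring?)")
  }
  if (length(idx) == 3) {
    tri <- ring[idx, , drop = FALSE]
    if (abs(ring_signed_area(tri)) > 0) tris[[length(tris) + 1L]] <- tri
  }
  tris
}

# intersection area of an arbitrary polygon `a` with a single ring treated as
# a filled region (via triangulation of the ring)
poly_ring_intersection_area <- function(a, ring) {
  tris <- triangulate_ring(ring)
  total <- 0
  for (tri in tris) {
    tri <- ensure_ccw(tri)
    for (ri in seq_along(a)) {
      clipped <- clip_ring_convex(a[[ri]], tri)
      if (nrow(clipped) >= 3) {
        part <- abs(ring_signed_area(clipped))
        total <- total + if (ri == 1) part else -part
      }
    }
  }
  max(total, 0)
}

#' Intersection area of two polygons
#'
#' Computes the area of the planar intersection of two simple polygons
#' (optionally with holes). Exact for the rectangle/grid tessellations used
#' throughout the package; general simple polygons are handled by
#' triangulating one operand and clipping the other against each triangle.
#'
#' @param a,b polygons (lists of rings; first ring outer, others holes).
#' @return Non-negative intersection area.
#' @export
poly_intersection_area <- function(a, b) {
  total <- poly_ring_intersection_area(a, b[[1]])
  if (length(b) > 1)
    for (h in b[-1]) total <- total - poly_ring_intersection_area(a, h)
  max(total, 0)
}

# Vectorised point-in-ring test. Returns integer vector per point:
# 0 = outside, 1 = strictly inside, 2 = on the boundary (within tol).
point_in_ring <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    k <- if (i == n) 1 else i + 1
    x2 <- ring[k, 1]; y2 <- ring[k, 2]
    # boundary: distance from point to segment <= tol
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
      qx <- x1 + t * dx; qy <- y1 + t * dy
      boundary <- boundary | ((px - qx)^2 + (py - qy)^2 <= tol * tol)
    }
    # ray casting (half-open rule)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py - y1) * dx / dy
      inside <- xor(inside, crosses & (px < xi))
    }
  }
  out <- integer(length(px))
  out[inside] <- 1L
  out[boundary] <- 2L
  out
}

# Vectorised point-in-polygon with holes: 2 boundary (any ring), 1 strictly
# inside (inside outer, outside all holes), 0 otherwise.
point_in_poly <- function(px, py, poly, tol = 1e-9) {
  status <- point_in_ring(px, py, poly[[1]], tol)
  if (length(poly) > 1) {
    for (h in poly[-1]) {
      hs <- point_in_ring(px, py, h, tol)
      status[hs == 1L & status == 1L] <- 0L
      status[hs == 2L & status != 0L] <- 2L
    }
  }
  status
}

poly_bbox <- function(poly) {
  xs <- unlist(lapply(poly, function(r) r[, 1]))
  ys <- unlist(lapply(poly, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
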