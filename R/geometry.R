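# Plane-geometry primitives used by the builder, the dynamics surgery and the
# metric predicates. Coordinates are plot-local Cartesian metres. Polygons are
# numeric matrices with columns x, y, one row per vertex, no repeated closing
# vertex; collinear vertices are legal (they carry topological junction nodes).

#' Signed area of a polygon
#'
#' Shoelace formula. Positive for counterclockwise vertex order, negative for
#' clockwise.
#'
#' @param poly Two-column numeric matrix of vertices (x, y), open ring.
#' @return Signed area in square metres.
#' @export
signed_area <- function(poly) {
  poly <- as_poly(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area-weighted centroid of a polygon boundary
#'
#' @param poly Two-column numeric matrix of vertices.
#' @return Numeric length-2 vector (x, y).
#' @export
poly_centroid <- function(poly) {
  poly <- matrix(as.numeric(poly), ncol = 2)
  if (nrow(poly) < 3) return(colMeans(poly))
  poly <- as_poly(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

as_poly <- function(poly) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  poly
}

# Drop consecutive duplicate vertices (and a duplicate closing vertex).
dedup_poly <- function(poly, tol = 1e-9) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  stopifnot(ncol(poly) == 2)
  n <- nrow(poly)
  if (n < 2) return(poly)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    if (keep[i] && max(abs(poly[i, ] - poly[i + 1L, ])) <= tol) keep[i + 1L] <- FALSE
  }
  # explicit closing vertex: drop the last, never the first
  if (n > 1 && keep[n] && max(abs(poly[n, ] - poly[1L, ])) <= tol) keep[n] <- FALSE
  poly[keep, , drop = FALSE]
}

# Orientation of the triangle p-q-r: > 0 counterclockwise, < 0 clockwise.
orient2 <- function(p, q, r) {
  (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
}

on_segment <- function(p, a, b, tol = 1e-9) {
  if (abs(orient2(a, b, p)) > tol * (1 + max(abs(c(a, b, p))))) return(FALSE)
  p[1] >= min(a[1], b[1]) - tol && p[1] <= max(a[1], b[1]) + tol &&
    p[2] >= min(a[2], b[2]) - tol && p[2] <= max(a[2], b[2]) + tol
}

# Proper crossing test (shared endpoints do not count as a crossing).
segments_cross <- function(a, b, c, d, tol = 1e-12) {
  o1 <- orient2(a, b, c); o2 <- orient2(a, b, d)
  o3 <- orient2(c, d, a); o4 <- orient2(c, d, b)
  if (((o1 > tol && o2 < -tol) || (o1 < -tol && o2 > tol)) &&
      ((o3 > tol && o4 < -tol) || (o3 < -tol && o4 > tol))) return(TRUE)
  FALSE
}

#' Test whether a polygon is simple
#'
#' Simple means no two non-adjacent edges cross and no edge backtracks onto
#' its neighbour. Collinear (straight-angle) vertices are allowed.
#'
#' @param poly Two-column numeric matrix of vertices.
#' @return Logical scalar.
#' @export
is_simple_polygon <- function(poly) {
  poly <- dedup_poly(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[idx(i + 1L), ]
    # adjacent edges must not fold back onto each other
    cpre <- poly[idx(i - 1L), ]
    v1 <- a - cpre; v2 <- b - a
    if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-12 && sum(v1 * v2) < 0) return(FALSE)
    for (j in seq_len(n)) {
      if (j == i || idx(j + 1L) == i || idx(i + 1L) == j) next
      if (segments_cross(a, b, poly[j, ], poly[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

#' Strict point-in-polygon test
#'
#' @param pts Two-column matrix of query points.
#' @param poly Two-column matrix of polygon vertices.
#' @return Logical vector; TRUE when the point lies strictly inside.
#' @export
points_strictly_inside <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- as_poly(poly)
  inside <- pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2],
                              boundary = FALSE)
  # inpolygon's boundary handling is numeric; exclude boundary points exactly
  n <- nrow(poly)
  for (k in seq_len(nrow(pts))) {
    if (!inside[k]) next
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (on_segment(pts[k, ], poly[i, ], poly[j, ])) { inside[k] <- FALSE; break }
    }
  }
  inside
}

# TRUE when polygon `inner` lies strictly inside polygon `outer`:
# all vertices strictly inside and no edge crossings.
poly_strictly_inside <- function(inner, outer) {
  inner <- dedup_poly(inner); outer <- dedup_poly(outer)
  if (!all(points_strictly_inside(inner, outer))) return(FALSE)
  ni <- nrow(inner); no <- nrow(outer)
  for (i in seq_len(ni)) {
    a <- inner[i, ]; b <- inner[if (i == ni) 1L else i + 1L, ]
    for (j in seq_len(no)) {
      c_ <- outer[j, ]; d <- outer[if (j == no) 1L else j + 1L, ]
      if (segments_cross(a, b, c_, d)) return(FALSE)
    }
  }
  TRUE
}

# TRUE when the interiors of two simple polygons overlap.
polys_overlap <- function(p1, p2) {
  p1 <- dedup_poly(p1); p2 <- dedup_poly(p2)
  if (any(points_strictly_inside(p1, p2))) return(TRUE)
  if (any(points_strictly_inside(p2, p1))) return(TRUE)
  n1 <- nrow(p1); n2 <- nrow(p2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (segments_cross(p1[i, ], p1[if (i == n1) 1L else i + 1L, ],
                       p2[j, ], p2[if (j == n2) 1L else j + 1L, ])) return(TRUE)
  }
  FALSE
}

#' Bounding box of a polygon
#' @param poly Two-column matrix of vertices.
#' @return Named vector `c(xmin, xmax, ymin, ymax)`.
#' @export
poly_bbox <- function(poly) {
  poly <- as_poly(poly)
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

# Axis-aligned rectangle helpers ------------------------------------------

#' Axis-aligned rectangle polygon
#'
#' Counterclockwise 4-vertex polygon matrix, the building block of
#' alley-cropping plot specs.
#'
#' @param xmin,ymin,xmax,ymax Rectangle extent in metres.
#' @return A 4 x 2 matrix of vertices.
#' @export
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Intersection of two axis-aligned bounding boxes; NULL when degenerate.
bbox_intersect <- function(b1, b2, tol = 1e-9) {
  x0 <- max(b1["xmin"], b2["xmin"]); x1 <- min(b1["xmax"], b2["xmax"])
  y0 <- max(b1["ymin"], b2["ymin"]); y1 <- min(b1["ymax"], b2["ymax"])
  if (x1 - x0 <= tol || y1 - y0 <= tol) return(NULL)
  c(xmin = unname(x0), xmax = unname(x1), ymin = unname(y0), ymax = unname(y1))
}

# Insert points that lie strictly inside a polygon edge (conformity nodes),
# ordered along the edge. Used so rebuilt faces share whole edges with their
# untouched neighbours.
insert_collinear_nodes <- function(poly, pts, tol = 1e-9) {
  poly <- dedup_poly(poly)
  if (is.null(pts) || nrow(pts) == 0) return(poly)
  out <- NULL
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    out <- rbind(out, a)
    hits <- NULL
    for (k in seq_len(nrow(pts))) {
      p <- pts[k, ]
      if (max(abs(p - a)) <= tol || max(abs(p - b)) <= tol) next
      if (on_segment(p, a, b, tol)) hits <- rbind(hits, p)
    }
    if (!is.null(hits)) {
      d <- (hits[, 1] - a[1]) * (b[1] - a[1]) + (hits[, 2] - a[2]) * (b[2] - a[2])
      out <- rbind(out, hits[order(d), , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  dedup_poly(out)
}

# Splice a rectangular notch out of a polygon. `notch` is an axis-aligned
# rectangle (bbox vector) one side of which lies on a single polygon edge;
# the polygon boundary is rerouted around the notch. Polygon must be
# counterclockwise; the result is counterclockwise.
splice_notch <- function(poly, notch, tol = 1e-9) {
  poly <- dedup_poly(poly)
  n <- nrow(poly)
  corners <- rect_poly(notch["xmin"], notch["ymin"], notch["xmax"], notch["ymax"])
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    # which notch side (as a whole) lies on edge a->b?
    for (s in 1:4) {
      p <- corners[s, ]; q <- corners[if (s == 4) 1L else s + 1L, ]
      if (on_segment(p, a, b, tol) && on_segment(q, a, b, tol)) {
        # order p,q along a->b
        dp <- sum((p - a) * (b - a)); dq <- sum((q - a) * (b - a))
        if (dp > dq) { tmp <- p; p <- q; q <- tmp }
        # interior normal: left of a->b
        dir <- (b - a) / sqrt(sum((b - a)^2))
        nrm <- c(-dir[2], dir[1])
        depth <- max(notch["xmax"] - notch["xmin"], notch["ymax"] - notch["ymin"])
        depth <- if (abs(dir[1]) > 0.5) notch["ymax"] - notch["ymin"] else notch["xmax"] - notch["xmin"]
        detour <- rbind(p, p + nrm * depth, q + nrm * depth, q)
        head_part <- poly[seq_len(i), , drop = FALSE]
        tail_part <- if (i < n) poly[(i + 1L):n, , drop = FALSE] else NULL
        out <- dedup_poly(rbind(head_part, detour, tail_part), tol)
        return(drop_folds(out, tol))
      }
    }
  }
  stop("splice_notch: notch is not flush with any polygon edge", call. = FALSE)
}

# Remove backtracking vertices (adjacent edges antiparallel), which arise
# when a spliced notch is flush with a polygon corner.
drop_folds <- function(poly, tol = 1e-9) {
  repeat {
    n <- nrow(poly)
    if (n < 3) return(poly)
    folded <- FALSE
    for (i in seq_len(n)) {
      a <- poly[if (i == 1L) n else i - 1L, ]
      b <- poly[i, ]
      c_ <- poly[if (i == n) 1L else i + 1L, ]
      v1 <- b - a; v2 <- c_ - b
      if (abs(v1[1] * v2[2] - v1[2] * v2[1]) <= tol && sum(v1 * v2) < 0) {
        poly <- poly[-i, , drop = FALSE]
        folded <- TRUE
        break
      }
    }
    if (!folded) return(poly)
  }
}
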