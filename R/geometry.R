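# Polygon and polyline geometry helpers.
#
# A polyline is an n x 2 numeric matrix with columns x, y. Closed polylines
# repeat the first vertex as the last row; constructors enforce this.

polyline <- function(points, source = c("proposed", "manual", "iso", "truth"),
                     closed = TRUE) {
  source <- match.arg(source)
  points <- as.matrix(points)
  if (ncol(points) != 2 || !is.numeric(points))
    stop("a polyline needs an n x 2 numeric matrix of (x, y)", call. = FALSE)
  if (!all(is.finite(points))) stop("non-finite polyline vertices", call. = FALSE)
  colnames(points) <- c("x", "y")
  if (closed && !isTRUE(all.equal(points[1, ], points[nrow(points), ],
                                  check.attributes = FALSE)))
    points <- rbind(points, points[1, , drop = FALSE])
  structure(points, class = c("polyline", class(points)), source = source)
}

# Vertices without the closing repeat.
open_vertices <- function(poly) {
  p <- unclass(poly)
  if (nrow(p) > 1 &&
      isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  p
}

# Signed shoelace area; positive for counter-clockwise traversal in the
# (x right, y down) image frame's mathematical orientation.
polygon_area_signed <- function(pts) {
  p <- if (inherits(pts, "polyline")) open_vertices(pts) else as.matrix(pts)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(pts) abs(polygon_area_signed(pts))

polygon_centroid <- function(pts) {
  p <- if (inherits(pts, "polyline")) open_vertices(pts) else as.matrix(pts)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(x = mean(x), y = mean(y)))
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

# Intersections of the ray origin + t*dir (t > 0) with the edges of a set of
# polylines; returns a list with t (distance when dir is unit) and points.
ray_polyline_intersections <- function(origin, dir, edges) {
  # edges: list with x1, y1, x2, y2 vectors
  ex <- edges$x2 - edges$x1
  ey <- edges$y2 - edges$y1
  wx <- edges$x1 - origin[1]
  wy <- edges$y1 - origin[2]
  denom <- dir[1] * ey - dir[2] * ex
  ok <- abs(denom) > 1e-12
  t <- (wx * ey - wy * ex) / denom
  s <- (wx * dir[2] - wy * dir[1]) / denom
  # s tolerance: a ray through a shared vertex must not lose the hit to
  # rounding on both adjacent edges
  keep <- ok & is.finite(t) & is.finite(s) & t > 1e-9 &
    s >= -1e-9 & s <= 1 + 1e-9
  t <- t[keep]
  list(t = t,
       x = origin[1] + t * dir[1],
       y = origin[2] + t * dir[2],
       edge = which(keep))
}

polyline_edges <- function(polys) {
  if (inherits(polys, "polyline")) polys <- list(polys)
  xs1 <- ys1 <- xs2 <- ys2 <- id <- numeric(0)
  for (k in seq_along(polys)) {
    p <- unclass(polys[[k]])
    n <- nrow(p)
    if (n < 2) next
    xs1 <- c(xs1, p[-n, 1]); ys1 <- c(ys1, p[-n, 2])
    xs2 <- c(xs2, p[-1, 1]); ys2 <- c(ys2, p[-1, 2])
    id <- c(id, rep(k, n - 1))
  }
  list(x1 = xs1, y1 = ys1, x2 = xs2, y2 = ys2, poly = id)
}

# Even-odd crossing test for one point against a polygon, vectorized over
# the polygon edges (used heavily by the nesting construction).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vx2 <- c(vx[-1], vx[1]); vy2 <- c(vy[-1], vy[1])
  crosses <- ((vy > py) != (vy2 > py))
  if (!any(crosses)) return(FALSE)
  xint <- vx[crosses] + (py - vy[crosses]) * (vx2[crosses] - vx[crosses]) /
    (vy2[crosses] - vy[crosses])
  sum(xint > px) %% 2 == 1
}

# Proper-crossing test for polygon simplicity: no two non-adjacent edges of
# the closed polygon may intersect.
is_simple_polygon <- function(pts) {
  p <- if (inherits(pts, "polyline")) open_vertices(pts) else as.matrix(pts)
  n <- nrow(p)
  if (n < 3) return(FALSE)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)]   # skip edges adjacent through the closure
    if (!length(j)) next
    d1 <- cross(x2[i] - x[i], y2[i] - y[i], x[j] - x[i], y[j] - y[i])
    d2 <- cross(x2[i] - x[i], y2[i] - y[i], x2[j] - x[i], y2[j] - y[i])
    d3 <- cross(x2[j] - x[j], y2[j] - y[j], x[i] - x[j], y[i] - y[j])
    d4 <- cross(x2[j] - x[j], y2[j] - y[j], x2[i] - x[j], y2[i] - y[j])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

# Rasterize a closed polygon to a binary mask: pixels whose centers fall
# inside or on the polygon.
rasterize_polygon <- function(poly, shape) {
  p <- open_vertices(if (inherits(poly, "polyline")) poly else
    polyline(poly, "manual"))
  h <- shape[1]; w <- shape[2]
  gx <- rep(seq_len(w), each = h)
  gy <- rep(seq_len(h), times = w)
  inside <- pracma::inpolygon(gx, gy, p[, 1], p[, 2], boundary = TRUE)
  matrix(as.numeric(inside), h, w)
}

# Draw polyline outlines into a mask by dense sampling of each edge.
rasterize_outline <- function(polys, shape) {
  if (inherits(polys, "polyline")) polys <- list(polys)
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0, h, w)
  for (p in polys) {
    v <- unclass(p)
    n <- nrow(v)
    if (n < 2) next
    seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
    for (i in seq_len(n - 1)) {
      m <- max(2L, ceiling(seg[i] / 0.5) + 1L)
      ts <- seq(0, 1, length.out = m)
      xs <- round(v[i, 1] + ts * (v[i + 1, 1] - v[i, 1]))
      ys <- round(v[i, 2] + ts * (v[i + 1, 2] - v[i, 2]))
      ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
      mask[cbind(ys[ok], xs[ok])] <- 1
    }
  }
  mask
}
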