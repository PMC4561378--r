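# Shared geometric fixtures, all built in code.

pixel_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

disk_mask <- function(h, w, cx, cy, r) {
  g <- pixel_grid(h, w)
  matrix(as.numeric((g$x - cx)^2 + (g$y - cy)^2 <= r^2), h, w)
}

rect_mask <- function(h, w, x0, x1, y0, y1) {
  g <- pixel_grid(h, w)
  matrix(as.numeric(g$x >= x0 & g$x <= x1 & g$y >= y0 & g$y <= y1), h, w)
}

# Rasterize an arbitrary closed polygon given as (x, y) vertex matrix.
poly_mask <- function(h, w, pts) {
  g <- pixel_grid(h, w)
  matrix(as.numeric(pracma::inpolygon(as.vector(g$x), as.vector(g$y),
                                      pts[, 1], pts[, 2], boundary = TRUE)),
         h, w)
}

circle_points <- function(cx, cy, r, n = 72) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Piecewise-constant two-phase image: `hi` inside a disk, `lo` outside.
two_phase_disk <- function(h = 120, w = 120, cx = 60, cy = 60, r = 30,
                           lo = 0.2, hi = 0.9) {
  mask <- disk_mask(h, w, cx, cy, r)
  list(img = lo + (hi - lo) * mask, mask = mask,
       cx = cx, cy = cy, r = r, lo = lo, hi = hi)
}

# Independent convex hull oracle: gift wrapping over a point set.
giftwrap_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[best, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
        (pts[best, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      d_best <- sum((pts[best, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_q > d_best)) best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  pts[hull, , drop = FALSE]
}

shoelace <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Construct a radial_profile object directly (unit-test fixture).
make_profile <- function(radii, ref = c(x = 0, y = 0)) {
  m <- length(radii)
  angles <- (seq_len(m) - 1) * 2 * pi / m
  structure(list(ref = ref, angles = angles, radii = radii,
                 hit_points = cbind(x = ref[1] + radii * cos(angles),
                                    y = ref[2] + radii * sin(angles)),
                 interpolated = rep(FALSE, m), grad = rep(1, m)),
            class = "radial_profile")
}

# Construct a search_band object from a list of closed contours given as
# vertex matrices, outermost first (unit-test fixture).
make_band <- function(contour_list, shape) {
  members <- lapply(seq_along(contour_list), function(i)
    list(id = i, level = i,
         xy = mammoseg::manual_contour(contour_list[[i]]),
         area = shoelace(contour_list[[i]]), parent = NA))
  structure(list(members = members,
                 innermost_id = length(contour_list),
                 band_mask = NULL,
                 chain_ids = seq_along(contour_list),
                 member_ids = seq_along(contour_list),
                 shape = shape),
            class = "search_band")
}
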