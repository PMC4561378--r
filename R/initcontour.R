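# Proposed initial level-set contour: radial rays from a reference point
# near the center of the innermost band contour, maximum-gradient
# intersections with the band's iso-level contours, and statistical
# clipping of outlying radii.

#' Radial maximum-gradient profile
#'
#' Casts `m` uniformly spaced rays from the reference point (the polygon
#' centroid of the innermost band contour unless overridden), intersects
#' each ray with every member contour of the search band, samples the
#' gradient magnitude at each intersection (bilinear), and keeps, per ray,
#' the intersection with the greatest gradient strength. Ties in gradient
#' are broken toward the intersection nearest the reference point. Rays
#' with no intersection get their radius linearly interpolated from the
#' nearest valid angular neighbors and are flagged.
#'
#' @param band a [extract_search_band()] result.
#' @param grad_mag gradient-magnitude matrix of the smoothed image.
#' @param m number of rays (>= 8); the default 360 gives 1-degree sampling.
#' @param ref optional reference point `c(x, y)`.
#' @return a `radial_profile`: `ref`, `angles` (radians), `radii`,
#'   `hit_points` (m x 2), `interpolated` flags, `grad` values.
#' @export
radial_profile <- function(band, grad_mag, m = 360, ref = NULL) {
  stopifnot(inherits(band, "search_band"))
  check_image(grad_mag, "grad_mag")
  if (m < 8) stop("`m` must be >= 8", call. = FALSE)
  inner <- Filter(function(cc) cc$id == band$innermost_id, band$members)[[1]]
  if (is.null(ref)) ref <- polygon_centroid(inner$xy)
  h <- nrow(grad_mag); w <- ncol(grad_mag)
  if (ref[1] < 1 || ref[1] > w || ref[2] < 1 || ref[2] > h)
    stop("reference point lies outside the image", call. = FALSE)
  edges <- polyline_edges(lapply(band$members, `[[`, "xy"))
  angles <- (seq_len(m) - 1) * 2 * pi / m
  radii <- rep(NA_real_, m)
  grads <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    d <- c(cos(angles[j]), sin(angles[j]))
    hit <- ray_polyline_intersections(ref, d, edges)
    if (!length(hit$t)) next
    gv <- bilinear_sample(grad_mag, hit$x, hit$y)
    best <- order(-gv, hit$t)[1]
    radii[j] <- hit$t[best]
    grads[j] <- gv[best]
  }
  miss <- is.na(radii)
  if (all(miss))
    stop("no ray intersects the search band contours", call. = FALSE)
  if (any(miss)) {
    # circular linear interpolation of radius over angle between the
    # nearest valid neighbors on either side
    ok <- which(!miss)
    for (j in which(miss)) {
      d_back <- (j - ok) %% m   # angular steps back to each valid ray
      d_fwd <- (ok - j) %% m    # angular steps forward
      p <- ok[which.min(d_back)]
      q <- ok[which.min(d_fwd)]
      db <- min(d_back); df <- min(d_fwd)
      wq <- db / (db + df)
      radii[j] <- (1 - wq) * radii[p] + wq * radii[q]
    }
  }
  hp <- cbind(x = ref[1] + radii * cos(angles),
              y = ref[2] + radii * sin(angles))
  structure(list(ref = ref, angles = angles, radii = radii,
                 hit_points = hp, interpolated = miss, grad = grads),
            class = "radial_profile")
}

#' Statistical clipping of a radial profile
#'
#' Radii at or beyond `r_ave + n * r_std` (mean and sample standard
#' deviation of the radii, `m - 1` denominator) are replaced by `r_ave`;
#' all others pass unchanged. Hit points of replaced rays are recomputed at
#' distance `r_ave` along the same ray. The replacement set is decided once
#' from the original statistics (single-pass semantics).
#'
#' @param profile a [radial_profile()].
#' @param n clipping multiplier, 1 or 2.
#' @return a clipped `radial_profile` with attributes `r_ave`, `r_std`,
#'   `replaced` (indices), `n_sigma`.
#' @export
clip_profile <- function(profile, n = 1) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!n %in% c(1, 2)) stop("`n` must be 1 or 2", call. = FALSE)
  r <- profile$radii
  if (length(r) < 2)
    stop("at least 2 radii are required (r_std undefined)", call. = FALSE)
  r_ave <- mean(r)
  r_std <- stats::sd(r)
  cutoff <- r_ave + n * r_std
  replaced <- which(r >= cutoff)
  r[replaced] <- r_ave
  out <- profile
  out$radii <- r
  out$hit_points <- cbind(x = profile$ref[1] + r * cos(profile$angles),
                          y = profile$ref[2] + r * sin(profile$angles))
  attr(out, "r_ave") <- r_ave
  attr(out, "r_std") <- r_std
  attr(out, "replaced") <- replaced
  attr(out, "n_sigma") <- n
  out
}

#' Initial contour from a radial profile
#'
#' Orders the hit points by angle and closes the polygon. A profile with
#' positive radii about a single reference point is star-shaped, hence
#' simple; the result is verified and a geometry error raised otherwise.
#'
#' @param profile a (possibly clipped) [radial_profile()].
#' @return a closed `polyline` with `source = "proposed"`.
#' @export
profile_to_contour <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  ord <- order(profile$angles)
  pts <- profile$hit_points[ord, , drop = FALSE]
  if (!is_simple_polygon(pts)) {
    # locate an offending vertex for the error message
    stop("profile yields a self-intersecting contour near angle ",
         sprintf("%.1f deg", profile$angles[ord][1] * 180 / pi),
         call. = FALSE)
  }
  polyline(pts, source = "proposed")
}

#' Validate a user-supplied (manual) initial contour
#'
#' @param points n x 2 matrix or data frame of (x, y) vertices, n >= 3,
#'   describing a simple polygon.
#' @return a closed `polyline` with `source = "manual"`.
#' @export
manual_contour <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) > 1 &&
      isTRUE(all.equal(points[1, ], points[nrow(points), ],
                       check.attributes = FALSE)))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3)
    stop("a contour needs at least 3 distinct vertices", call. = FALSE)
  if (!is_simple_polygon(points))
    stop("contour is self-intersecting", call. = FALSE)
  polyline(points, source = "manual")
}
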