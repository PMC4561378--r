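# Synthetic mammography-like mass phantoms with ground truth, emulating
# two margin classes: bright masses with sharp, distinct margins, and
# masses with blurred/obscured margins containing interior low-signal
# areas, both on textured backgrounds.

#' Phantom specification
#'
#' Defaults encode the two margin classes on a 208 x 208 grid (the size of
#' a cropped sub-mammogram). Distinct-margin masses get a sharp edge
#' (sub-pixel blur) and no interior holes; ill-defined masses get a heavy
#' edge blur and interior low-signal depressions.
#'
#' @param size image dimensions `c(h, w)`.
#' @param radius mean mass radius in pixels (< min(size)/3).
#' @param margin `"distinct"` or `"ill_defined"`.
#' @param edge_softness Gaussian std (px) of the margin blur; defaults to
#'   0.8 (distinct) or 4 (ill-defined).
#' @param spiculation_amp radial perturbation amplitude as a fraction of
#'   the radius; defaults 0.05 (distinct) / 0.12 (ill-defined).
#' @param spiculation_freq integer number of boundary lobes.
#' @param n_holes number of interior low-signal depressions; ill-defined
#'   masses require at least 1 (default 3).
#' @param hole_depth intensity drop at the hole centers.
#' @param background_texture_sd standard deviation of the correlated
#'   background texture.
#' @param background_level mean background intensity.
#' @param contrast mass-over-background intensity gap.
#' @param seed integer RNG seed governing every stochastic element.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(208, 208), radius = 40,
                         margin = c("distinct", "ill_defined"),
                         edge_softness = NULL,
                         spiculation_amp = NULL, spiculation_freq = NULL,
                         n_holes = NULL, hole_depth = 0.3,
                         background_texture_sd = 0.03,
                         background_level = 0.35, contrast = 0.4,
                         seed = 1) {
  margin <- match.arg(margin)
  distinct <- margin == "distinct"
  if (is.null(edge_softness)) edge_softness <- if (distinct) 0.8 else 4
  if (is.null(spiculation_amp)) spiculation_amp <- if (distinct) 0.05 else 0.12
  if (is.null(spiculation_freq)) spiculation_freq <- if (distinct) 8L else 7L
  if (is.null(n_holes)) n_holes <- if (distinct) 0L else 3L
  if (radius >= min(size) / 3)
    stop("`radius` must be smaller than min(size)/3", call. = FALSE)
  if (distinct && edge_softness > 1)
    stop("distinct margins require `edge_softness` <= 1", call. = FALSE)
  if (!distinct && (edge_softness < 3 || n_holes < 1))
    stop("ill-defined margins require `edge_softness` >= 3 and `n_holes` >= 1",
         call. = FALSE)
  structure(list(size = as.integer(size), radius = radius, margin = margin,
                 edge_softness = edge_softness,
                 spiculation_amp = spiculation_amp,
                 spiculation_freq = as.integer(spiculation_freq),
                 n_holes = as.integer(n_holes), hole_depth = hole_depth,
                 background_texture_sd = background_texture_sd,
                 background_level = background_level, contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic mass phantom
#'
#' The mass boundary is the polar curve
#' `radius * (1 + spiculation_amp * cos(spiculation_freq * theta))` about a
#' jittered center; the interior is raised by `contrast` over a textured
#' background (Gaussian white noise, spatially correlated by smoothing and
#' rescaled to `background_texture_sd`), the margin is blurred with
#' `edge_softness`, and interior low-signal areas are Gaussian
#' depressions. Fully deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom`: `image` (matrix in \[0, 1\]), `truth_mask`,
#'   `truth_contour` (closed polyline), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  with_seed(spec$seed, {
    center <- c(x = w / 2 + stats::runif(1, -10, 10),
                y = h / 2 + stats::runif(1, -10, 10))
    theta <- (0:359) * pi / 180
    rr <- spec$radius *
      (1 + spec$spiculation_amp * cos(spec$spiculation_freq * theta))
    truth <- polyline(cbind(x = center[1] + rr * cos(theta),
                            y = center[2] + rr * sin(theta)),
                      source = "truth")
    truth_mask <- rasterize_polygon(truth, c(h, w))
    noise <- matrix(stats::rnorm(h * w), h, w)
    noise <- gaussian_blur(noise, 4)
    noise <- noise / stats::sd(noise) * spec$background_texture_sd
    img <- spec$background_level + noise
    soft <- if (spec$edge_softness > 0)
      gaussian_blur(truth_mask, spec$edge_softness) else truth_mask
    img <- img + spec$contrast * soft
    if (spec$n_holes > 0) {
      sigma_h <- spec$radius / 5
      for (k in seq_len(spec$n_holes)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.5 * spec$radius)
        hx <- center[1] + rad * cos(ang)
        hy <- center[2] + rad * sin(ang)
        gx <- matrix(rep(seq_len(w), each = h), h, w)
        gy <- matrix(rep(seq_len(h), times = w), h, w)
        d2 <- (gx - hx)^2 + (gy - hy)^2
        img <- img - spec$hole_depth * exp(-d2 / (2 * sigma_h^2))
      }
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, truth_mask = truth_mask,
                   truth_contour = truth, spec = spec),
              class = "phantom")
  })
}

#' Loose enclosing contour emulating a manual ROI
#'
#' Takes the convex hull of the truth contour, parameterizes it radially
#' about its centroid at 1-degree steps, and pushes every boundary point
#' outward by `dilation` pixels, yielding a loose curve that strictly
#' encloses the truth mask, as a human operator's rough ROI would.
#'
#' @param truth a closed truth `polyline`.
#' @param dilation outward offset in pixels (> 0).
#' @param shape image dimensions `c(h, w)`; the offset curve must stay
#'   inside.
#' @return a closed `polyline` with `source = "manual"`.
#' @export
make_manual_init <- function(truth, dilation, shape) {
  stopifnot(inherits(truth, "polyline"))
  if (!is.numeric(dilation) || dilation <= 0)
    stop("`dilation` must be > 0", call. = FALSE)
  hull <- hull_polygon(open_vertices(truth))
  ctr <- polygon_centroid(hull)
  edges <- polyline_edges(polyline(hull, "manual"))
  theta <- (0:359) * pi / 180
  pts <- t(vapply(theta, function(a) {
    d <- c(cos(a), sin(a))
    hit <- ray_polyline_intersections(ctr, d, edges)
    r <- if (length(hit$t)) max(hit$t) else 0
    ctr + (r + dilation) * d
  }, numeric(2)))
  colnames(pts) <- c("x", "y")
  if (any(pts[, 1] < 1 | pts[, 1] > shape[2] |
          pts[, 2] < 1 | pts[, 2] > shape[1]))
    stop("offset contour exits the image", call. = FALSE)
  polyline(pts, source = "manual")
}
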