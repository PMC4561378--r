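# Iso-level decomposition of the smoothed image: ordered thresholds,
# sub-level region boundaries, their nesting forest, and the dense nested
# band that serves as the search space for the initial contour.

#' Equally spaced threshold set
#'
#' Builds partition weights `w_k = k / n_levels` and threshold values
#' `t_k = I_max * w_k`. Thresholds below the image minimum are dropped with
#' a warning so that the returned set satisfies `t_1 >= I_min`.
#'
#' @param img numeric matrix.
#' @param n_levels number of levels N (>= 2).
#' @return a `threshold_set`: list with `weights`, `values`, `n_levels`.
#' @export
compute_thresholds <- function(img, n_levels = 24) {
  check_image(img)
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  imax <- max(img); imin <- min(img)
  if (imax <= imin)
    stop("degenerate image: I_max equals I_min, no thresholds exist",
         call. = FALSE)
  w <- seq_len(n_levels) / n_levels
  t <- imax * w
  keep <- t >= imin
  if (any(!keep)) {
    warning(sprintf("%d threshold(s) below I_min = %g dropped", sum(!keep),
                    imin), call. = FALSE)
    w <- w[keep]; t <- t[keep]
  }
  structure(list(weights = w, values = t, n_levels = length(t)),
            class = "threshold_set")
}

#' Iso-level contour map with nesting forest
#'
#' For each threshold `t_i`, the boundaries of the sub-level region
#' `R(t_i) = {(x, y) | I(x, y) <= t_i}` are extracted by marching squares
#' at level `t_i` (sub-pixel coordinates retained). The image is framed by
#' a one-pixel super-maximal border first so every boundary closes. Nesting
#' is established by point-in-polygon containment: the parent of a contour
#' is the smallest-area contour strictly enclosing it.
#'
#' @param img numeric matrix.
#' @param thresholds a [compute_thresholds()] result.
#' @param min_vertices contours with fewer vertices are discarded.
#' @param min_area contours enclosing less than this area (px^2) are
#'   discarded: residual background texture crosses mid-range thresholds
#'   in many small closed wiggles that are not candidate mass boundaries,
#'   and dropping them keeps the nesting graph tractable.
#' @return an `iso_level_map`: list of contour records (`id`, `level`,
#'   `xy` polyline, `area`, `parent`) plus the threshold set.
#' @export
iso_level_map <- function(img, thresholds, min_vertices = 8, min_area = 64) {
  check_image(img)
  stopifnot(inherits(thresholds, "threshold_set"))
  h <- nrow(img); w <- ncol(img)
  pad_val <- max(img) + 0.05
  padded <- matrix(pad_val, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- img
  contours <- list()
  for (t in thresholds$values) {
    cls <- grDevices::contourLines(seq_len(h + 2), seq_len(w + 2), padded,
                                   levels = t)
    for (cl in cls) {
      # contourLines' x follows dim 1 (rows, our y); y follows columns.
      xy <- cbind(x = cl$y - 1, y = cl$x - 1)
      if (nrow(xy) < min_vertices) next
      # contours produced by the super-maximal frame run between the pad
      # ring (coordinate 0 / n+1) and the first pixel row/column, i.e.
      # outside the pixel grid; they are padding artifacts, not iso-level
      # boundaries of the image itself
      outside <- mean(xy[, 1] < 1 | xy[, 1] > w | xy[, 2] < 1 | xy[, 2] > h)
      if (outside > 0.25) next
      a <- polygon_area(xy)
      if (a < min_area) next
      pl <- polyline(xy, source = "iso")
      contours[[length(contours) + 1L]] <-
        list(id = length(contours) + 1L, level = t, xy = pl,
             area = a, parent = NA_integer_)
    }
  }
  # nesting: parent = smallest strictly larger contour containing a
  # representative vertex (sub-pixel coordinates make this stable)
  n <- length(contours)
  if (n > 1) {
    areas <- vapply(contours, `[[`, numeric(1), "area")
    verts <- lapply(contours, function(cc) open_vertices(cc$xy))
    bbox <- t(vapply(verts, function(v)
      c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2])), numeric(4)))
    ord <- order(areas)
    for (ii in seq_len(n)) {
      i <- ord[ii]
      rep_pt <- verts[[i]][1, ]
      for (jj in seq_len(n)) {
        j <- ord[jj]
        if (areas[j] <= areas[i] || j == i) next
        if (rep_pt[1] < bbox[j, 1] || rep_pt[1] > bbox[j, 2] ||
            rep_pt[2] < bbox[j, 3] || rep_pt[2] > bbox[j, 4]) next
        v <- verts[[j]]
        if (point_in_polygon(rep_pt[1], rep_pt[2], v[, 1], v[, 2])) {
          contours[[i]]$parent <- j
          break
        }
      }
    }
  }
  structure(list(contours = contours, thresholds = thresholds,
                 shape = c(h, w)),
            class = "iso_level_map")
}

# All maximal root-to-leaf chains of the nesting forest, ordered outer to
# inner.
nesting_chains <- function(map) {
  contours <- map$contours
  n <- length(contours)
  if (n == 0) return(list())
  parents <- vapply(contours, function(cc) {
    if (is.na(cc$parent)) NA_integer_ else as.integer(cc$parent)
  }, integer(1))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parents[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  leaves <- which(!seq_len(n) %in% parents[!is.na(parents)])
  chains <- lapply(leaves, function(leaf) {
    chain <- leaf
    while (!is.na(parents[chain[1]])) chain <- c(parents[chain[1]], chain)
    chain
  })
  # keep only maximal chains (drop chains that are prefixes of longer ones)
  chains[order(-lengths(chains))]
}

#' Extract the dense nested search band
#'
#' Identifies the region where iso-level contours concentrate: the band of
#' consecutively nested contours whose inter-contour spacing is small.
#' Each root-to-leaf chain of the nesting forest is parameterized by the
#' mean radius of its contours about the innermost contour's centroid. A
#' chain qualifies only if its median consecutive gap is at most
#' `max_spacing` pixels (a uniformly sparse chain - e.g. the equally
#' spaced contours of a linear intensity ramp - is not a boundary
#' structure); within qualifying chains, maximal runs of consecutive gaps
#' `<= max_spacing` with at least `min_run` contours are band candidates.
#' Among candidates the one whose outermost contour encloses the largest
#' area wins (the base contour delineating the mass, rather than a dense
#' structure around an interior low-signal area), with ties broken toward
#' the longer run.
#'
#' @param map an [iso_level_map()].
#' @param min_run minimum number of contours in the band.
#' @param max_spacing density cap in pixels for consecutive contour
#'   spacing.
#' @return a `search_band`: member contour records (outer to inner),
#'   innermost contour id, binary band mask (morphological closing of the
#'   member outlines), and the full chain used.
#' @export
extract_search_band <- function(map, min_run = 4, max_spacing = 5) {
  stopifnot(inherits(map, "iso_level_map"))
  if (min_run < 2) stop("`min_run` must be >= 2", call. = FALSE)
  chains <- nesting_chains(map)
  best <- NULL
  for (chain in chains) {
    if (length(chain) < min_run) next
    inner <- chain[length(chain)]
    ctr <- polygon_centroid(map$contours[[inner]]$xy)
    radii <- vapply(chain, function(i) {
      v <- open_vertices(map$contours[[i]]$xy)
      mean(sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2))
    }, numeric(1))
    gaps <- abs(diff(radii))
    if (!length(gaps) || stats::median(gaps) > max_spacing) next
    ok <- gaps <= max_spacing
    r <- rle(ok)
    if (!any(r$values)) next
    lens <- r$lengths[r$values]
    pos <- (cumsum(r$lengths) - r$lengths + 1)[r$values]
    for (k in seq_along(lens)) {
      run_len <- lens[k] + 1L   # lens[k] dense gaps span lens[k]+1 contours
      if (run_len < min_run) next
      idx <- chain[pos[k]:(pos[k] + lens[k])]
      outer_area <- map$contours[[idx[1]]]$area
      if (is.null(best) || outer_area > best$outer_area ||
          (outer_area == best$outer_area && run_len > best$run_len))
        best <- list(ids = idx, outer_area = outer_area,
                     run_len = run_len, chain = chain)
    }
  }
  if (is.null(best))
    stop("search band not found: no dense nested chain of length >= ",
         min_run, call. = FALSE)
  members <- map$contours[best$ids]
  outline <- rasterize_outline(lapply(members, `[[`, "xy"), map$shape)
  band_mask <- EBImage::closing(outline, EBImage::makeBrush(5, "disc"))
  band_mask <- matrix(as.numeric(band_mask > 0), map$shape[1], map$shape[2])
  structure(list(members = members,
                 innermost_id = best$ids[length(best$ids)],
                 band_mask = band_mask,
                 chain_ids = best$chain,
                 member_ids = best$ids,
                 shape = map$shape),
            class = "search_band")
}
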