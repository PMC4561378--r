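# Level-set evolution: the piecewise-constant two-phase (Chan-Vese) model
# and the selective local/global signed-pressure-force (SBGFRLS) model.
# Both are deterministic explicit iterations on the full domain.

#' Chan-Vese evolution parameters
#'
#' @param mu length (curvature) weight, >= 0.
#' @param nu area weight, >= 0; 0 by default.
#' @param lam1,lam2 positive foreground/background variance weights.
#' @param eps Heaviside/Dirac regularization width (in units of phi).
#' @param dt explicit time step.
#' @param max_iters iteration cap.
#' @param tol stopping tolerance: relative change of the zero-level mask
#'   over a `patience`-iteration window, in units of the current mask area.
#' @param patience length (iterations) of the stopping window; it must
#'   exceed the silent plateau after a signed-distance reset (about 20
#'   iterations at these defaults), during which no pixel changes sign
#'   even though the contour is still being driven.
#' @param min_iters warm-up iterations before the stopping rule may fire
#'   (the regularized Dirac makes the first sign flips late, so early
#'   iterations can look stationary while the force is still large).
#' @param reinit_every period (iterations) of the signed-distance reset of
#'   phi; 0 disables it.
#' @return validated `chan_vese_params` list.
#' @export
chan_vese_params <- function(mu = 0.2, nu = 0, lam1 = 2.5, lam2 = 1,
                             eps = 1, dt = 1, max_iters = 500,
                             tol = 1e-3, patience = 50, min_iters = 60,
                             reinit_every = 50) {
  if (mu < 0 || nu < 0) stop("`mu` and `nu` must be >= 0", call. = FALSE)
  if (lam1 <= 0 || lam2 <= 0) stop("`lam1`, `lam2` must be > 0", call. = FALSE)
  check_scalar(eps, "eps"); check_scalar(dt, "dt"); check_scalar(tol, "tol")
  structure(list(mu = mu, nu = nu, lam1 = lam1, lam2 = lam2, eps = eps,
                 dt = dt, max_iters = as.integer(max_iters), tol = tol,
                 patience = as.integer(patience),
                 min_iters = as.integer(min_iters),
                 reinit_every = as.integer(reinit_every)),
            class = "chan_vese_params")
}

#' SBGFRLS (signed pressure force) evolution parameters
#'
#' @param alpha balloon weight; positive values expand the contour over
#'   regions brighter than the mean of the two region means.
#' @param sigma_g Gaussian regularization std (pixels) applied to phi each
#'   iteration.
#' @param dt explicit time step.
#' @param max_iters iteration cap.
#' @param tol,patience,min_iters stopping rule as in [chan_vese_params()];
#'   the SBGFRLS update moves fast, so its warm-up is short.
#' @return validated `spf_params` list.
#' @export
spf_params <- function(alpha = 5, sigma_g = 1, dt = 1, max_iters = 300,
                       tol = 1e-3, patience = 10, min_iters = 15) {
  if (alpha == 0) stop("`alpha` must be non-zero", call. = FALSE)
  check_scalar(sigma_g, "sigma_g"); check_scalar(dt, "dt")
  structure(list(alpha = alpha, sigma_g = sigma_g, dt = dt,
                 max_iters = as.integer(max_iters), tol = tol,
                 patience = as.integer(patience),
                 min_iters = as.integer(min_iters)),
            class = "spf_params")
}

signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  inside <- EBImage::distmap(m)
  outside <- EBImage::distmap(1 - m)
  as.matrix(inside) - as.matrix(outside)
}

#' Initialize a level-set field from a contour
#'
#' Rasterizes the closed contour and returns the signed Euclidean distance
#' to its boundary, positive inside.
#'
#' @param contour a closed `polyline` (e.g. [profile_to_contour()] or
#'   [manual_contour()]).
#' @param shape image dimensions `c(h, w)`.
#' @return numeric matrix `phi` with both signs present.
#' @export
init_levelset <- function(contour, shape) {
  stopifnot(inherits(contour, "polyline"))
  v <- open_vertices(contour)
  if (any(v[, 1] < 1 | v[, 1] > shape[2] | v[, 2] < 1 | v[, 2] > shape[1]))
    stop("contour extends outside the image", call. = FALSE)
  mask <- rasterize_polygon(contour, shape)
  if (sum(mask) == 0 || sum(mask) == length(mask))
    stop("contour rasterization gives an empty or full mask", call. = FALSE)
  signed_distance(mask)
}

heaviside_eps <- function(z, eps) 0.5 * (1 + (2 / pi) * atan(z / eps))
dirac_eps <- function(z, eps) (1 / pi) * eps / (eps^2 + z^2)

#' Region means inside and outside the contour
#'
#' `c1` and `c2` are the Heaviside-weighted mean intensities of the regions
#' where `phi > 0` and `phi < 0`, using the regularized Heaviside
#' `H_eps(z) = (1 + (2/pi) atan(z/eps)) / 2`.
#'
#' @param img numeric matrix.
#' @param phi level-set field, same shape.
#' @param eps regularization width.
#' @return a `region_stats` list with `c1`, `c2`.
#' @export
region_means <- function(img, phi, eps = 1) {
  check_image(img); check_scalar(eps, "eps")
  if (!identical(dim(img), dim(phi)))
    stop("`img` and `phi` shapes differ", call. = FALSE)
  H <- heaviside_eps(phi, eps)
  sH <- sum(H); sHc <- sum(1 - H)
  if (sH <= 0 || sHc <= 0)
    stop("degenerate partition: one region is empty", call. = FALSE)
  structure(list(c1 = sum(img * H) / sH, c2 = sum(img * (1 - H)) / sHc),
            class = "region_stats")
}

curvature <- function(phi) {
  gx <- grad_x(phi); gy <- grad_y(phi)
  nrm <- sqrt(gx^2 + gy^2 + 1e-8)
  divergence(gx / nrm, gy / nrm)
}

check_phi <- function(phi, it, dt) {
  if (!all(is.finite(phi)))
    stop(sprintf("level set became non-finite at iteration %d (dt = %g)",
                 it, dt), call. = FALSE)
  pos <- any(phi > 0); neg <- any(phi < 0)
  if (!pos || !neg)
    stop(sprintf("contour vanished at iteration %d", it), call. = FALSE)
  invisible(TRUE)
}

evolve_result <- function(phi, stats, log, converged, iterations) {
  structure(list(phi = phi, stats = stats, log = log,
                 converged = converged, iterations = iterations),
            class = "levelset_result")
}

#' Chan-Vese level-set evolution
#'
#' Explicit iteration of the two-phase piecewise-constant gradient flow
#' `phi_t = delta_eps(phi) * (mu * curvature - nu - lam1 (I - c1)^2 +
#' lam2 (I - c2)^2)`, with the region means `c1`, `c2` recomputed every
#' iteration. Stops once the zero-level mask differs from the mask
#' `patience` iterations earlier by less than `tol` (relative to the
#' current mask area), after a `min_iters` warm-up, or at `max_iters`.
#' Optionally resets phi to a signed distance function periodically.
#' Statistics and updates run on the full domain.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param phi0 initial level-set field (see [init_levelset()]).
#' @param params a [chan_vese_params()] bundle.
#' @return a `levelset_result`: final `phi`, final `region_stats`, an
#'   iteration `log` data frame, `converged`, `iterations`.
#' @export
evolve_chan_vese <- function(img, phi0, params = chan_vese_params()) {
  check_image(img)
  stopifnot(inherits(params, "chan_vese_params"))
  if (!identical(dim(img), dim(phi0)))
    stop("`img` and `phi0` shapes differ", call. = FALSE)
  phi <- phi0
  check_phi(phi, 0L, params$dt)
  window <- vector("list", params$patience)
  log <- vector("list", params$max_iters)
  stats <- NULL
  it <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iters)) {
    stats <- region_means(img, phi, params$eps)
    force_field <- params$mu * curvature(phi) - params$nu -
      params$lam1 * (img - stats$c1)^2 + params$lam2 * (img - stats$c2)^2
    phi <- phi + params$dt * dirac_eps(phi, params$eps) * force_field
    check_phi(phi, it, params$dt)
    if (params$reinit_every > 0 && it %% params$reinit_every == 0)
      phi <- signed_distance(phi > 0)
    mask <- phi > 0
    slot <- (it - 1L) %% params$patience + 1L
    ref <- window[[slot]]   # mask from `patience` iterations ago
    change <- if (is.null(ref)) NA_real_ else
      sum(mask != ref) / max(1, sum(mask))
    window[[slot]] <- mask
    log[[it]] <- c(iter = it, c1 = stats$c1, c2 = stats$c2,
                   area = sum(mask), change = change)
    if (it >= params$min_iters && !is.na(change) && change < params$tol) {
      converged <- TRUE
      break
    }
  }
  stats <- region_means(img, phi, params$eps)
  evolve_result(phi, stats, as.data.frame(do.call(rbind, log[seq_len(it)])),
                converged, it)
}

#' Signed pressure force map
#'
#' `spf = (I - (c1 + c2)/2) / max |I - (c1 + c2)/2|`; values lie in
#' \[-1, 1\] and are positive exactly where the intensity exceeds the mean
#' of the two region means.
#'
#' @param img numeric matrix.
#' @param stats a `region_stats` with `c1`, `c2`.
#' @return matrix in \[-1, 1\] with `max(abs(.)) == 1`.
#' @export
spf_map <- function(img, stats) {
  check_image(img)
  dev <- img - (stats$c1 + stats$c2) / 2
  den <- max(abs(dev))
  if (den <= 0)
    stop("degenerate signed pressure force: image equals (c1 + c2)/2 everywhere",
         call. = FALSE)
  dev / den
}

#' Selective local/global (SBGFRLS) level-set evolution
#'
#' Iterates `phi <- phi + dt * alpha * spf * |grad phi|`, then penalizes
#' phi to be binary (sign projection to +/-1) and regularizes it with a
#' Gaussian kernel of std `sigma_g`. Region means are recomputed from the
#' current sign of phi each iteration. Stopping as in
#' [evolve_chan_vese()].
#'
#' @param img numeric matrix in \[0, 1\].
#' @param phi0 initial level-set field.
#' @param params an [spf_params()] bundle.
#' @return a `levelset_result`.
#' @export
evolve_sbgfrls <- function(img, phi0, params = spf_params()) {
  check_image(img)
  stopifnot(inherits(params, "spf_params"))
  if (!identical(dim(img), dim(phi0)))
    stop("`img` and `phi0` shapes differ", call. = FALSE)
  phi <- phi0
  check_phi(phi, 0L, params$dt)
  window <- vector("list", params$patience)
  log <- vector("list", params$max_iters)
  stats <- NULL
  it <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iters)) {
    stats <- region_means(img, phi, eps = 1e-6)   # effectively hard means
    spf <- spf_map(img, stats)
    gn <- sqrt(grad_x(phi)^2 + grad_y(phi)^2)
    phi <- phi + params$dt * params$alpha * spf * gn
    check_phi(phi, it, params$dt)
    phi <- ifelse(phi > 0, 1, -1)
    phi <- gaussian_blur(phi, params$sigma_g)
    check_phi(phi, it, params$dt)
    mask <- phi > 0
    slot <- (it - 1L) %% params$patience + 1L
    ref <- window[[slot]]
    change <- if (is.null(ref)) NA_real_ else
      sum(mask != ref) / max(1, sum(mask))
    window[[slot]] <- mask
    log[[it]] <- c(iter = it, c1 = stats$c1, c2 = stats$c2,
                   area = sum(mask), change = change)
    if (it >= params$min_iters && !is.na(change) && change < params$tol) {
      converged <- TRUE
      break
    }
  }
  stats <- region_means(img, phi, eps = 1e-6)
  evolve_result(phi, stats, as.data.frame(do.call(rbind, log[seq_len(it)])),
                converged, it)
}

#' Binary mask from a level-set field
#'
#' Thresholds at `phi > 0`, keeps the largest 4-connected component, and
#' optionally fills interior holes.
#'
#' @param phi level-set field.
#' @param fill_holes fill interior holes of the retained component.
#' @return binary matrix (0/1).
#' @export
mask_from_levelset <- function(phi, fill_holes = FALSE) {
  mask <- matrix(as.numeric(phi > 0), nrow(phi), ncol(phi))
  if (sum(mask) == 0) stop("empty mask: no positive phi", call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  mask <- matrix(as.numeric(lab == keep), nrow(phi), ncol(phi))
  if (fill_holes) mask <- as.matrix(EBImage::fillHull(mask))
  mask
}
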