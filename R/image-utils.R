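# Low-level raster utilities shared by all modules.
#
# Convention: an image is a plain numeric matrix with img[y, x]
# (row = y, column = x), pixel centers at integer coordinates, 1-based,
# origin at the top-left. Intensities live in [0, 1].

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 3 || ncol(img) < 3)
    stop(sprintf("`%s` must be at least 3 x 3 pixels", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

check_scalar <- function(x, arg, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0))
    stop(sprintf("`%s` must be a %s finite scalar", arg,
                 if (positive) "positive" else "single"), call. = FALSE)
  invisible(x)
}

#' Rescale an image to the unit interval
#'
#' Divides by `by` when given (e.g. the dtype maximum of an integer image),
#' otherwise maps the observed range linearly onto \[0, 1\].
#'
#' @param img numeric matrix.
#' @param by optional positive divisor; when supplied values are divided by
#'   it and clipped to \[0, 1\].
#' @return numeric matrix in \[0, 1\].
#' @export
rescale_unit <- function(img, by = NULL) {
  check_image(img)
  if (!is.null(by)) {
    check_scalar(by, "by")
    return(pmin(pmax(img / by, 0), 1))
  }
  rng <- range(img)
  if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img - rng[1]
}

# Neighbor shifts with reflective (Neumann) boundaries: the out-of-range
# neighbor is the edge pixel itself, so differences vanish across borders
# and constant images stay exact fixed points of the PDEs.
shift_xp <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]
shift_xm <- function(m) m[, c(1, 1:(ncol(m) - 1)), drop = FALSE]
shift_yp <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]
shift_ym <- function(m) m[c(1, 1:(nrow(m) - 1)), , drop = FALSE]

# Central differences; unit pixel spacing.
grad_x <- function(m) (shift_xp(m) - shift_xm(m)) / 2
grad_y <- function(m) (shift_yp(m) - shift_ym(m)) / 2

divergence <- function(p, q) grad_x(p) + grad_y(q)

#' Gradient magnitude by central differences
#'
#' @param img numeric matrix.
#' @return matrix of `sqrt(gx^2 + gy^2)`, reflective boundaries.
#' @export
gradient_magnitude <- function(img) {
  check_image(img)
  sqrt(grad_x(img)^2 + grad_y(img)^2)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian convolution with symmetric (mirror) padding.
gaussian_blur <- function(img, sigma) {
  check_scalar(sigma, "sigma")
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  pad_idx <- function(n) {
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    pmin(pmax(idx, 1L), n)
  }
  p <- img[pad_idx(h), ]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[i:(i + h - 1L), , drop = FALSE]
  p <- out[, pad_idx(w)]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[, i:(i + w - 1L), drop = FALSE]
  out
}

# Bilinear sampling of a field at continuous (x, y); clamped at borders.
bilinear_sample <- function(field, x, y) {
  h <- nrow(field); w <- ncol(field)
  x <- pmin(pmax(x, 1), w); y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * field[i00] + fx * field[i01]) +
    fy * ((1 - fx) * field[i10] + fx * field[i11])
}

# Evaluate a block of code with a temporarily seeded RNG, restoring any
# pre-existing global state afterwards (no global side effects).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
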