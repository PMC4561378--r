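# Readers and writers: grayscale PNG/TIFF images, contour CSV polylines,
# descriptor CSV rows, run configuration files.

#' Load a grayscale image
#'
#' Reads PNG or TIFF (8- or 16-bit); color images are averaged to one
#' channel. Both readers return values already scaled to \[0, 1\] by the
#' dtype maximum. The result is an image matrix `img[y, x]`.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix in \[0, 1\].
#' @export
load_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])],
                                          c(1, 2), mean)
  img <- pmin(pmax(arr, 0), 1)
  check_image(img)
  img
}

#' Write a grayscale image
#'
#' @param img matrix in \[0, 1\].
#' @param path output path (.png, .tif or .tiff).
#' @return invisibly, `path`.
#' @export
write_gray_image <- function(img, path) {
  check_image(img)
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask binary matrix.
#' @param path output .png path.
#' @return invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path .png path; any value > 0.5 is foreground.
#' @return binary matrix (0/1).
#' @export
read_mask_png <- function(path) {
  img <- load_gray_image(path)
  matrix(as.numeric(img > 0.5), nrow(img), ncol(img))
}

#' Read a contour from CSV
#'
#' Expects a header containing `x` and `y` columns and at least 3 rows;
#' extra columns are ignored with a warning. Malformed rows raise a parse
#' error naming the line.
#'
#' @param path CSV path.
#' @return a closed `polyline` (source `"manual"`).
#' @export
read_contour_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read contour: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  if (!all(c("x", "y") %in% names(df)))
    stop("contour CSV must have columns `x` and `y`", call. = FALSE)
  extra <- setdiff(names(df), c("x", "y", "contour"))
  if (length(extra))
    warning("ignoring extra contour CSV columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop(sprintf("malformed contour row at line %d", bad[1] + 1L),
         call. = FALSE)
  if (nrow(df) < 3)
    stop("a contour needs at least 3 vertices", call. = FALSE)
  manual_contour(cbind(x = xs, y = ys))
}

#' Write a contour to CSV
#'
#' One `x,y` row per vertex (closing vertex omitted), plus a `contour` id
#' column for multi-contour files.
#'
#' @param contour a `polyline` or list of polylines.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_contour_csv <- function(contour, path) {
  polys <- if (inherits(contour, "polyline")) list(contour) else contour
  rows <- do.call(rbind, lapply(seq_along(polys), function(i) {
    v <- open_vertices(polys[[i]])
    data.frame(x = v[, 1], y = v[, 2], contour = i)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a shape-descriptor bundle as a one-row CSV
#'
#' Columns: area, F1, F2, F3, SC, SR, FD_1..FD_k.
#'
#' @param desc a [describe_mask()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_descriptors_csv <- function(desc, path) {
  stopifnot(inherits(desc, "shape_descriptors"))
  row <- c(area = desc$area, F1 = desc$F1, F2 = desc$F2, F3 = desc$F3,
           SC = desc$SC, SR = desc$SR, desc$FD)
  df <- as.data.frame(as.list(row), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normalize and validate a run configuration
#'
#' Fills defaults for any omitted field and validates the rest; the result
#' round-trips through [write_run_config()] / [read_run_config()].
#'
#' @param config named list; recognized fields: `input`, `out_dir`,
#'   `model`, `tv_lam`, `n_levels`, `min_run`, `m`, `n_sigma`,
#'   `manual_contour`.
#' @return validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  defaults <- list(input = NULL, out_dir = "mammoseg_out",
                   model = "chanvese", tv_lam = 0.05, n_levels = 24L,
                   min_run = 4L, m = 360L, n_sigma = 1,
                   manual_contour = NULL)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (!cfg$model %in% c("chanvese", "spf"))
    stop("`model` must be 'chanvese' or 'spf'", call. = FALSE)
  if (!cfg$n_sigma %in% c(1, 2))
    stop("`n_sigma` must be 1 or 2", call. = FALSE)
  if (cfg$tv_lam < 0) stop("`tv_lam` must be >= 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}
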