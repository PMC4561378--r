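# Pairwise segmentation comparison and cohort-level agreement statistics.

#' Jaccard similarity coefficient of two binary masks
#'
#' Intersection over union of the foregrounds; 1 for identical masks.
#'
#' @param maskX,maskY binary matrices of equal shape.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(maskX, maskY) {
  if (!identical(dim(maskX), dim(maskY)))
    stop("masks must have the same shape", call. = FALSE)
  a <- maskX > 0; b <- maskY > 0
  u <- sum(a | b)
  if (u == 0) stop("both masks are empty: Jaccard undefined", call. = FALSE)
  sum(a & b) / u
}

#' Percentage difference of two descriptor values
#'
#' `|b - a| / mean(a, b) * 100` by default; set `signed = TRUE` for the
#' signed version `(b - a) / mean(a, b) * 100`. Magnitudes are the
#' conventional way these differences are tabulated.
#'
#' @param a,b scalar descriptor values with a positive average.
#' @param signed keep the sign of `b - a`.
#' @return percentage (scalar).
#' @export
pct_diff <- function(a, b, signed = FALSE) {
  avg <- (a + b) / 2
  if (avg <= 0)
    stop("percentage difference undefined: average is not positive",
         call. = FALSE)
  d <- (b - a) / avg * 100
  if (signed) d else abs(d)
}

#' Euclidean distance between two Fourier-descriptor vectors
#'
#' @param fdX,fdY numeric vectors of length 60.
#' @return non-negative scalar.
#' @export
df_distance <- function(fdX, fdY) {
  if (length(fdX) != 60 || length(fdY) != 60)
    stop("Fourier descriptor vectors must have length 60", call. = FALSE)
  sqrt(sum((fdY - fdX)^2))
}

#' Bland-Altman agreement of two measurement series
#'
#' Differences `d = ys - xs`; bias is their mean, the 95% limits of
#' agreement are `bias +/- 1.96 * sd(d)` (sample standard deviation), and
#' `outside` counts points beyond the limits.
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`, `outside`,
#'   `means`, `diffs`.
#' @export
bland_altman <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3)
    stop("need equal-length series of at least 3 values", call. = FALSE)
  d <- ys - xs
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  list(bias = bias, loa_low = lo, loa_high = hi, sd = s,
       outside = sum(d < lo | d > hi),
       means = (xs + ys) / 2, diffs = d)
}

#' Pearson correlation and least-squares regression
#'
#' Pearson `r` between `xs` and `ys`, the least-squares slope of `ys` on
#' `xs`, and the two-sided p-value for `r` from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param xs,ys numeric vectors of equal length >= 3; `xs` must vary.
#' @return list with `r`, `slope`, `intercept`, `p`, `n`.
#' @export
pearson_regression <- function(xs, ys) {
  n <- length(xs)
  if (length(ys) != n || n < 3)
    stop("need equal-length series of at least 3 values", call. = FALSE)
  if (stats::sd(xs) == 0)
    stop("`xs` has zero variance", call. = FALSE)
  r <- stats::cor(xs, ys)
  fit <- stats::lm.fit(cbind(1, xs), ys)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), p = p, n = n)
}

#' Pairwise comparison of two segmentations
#'
#' Bundles the Jaccard overlap, the Fourier-descriptor distance and the
#' percentage differences of F1, F2, F3, SC and SR between the
#' segmentation from one initialization (`X`, e.g. manual) and another
#' (`Y`, e.g. proposed).
#'
#' @param maskX,maskY binary masks of equal shape.
#' @param descX,descY optional [describe_mask()] bundles; computed when
#'   `NULL`.
#' @param signed report signed percentage differences.
#' @return a `pair_comparison` list: `jsc`, `df`, `pdF1`, `pdF2`, `pdF3`,
#'   `pdSC`, `pdSR`, plus both descriptor bundles.
#' @export
compare_pair <- function(maskX, maskY, descX = NULL, descY = NULL,
                         signed = FALSE) {
  if (is.null(descX)) descX <- describe_mask(maskX)
  if (is.null(descY)) descY <- describe_mask(maskY)
  structure(list(
    jsc = jaccard(maskX, maskY),
    df = df_distance(descX$FD, descY$FD),
    pdF1 = pct_diff(descX$F1, descY$F1, signed),
    pdF2 = pct_diff(descX$F2, descY$F2, signed),
    pdF3 = pct_diff(descX$F3, descY$F3, signed),
    pdSC = pct_diff(descX$SC, descY$SC, signed),
    pdSR = pct_diff(descX$SR, descY$SR, signed),
    descX = descX, descY = descY),
    class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("JSC=%.3f  DF=%.4f\n", x$jsc, x$df))
  cat(sprintf("%%dF1=%.1f  %%dF2=%.1f  %%dF3=%.1f  %%dSC=%.1f  %%dSR=%.1f\n",
              x$pdF1, x$pdF2, x$pdF3, x$pdSC, x$pdSR))
  invisible(x)
}

#' Cohort agreement report across descriptor pairs
#'
#' For each descriptor column pair `<name>_x` / `<name>_y` in `table`,
#' computes Bland-Altman bias and limits of agreement plus Pearson
#' regression of y on x.
#'
#' @param table data frame with paired descriptor columns (suffixes `_x`,
#'   `_y`).
#' @param descriptors base names to report on.
#' @return data frame with one row per descriptor: bias, loa, r, slope, p.
#' @export
agreement_report <- function(table,
                             descriptors = c("F1", "F2", "F3", "SC", "SR")) {
  rows <- lapply(descriptors, function(d) {
    xs <- table[[paste0(d, "_x")]]
    ys <- table[[paste0(d, "_y")]]
    if (is.null(xs) || is.null(ys)) return(NULL)
    ba <- bland_altman(xs, ys)
    pr <- pearson_regression(xs, ys)
    data.frame(descriptor = d, bias = ba$bias, loa_low = ba$loa_low,
               loa_high = ba$loa_high, outside = ba$outside,
               r = pr$r, slope = pr$slope, p = pr$p)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
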