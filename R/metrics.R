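## Four agreement metrics between an automatic (A) and a manual (M)
## segmentation: root mean squared contour distance (RMSd), Pearson
## cross-correlation of the mean-removed binary masks (CCC), percent
## area error (PE) and edge error sum (ES).

#' Evenly resample a contour to N points
#'
#' Keeps the points at original indices `round(i * L / N)` for
#' `i = 0..N-1` (ties round half up), preserving order.
#'
#' @param contour data frame with columns `x`, `y`.
#' @param n target number of points, `1 <= n <= nrow(contour)`.
#' @return The decimated contour.
#' @export
resample_even <- function(contour, n) {
  contour <- as.data.frame(contour)
  L <- nrow(contour)
  if (n <= 0) abort_validation("n must be positive")
  if (n > L) abort_validation("cannot resample a contour to more points")
  keep <- floor((0:(n - 1)) * L / n + 0.5) + 1L
  contour[keep, , drop = FALSE]
}

## Rotate a closed contour so that its minimal-(y, x) point comes first,
## and orient it clockwise in image coordinates (positive shoelace sum
## with y growing downward).
canonicalize_contour <- function(contour) {
  contour <- as.data.frame(contour)
  n <- nrow(contour)
  if (n >= 3L) {
    x <- contour$x; y <- contour$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    if (sum(x * yn - xn * y) < 0)
      contour <- contour[rev(seq_len(n)), , drop = FALSE]
  }
  root <- order(contour$y, contour$x)[1]
  idx <- ((root - 1L + 0:(n - 1L)) %% n) + 1L
  out <- contour[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Root mean squared distance between paired contour points
#'
#' Both contours are re-rooted at their minimal-(y, x) point and
#' oriented clockwise; the longer one is evenly decimated to the length
#' N of the shorter; the metric is
#' `sqrt(mean(||p_i^A - p_i^M||^2))` over the index-paired points.
#'
#' @param auto,manual contours (data frames with columns `x`, `y`).
#' @return RMSd in pixels.
#' @export
rmsd_contours <- function(auto, manual) {
  auto <- as.data.frame(auto); manual <- as.data.frame(manual)
  if (nrow(auto) == 0L || nrow(manual) == 0L)
    abort_validation("contours must be non-empty")
  a <- canonicalize_contour(auto)
  m <- canonicalize_contour(manual)
  n <- min(nrow(a), nrow(m))
  a <- resample_even(a, n)
  m <- resample_even(m, n)
  sqrt(mean((a$x - m$x)^2 + (a$y - m$y)^2))
}

#' Cross-correlation coefficient of two masks
#'
#' Pearson correlation of the two mean-removed binary images over all
#' pixels.
#'
#' @param A,M 0/1 masks of identical shape.
#' @return CCC in \[-1, 1\].
#' @export
ccc_masks <- function(A, M) {
  assert_mask(A, "A"); assert_mask(M, "M")
  if (!all(dim(A) == dim(M))) abort_validation("mask shapes differ")
  a <- A - mean(A); m <- M - mean(M)
  da <- sum(a * a); dm <- sum(m * m)
  if (da == 0 || dm == 0)
    abort_undefined("CCC undefined for a constant mask")
  sum(a * m) / sqrt(da * dm)
}

#' Percent area error
#'
#' `PE = 100 * | |A| - |M| | / |M|` with `|X|` the foreground pixel
#' count.
#'
#' @inheritParams ccc_masks
#' @return PE in percent.
#' @export
percent_error <- function(A, M) {
  assert_mask(A, "A"); assert_mask(M, "M")
  if (sum(M) == 0) abort_validation("manual mask is empty")
  100 * abs(sum(A) - sum(M)) / sum(M)
}

#' Edge error sum
#'
#' `ES = 100 * (|A & !M| + |!A & M|) / |M|`: false-positive plus
#' false-negative pixels relative to the manual area.
#'
#' @inheritParams ccc_masks
#' @return ES in percent.
#' @export
error_sum <- function(A, M) {
  assert_mask(A, "A"); assert_mask(M, "M")
  if (!all(dim(A) == dim(M))) abort_validation("mask shapes differ")
  if (sum(M) == 0) abort_validation("manual mask is empty")
  fp <- sum(A == 1 & M == 0)
  fn <- sum(A == 0 & M == 1)
  100 * (fp + fn) / sum(M)
}

#' All four agreement metrics for one mask pair
#'
#' Contours for the RMSd are traced from the largest component of each
#' mask with [extract_contour()].
#'
#' @param auto_mask,manual_mask 0/1 masks of identical shape.
#' @return A list of class `lv_metrics` with `rmsd`, `ccc`, `pe`, `es`
#'   and `n_points` (the common resampled contour length).
#' @export
evaluate_pair <- function(auto_mask, manual_mask) {
  if (!all(dim(auto_mask) == dim(manual_mask)))
    abort_validation("mask shapes differ")
  ca <- extract_contour(largest_component(auto_mask))
  cm <- extract_contour(largest_component(manual_mask))
  structure(list(rmsd = rmsd_contours(ca, cm),
                 ccc = ccc_masks(auto_mask, manual_mask),
                 pe = percent_error(auto_mask, manual_mask),
                 es = error_sum(auto_mask, manual_mask),
                 n_points = min(nrow(ca), nrow(cm))),
            class = "lv_metrics")
}

#' @export
print.lv_metrics <- function(x, ...) {
  cat(sprintf("RMSd %.3f px | CCC %.4f | PE %.2f%% | ES %.2f%% (N = %d)\n",
              x$rmsd, x$ccc, x$pe, x$es, x$n_points))
  invisible(x)
}

#' Aggregate metrics over a set of mask pairs
#'
#' @param auto_masks,manual_masks lists of 0/1 masks, paired by index.
#' @return A data frame with one row per pair plus attributes `mean` and
#'   `sd` (named vectors over the four metrics).
#' @export
evaluate_batch <- function(auto_masks, manual_masks) {
  if (length(auto_masks) != length(manual_masks))
    abort_validation("mask lists must have equal length")
  rows <- lapply(seq_along(auto_masks), function(i) {
    m <- evaluate_pair(auto_masks[[i]], manual_masks[[i]])
    data.frame(pair = i, rmsd = m$rmsd, ccc = m$ccc, pe = m$pe, es = m$es)
  })
  df <- do.call(rbind, rows)
  attr(df, "mean") <- colMeans(df[, c("rmsd", "ccc", "pe", "es")])
  attr(df, "sd") <- vapply(df[, c("rmsd", "ccc", "pe", "es")], sd, numeric(1))
  df
}
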