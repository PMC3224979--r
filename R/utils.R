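## Shared validation helpers, condition classes and morphology kernels.

abort_lv <- function(msg, class) {
  stop(structure(class = c(class, "echolv_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_validation   <- function(msg) abort_lv(msg, "echolv_validation_error")
abort_format       <- function(msg) abort_lv(msg, "echolv_format_error")
abort_config       <- function(msg) abort_lv(msg, "echolv_config_error")
abort_segmentation <- function(msg) abort_lv(msg, "echolv_segmentation_error")
abort_tracking     <- function(msg) abort_lv(msg, "echolv_tracking_error")
abort_undefined    <- function(msg) abort_lv(msg, "echolv_undefined_metric_error")

assert_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    abort_validation(sprintf("%s must be a numeric matrix", what))
  if (any(!is.finite(img)))
    abort_validation(sprintf("%s contains non-finite values", what))
  if (min(img) < 0 || max(img) > 1)
    abort_validation(sprintf("%s intensities must lie in [0, 1]", what))
  invisible(img)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    abort_validation(sprintf("%s must be a numeric or integer matrix", what))
  if (!all(mask %in% c(0, 1)))
    abort_validation(sprintf("%s must be binary (0/1)", what))
  invisible(mask)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Lower median: the ceiling(n/2)-th order statistic, so that for even
## pixel counts the smaller of the two central values is used (a
## deterministic tie rule; at least half of the pixels are >= it).
lower_median <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

## Euclidean disk structuring element: offsets (i, j) with i^2 + j^2 <= r^2,
## as a (2r+1) x (2r+1) 0/1 matrix.  Note this is NOT a filled box: for
## r = 1 it is the 4-neighbour cross.
disk_kernel <- function(r) {
  if (r < 1) abort_validation("structuring element radius must be >= 1")
  d <- 2L * as.integer(r) + 1L
  i <- matrix(rep(-r:r, d), d, d)
  k <- (i^2 + t(i)^2) <= r^2
  storage.mode(k) <- "double"
  k
}

## Grayscale (and binary) morphology on plain matrices via EBImage.
## EBImage uses clamped-neighbourhood semantics at the borders (the
## structuring element is intersected with the image domain).
gray_erode  <- function(img, kern) EBImage::erode(img, kern)
gray_dilate <- function(img, kern) EBImage::dilate(img, kern)
gray_open   <- function(img, kern) gray_dilate(gray_erode(img, kern), kern)
gray_close  <- function(img, kern) gray_erode(gray_dilate(img, kern), kern)

binary_open <- function(mask, kern) {
  m <- gray_open(mask + 0, kern)
  (m > 0.5) + 0
}
binary_close <- function(mask, kern) {
  m <- gray_close(mask + 0, kern)
  (m > 0.5) + 0
}

## Largest 8-connected component of a binary mask (ties broken by the
## component whose first pixel comes first in raster order).
largest_component <- function(mask) {
  lab <- cpp_label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n == 0L) return(mask * 0)
  counts <- tabulate(lab[lab > 0L], nbins = n)
  best <- which.max(counts)
  (lab == best) + 0
}

## Morphological reconstruction by erosion, via duality with the
## compiled reconstruction-by-dilation (requires marker >= mask).
reconstruct_erosion <- function(marker, mask) {
  -cpp_reconstruct_dilation(-marker, -mask)
}
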