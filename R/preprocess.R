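## Five-stage preprocessing chain turning raw noisy echo frames into
## watershed-ready images: ECG-synchronized time averaging, optional
## shift-invariant wavelet denoising, self-reinforcing LoG edge
## enhancement, morphological smoothing, and homotopy modification.

#' Preprocessing configuration
#'
#' @param wavelet_levels number of stationary wavelet decomposition
#'   levels (order-12 Daubechies filters).
#' @param log_sigma Gaussian scale (pixels) of the Laplacian-of-Gaussian
#'   edge-enhancement kernel.
#' @param log_gain gain `alpha` of the LoG sharpening; `alpha = 0` makes
#'   the stage an identity.
#' @param r_open_close radius of the disk used by the first
#'   closing/opening pair of the morphological smoothing stage.
#' @param r_final_close radius of the disk used by the final closing.
#' @param enable_wavelet logical; the wavelet stage is the costliest one
#'   and may be skipped for high-quality input.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(wavelet_levels = 4L, log_sigma = 2.0,
                              log_gain = 1.0, r_open_close = 1L,
                              r_final_close = 3L, enable_wavelet = TRUE) {
  if (wavelet_levels < 1L) abort_validation("wavelet_levels must be >= 1")
  if (log_sigma <= 0) abort_validation("log_sigma must be positive")
  if (log_gain < 0) abort_validation("log_gain must be non-negative")
  if (r_open_close < 1L || r_final_close < 1L)
    abort_validation("structuring element radii must be >= 1")
  structure(list(wavelet_name = "db12",
                 wavelet_levels = as.integer(wavelet_levels),
                 log_sigma = log_sigma, log_gain = log_gain,
                 r_open_close = as.integer(r_open_close),
                 r_final_close = as.integer(r_final_close),
                 enable_wavelet = isTRUE(enable_wavelet)),
            class = "preprocess_config")
}

## Frame indices (1-based into seq$frames) of the two cycles used for
## averaging: cycle 1 = [R1, R2), cycle 2 = [R2, R3) or [R2, end).
cycle_ranges <- function(seq) {
  r <- seq$r_wave_indices
  if (length(r) < 2L)
    abort_validation("two-cycle averaging requires at least two R waves")
  c1 <- (r[1] + 1L):r[2]
  end2 <- if (length(r) >= 3L) r[3] else n_frames(seq)
  if (end2 <= r[2]) abort_validation("second cycle is empty")
  c2 <- (r[2] + 1L):end2
  list(c1 = c1, c2 = c2)
}

#' ECG-synchronized temporal average
#'
#' Pixelwise arithmetic mean of four frames: frames `k` and `k+1` of
#' each of the two consecutive cardiac cycles, with the cycles aligned
#' on their R-wave start frames.  For the last frame of a cycle, `k+1`
#' wraps to the cycle's first frame (cardiac periodicity).  If the
#' second cycle is too short to supply frame `k`, the average falls back
#' to the two frames of cycle 1 alone.
#'
#' @param seq an [echo_sequence()] with at least two R waves.
#' @param k 0-based frame index within the cycle.
#' @return The composite image (numeric matrix in \[0, 1\]).
#' @export
time_average <- function(seq, k) {
  cyc <- cycle_ranges(seq)
  n1 <- length(cyc$c1); n2 <- length(cyc$c2)
  if (k < 0L || k >= n1)
    abort_validation(sprintf("frame index k = %d out of cycle range [0, %d]",
                             k, n1 - 1L))
  idx1 <- cyc$c1[c(k + 1L, (k + 1L) %% n1 + 1L)]           # k and wrapped k+1
  use <- seq$frames[idx1]
  if (k < n2) {
    idx2 <- cyc$c2[c(k + 1L, (k + 1L) %% n2 + 1L)]
    use <- c(use, seq$frames[idx2])
  }
  Reduce(`+`, use) / length(use)
}

#' Shift-invariant wavelet denoising
#'
#' Stationary (undecimated) order-12 Daubechies wavelet transform with
#' soft thresholding of every detail band.  The noise scale `sigma` is
#' estimated from the median absolute deviation of the finest diagonal
#' detail band; each band is then shrunk at the Bayes-adaptive threshold
#' `sigma^2 / sigma_x` with `sigma_x^2` the band's estimated signal
#' variance, which preserves edges far better than the universal
#' threshold in a redundant transform.  Because every convolution in the
#' transform is circular, the operation commutes exactly with integer
#' circular shifts of the input.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param cfg a [preprocess_config()].
#' @return The denoised image, clipped to \[0, 1\].
#' @export
wavelet_denoise <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  J <- cfg$wavelet_levels
  if (min(dim(img)) < 2^J)
    abort_validation(sprintf(
      "image dimensions must be >= 2^%d for %d decomposition levels", J, J))
  w <- swt2(img, J)
  hh1 <- w$detail[[1]]$HH
  sigma <- median(abs(hh1 - median(hh1))) / 0.6745
  for (j in seq_len(J)) {
    for (band in c("LH", "HL", "HH")) {
      d <- w$detail[[j]][[band]]
      sigma_x <- sqrt(max(mean(d^2) - sigma^2, .Machine$double.eps))
      w$detail[[j]][[band]] <- soft_threshold(d, sigma^2 / sigma_x)
    }
  }
  clip01(iswt2(w))
}

## The Laplacian-of-Gaussian splits into two separable terms,
## LoG = Gxx (x) G(y) + G(x) Gyy (y), truncated at 4 sigma.  The
## second-derivative taps are recentred to sum exactly to zero so the
## filter response to a constant image vanishes identically (truncation
## would otherwise leave a tiny residual).
log_filters_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  t <- -r:r
  g <- exp(-t^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  gxx <- (t^2 - sigma^2) / sigma^4 * g
  list(g = g, gxx = gxx - mean(gxx))
}

## Effective 2D LoG kernel (used by tests and documentation).
log_kernel <- function(sigma) {
  f <- log_filters_1d(sigma)
  outer(f$gxx, f$g) + outer(f$g, f$gxx)
}

#' Self-reinforcing Laplacian-of-Gaussian edge enhancement
#'
#' Computes `clip(m - alpha * (LoG_sigma * m))` where `*` is 2D
#' convolution with reflective borders.  Subtracting the LoG response
#' sharpens intensity steps (overshoot on the bright side, undershoot on
#' the dark side), which raises the contrast across the cavity edge and
#' pulls the subsequent watershed dam towards it.
#'
#' @inheritParams wavelet_denoise
#' @return The edge-enhanced image, clipped to \[0, 1\].
#' @export
edge_enhance_log <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  if (cfg$log_gain == 0) return(img)
  f <- log_filters_1d(cfg$log_sigma)
  col_k <- function(v) matrix(v, ncol = 1)
  row_k <- function(v) matrix(v, nrow = 1)
  resp <- cpp_convolve_reflect(cpp_convolve_reflect(img, col_k(f$gxx)),
                               row_k(f$g)) +
          cpp_convolve_reflect(cpp_convolve_reflect(img, col_k(f$g)),
                               row_k(f$gxx))
  clip01(img - cfg$log_gain * resp)
}

#' Morphological smoothing
#'
#' Grayscale closing then opening with a disk of radius `r_open_close`,
#' followed by a closing with a disk of radius `r_final_close`.  Removes
#' isolated single-pixel extrema and small islands/holes that would
#' otherwise seed spurious watershed basins.
#'
#' @inheritParams wavelet_denoise
#' @return The smoothed image.
#' @export
morph_smooth <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  k1 <- disk_kernel(cfg$r_open_close)
  k3 <- disk_kernel(cfg$r_final_close)
  gray_close(gray_open(gray_close(img, k1), k1), k3)
}

#' Homotopy modification (minima imposition)
#'
#' Eliminates every regional minimum lying below the lower-median pixel
#' intensity: the sub-median basins are flooded shut by morphological
#' reconstruction (geodesic erosion of `pmax(img, T)` above `img`), so
#' that the minima of one dark blood pool merge into a single plateau
#' at the threshold while shallower minima above the threshold are left
#' untouched.  The median threshold reflects the assumption that the
#' dark ventricular cavity occupies a large share of the field of view;
#' the merging is what lets the watershed flood each blood pool as one
#' basin instead of shattering it over speckle-induced dimples, while
#' the surviving supra-threshold minima seed the small myocardial
#' regions whose dams confine the ventricle basin at the wall.
#'
#' @param img numeric matrix in \[0, 1\].
#' @return A list with `image` (the homotopy-modified image) and
#'   `markers` (0/1 mask of its regional minima -- the watershed seeds).
#' @export
homotopy_modify <- function(img) {
  assert_image(img)
  thr <- lower_median(as.vector(img))
  if (sum(img <= thr) == 0)
    abort_validation("no pixel at or below the median intensity")
  out <- reconstruct_erosion(pmax(img, thr), img)
  markers <- cpp_regional_minima(out) + 0
  list(image = out, markers = markers)
}

#' Run the full preprocessing chain for one temporal frame
#'
#' Composition: [time_average()] -> [wavelet_denoise()] (if enabled) ->
#' [edge_enhance_log()] -> [morph_smooth()] -> [homotopy_modify()].
#'
#' @param seq an [echo_sequence()].
#' @param k 0-based frame index within cycle 1.
#' @param cfg a [preprocess_config()].
#' @return A list of class `lv_preprocessed` with elements `image` (the
#'   homotopy-modified image fed to the watershed), `markers` (marker
#'   mask), `averaged` (the stage-1 time-averaged image, used later by
#'   the contour correction), and `k`.
#' @export
preprocess_frame <- function(seq, k, cfg = preprocess_config()) {
  avg <- time_average(seq, k)
  x <- avg
  if (cfg$enable_wavelet) x <- wavelet_denoise(x, cfg)
  x <- edge_enhance_log(x, cfg)
  x <- morph_smooth(x, cfg)
  hm <- homotopy_modify(x)
  structure(list(image = hm$image, markers = hm$markers,
                 averaged = avg, k = k),
            class = "lv_preprocessed")
}
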