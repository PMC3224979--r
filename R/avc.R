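## Per-frame ventricular area, the area variation curve (AVC) and the
## area variation fraction (AVF).

#' Ventricular area of one mask
#'
#' Pixel count times pixel area, reported in cm^2.
#'
#' @param mask 0/1 cavity mask.
#' @param pixel_spacing `(dy, dx)` in mm per pixel.
#' @return Area in cm^2.
#' @export
frame_area <- function(mask, pixel_spacing) {
  assert_mask(mask)
  if (any(pixel_spacing <= 0)) abort_validation("pixel spacing must be positive")
  sum(mask) * pixel_spacing[1] * pixel_spacing[2] / 100
}

#' Build the area variation curve
#'
#' One area per segmented frame, at times `frame / frame_rate`; failed
#' frames contribute missing values rather than being dropped.
#'
#' @param results an [segment_sequence()] result (class
#'   `lv_segmentation`) or its `results` list.
#' @param seq the [echo_sequence()] the segmentation was run on.
#' @return A data frame of class `lv_avc` with columns `frame`,
#'   `time_s`, `area_cm2` and attribute `pixel_area_cm2`.
#' @export
build_avc <- function(results, seq) {
  if (inherits(results, "lv_segmentation")) results <- results$results
  if (length(results) == 0L) abort_validation("no segmentation results")
  areas <- vapply(results, function(r) {
    if (isTRUE(r$ok) && !is.null(r$corrected_mask))
      frame_area(r$corrected_mask, seq$pixel_spacing)
    else NA_real_
  }, numeric(1))
  if (all(is.na(areas)))
    abort_validation("every frame failed; no area curve can be built")
  frames <- vapply(results, function(r) r$frame_index, numeric(1))
  df <- data.frame(frame = as.integer(frames),
                   time_s = frames / seq$frame_rate,
                   area_cm2 = areas)
  attr(df, "pixel_area_cm2") <- prod(seq$pixel_spacing) / 100
  class(df) <- c("lv_avc", "data.frame")
  df
}

#' Detect end-diastolic and end-systolic frames
#'
#' End-diastole is the first frame strictly after the R wave with a
#' present area; end-systole is the frame of minimal present area
#' (earliest frame on ties).
#'
#' @param avc an `lv_avc` data frame.
#' @param r_wave_frame 0-based frame index of the R wave.
#' @return A list with `ed_index` and `es_index` (0-based).
#' @export
detect_ed_es <- function(avc, r_wave_frame = 0L) {
  present <- which(!is.na(avc$area_cm2))
  if (length(present) < 2L)
    abort_validation("at least two present areas are required")
  if (r_wave_frame > max(avc$frame))
    abort_validation("R-wave frame beyond the area curve")
  after <- present[avc$frame[present] > r_wave_frame]
  if (length(after) == 0L)
    abort_validation("no segmented frame after the R wave")
  ed <- avc$frame[after[1]]
  es <- avc$frame[present[which.min(avc$area_cm2[present])]]
  list(ed_index = as.integer(ed), es_index = as.integer(es))
}

#' Area variation fraction
#'
#' `AVF = 100 * (A - E) / A` with `A` the end-diastolic and `E` the
#' end-systolic area.
#'
#' @param ed_area end-diastolic area (largest), cm^2.
#' @param es_area end-systolic area (smallest), cm^2.
#' @return AVF in percent.
#' @export
compute_avf <- function(ed_area, es_area) {
  if (ed_area <= 0) abort_validation("end-diastolic area must be positive")
  if (es_area < 0) abort_validation("end-systolic area must be non-negative")
  if (es_area > ed_area)
    abort_validation("end-systolic area exceeds end-diastolic area")
  100 * (ed_area - es_area) / ed_area
}

#' AVF report from an area curve
#'
#' Applies the automatic end-diastole/end-systole detection rule and
#' evaluates the area variation fraction.
#'
#' @inheritParams detect_ed_es
#' @return A list of class `lv_avf` with `avf`, `ed_index`, `es_index`,
#'   `ed_area`, `es_area`.
#' @export
avf_report <- function(avc, r_wave_frame = 0L) {
  idx <- detect_ed_es(avc, r_wave_frame)
  ed_area <- avc$area_cm2[avc$frame == idx$ed_index]
  es_area <- avc$area_cm2[avc$frame == idx$es_index]
  structure(list(avf = compute_avf(ed_area, es_area),
                 ed_index = idx$ed_index, es_index = idx$es_index,
                 ed_area = ed_area, es_area = es_area),
            class = "lv_avf")
}

#' @export
print.lv_avf <- function(x, ...) {
  cat(sprintf("AVF = %.1f%%  (ED frame %d: %.3f cm^2; ES frame %d: %.3f cm^2)\n",
              x$avf, x$ed_index, x$ed_area, x$es_index, x$es_area))
  invisible(x)
}

#' @export
print.lv_avc <- function(x, ...) {
  ok <- sum(!is.na(x$area_cm2))
  cat(sprintf("<lv_avc> %d frames (%d segmented), area %.3f .. %.3f cm^2\n",
              nrow(x), ok, min(x$area_cm2, na.rm = TRUE),
              max(x$area_cm2, na.rm = TRUE)))
  invisible(x)
}

#' Plot an area variation curve
#'
#' @param x an `lv_avc` data frame.
#' @param ... passed on to [plot()].
#' @export
plot.lv_avc <- function(x, ...) {
  plot(x$time_s, x$area_cm2, type = "o", pch = 16,
       xlab = "time (s)", ylab = expression(area ~ (cm^2)),
       main = "Left-ventricular area variation curve", ...)
  miss <- which(is.na(x$area_cm2))
  if (length(miss) > 0)
    points(x$time_s[miss], rep(min(x$area_cm2, na.rm = TRUE), length(miss)),
           pch = 4, col = "red")
  invisible(x)
}
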