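## Reading and writing echo sequences, masks, contours and area curves.
##
## On-disk formats: PNG or TIFF rasters for frames and masks; CSV with
## header "x,y" for contours (0-based integer pixel coordinates); CSV
## with header "frame,time_s,area_cm2" for area curves; a JSON sidecar
## (keys frame_rate_hz, pixel_spacing_mm = [dy, dx], r_wave_indices)
## for acquisition metadata.

#' Construct an echocardiographic frame sequence
#'
#' Bundles an ordered list of grayscale frames with acquisition timing,
#' the pixel spacing and the ECG R-wave frame indices that delimit
#' cardiac cycles.
#'
#' @param frames list of numeric matrices in \[0, 1\], all the same size.
#' @param frame_rate acquisition rate in frames per second.
#' @param pixel_spacing numeric length-2, `(dy, dx)` in mm per pixel.
#' @param r_wave_indices strictly increasing 0-based frame indices of the
#'   ECG R waves (at least two, marking the starts of consecutive cycles).
#' @return An object of class `echo_sequence`.
#' @export
echo_sequence <- function(frames, frame_rate, pixel_spacing, r_wave_indices) {
  if (!is.list(frames) || length(frames) == 0L)
    abort_validation("frames must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_format("all frames must share identical dimensions")
  for (f in frames) assert_image(f, "frame")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    abort_validation("frame_rate must be a positive scalar (Hz)")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 2L ||
      any(pixel_spacing <= 0))
    abort_validation("pixel_spacing must be two positive values (dy, dx) in mm")
  r <- as.integer(r_wave_indices)
  if (length(r) < 2L)
    abort_validation("at least two R-wave indices are required")
  if (any(diff(r) <= 0L))
    abort_validation("r_wave_indices must be strictly increasing")
  if (min(r) < 0L || max(r) > length(frames) - 1L)
    abort_validation("r_wave_indices out of frame range")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_spacing = as.numeric(pixel_spacing),
                 r_wave_indices = r),
            class = "echo_sequence")
}

#' @export
print.echo_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<echo_sequence> %d frames of %dx%d px, %.1f fps, spacing %.3gx%.3g mm\n",
    length(x$frames), d[1], d[2], x$frame_rate,
    x$pixel_spacing[1], x$pixel_spacing[2]))
  cat("  R waves at frames:", paste(x$r_wave_indices, collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(seq) length(seq$frames)

read_frame_file <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", low)) {
    img <- tiff::readTIFF(path)
  } else {
    abort_format(sprintf("unsupported frame format: %s", path))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]   # keep first channel
  img
}

#' Load an echo sequence from disk
#'
#' Frames come either from a directory of lexicographically ordered
#' PNG/TIFF files or from a single multi-frame TIFF; readers rescale
#' 8-bit and 16-bit samples onto \[0, 1\].  Acquisition metadata is read
#' from a JSON sidecar with keys `frame_rate_hz`, `pixel_spacing_mm`
#' (\code{[dy, dx]}) and `r_wave_indices`.
#'
#' @param frames_path directory of frames, or a multi-frame TIFF file.
#' @param metadata_path path to the JSON metadata sidecar.
#' @return An [echo_sequence()].
#' @export
load_sequence <- function(frames_path, metadata_path) {
  meta <- load_metadata(metadata_path)
  if (dir.exists(frames_path)) {
    files <- sort(list.files(frames_path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      abort_format(sprintf("no PNG/TIFF frames found in %s", frames_path))
    frames <- lapply(files, read_frame_file)
  } else if (file.exists(frames_path) &&
             grepl("\\.tiff?$", tolower(frames_path))) {
    frames <- tiff::readTIFF(frames_path, all = TRUE)
    frames <- lapply(frames, function(img) {
      if (length(dim(img)) == 3L) img[, , 1] else img
    })
  } else {
    abort_format(sprintf("frames_path not found: %s", frames_path))
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_format("frames have inconsistent dimensions")
  echo_sequence(frames, meta$frame_rate_hz, meta$pixel_spacing_mm,
                meta$r_wave_indices)
}

load_metadata <- function(path) {
  if (!file.exists(path))
    abort_config(sprintf("metadata file not found: %s", path))
  meta <- jsonlite::fromJSON(path)
  need <- c("frame_rate_hz", "pixel_spacing_mm", "r_wave_indices")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0L)
    abort_config(sprintf("metadata missing keys: %s",
                         paste(missing, collapse = ", ")))
  meta
}

#' Write an echo sequence to a directory of PNG frames plus metadata JSON
#'
#' @param seq an [echo_sequence()].
#' @param dir output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_sequence <- function(seq, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nd <- max(4L, nchar(as.character(n_frames(seq) - 1L)))
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]],
                  file.path(dir, sprintf("frame_%0*d.png", nd, i - 1L)))
  }
  meta <- list(frame_rate_hz = seq$frame_rate,
               pixel_spacing_mm = seq$pixel_spacing,
               r_wave_indices = seq$r_wave_indices)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / load a contour as CSV
#'
#' Contours are ordered closed boundary traces stored as integer 0-based
#' `(x, y)` pixel coordinates, one point per row under a `x,y` header.
#' The round trip `load_contour_csv(write_contour_csv(c))` is the identity.
#'
#' @param contour data frame (or matrix) with columns `x` and `y`.
#' @param path CSV file path.
#' @return `write_contour_csv` returns `path` invisibly;
#'   `load_contour_csv` returns a data frame with integer columns `x`, `y`.
#' @export
write_contour_csv <- function(contour, path) {
  contour <- as.data.frame(contour)
  if (!all(c("x", "y") %in% names(contour)))
    abort_validation("contour must have columns x and y")
  if (nrow(contour) == 0L) abort_validation("contour is empty")
  write.csv(contour[, c("x", "y")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
load_contour_csv <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  raw <- tryCatch(read.csv(path, colClasses = "character"),
                  error = function(e) abort_format(conditionMessage(e)))
  if (nrow(raw) == 0L) abort_validation("contour file has no points")
  if (!all(c("x", "y") %in% names(raw)))
    abort_format("contour CSV must have header x,y")
  sx <- suppressWarnings(as.numeric(raw$x))
  sy <- suppressWarnings(as.numeric(raw$y))
  if (any(is.na(sx)) || any(is.na(sy)) ||
      any(sx != round(sx)) || any(sy != round(sy)))
    abort_format("contour CSV rows must be integer coordinates")
  data.frame(x = as.integer(sx), y = as.integer(sy))
}

#' Write / load a binary mask as PNG
#'
#' Foreground (1) maps to white, background (0) to black; the round trip
#' is lossless.  Loading a PNG with any gray level other than pure black
#' or white is a format error.
#'
#' @param mask 0/1 matrix.
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `load_mask_png`
#'   returns a 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
load_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (!all(img %in% c(0, 1)))
    abort_format("PNG is not a binary mask (pixel values other than 0/255)")
  img + 0
}

#' Write / load an area curve as CSV
#'
#' Columns `frame` (0-based index), `time_s`, `area_cm2`; failed frames
#' carry empty `area_cm2` fields.
#'
#' @param avc an [build_avc()] result (class `lv_avc`) or a data frame
#'   with those columns.
#' @param path CSV file path.
#' @return `write_area_curve_csv` returns `path` invisibly;
#'   `load_area_curve_csv` returns a data frame.
#' @export
write_area_curve_csv <- function(avc, path) {
  df <- as.data.frame(avc)[, c("frame", "time_s", "area_cm2")]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_area_curve_csv
#' @export
load_area_curve_csv <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- read.csv(path)
  if (!all(c("frame", "time_s", "area_cm2") %in% names(df)))
    abort_format("area curve CSV must have header frame,time_s,area_cm2")
  df
}
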