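## Atrioventricular barrier handling, marker-controlled watershed,
## ventricle-region selection, contour correction, and the per-sequence
## driver that ties them together.

#' Atrioventricular barrier
#'
#' A horizontal run of pixels that acts as a watershed dam across the
#' mitral valve plane, preventing the flooded ventricle basin from
#' merging with the atrium while the valve is open.  Coordinates are
#' 0-based; `y` is the image row.
#'
#' @param x_start,x_end inclusive column range (`x_start <= x_end`).
#' @param y row index.
#' @param kind `"primary"` (tracked frame to frame) or `"secondary"`
#'   (static, placed against a poorly contrasted wall).
#' @return An object of class `lv_barrier`.
#' @export
barrier <- function(x_start, x_end, y, kind = c("primary", "secondary")) {
  kind <- match.arg(kind)
  if (x_start > x_end) abort_validation("barrier requires x_start <= x_end")
  if (x_start < 0 || y < 0)
    abort_validation("barrier coordinates must be non-negative")
  structure(list(x_start = as.integer(x_start), x_end = as.integer(x_end),
                 y = as.integer(y), kind = kind),
            class = "lv_barrier")
}

#' @export
print.lv_barrier <- function(x, ...) {
  cat(sprintf("<lv_barrier %s> x in [%d, %d], y = %d\n",
              x$kind, x$x_start, x$x_end, x$y))
  invisible(x)
}

check_barrier_bounds <- function(b, dim) {
  if (b$y < 0 || b$y > dim[1] - 1L || b$x_start < 0 || b$x_end > dim[2] - 1L)
    abort_validation(sprintf(
      "barrier (x in [%d, %d], y = %d) outside a %dx%d image",
      b$x_start, b$x_end, b$y, dim[1], dim[2]))
  invisible(b)
}

#' Rasterize barriers into an image
#'
#' Sets every barrier pixel to the maximum intensity 1.0 so that the
#' watershed flood cannot cross the valve plane there.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param barriers a single [barrier()] or a list of them.
#' @return A copy of `img` with the barrier pixels set to 1.
#' @export
rasterize_barrier <- function(img, barriers) {
  assert_image(img)
  if (inherits(barriers, "lv_barrier")) barriers <- list(barriers)
  out <- img
  for (b in barriers) {
    check_barrier_bounds(b, dim(img))
    out[b$y + 1L, (b$x_start:b$x_end) + 1L] <- 1
  }
  out
}

barrier_pixels <- function(b, dim) {
  cbind(row = rep(b$y + 1L, b$x_end - b$x_start + 1L),
        col = (b$x_start:b$x_end) + 1L)
}

#' Track the barrier from the previous frame's watershed mask
#'
#' The updated barrier keeps the originally prescribed x-range and moves
#' vertically to the row of the lowest-positioned foreground pixel of
#' the previous frame's watershed mask (rows grow downward, so "lowest"
#' means the largest row index).
#'
#' @param prev the previous [barrier()].
#' @param prev_mask the previous frame's watershed mask (0/1 matrix).
#' @return The updated primary [barrier()].
#' @export
update_barrier <- function(prev, prev_mask) {
  rows <- which(rowSums(prev_mask) > 0)
  if (length(rows) == 0L)
    abort_tracking("previous watershed mask is empty; barrier not updated")
  barrier(prev$x_start, prev$x_end, max(rows) - 1L, kind = "primary")
}

#' Marker-controlled watershed transform
#'
#' Immersion flooding from the marker components: each 8-connected
#' marker component seeds one catchment basin, basins grow in order of
#' pixel intensity (ties first-in-first-out, initial frontier in raster
#' order), and a dam pixel (label 0) is laid wherever two distinct
#' basins meet, so that basins never merge.
#'
#' @param img the (preprocessed, barrier-rasterized) image to flood.
#' @param markers either a 0/1 marker mask (components are labelled
#'   internally) or an integer label matrix.
#' @return An integer label matrix: 0 for watershed-line pixels, k >= 1
#'   for basin k.
#' @export
watershed_segment <- function(img, markers) {
  assert_image(img)
  if (!is.matrix(markers) || !all(dim(markers) == dim(img)))
    abort_validation("markers must be a matrix matching the image shape")
  m <- matrix(as.integer(markers), nrow(markers), ncol(markers))
  if (all(m == 0L)) abort_validation("marker mask is empty")
  if (max(m) <= 1L) m <- cpp_label8(m)
  cpp_watershed(img, m)
}

#' Select the ventricular basin
#'
#' Among basins whose centroid lies in the central window (the middle
#' half of each image dimension) or that contain the reference point,
#' returns the one with the largest pixel count.  The reference point
#' defaults (in [segment_sequence()]) to the barrier midpoint displaced
#' upward by a quarter of the image height, a point expected to lie
#' inside the ventricle.
#'
#' @param labels watershed label matrix from [watershed_segment()].
#' @param ref_point optional `(x, y)` 0-based reference point.
#' @return A 0/1 mask of the selected basin.
#' @export
select_ventricle_region <- function(labels, ref_point = NULL) {
  n <- max(labels)
  if (n < 1L) abort_validation("label image contains no basin")
  H <- nrow(labels); W <- ncol(labels)
  counts <- tabulate(labels[labels > 0L], nbins = n)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  cy <- tapply(idx[, 1], lab, mean) - 1   # 0-based centroid row
  cx <- tapply(idx[, 2], lab, mean) - 1
  ids <- as.integer(names(cy))
  central <- cy >= H / 4 & cy <= 3 * H / 4 & cx >= W / 4 & cx <= 3 * W / 4
  qualifies <- central
  if (!is.null(ref_point)) {
    rx <- as.integer(round(ref_point[1])); ry <- as.integer(round(ref_point[2]))
    if (rx >= 0 && rx < W && ry >= 0 && ry < H) {
      at_ref <- labels[ry + 1L, rx + 1L]
      qualifies <- qualifies | (ids == at_ref)
    }
  }
  cand <- ids[qualifies]
  if (length(cand) == 0L)
    abort_segmentation(
      "no central basin: possible undersegmentation/leakage; consider a secondary barrier")
  best <- cand[which.max(counts[cand])]
  (labels == best) + 0
}

#' Contour correction
#'
#' The watershed contour typically sits within the myocardium, so the
#' watershed area overestimates the cavity.  This step separates muscle
#' from blood pool inside the watershed region by thresholding at half
#' the mean intensity along the watershed contour, smooths the muscle
#' mask (binary closing then opening, disk radius 3), subtracts it from
#' the watershed mask, smooths the remaining cavity estimate (closing
#' then opening, disk radius 9), and finally clamps the result to the
#' watershed mask, keeping the largest connected component.
#'
#' @param watershed_mask 0/1 mask of the selected basin.
#' @param original the intensity image the threshold is computed on (the
#'   time-averaged frame, not the edge-enhanced one).
#' @return The corrected cavity mask, a subset of `watershed_mask`.
#' @export
correct_contour <- function(watershed_mask, original) {
  assert_mask(watershed_mask)
  assert_image(original, "original image")
  if (sum(watershed_mask) == 0) abort_validation("watershed mask is empty")
  ctr <- extract_contour(largest_component(watershed_mask))
  thr <- 0.5 * mean(original[cbind(ctr$y + 1L, ctr$x + 1L)])
  muscle <- (watershed_mask == 1 & original >= thr) + 0
  k3 <- disk_kernel(3)
  muscle <- binary_open(binary_close(muscle, k3), k3)
  cavity <- (watershed_mask == 1 & muscle == 0) + 0
  k9 <- disk_kernel(9)
  cavity <- binary_open(binary_close(cavity, k9), k9)
  cavity <- (cavity == 1 & watershed_mask == 1) + 0
  if (sum(cavity) == 0)
    abort_segmentation("empty cavity after muscle subtraction")
  largest_component(cavity)
}

#' Trace the outer boundary of a mask
#'
#' Moore boundary tracing: the ordered, clockwise (in image coordinates,
#' y growing downward), 8-connected outer boundary of a single-component
#' mask, starting at the boundary pixel with minimal `(y, x)`.
#'
#' @param mask 0/1 matrix with exactly one 8-connected component.
#' @return A data frame with integer 0-based columns `x`, `y`.
#' @export
extract_contour <- function(mask) {
  assert_mask(mask)
  if (sum(mask) == 0) abort_validation("cannot trace an empty mask")
  lab <- cpp_label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  if (max(lab) > 1L)
    abort_validation("mask has multiple connected components")
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  ord <- order(fg[, 1], fg[, 2])
  start <- fg[ord[1], ]                       # min row, then min col
  if (nrow(fg) == 1L)
    return(data.frame(x = unname(start[2]) - 1L, y = unname(start[1]) - 1L))
  ## clockwise neighbour ring starting west: W NW N NE E SE S SW (dr, dc)
  ring <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  inside <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W
  ## one Moore step: from pixel `cur`, scanning clockwise from the
  ## backtrack direction, return the first foreground neighbour and the
  ## backtrack direction to use from there
  step <- function(cur, back_dir) {
    for (s in 0:7) {
      d <- (back_dir - 1L + s) %% 8L + 1L
      rr <- cur[1] + ring[d, 1]; cc <- cur[2] + ring[d, 2]
      if (inside(rr, cc) && mask[rr, cc] == 1) {
        prev_d <- (d - 2L) %% 8L + 1L         # last background examined
        br <- cur[1] + ring[prev_d, 1] - rr   # relative to the new pixel
        bc <- cur[2] + ring[prev_d, 2] - cc
        nb <- which(ring[, 1] == br & ring[, 2] == bc)
        return(list(pix = c(rr, cc), back_dir = nb, dir = d))
      }
    }
    NULL
  }
  first <- step(start, 1L)                    # entered from the west
  if (is.null(first))                         # no fg neighbour at all
    return(data.frame(x = unname(start[2]) - 1L, y = unname(start[1]) - 1L))
  pts_r <- start[1]; pts_c <- start[2]
  cur <- first$pix; back_dir <- first$back_dir
  limit <- 4L * nrow(fg) + 16L
  repeat {
    ## stop when the walk re-enters the start pixel and leaves it the
    ## same way it did the first time (Jacob's stopping criterion)
    if (all(cur == start)) {
      nxt <- step(cur, back_dir)
      if (!is.null(nxt) && nxt$dir == first$dir) break
    }
    pts_r <- c(pts_r, cur[1]); pts_c <- c(pts_c, cur[2])
    mv <- step(cur, back_dir)
    if (is.null(mv)) break
    cur <- mv$pix; back_dir <- mv$back_dir
    if (length(pts_r) > limit)
      abort_segmentation("contour tracing failed to terminate")
  }
  ## drop a repeated closing point if the walk re-appended the start
  n <- length(pts_r)
  if (n > 1L && pts_r[n] == pts_r[1] && pts_c[n] == pts_c[1]) {
    pts_r <- pts_r[-n]; pts_c <- pts_c[-n]
  }
  data.frame(x = pts_c - 1L, y = pts_r - 1L)
}

#' Segment a full cardiac cycle
#'
#' Runs, for every frame of the first cardiac cycle: preprocessing,
#' barrier rasterization, marker-controlled watershed, ventricle-region
#' selection and contour correction; the primary barrier is then updated
#' from the frame's watershed mask before the next frame.  Barrier
#' pixels are excluded from masks and area counts.  Frames that fail are
#' flagged and skipped rather than aborting the run, unless more than
#' half of all frames fail.
#'
#' @param seq an [echo_sequence()].
#' @param initial_barrier the manually placed primary [barrier()] for
#'   frame 0.
#' @param secondary optional list of static secondary [barrier()]s.
#' @param cfg a [preprocess_config()].
#' @param preprocessed optional list of [preprocess_frame()] results
#'   (one per cycle-1 frame).  Preprocessing does not depend on the
#'   barrier, so repeated runs over the same sequence -- e.g. the
#'   barrier-variability experiment -- can share it.
#' @return An object of class `lv_segmentation`: a list with `results`
#'   (one entry per frame: `frame_index`, `watershed_mask`,
#'   `corrected_mask`, `contour`, `barrier_used`, `ok`, `error`), the
#'   input `seq`, and `barrier_trace` (the tracked barrier row per
#'   frame).
#' @export
segment_sequence <- function(seq, initial_barrier, secondary = list(),
                             cfg = preprocess_config(), preprocessed = NULL) {
  d <- dim(seq$frames[[1]])
  check_barrier_bounds(initial_barrier, d)
  for (b in secondary) check_barrier_bounds(b, d)
  n1 <- length(cycle_ranges(seq)$c1)
  cur <- initial_barrier
  results <- vector("list", n1)
  trace <- integer(n1)
  for (k in 0:(n1 - 1L)) {
    trace[k + 1L] <- cur$y
    res <- tryCatch({
      pp <- if (!is.null(preprocessed)) preprocessed[[k + 1L]]
            else preprocess_frame(seq, k, cfg)
      seg <- segment_frame(pp, cur, secondary)
      seg
    }, echolv_error = function(e) {
      list(ok = FALSE, error = conditionMessage(e),
           watershed_mask = NULL, corrected_mask = NULL, contour = NULL)
    })
    res$frame_index <- k
    res$barrier_used <- cur
    results[[k + 1L]] <- res
    if (isTRUE(res$ok)) {
      upd <- tryCatch(update_barrier(cur, res$watershed_mask),
                      echolv_tracking_error = function(e) cur)
      cur <- upd
    }
  }
  n_fail <- sum(!vapply(results, function(r) isTRUE(r$ok), logical(1)))
  if (n_fail > n1 / 2)
    abort_segmentation(sprintf("%d of %d frames failed to segment",
                               n_fail, n1))
  structure(list(results = results, seq = seq, barrier_trace = trace,
                 initial_barrier = initial_barrier, secondary = secondary,
                 config = cfg),
            class = "lv_segmentation")
}

## One frame: barrier rasterization, marker split, watershed, selection,
## correction, contour.
segment_frame <- function(pp, primary, secondary = list()) {
  barriers <- c(list(primary), secondary)
  img <- rasterize_barrier(pp$image, barriers)
  markers <- pp$markers
  for (b in barriers) {
    px <- barrier_pixels(b, dim(img))
    markers[px] <- 0                   # a barrier also severs markers
  }
  if (sum(markers) == 0)
    abort_segmentation("barrier removed every marker pixel")
  labels <- watershed_segment(img, markers)
  H <- nrow(img)
  ref <- c((primary$x_start + primary$x_end) / 2, primary$y - H / 4)
  ws_mask <- select_ventricle_region(labels, ref_point = ref)
  for (b in barriers) ws_mask[barrier_pixels(b, dim(img))] <- 0
  ws_mask <- largest_component(ws_mask)
  corrected <- correct_contour(ws_mask, pp$averaged)
  contour <- extract_contour(corrected)
  list(ok = TRUE, error = NULL, watershed_mask = ws_mask,
       corrected_mask = corrected, contour = contour)
}

#' @export
print.lv_segmentation <- function(x, ...) {
  ok <- vapply(x$results, function(r) isTRUE(r$ok), logical(1))
  cat(sprintf("<lv_segmentation> %d frames, %d segmented, %d failed\n",
              length(ok), sum(ok), sum(!ok)))
  if (any(!ok))
    cat("  failed frames:", paste(which(!ok) - 1L, collapse = ", "), "\n")
  cat(sprintf("  barrier rows: %s\n",
              paste(range(x$barrier_trace), collapse = " .. ")))
  invisible(x)
}
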