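## Synthetic beating-heart phantom: a four-chamber-like scene with a
## vertically elongated left-ventricular cavity whose area follows a
## smooth two-phase systole/diastole profile, a left atrium below the
## valve plane that connects to the cavity through a gap while the
## mitral valve is open, right-heart chambers for scene realism, fully
## developed multiplicative speckle, and exact per-frame ground truth.

#' Phantom parameters
#'
#' Defaults emulate the acquisition geometry the pipeline targets:
#' 256x256 frames at 44 frames/s, 37 frames per cardiac cycle, two
#' consecutive near-identical cycles, end-diastolic cavity covering 20%
#' of the image and end-systolic 12.8% (true area variation fraction
#' near 36%), dark blood pools (0.10) inside brighter myocardium (0.70),
#' a mitral gap open during the 0.55-0.95 fraction of the cycle, and
#' unit-mean gamma speckle with dispersion 0.15.
#'
#' @param image_size `(H, W)` in pixels.
#' @param frames_per_cycle frames in one cardiac cycle (>= 8).
#' @param n_cycles number of consecutive cycles (the pipeline expects 2).
#' @param frame_rate frames per second.
#' @param ed_area_frac,es_area_frac cavity area at end-diastole /
#'   end-systole as a fraction of the image area.
#' @param valve_open_window fraction-of-cycle interval during which the
#'   mitral gap is open.
#' @param valve_gap_width width of the open mitral gap, pixels.
#' @param cavity_intensity,muscle_intensity,atrium_intensity mean gray
#'   levels of the blood pools and the myocardium.
#' @param speckle_scale dispersion of the unit-mean multiplicative gamma
#'   speckle (0 disables noise).
#' @param cycle_jitter half-width of the uniform per-cycle additive
#'   intensity offset applied to the second cycle.
#' @param pixel_spacing_mm `(dy, dx)` in mm per pixel.
#' @param seed integer seed; the generator is deterministic given it.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(256L, 256L),
                           frames_per_cycle = 37L, n_cycles = 2L,
                           frame_rate = 44, ed_area_frac = 0.20,
                           es_area_frac = 0.128,
                           valve_open_window = c(0.55, 0.95),
                           valve_gap_width = 10L,
                           cavity_intensity = 0.10,
                           muscle_intensity = 0.70,
                           atrium_intensity = 0.10,
                           speckle_scale = 0.15, cycle_jitter = 0.02,
                           pixel_spacing_mm = c(0.5, 0.5), seed = 1L) {
  if (!(es_area_frac > 0 && es_area_frac < ed_area_frac && ed_area_frac < 1))
    abort_validation("need 0 < es_area_frac < ed_area_frac < 1")
  if (frames_per_cycle < 8L) abort_validation("frames_per_cycle must be >= 8")
  if (any(c(cavity_intensity, muscle_intensity, atrium_intensity) < 0) ||
      any(c(cavity_intensity, muscle_intensity, atrium_intensity) > 1))
    abort_validation("intensities must lie in [0, 1]")
  if (speckle_scale < 0) abort_validation("speckle_scale must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 frames_per_cycle = as.integer(frames_per_cycle),
                 n_cycles = as.integer(n_cycles), frame_rate = frame_rate,
                 ed_area_frac = ed_area_frac, es_area_frac = es_area_frac,
                 valve_open_window = valve_open_window,
                 valve_gap_width = as.integer(valve_gap_width),
                 cavity_intensity = cavity_intensity,
                 muscle_intensity = muscle_intensity,
                 atrium_intensity = atrium_intensity,
                 speckle_scale = speckle_scale, cycle_jitter = cycle_jitter,
                 pixel_spacing_mm = pixel_spacing_mm,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

## Smooth two-phase area profile in cycle phase p in [0, 1): a cosine
## contraction from end-diastole to end-systole over the first 35% of
## the cycle, then a cosine refill.  Returns the cavity area as a
## fraction of its end-diastolic value.
area_profile <- function(p, u_es, t_sys = 0.35) {
  ifelse(p <= t_sys,
         1 - (1 - u_es) * (1 - cos(pi * p / t_sys)) / 2,
         u_es + (1 - u_es) * (1 - cos(pi * (p - t_sys) / (1 - t_sys))) / 2)
}

## Valve-plane (cavity base) row excursion: the base rises during
## systole and returns before the valve opens, so the mitral gap always
## pierces a stationary base.  0-based continuous row.
base_row_profile <- function(p, base_max, excursion) {
  g <- ifelse(p <= 0.35, (1 - cos(pi * p / 0.35)) / 2,
              ifelse(p <= 0.45, (1 + cos(pi * (p - 0.35) / 0.10)) / 2, 0))
  base_max - excursion * g
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

## separable Gaussian blur with reflective borders
gaussian_blur <- function(img, g) {
  cpp_convolve_reflect(cpp_convolve_reflect(img, matrix(g, ncol = 1)),
                       matrix(g, nrow = 1))
}

#' Generate a synthetic echo sequence with ground truth
#'
#' The left-ventricular cavity is a vertically elongated truncated
#' ellipse whose area interpolates the end-diastolic and end-systolic
#' fractions with a smooth two-phase profile; area change is
#' predominantly longitudinal.  During the valve-open window a gap
#' connects the cavity to a dark atrial pool below the valve plane.
#' Clean frames are blurred with a small Gaussian and multiplied by
#' i.i.d. unit-mean gamma speckle; cycle 2 repeats the geometry of
#' cycle 1 with independent noise and a small intensity offset.  Noise
#' is drawn from one substream per frame, so any frame is reproducible
#' independently of evaluation order.
#'
#' @param params a [phantom_params()] list.
#' @return A list with `sequence` (an [echo_sequence()]) and `truth`
#'   (class `phantom_truth`): per-frame cavity `masks`, `areas_cm2`,
#'   `valve_open` flags, `valve_row` (0-based), `true_avf`, `ed_index`,
#'   `es_index`, and the `params` used.
#' @export
generate_phantom <- function(params = phantom_params()) {
  H <- params$image_size[1]; W <- params$image_size[2]
  fpc <- params$frames_per_cycle
  nf <- fpc * params$n_cycles
  u_es <- params$es_area_frac / params$ed_area_frac

  ## geometry derived from the area targets; aspect fixed so the cavity
  ## is vertically elongated and the ellipse is cut at 0.88 b (flat
  ## annulus).  Truncated-ellipse area = (pi - 0.0769) a b.
  cut <- 0.88
  trunc_factor <- pi - (acos(cut) - cut * sqrt(1 - cut^2))
  ed_px <- params$ed_area_frac * H * W
  aspect <- 1.32
  b0 <- sqrt(ed_px * aspect / trunc_factor)
  a0 <- b0 / aspect
  cx <- (W + 1) / 2                       # 1-based continuous centres
  base_max <- 0.66 * H                    # 1-based row of the ED base
  excursion <- 10 * H / 256
  band_t <- 8 * H / 256                   # thin basal band above atrium
  la_b <- 0.117 * H; la_a <- 0.1875 * W
  rv_cx <- 0.17 * W; rv_cy <- 0.39 * H; rv_a <- 0.07 * W; rv_b <- 0.195 * H
  ra_cx <- 0.175 * W; ra_cy <- 0.765 * H; ra_a <- 0.0625 * W; ra_b <- 0.094 * H

  cols <- matrix(rep(1:W, each = H), H, W)
  rows <- matrix(rep(1:H, W), H, W)
  in_ellipse <- function(cx0, cy0, a, b)
    ((cols - cx0) / a)^2 + ((rows - cy0) / b)^2 <= 1
  ## ultrasound scan sector: transducer at the top of the image,
  ## half-angle 60 degrees, maximal depth 1.05 H.  The sector leaves
  ## roughly 15% of the frame dark, which together with the blood pools
  ## puts the median pixel intensity between pool and muscle levels.
  ## The edge is feathered over ~10 px (gain roll-off), so unlike
  ## tissue interfaces it produces no sharpening overshoot downstream.
  depth <- rows - 0
  d_ang <- (depth * tan(60 * pi / 180) - abs(cols - cx)) * cos(60 * pi / 180)
  d_rad <- 1.05 * H - sqrt(pmax(depth, 0)^2 + (cols - cx)^2)
  d_sector <- pmin(depth, d_ang, d_rad)
  sector_fade <- pmin(1, pmax(0, (d_sector + 2) / (10 * H / 256)))
  gap_cols <- {
    w <- params$valve_gap_width
    lo <- floor(cx - w / 2)
    cols >= lo & cols <= lo + w - 1
  }
  blur <- gaussian_kernel_1d(1.5 * H / 256)

  set.seed(params$seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, nf)
  cycle_offset <- c(0, runif(params$n_cycles - 1L,
                             -params$cycle_jitter, params$cycle_jitter))

  frames <- vector("list", nf)
  masks <- vector("list", fpc)
  valve_row <- integer(fpc)
  valve_open <- logical(fpc)
  for (t in seq_len(nf) - 1L) {
    cyc <- t %/% fpc
    k <- t %% fpc
    p <- k / fpc
    u <- area_profile(p, u_es)
    b <- b0 * u^0.7
    a <- a0 * u^0.3
    yv <- base_row_profile(p, base_max, excursion)
    cy <- yv - cut * b
    open <- p >= params$valve_open_window[1] & p < params$valve_open_window[2]

    cav <- in_ellipse(cx, cy, a, b) & rows <= yv
    ## the atrial roof follows the mitral annulus, keeping the basal
    ## band (closed leaflets / annulus tissue) thin through the cycle;
    ## the atria fill during ventricular systole, so they swell as the
    ## ventricle shrinks (area factor up to ~1.45 at end-systole)
    la_top <- yv + band_t
    atr_s <- sqrt(1 + 0.45 * (1 - u))
    la_cy <- la_top + la_b * atr_s
    bright <- min(1, params$muscle_intensity + 0.30)
    img <- matrix(params$muscle_intensity, H, W)
    img[in_ellipse(rv_cx, rv_cy, rv_a, rv_b)] <- 0.12
    img[in_ellipse(ra_cx, ra_cy, ra_a * atr_s, ra_b * atr_s)] <- 0.12
    ## echogenic basal band (closed leaflets reflect strongly)
    band <- rows > yv & rows <= la_top + 1 & abs(cols - cx) <= la_a + 6
    img[band] <- bright
    img[in_ellipse(cx, la_cy, la_a * atr_s, la_b * atr_s)] <-
      params$atrium_intensity
    if (open)
      img[gap_cols & rows > yv & rows <= la_top + 1] <- params$cavity_intensity
    img[cav] <- params$cavity_intensity
    ## specular endocardial border straddling the blood-muscle
    ## interface (the reflection arises at the boundary itself); the
    ## open mitral orifice stays anechoic
    rim <- in_ellipse(cx, cy, a + 1, b + 1) & rows <= yv + 1 &
      !(in_ellipse(cx, cy, a - 1.5, b - 1.5) & rows <= yv)
    if (open) rim <- rim & !gap_cols
    img[rim] <- bright
    img <- img * sector_fade + 0.03 * (1 - sector_fade)

    clean <- gaussian_blur(img, blur)
    set.seed(frame_seeds[t + 1L])
    if (params$speckle_scale > 0) {
      shape <- 1 / params$speckle_scale^2
      s <- matrix(rgamma(H * W, shape = shape, rate = shape), H, W)
    } else s <- 1
    frames[[t + 1L]] <- clip01(clean * s + cycle_offset[cyc + 1L])

    if (cyc == 0L) {
      masks[[k + 1L]] <- cav + 0
      ## the valve plane runs through the middle of the leaflet band
      valve_row[k + 1L] <- round(yv + band_t / 2) - 1L   # 0-based
      valve_open[k + 1L] <- open
    }
  }

  seqc <- echo_sequence(frames, params$frame_rate, params$pixel_spacing_mm,
                        r_wave_indices = (0:(params$n_cycles - 1L)) * fpc)
  areas <- vapply(masks, function(m)
    frame_area(m, params$pixel_spacing_mm), numeric(1))
  ed <- 2L                                  # first frame after the R wave
  es <- which.min(areas)
  truth <- structure(
    list(masks = masks, areas_cm2 = areas, valve_open = valve_open,
         valve_row = valve_row,
         ed_index = ed - 1L, es_index = es - 1L,
         true_avf = compute_avf(areas[ed], areas[es]),
         params = params),
    class = "phantom_truth")
  list(sequence = seqc, truth = truth)
}

#' True initial barrier for a phantom
#'
#' A primary barrier at the true valve-plane row of frame 0, spanning
#' the mitral gap with a margin on each side (narrower than the annulus,
#' as an operator tracing the valve would draw it).
#'
#' @param gt a `phantom_truth` object.
#' @return A primary [barrier()].
#' @export
true_initial_barrier <- function(gt) {
  p <- gt$params
  W <- p$image_size[2]
  cx <- (W + 1) / 2
  w <- p$valve_gap_width
  lo <- floor(cx - w / 2) - 1L              # 0-based gap start
  margin <- 4L
  barrier(lo - margin, lo + w - 1L + margin, gt$valve_row[1],
          kind = "primary")
}

#' Automated barrier-placement variability experiment
#'
#' Emulates several operators each repeatedly tracing the initial
#' atrioventricular barrier: endpoints of the true barrier are jittered
#' uniformly within `(±dx, ±dy)` pixels, the full pipeline is run for
#' every placement, and per-frame area statistics plus the spread of the
#' measured area variation fraction are reported.
#'
#' @param seq the phantom [echo_sequence()].
#' @param gt the matching `phantom_truth`.
#' @param n_operators,n_reps number of simulated operators and of
#'   repetitions per operator.
#' @param jitter `(dx, dy)` maximal endpoint displacement in pixels.
#' @param seed seed for the barrier draws (the pipeline itself is
#'   deterministic).
#' @param cfg a [preprocess_config()].
#' @return A list of class `lv_variability`: `per_frame` (data frame
#'   with `frame`, `mean_area_cm2`, `sd_percent`), `avf` (per-run AVF),
#'   `avf_mean`, `avf_sd`, `n_runs`, `n_failed`, `barriers`.
#' @export
barrier_perturbation_harness <- function(seq, gt, n_operators = 4L,
                                         n_reps = 10L, jitter = c(3L, 2L),
                                         seed = 1L,
                                         cfg = preprocess_config()) {
  b0 <- true_initial_barrier(gt)
  n_runs <- n_operators * n_reps
  set.seed(seed)
  draws <- matrix(c(
    sample(-jitter[1]:jitter[1], n_runs, replace = TRUE),
    sample(-jitter[1]:jitter[1], n_runs, replace = TRUE),
    sample(-jitter[2]:jitter[2], n_runs, replace = TRUE)), ncol = 3)
  d <- dim(seq$frames[[1]])
  ## preprocessing is barrier-independent: compute it once, share it
  n1 <- gt$params$frames_per_cycle
  pps <- lapply(0:(n1 - 1L), function(k) preprocess_frame(seq, k, cfg))
  avfs <- rep(NA_real_, n_runs)
  areas <- NULL
  barriers <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    b <- barrier(max(0L, b0$x_start + draws[i, 1]),
                 min(d[2] - 1L, b0$x_end + draws[i, 2]),
                 max(0L, min(d[1] - 1L, b0$y + draws[i, 3])))
    barriers[[i]] <- b
    run <- tryCatch({
      segr <- segment_sequence(seq, b, cfg = cfg, preprocessed = pps)
      avc <- build_avc(segr, seq)
      list(avf = avf_report(avc)$avf, areas = avc$area_cm2)
    }, echolv_error = function(e) NULL)
    if (is.null(run)) next
    avfs[i] <- run$avf
    areas <- cbind(areas, run$areas)
  }
  ok <- !is.na(avfs)
  if (!any(ok)) abort_segmentation("every perturbed run failed")
  mean_area <- rowMeans(areas, na.rm = TRUE)
  sd_area <- apply(areas, 1, sd, na.rm = TRUE)
  per_frame <- data.frame(frame = seq_len(nrow(areas)) - 1L,
                          mean_area_cm2 = mean_area,
                          sd_percent = 100 * sd_area / mean_area)
  structure(list(per_frame = per_frame, avf = avfs[ok],
                 avf_mean = mean(avfs[ok]), avf_sd = sd(avfs[ok]),
                 n_runs = n_runs, n_failed = sum(!ok),
                 barriers = barriers),
            class = "lv_variability")
}

#' @export
print.lv_variability <- function(x, ...) {
  cat(sprintf(
    "<lv_variability> %d runs (%d failed)\n  AVF %.1f%% +/- %.2f%% (range %.1f .. %.1f)\n",
    x$n_runs, x$n_failed, x$avf_mean, x$avf_sd, min(x$avf), max(x$avf)))
  cat(sprintf("  per-frame area sd: %.2f%% .. %.2f%% of the mean\n",
              min(x$per_frame$sd_percent), max(x$per_frame$sd_percent)))
  invisible(x)
}

#' @export
plot.lv_variability <- function(x, ...) {
  pf <- x$per_frame
  sdv <- pf$mean_area_cm2 * pf$sd_percent / 100
  plot(pf$frame, pf$mean_area_cm2, type = "o", pch = 16,
       ylim = range(pf$mean_area_cm2 + sdv, pf$mean_area_cm2 - sdv),
       xlab = "frame", ylab = expression(area ~ (cm^2)),
       main = "Barrier-placement variability", ...)
  arrows(pf$frame, pf$mean_area_cm2 - sdv, pf$frame, pf$mean_area_cm2 + sdv,
         angle = 90, code = 3, length = 0.02)
  invisible(x)
}
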