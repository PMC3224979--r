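make_seq <- function(frames, r = c(0L, 2L), rate = 44) {
  echo_sequence(frames, rate, c(0.5, 0.5), r)
}

test_that("time_average is the four-frame ECG-synchronised mean", {
  c1 <- lapply(c(0.2, 0.4), function(v) matrix(v, 8, 8))
  c2 <- lapply(c(0.6, 0.8), function(v) matrix(v, 8, 8))
  s <- make_seq(c(c1, c2))
  expect_equal(time_average(s, 0), matrix(0.5, 8, 8))

  F <- matrix(runif(64), 8, 8)
  s2 <- make_seq(rep(list(F), 4))
  expect_equal(time_average(s2, 0), F)

  set.seed(3)
  frames <- lapply(1:8, function(i) matrix(runif(64), 8, 8))
  s3 <- make_seq(frames, r = c(0L, 4L))
  for (k in 0:3) {
    pick <- list(frames[[k + 1]], frames[[(k + 1) %% 4 + 1]],
                 frames[[k + 5]], frames[[(k + 1) %% 4 + 5]])
    expect_equal(time_average(s3, k), oracle_mean_frames(pick))
  }
  expect_error(time_average(s3, 4), class = "echolv_validation_error")
  expect_error(time_average(s3, -1), class = "echolv_validation_error")
})

test_that("time_average is permutation-invariant over its four frames", {
  set.seed(4)
  frames <- lapply(1:8, function(i) matrix(runif(64), 8, 8))
  s <- make_seq(frames, r = c(0L, 4L))
  ## swapping the two cycles presents the same four frames in new order
  s_swap <- make_seq(c(frames[5:8], frames[1:4]), r = c(0L, 4L))
  for (k in 0:3) expect_equal(time_average(s, k), time_average(s_swap, k))
})

test_that("last-frame averaging wraps within the cycle, short cycles fall back", {
  frames <- lapply(1:7, function(i) matrix(i / 10, 8, 8))
  s <- make_seq(frames, r = c(0L, 4L))        # cycle 2 has 3 frames
  ## k = 3: cycle-1 frames 3,0 (wrap); cycle 2 too short -> two-frame mean
  expect_equal(time_average(s, 3), matrix(mean(c(0.4, 0.1)), 8, 8))
  ## k = 2: cycle-2 wraps to its own first frame
  expect_equal(time_average(s, 2),
               matrix(mean(c(0.3, 0.4, 0.7, 0.5)), 8, 8))
})

test_that("wavelet denoising is exact on constants and reduces noise", {
  cfg <- preprocess_config(wavelet_levels = 3L)
  expect_equal(wavelet_denoise(matrix(0, 32, 32), cfg), matrix(0, 32, 32),
               tolerance = 1e-12)
  expect_equal(wavelet_denoise(matrix(0.4, 32, 32), cfg), matrix(0.4, 32, 32),
               tolerance = 1e-12)

  clean <- matrix(0.2, 64, 64); clean[20:50, 20:50] <- 0.8
  set.seed(5)
  noisy <- pmin(pmax(clean + matrix(rnorm(4096, 0, 0.05), 64, 64), 0), 1)
  den <- wavelet_denoise(noisy)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))

  expect_error(wavelet_denoise(matrix(0.1, 8, 8), preprocess_config(wavelet_levels = 4L)),
               class = "echolv_validation_error")
})

test_that("wavelet denoising commutes with circular shifts", {
  set.seed(6)
  x <- matrix(runif(48 * 48), 48, 48)
  x[10:30, 15:35] <- x[10:30, 15:35] * 0.2
  cfg <- preprocess_config(wavelet_levels = 3L)
  sh <- function(m, dr, dc) m[c((dr + 1):nrow(m), 1:dr), c((dc + 1):ncol(m), 1:dc)]
  d1 <- wavelet_denoise(x, cfg)
  d2 <- wavelet_denoise(sh(x, 3, 5), cfg)
  expect_equal(d2, sh(d1, 3, 5), tolerance = 1e-10)
})

test_that("LoG edge enhancement sharpens steps and is exact where expected", {
  cst <- matrix(0.37, 32, 32)
  expect_equal(edge_enhance_log(cst), cst, tolerance = 1e-12)
  expect_identical(edge_enhance_log(cst, preprocess_config(log_gain = 0)), cst)

  step <- matrix(0.2, 32, 32); step[, 17:32] <- 0.8
  out <- edge_enhance_log(step)
  dmax <- max(abs(out[, -1] - out[, -32]))
  expect_gt(dmax, 0.6)

  ## unit impulse responds with (impulse - LoG kernel), against a
  ## double-loop convolution oracle on the interior
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  k <- echolv:::log_kernel(2.0)
  expected <- imp - oracle_conv2_interior(imp, k)
  out2 <- edge_enhance_log(imp)
  interior <- 10:24
  expect_equal(out2[interior, interior],
               pmin(pmax(expected[interior, interior], 0), 1),
               tolerance = 1e-12)
})

test_that("morphological smoothing removes isolated extrema (oracle-checked)", {
  cst <- matrix(0.5, 16, 16)
  expect_equal(morph_smooth(cst), cst)

  cfg <- preprocess_config()
  k1 <- echolv:::disk_kernel(1)

  spike <- matrix(0, 16, 16); spike[8, 8] <- 1
  after <- morph_smooth(spike)
  expect_equal(max(after), 0)                 # bright spike removed
  ## opening r=1 alone equals the min/max oracle
  open1 <- echolv:::gray_open(spike, k1)
  expect_equal(open1, oracle_morph(oracle_morph(spike, k1, min), k1, max))

  hole <- matrix(0.8, 16, 16); hole[8, 8] <- 0.1
  after2 <- morph_smooth(hole)
  expect_equal(min(after2), 0.8)              # dark hole filled
  close1 <- echolv:::gray_close(hole, k1)
  expect_equal(close1, oracle_morph(oracle_morph(hole, k1, max), k1, min))
})

test_that("the close/open pair is idempotent", {
  set.seed(8)
  x <- matrix(runif(400), 20, 20)
  k1 <- echolv:::disk_kernel(1)
  once <- echolv:::gray_open(echolv:::gray_close(x, k1), k1)
  twice <- echolv:::gray_open(echolv:::gray_close(once, k1), k1)
  expect_equal(twice, once)
})

test_that("homotopy modification eliminates exactly the sub-median minima", {
  ## constant image: a single plateau, returned unchanged
  cst <- matrix(0.5, 12, 12)
  hm <- homotopy_modify(cst)
  expect_equal(hm$image, cst)
  expect_equal(hm$markers, matrix(1, 12, 12))

  ## two deep wells below the median merge into plateaus at the
  ## threshold; a shallow dip above the median survives untouched
  img <- matrix(0.65, 16, 16)
  img[, 1:8] <- 0.35                          # dark half fixes the median
  img[4:6, 3:5] <- 0.1
  img[10:12, 3:5] <- 0.2
  img[4, 13] <- 0.55
  thr <- echolv:::lower_median(as.vector(img))
  expect_equal(thr, 0.35)
  hm2 <- homotopy_modify(img)
  expect_true(all(hm2$image[4:6, 3:5] == thr))
  expect_true(all(hm2$image[10:12, 3:5] == thr))
  expect_equal(hm2$image[4, 13], 0.55)
  expect_equal(hm2$markers, oracle_regional_minima(hm2$image) + 0)

  ## minima of the output are exactly the returned markers on random
  ## images (flood-fill oracle); the modification only raises pixels
  set.seed(9)
  for (i in 1:20) {
    x <- matrix(round(runif(256), 2), 16, 16)
    h <- homotopy_modify(x)
    expect_identical(oracle_regional_minima(h$image) + 0, h$markers)
    expect_true(all(h$image >= x - 1e-12))
    expect_true(all(h$image <= pmax(x, echolv:::lower_median(as.vector(x))) + 1e-12))
  }
})

test_that("preprocess_frame equals the manual five-stage chain", {
  ph <- cached_phantom(11, image_size = c(64L, 64L), frames_per_cycle = 8L)
  s <- ph$sequence
  pp <- preprocess_frame(s, 2)
  x <- time_average(s, 2)
  manual <- wavelet_denoise(x)
  manual <- edge_enhance_log(manual)
  manual <- morph_smooth(manual)
  hm <- homotopy_modify(manual)
  expect_equal(pp$image, hm$image)
  expect_equal(pp$markers, hm$markers)
  expect_equal(pp$averaged, x)

  ## without noise, skipping the wavelet stage barely changes the output
  ph0 <- cached_phantom(12, image_size = c(64L, 64L), frames_per_cycle = 8L,
                        speckle_scale = 0, cycle_jitter = 0)
  a <- preprocess_frame(ph0$sequence, 1)
  b <- preprocess_frame(ph0$sequence, 1, preprocess_config(enable_wavelet = FALSE))
  expect_lt(mean((a$image - b$image)^2), 1e-3)
})

test_that("all stages preserve shape and the [0, 1] range", {
  ph <- cached_phantom(11, image_size = c(64L, 64L), frames_per_cycle = 8L)
  x <- time_average(ph$sequence, 1)
  for (f in list(function(z) wavelet_denoise(z),
                 function(z) edge_enhance_log(z),
                 function(z) morph_smooth(z),
                 function(z) homotopy_modify(z)$image)) {
    y <- f(x)
    expect_identical(dim(y), dim(x))
    expect_true(all(y >= 0 & y <= 1))
  }
})
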