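test_that("barriers rasterize to maximal intensity at exactly their pixels", {
  z <- matrix(0, 10, 10)
  out <- rasterize_barrier(z, barrier(2, 7, 5))
  expect_equal(sum(out == 1), 6)
  expect_true(all(out[6, 3:8] == 1))
  expect_equal(sum(out), 6)

  out1 <- rasterize_barrier(z, barrier(4, 4, 0))
  expect_equal(which(out1 == 1), 41L)          # row 1, col 5 (x = 4, y = 0)

  expect_error(rasterize_barrier(z, barrier(2, 7, 12)),
               class = "echolv_validation_error")
  expect_error(barrier(7, 2, 5), class = "echolv_validation_error")
})

test_that("barrier tracking follows the lowest mask pixel", {
  m <- matrix(0, 200, 200)
  m[90:121, 50:80] <- 1
  b <- update_barrier(barrier(40, 90, 100), m)
  expect_equal(b$y, 120)                        # 0-based lowest row
  expect_equal(c(b$x_start, b$x_end), c(40, 90))
  expect_equal(b$kind, "primary")

  m1 <- matrix(0, 100, 100); m1[78, 51] <- 1
  expect_equal(update_barrier(barrier(10, 20, 5), m1)$y, 77)

  expect_error(update_barrier(barrier(10, 20, 5), matrix(0, 50, 50)),
               class = "echolv_tracking_error")
})

test_that("watershed floods two wells into two dam-separated basins", {
  img <- matrix(0.9, 16, 16)
  img[4:6, 4:6] <- 0; img[10:13, 10:13] <- 0
  markers <- matrix(0L, 16, 16)
  markers[5, 5] <- 1L; markers[11, 11] <- 2L
  lab <- watershed_segment(img, markers)
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), c(1L, 2L))
  expect_true(sum(lab == 0) > 0)                # a dam line exists
  expect_identical(lab, oracle_watershed(img, markers))

  ## dam property: no pixel touches two different basins
  H <- 16
  for (i in 1:H) for (j in 1:H) {
    if (lab[i, j] == 0L) next
    nbr <- lab[max(1, i - 1):min(H, i + 1), max(1, j - 1):min(H, j + 1)]
    expect_true(all(nbr[nbr > 0] == lab[i, j]))
  }
})

test_that("degenerate watershed cases behave as specified", {
  ## single marker at the global minimum: one basin, no interior dams
  img <- matrix(0.5, 8, 8); img[4, 4] <- 0
  markers <- matrix(0L, 8, 8); markers[4, 4] <- 1L
  lab <- watershed_segment(img, markers)
  expect_true(all(lab == 1L))

  ## monotone ramp with one low-end marker: everything floods to it
  ramp <- matrix(rep(seq(0, 1, length.out = 12), each = 12), 12, 12)
  m2 <- matrix(0L, 12, 12); m2[, 1][6] <- 1L
  expect_true(all(watershed_segment(ramp, m2) == 1L))

  expect_error(watershed_segment(img, matrix(0L, 8, 8)),
               class = "echolv_validation_error")
})

test_that("ventricle selection prefers the largest central basin", {
  lab <- matrix(0L, 40, 40)
  lab[15:25, 15:25] <- 1L                       # large central region
  lab[1:5, 1:5] <- 2L; lab[1:5, 36:40] <- 3L    # small corner regions
  lab[36:40, 1:5] <- 4L; lab[36:40, 36:40] <- 5L
  m <- select_ventricle_region(lab)
  expect_equal(m, (lab == 1L) + 0)

  ## single basin
  lab1 <- matrix(1L, 20, 20)
  expect_equal(select_ventricle_region(lab1), matrix(1, 20, 20))

  ## only border basins and a dam at the reference point
  lab2 <- matrix(0L, 40, 40)
  lab2[1:4, ] <- 1L; lab2[37:40, ] <- 2L
  expect_error(select_ventricle_region(lab2, ref_point = c(20, 20)),
               class = "echolv_segmentation_error")

  ## a non-central basin qualifies through the reference point
  m3 <- select_ventricle_region(lab2, ref_point = c(20, 1))
  expect_equal(m3, (lab2 == 1L) + 0)
})

test_that("contour tracing is clockwise from the minimal-(y, x) pixel", {
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  ct <- extract_contour(m)
  expect_equal(ct$x, c(1, 2, 3, 3, 3, 2, 1, 1))
  expect_equal(ct$y, c(1, 1, 1, 2, 3, 3, 3, 2))

  expect_equal(extract_contour(matrix(c(0, 0, 0, 1), 2, 2)),
               data.frame(x = 1L, y = 1L))
  expect_error(extract_contour(matrix(0, 4, 4)),
               class = "echolv_validation_error")
  two <- matrix(0, 6, 6); two[1, 1] <- 1; two[5, 5] <- 1
  expect_error(extract_contour(two), class = "echolv_validation_error")

  ## 2x2 square: the four pixels in clockwise order
  m2 <- matrix(0, 4, 4); m2[2:3, 3:4] <- 1
  ct2 <- extract_contour(m2)
  expect_equal(ct2$x, c(2, 3, 3, 2))
  expect_equal(ct2$y, c(1, 1, 2, 2))
})

test_that("contour tracing closes around blobs with concavities", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(0, 20, 20)
    m[5:15, 5:15] <- 1
    m[sample(5:15, 3), 5] <- 0                 # notch the left edge
    m <- echolv:::largest_component(m)
    ct <- extract_contour(m)
    ## consecutive points 8-connected, no immediate repeats
    d <- pmax(abs(diff(ct$x)), abs(diff(ct$y)))
    expect_true(all(d == 1))
    ## every traced point is a boundary pixel of the mask
    expect_true(all(m[cbind(ct$y + 1, ct$x + 1)] == 1))
  }
})

test_that("contour correction recovers a dark cavity inside a bright annulus", {
  H <- 80
  d <- sqrt(outer((1:H) - 40.5, (1:H) - 40.5, function(a, b) a^2 + b^2))
  ws <- (d <= 30) + 0
  orig <- matrix(0.8, H, H)
  orig[d <= 20] <- 0.1
  corr <- correct_contour(ws, orig)
  expect_true(all(corr <= ws))                  # containment, exact
  a20 <- sum(d <= 20)
  expect_lt(abs(sum(corr) - a20) / a20, 0.15)

  ## uniformly dark interior: nothing is classified as muscle
  orig2 <- matrix(0, H, H)
  ring <- d > 28 & d <= 30
  orig2[ring] <- 0.8
  corr2 <- correct_contour(ws, orig2)
  expect_gt(sum(corr2), 0.85 * sum(ws))

  ## uniformly bright: the whole region is muscle, no cavity remains
  expect_error(correct_contour(ws, matrix(0.8, H, H)),
               class = "echolv_segmentation_error")
})

test_that("segmentation results are deterministic and contained", {
  pp <- cached_preprocessed(1)[[3]]
  ph <- cached_phantom(1)
  b <- true_initial_barrier(ph$truth)
  r1 <- echolv:::segment_frame(pp, b)
  r2 <- echolv:::segment_frame(pp, b)
  expect_identical(r1$corrected_mask, r2$corrected_mask)
  expect_identical(r1$contour, r2$contour)
  expect_true(all(r1$corrected_mask <= r1$watershed_mask))
})

test_that("an out-of-image initial barrier fails before any processing", {
  ph <- cached_phantom(1)
  expect_error(segment_sequence(ph$sequence, barrier(10, 20, 400)),
               class = "echolv_validation_error")
})
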