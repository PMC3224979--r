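square_contour <- function(n = 8) {
  ## clockwise boundary of an n x n square at origin (x, y), 0-based
  top <- data.frame(x = 0:(n - 1), y = 0)
  right <- data.frame(x = n - 1, y = 1:(n - 1))
  bottom <- data.frame(x = (n - 2):0, y = n - 1)
  left <- data.frame(x = 0, y = (n - 2):1)
  rbind(top, right, bottom, left)
}

test_that("even resampling keeps the round(i*L/N) points in order", {
  ct <- data.frame(x = 0:9, y = rep(0, 10))
  expect_equal(resample_even(ct, 5)$x, c(0, 2, 4, 6, 8))
  expect_identical(resample_even(ct, 10), ct)
  ct7 <- data.frame(x = 0:6, y = rep(1, 7))
  expect_equal(resample_even(ct7, 5)$x, c(0, 1, 3, 4, 6))
  expect_error(resample_even(ct7, 9), class = "echolv_validation_error")
  expect_error(resample_even(ct7, 0), class = "echolv_validation_error")
})

test_that("RMSd of paired contours", {
  sq <- square_contour(6)
  expect_equal(rmsd_contours(sq, sq), 0)
  expect_equal(rmsd_contours(data.frame(x = 0, y = 0),
                             data.frame(x = 3, y = 4)), 5)

  ## translation by (dx, dy) gives exactly sqrt(dx^2 + dy^2)
  tr <- sq; tr$x <- tr$x + 2; tr$y <- tr$y + 1
  expect_equal(rmsd_contours(sq, tr), sqrt(5))

  ## paired-index oracle on equal-length contours
  set.seed(31)
  for (i in 1:20) {
    a <- canon <- echolv:::canonicalize_contour(
      data.frame(x = sample(0:20, 8), y = sample(0:20, 8)))
    b <- echolv:::canonicalize_contour(
      data.frame(x = sample(0:20, 8), y = sample(0:20, 8)))
    expected <- sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2))
    expect_equal(rmsd_contours(a, b), expected)
    expect_equal(rmsd_contours(b, a), expected)   # symmetric at equal length
  }
  expect_error(rmsd_contours(data.frame(x = integer(), y = integer()), sq),
               class = "echolv_validation_error")
})

test_that("CCC is the Pearson correlation of mean-removed masks", {
  set.seed(32)
  m <- random_mask(8)
  expect_equal(ccc_masks(m, m), 1.0)
  expect_equal(ccc_masks(m, 1 - m), -1.0)
  for (i in 1:20) {
    a <- random_mask(8); b <- random_mask(8)
    expect_equal(ccc_masks(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(ccc_masks(matrix(1, 4, 4), m[1:4, 1:4]),
               class = "echolv_undefined_metric_error")
})

test_that("PE and ES match pixel-count oracles", {
  a <- matrix(0, 10, 10); a[1:11] <- 1          # wraps column-major: 11 px
  m <- matrix(0, 10, 10); m[1:10] <- 1
  expect_equal(percent_error(a, m), 10)
  expect_equal(percent_error(m, m), 0)
  expect_equal(error_sum(m, m), 0)

  d1 <- matrix(0, 10, 10); d1[1:5, 1] <- 1
  d2 <- matrix(0, 10, 10); d2[6:10, 2] <- 1
  expect_equal(error_sum(d1, d2), 200)          # disjoint equal areas

  set.seed(33)
  for (i in 1:20) {
    A <- random_mask(8); M <- random_mask(8)
    expect_equal(percent_error(A, M), 100 * abs(sum(A) - sum(M)) / sum(M))
    es_oracle <- 100 * sum(xor(A == 1, M == 1)) / sum(M)
    expect_equal(error_sum(A, M), es_oracle)
  }
  expect_error(percent_error(a, matrix(0, 10, 10)),
               class = "echolv_validation_error")
})

test_that("ES equals PE when one mask contains the other", {
  set.seed(34)
  for (i in 1:10) {
    M <- matrix(0, 12, 12)
    M[4:9, 4:9] <- 1
    A <- M
    drop <- which(M == 1)[sample(36, 5)]
    A[drop] <- 0                                # A strictly inside M
    expect_equal(error_sum(A, M), percent_error(A, M))
  }
})

test_that("all four metrics are translation invariant", {
  base <- matrix(0, 24, 24); base[6:12, 7:14] <- 1
  other <- matrix(0, 24, 24); other[7:14, 8:13] <- 1
  shift <- function(m, dr, dc) {
    out <- matrix(0, 24, 24)
    out[(6:14) + dr - 5, (7:14) + dc - 6] <- m[6:14, 7:14]
    out
  }
  r0 <- evaluate_pair(base, other)
  bs <- shift(base, 8, 7); os <- shift(other, 8, 7)
  r1 <- evaluate_pair(bs, os)
  expect_equal(r1$rmsd, r0$rmsd)
  expect_equal(r1$pe, r0$pe)
  expect_equal(r1$es, r0$es)
  ## CCC depends only on overlap counts, preserved under translation
  expect_equal(r1$ccc, r0$ccc, tolerance = 1e-12)
})

test_that("evaluate_pair and batch aggregation", {
  m <- matrix(0, 16, 16); m[5:11, 5:11] <- 1
  r <- evaluate_pair(m, m)
  expect_equal(r$rmsd, 0); expect_equal(r$ccc, 1)
  expect_equal(r$pe, 0); expect_equal(r$es, 0)

  dil <- (EBImage::dilate(m, matrix(1, 3, 3)) > 0) + 0
  r2 <- evaluate_pair(dil, m)
  expect_equal(r2$pe, 100 * (sum(dil) - sum(m)) / sum(m))
  expect_equal(r2$es, r2$pe)                    # dilation contains m

  set.seed(35)
  autos <- replicate(5, random_mask(10), simplify = FALSE)
  mans <- replicate(5, random_mask(10), simplify = FALSE)
  df <- evaluate_batch(autos, mans)
  expect_equal(nrow(df), 5)
  expect_equal(attr(df, "mean")[["pe"]],
               mean(vapply(1:5, function(i) percent_error(autos[[i]], mans[[i]]),
                           numeric(1))))
})
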