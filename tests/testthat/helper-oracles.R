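## Independent brute-force oracles used to verify the implementation.
## These deliberately use naive per-pixel/per-point loops.

## pixelwise mean of a list of frames
oracle_mean_frames <- function(frames) {
  out <- frames[[1]] * 0
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      v <- vapply(frames, function(f) f[i, j], numeric(1))
      out[i, j] <- mean(v)
    }
  }
  out
}

## full 2D convolution restricted to interior pixels (no border effects)
oracle_conv2_interior <- function(img, kern) {
  rh <- (nrow(kern) - 1) / 2; rw <- (ncol(kern) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  for (i in (rh + 1):(H - rh)) {
    for (j in (rw + 1):(W - rw)) {
      s <- 0
      for (a in -rh:rh) for (b in -rw:rw)
        s <- s + img[i - a, j - b] * kern[rh + 1 + a, rw + 1 + b]
      out[i, j] <- s
    }
  }
  out
}

## grayscale erosion/dilation with clamped neighbourhood (min/max over
## the structuring element intersected with the image)
oracle_morph <- function(img, kern, op = min) {
  r <- (nrow(kern) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in 1:H) {
    for (j in 1:W) {
      v <- c()
      for (a in -r:r) for (b in -r:r) {
        if (kern[a + r + 1, b + r + 1] == 0) next
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) v <- c(v, img[ii, jj])
      }
      out[i, j] <- op(v)
    }
  }
  out
}

## regional minima by explicit plateau flood fill (8-connected)
oracle_regional_minima <- function(img) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0L, H, W)
  seen <- matrix(FALSE, H, W)
  for (i0 in 1:H) for (j0 in 1:W) {
    if (seen[i0, j0]) next
    v <- img[i0, j0]
    comp <- matrix(c(i0, j0), 1)
    seen[i0, j0] <- TRUE
    q <- list(c(i0, j0))
    is_min <- TRUE
    while (length(q) > 0) {
      p <- q[[1]]; q <- q[-1]
      for (a in -1:1) for (b in -1:1) {
        if (a == 0 && b == 0) next
        ii <- p[1] + a; jj <- p[2] + b
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        if (img[ii, jj] < v) is_min <- FALSE
        if (img[ii, jj] == v && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          q <- c(q, list(c(ii, jj)))
          comp <- rbind(comp, c(ii, jj))
        }
      }
    }
    if (is_min) out[comp] <- 1L
  }
  out
}

## Marker-controlled watershed with dams, by explicit ordered flooding:
## the frontier is rescanned for the (value, insertion-order) minimum at
## every step.  Same semantics as the compiled implementation (initial
## frontier in raster order, neighbours pushed row-major), independent
## code path.
oracle_watershed <- function(img, markers) {
  H <- nrow(img); W <- ncol(img)
  lab <- markers
  dam <- matrix(FALSE, H, W)
  queued <- matrix(FALSE, H, W)
  fr <- integer(0); fc <- integer(0); fv <- numeric(0); fs <- integer(0)
  seqno <- 0L
  nb <- rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1),
              c(1,-1), c(1,0), c(1,1))
  push <- function(i, j) {
    fr <<- c(fr, i); fc <<- c(fc, j); fv <<- c(fv, img[i, j])
    fs <<- c(fs, seqno); seqno <<- seqno + 1L
    queued[i, j] <<- TRUE
  }
  for (i in 1:H) for (j in 1:W) {
    if (lab[i, j] != 0L) next
    hasm <- FALSE
    for (k in 1:8) {
      ii <- i + nb[k, 1]; jj <- j + nb[k, 2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && lab[ii, jj] > 0L)
        hasm <- TRUE
    }
    if (hasm) push(i, j)
  }
  while (length(fr) > 0) {
    o <- order(fv, fs)[1]
    i <- fr[o]; j <- fc[o]
    fr <- fr[-o]; fc <- fc[-o]; fv <- fv[-o]; fs <- fs[-o]
    if (lab[i, j] != 0L || dam[i, j]) next
    labs <- integer(0)
    for (k in 1:8) {
      ii <- i + nb[k, 1]; jj <- j + nb[k, 2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && lab[ii, jj] > 0L)
        labs <- union(labs, lab[ii, jj])
    }
    if (length(labs) > 1) {
      dam[i, j] <- TRUE
    } else if (length(labs) == 1) {
      lab[i, j] <- labs
      for (k in 1:8) {
        ii <- i + nb[k, 1]; jj <- j + nb[k, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            lab[ii, jj] == 0L && !queued[ii, jj] && !dam[ii, jj])
          push(ii, jj)
      }
    }
  }
  lab
}

## Pearson correlation by the direct formula over flattened pixels
oracle_pearson <- function(A, M) {
  a <- as.vector(A); m <- as.vector(M)
  am <- a - mean(a); mm <- m - mean(m)
  sum(am * mm) / sqrt(sum(am^2) * sum(mm^2))
}

## random connected-ish binary mask on an n x n grid
random_mask <- function(n, p = 0.5) {
  m <- matrix(as.integer(runif(n * n) < p), n, n)
  if (sum(m) == 0) m[sample(n, 1), sample(n, 1)] <- 1L
  m
}

## random marker label image with <= k separated seeds
random_markers <- function(n, k) {
  m <- matrix(0L, n, n)
  pts <- sample(n * n, k)
  m[pts] <- seq_len(k)
  m
}
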