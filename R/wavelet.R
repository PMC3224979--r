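## Undecimated (shift-invariant) 2D wavelet transform with the
## order-12 Daubechies filter pair, used by the denoising stage.
##
## The transform is the "a trous" stationary wavelet transform: no
## decimation, the analysis filters are upsampled by 2^(j-1) at level j,
## and all convolutions are circular.  For an orthonormal quadrature
## mirror pair (|H(w)|^2 + |G(w)|^2 = 2) one level is inverted exactly by
## correlating each band with its own filter and halving the sum, which
## makes the round trip exact to floating-point precision and the whole
## transform equivariant under integer circular shifts.

## Daubechies order-12 orthonormal scaling (lowpass) filter, 24 taps.
DB12_H <- c(
  -1.529071758068511e-06,  1.2776952219379767e-05, -2.4241545757030785e-05,
  -8.850410920820432e-05,  3.8865306282093143e-04,  6.545128212509596e-06,
  -2.1795036186277603e-03, 2.2486072409952378e-03,  6.71149900879551e-03,
  -1.2840825198300683e-02, -1.221864906974828e-02,  4.154627749508444e-02,
   1.0849130255822185e-02, -9.643212009650708e-02,  5.35956967435215e-03,
   1.8247860592757967e-01, -2.3779257256069726e-02, -3.161784537527855e-01,
  -4.476388565377463e-02,  5.158864784278157e-01,   6.571987225793071e-01,
   3.7735513521421266e-01, 1.0956627282118515e-01,  1.3112257957229518e-02)

## Quadrature mirror highpass: g[n] = (-1)^n h[L-1-n]
DB12_G <- rev(DB12_H) * rep(c(1, -1), length.out = length(DB12_H))

## Frequency response of the filter upsampled by `step`, sampled on a
## circular grid of length n (taps wrap around for short signals).
upsampled_filter_fft <- function(f, step, n) {
  v <- numeric(n)
  idx <- ((seq_along(f) - 1L) * step) %% n
  for (k in seq_along(f)) v[idx[k] + 1L] <- v[idx[k] + 1L] + f[k]
  fft(v)
}

## Circular convolution of every column of X with a filter given by its
## length-nrow(X) DFT; conj = TRUE computes circular correlation instead.
## The forward FFT of X is computed once and shared between the two
## filters of a quadrature pair.
conv_cols_pair <- function(X, Fh, Fg, conj = FALSE) {
  if (conj) { Fh <- Conj(Fh); Fg <- Conj(Fg) }
  Xf <- mvfft(X)
  n <- nrow(X)
  list(Re(mvfft(Xf * Fh, inverse = TRUE)) / n,
       Re(mvfft(Xf * Fg, inverse = TRUE)) / n)
}

## Forward stationary 2D wavelet transform.  Returns a list with the
## final approximation `LL` and one list per level holding the LH, HL
## and HH detail bands (level 1 = finest).
swt2 <- function(img, levels) {
  H <- nrow(img); W <- ncol(img)
  a <- img
  detail <- vector("list", levels)
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    Fh_c <- upsampled_filter_fft(DB12_H, step, H)
    Fg_c <- upsampled_filter_fft(DB12_G, step, H)
    Fh_r <- upsampled_filter_fft(DB12_H, step, W)
    Fg_r <- upsampled_filter_fft(DB12_G, step, W)
    lh <- conv_cols_pair(a, Fh_c, Fg_c)
    ll_lh <- conv_cols_pair(t(lh[[1]]), Fh_r, Fg_r)
    hl_hh <- conv_cols_pair(t(lh[[2]]), Fh_r, Fg_r)
    detail[[j]] <- list(LH = t(ll_lh[[2]]), HL = t(hl_hh[[1]]),
                        HH = t(hl_hh[[2]]))
    a <- t(ll_lh[[1]])
  }
  list(LL = a, detail = detail, levels = levels, dim = c(H, W))
}

## Inverse stationary 2D wavelet transform.
iswt2 <- function(w) {
  a <- w$LL
  H <- w$dim[1]; W <- w$dim[2]
  for (j in rev(seq_len(w$levels))) {
    step <- 2L^(j - 1L)
    Fh_c <- upsampled_filter_fft(DB12_H, step, H)
    Fg_c <- upsampled_filter_fft(DB12_G, step, H)
    Fh_r <- upsampled_filter_fft(DB12_H, step, W)
    Fg_r <- upsampled_filter_fft(DB12_G, step, W)
    d <- w$detail[[j]]
    rec_row <- function(X, Y) {
      Xf <- mvfft(t(X)) * Conj(Fh_r) + mvfft(t(Y)) * Conj(Fg_r)
      t(Re(mvfft(Xf, inverse = TRUE))) / (2 * W)
    }
    L1 <- rec_row(a, d$LH)
    H1 <- rec_row(d$HL, d$HH)
    Xf <- mvfft(L1) * Conj(Fh_c) + mvfft(H1) * Conj(Fg_c)
    a <- Re(mvfft(Xf, inverse = TRUE)) / (2 * H)
  }
  a
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
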