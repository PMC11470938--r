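# bior2.6 biorthogonal spline filter bank (14 taps), standard published
# coefficients. dec_* analyse, rec_* synthesise.
.bior26 <- local({
  dec_lo <- c(0, -0.006905339660024878, 0.013810679320049757,
              0.04695630968816917, -0.1077232986963881, -0.16987135563661201,
              0.4474660099696121, 0.966747552403483, 0.4474660099696121,
              -0.16987135563661201, -0.1077232986963881, 0.04695630968816917,
              0.013810679320049757, -0.006905339660024878)
  dec_hi <- c(0, 0, 0, 0, 0, 0.3535533905932738, -0.7071067811865476,
              0.3535533905932738, 0, 0, 0, 0, 0, 0)
  rec_lo <- c(0, 0, 0, 0, 0, 0.3535533905932738, 0.7071067811865476,
              0.3535533905932738, 0, 0, 0, 0, 0, 0)
  rec_hi <- c(0, 0.006905339660024878, 0.013810679320049757,
              -0.04695630968816917, -0.1077232986963881, 0.16987135563661201,
              0.4474660099696121, -0.966747552403483, 0.4474660099696121,
              0.16987135563661201, -0.1077232986963881, -0.04695630968816917,
              0.013810679320049757, 0.006905339660024878)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi,
       length = 14L)
})

# circular convolution of x with filter h (h zero-padded to length(x)), via FFT
.circconv <- function(x, h) {
  n <- length(x)
  if (length(h) > n) stop("filter longer than signal in circular convolution")
  H <- stats::fft(c(h, rep(0, n - length(h))))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# circular left-shift by k (k >= 0): y[i] = x[i + k]
.circshift_left <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(k + 1):n], x[1:k])
}

.upsample_filter <- function(h, u) {
  if (u == 1L) return(h)
  out <- numeric(u * length(h))
  out[seq(1, length(out), by = u)] <- h
  out
}

#' Stationary wavelet transform with the bior2.6 wavelet
#'
#' Undecimated (à trous) periodized SWT. At level `j` the analysis filters are
#' upsampled by `2^(j-1)` and applied as a centred circular correlation, so the
#' coefficient series stay aligned with the input (shift-invariant).
#'
#' @param x numeric series; its length must be a multiple of `2^levels`.
#' @param levels number of decomposition levels.
#' @return list with one element per level (finest first), each a list with
#'   elements `a` (approximation) and `d` (detail), both `length(x)` long.
#' @seealso [iswt_bior26()], [swt_bandpass()]
#' @export
swt_bior26 <- function(x, levels) {
  n <- length(x)
  stopifnot(levels >= 1)
  if (n %% 2^levels != 0)
    stop("series length must be a multiple of 2^levels for the periodized SWT")
  f <- .bior26
  half <- f$length / 2L  # centring shift of the 14-tap bank
  a <- as.numeric(x)
  out <- vector("list", levels)
  for (j in seq_len(levels)) {
    u <- 2L^(j - 1L)
    ca <- .circshift_left(.circconv(a, .upsample_filter(f$dec_lo, u)), half * u)
    cd <- .circshift_left(.circconv(a, .upsample_filter(f$dec_hi, u)), half * u)
    out[[j]] <- list(a = ca, d = cd)
    a <- ca
  }
  out
}

#' Inverse stationary wavelet transform (bior2.6)
#'
#' Reconstructs the series from SWT coefficients, averaging the even/odd
#' synthesis branches; exact inverse of [swt_bior26()] to machine precision.
#'
#' @param coeffs list as returned by [swt_bior26()] (finest level first).
#' @return numeric series of the original length.
#' @export
iswt_bior26 <- function(coeffs) {
  f <- .bior26
  half <- f$length / 2L
  levels <- length(coeffs)
  a <- coeffs[[levels]]$a
  for (j in rev(seq_len(levels))) {
    u <- 2L^(j - 1L)
    rec <- 0.5 * (.circconv(a, .upsample_filter(f$rec_lo, u)) +
                  .circconv(coeffs[[j]]$d, .upsample_filter(f$rec_hi, u)))
    a <- .circshift_left(rec, (half - 1L) * u)
  }
  a
}

# symmetric (reflect) padding to the next multiple of 2^levels, split evenly
.pad_reflect <- function(x, levels) {
  n <- length(x)
  m <- 2L^levels
  total <- (m - n %% m) %% m
  left <- total %/% 2L
  right <- total - left
  if (total == 0L) return(list(x = x, left = 0L, n = n))
  if (left > n || right > n) {
    # very short series: repeat reflection as needed
    while (left > 0 || right > 0) {
      lpad <- min(left, length(x)); rpad <- min(right, length(x))
      x <- c(rev(x[seq_len(lpad)]), x, rev(x)[seq_len(rpad)])
      left <- left - lpad; right <- right - rpad
    }
    return(list(x = x, left = (length(x) - n) %/% 2L, n = n))
  }
  list(x = c(rev(x[seq_len(left)]), x, rev(x)[n - seq_len(right) + 1L]),
       left = left, n = n)
}

# detail levels whose nominal dyadic band [fs/2^(j+1), fs/2^j] intersects
# the open interval (f_lo, f_hi)
.band_levels <- function(fs, f_lo, f_hi) {
  keep <- integer(0)
  j <- 1L
  repeat {
    lo <- fs / 2^(j + 1); hi <- fs / 2^j
    if (lo < f_hi && hi > f_lo) keep <- c(keep, j)
    if (hi <= f_lo) break
    j <- j + 1L
    if (j > 24L) break
  }
  if (!length(keep))
    stop("sampling rate too low to represent the requested band")
  keep
}

#' Band-isolated SWT reconstruction
#'
#' Computes the bior2.6 SWT, keeps only the detail levels whose nominal dyadic
#' band intersects `(f_lo, f_hi)`, zeroes everything else (including the
#' deepest approximation), and reconstructs. At 60 Hz with the default
#' 10-20 Hz band the retained levels are d1 (15-30 Hz) and d2 (7.5-15 Hz).
#' The series is reflect-padded to the next multiple of `2^levels`; the pad is
#' stripped after reconstruction.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz (default 10 and 20).
#' @return numeric series, the band-limited reconstruction, same length as `x`.
#' @export
swt_bandpass <- function(x, fs, f_lo = 10, f_hi = 20) {
  if (fs / 2 < f_hi)
    stop("sampling rate too low to represent ", f_hi, " Hz")
  keep <- .band_levels(fs, f_lo, f_hi)
  levels <- max(keep)
  p <- .pad_reflect(as.numeric(x), levels)
  cf <- swt_bior26(p$x, levels)
  for (j in seq_len(levels)) {
    cf[[j]]$a <- numeric(length(p$x))  # only the deepest a is used by iswt
    if (!(j %in% keep)) cf[[j]]$d <- numeric(length(p$x))
  }
  r <- iswt_bior26(cf)
  r[p$left + seq_len(p$n)]
}

#' Brick-wall FFT band-pass filter
#'
#' Frequency-domain ideal band-pass: Fourier coefficients with
#' `f_lo <= |f| <= f_hi` are kept, all others (including DC) zeroed. Used as
#' the independent oracle against the stationary-wavelet band isolation.
#'
#' @inheritParams swt_bandpass
#' @return filtered series, same length as `x`.
#' @export
fft_bandpass <- function(x, fs, f_lo = 10, f_hi = 20) {
  if (fs / 2 < f_hi)
    stop("sampling rate too low to represent ", f_hi, " Hz")
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided |frequency|
  X <- stats::fft(as.numeric(x))
  X[!(f >= f_lo & f <= f_hi)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}
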