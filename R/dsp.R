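#' Hamming window
#'
#' Periodic-symmetric Hamming window as used for short-time analysis frames.
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @keywords internal
hamming_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density estimate
#'
#' Averaged-periodogram PSD with Hamming-windowed, 50%-overlapping segments.
#' Used for the low-frequency energy ratio and for spectral sanity checks on
#' generated audio.
#'
#' @param x Numeric waveform.
#' @param fs Sample rate in Hz.
#' @param nfft Segment length in samples (default 2048). Shortened to
#'   `length(x)` for short inputs.
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz), one-sided.
#' @export
welch_psd <- function(x, fs, nfft = 2048, overlap = 0.5) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  if (n < 8) stop("welch_psd: input too short")
  nfft <- min(nfft, n)
  hop <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  w <- hamming_window(nfft)
  scale <- fs * sum(w^2)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (length(starts) * scale)
  half <- floor(nfft / 2)
  onesided <- pxx[1:(half + 1)]
  # fold the negative-frequency half into interior bins
  if (nfft %% 2 == 0) {
    onesided[2:half] <- 2 * onesided[2:half]
  } else {
    onesided[2:(half + 1)] <- 2 * onesided[2:(half + 1)]
  }
  list(freq = (0:half) * fs / nfft, psd = onesided)
}

#' Band-energy fraction of a PSD
#'
#' Trapezoidal integral of the PSD below `cutoff_hz` divided by the integral
#' over the full one-sided band.
#'
#' @param freq,psd Vectors as returned by [welch_psd()].
#' @param cutoff_hz Upper edge of the numerator band (exclusive).
#' @return Fraction in \[0, 1\].
#' @keywords internal
band_energy_fraction <- function(freq, psd, cutoff_hz) {
  trapz <- function(x, y) {
    if (length(x) < 2) return(0)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  total <- trapz(freq, psd)
  if (total <= 0) return(NA_real_)
  lo <- freq < cutoff_hz
  if (!any(lo)) return(0)
  # include the interpolated point at the cutoff for an exact band edge
  idx <- which(lo)
  f_lo <- freq[idx]
  p_lo <- psd[idx]
  k <- max(idx)
  if (k < length(freq)) {
    fr <- (cutoff_hz - freq[k]) / (freq[k + 1] - freq[k])
    f_lo <- c(f_lo, cutoff_hz)
    p_lo <- c(p_lo, psd[k] + fr * (psd[k + 1] - psd[k]))
  }
  trapz(f_lo, p_lo) / total
}

#' Bilinear sample of a 2-D field at fractional coordinates
#'
#' Samples `img[(y, x)]` at real-valued positions with bilinear interpolation;
#' coordinates are zero-based, positions outside the field read as zero. This
#' is the interpolation core shared by the offset-sampled convolution and by
#' image resizing.
#'
#' @param img Numeric matrix (H x W).
#' @param ys,xs Zero-based fractional row/column positions (equal length).
#' @return Numeric vector of sampled values.
#' @export
bilinear_sample <- function(img, ys, xs) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;  fx <- xs - x0
  pick <- function(yy, xx) {
    ok <- yy >= 0 & yy <= (H - 1) & xx >= 0 & xx <= (W - 1)
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v00 <- pick(y0, x0); v01 <- pick(y0, x0 + 1)
  v10 <- pick(y0 + 1, x0); v11 <- pick(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Bilinear image resize
#'
#' Resizes a matrix to `out_h` x `out_w` with align-corners bilinear
#' interpolation (deterministic, no antialias filter).
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  ys <- if (out_h == 1) rep(0, 1) else (0:(out_h - 1)) * (H - 1) / (out_h - 1)
  xs <- if (out_w == 1) rep(0, 1) else (0:(out_w - 1)) * (W - 1) / (out_w - 1)
  grid_y <- rep(ys, times = out_w)
  grid_x <- rep(xs, each = out_h)
  matrix(bilinear_sample(img, grid_y, grid_x), nrow = out_h, ncol = out_w)
}

#' Root-mean-square of a waveform
#' @param x Numeric vector.
#' @return Scalar RMS.
#' @keywords internal
rms <- function(x) sqrt(mean(x^2))

#' Normalize a waveform to unit RMS
#' @param x Numeric vector with nonzero energy.
#' @return Rescaled vector with RMS 1.
#' @keywords internal
unit_rms <- function(x) {
  r <- rms(x)
  if (r == 0) stop("cannot normalize a silent waveform")
  x / r
}
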