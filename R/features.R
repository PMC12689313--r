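# The four acoustic feature representations and the adaptive filter-bank
# enhancement. All filter banks share one substrate: per-frame, per-filter
# energies E_i = sum_f H_i(f) * P_t(f), on which the enhancement operates
# before any log compression.

#' Short-time Fourier transform of a segment
#'
#' Windows the waveform into Hamming frames on the given grid and computes
#' the per-frame DFT. The frame count is `floor((len - N) / hop) + 1`.
#'
#' @param segment An `audio_segment`, `audio_signal` or numeric waveform.
#' @param grid A [frame_grid()]; defaults to 20 ms / 10 ms at the segment's
#'   sample rate.
#' @return Object of class `spectrum`: list with `stft` (complex N x T),
#'   `power` (N x T), `sample_rate`, `grid`.
#' @export
stft_frames <- function(segment, grid = NULL) {
  x <- if (is.list(segment)) segment$samples else as.numeric(segment)
  fs <- if (is.list(segment)) segment$sample_rate else SNORE_SR
  if (is.null(grid)) grid <- frame_grid(fs)
  N <- grid$frame_length
  if (N > length(x)) stop("frame longer than segment")
  starts <- seq(1L, length(x) - N + 1L, by = grid$hop)
  frames <- vapply(starts, function(s) x[s:(s + N - 1L)] * grid$window,
                   numeric(N))
  X <- stats::mvfft(matrix(frames, nrow = N))
  structure(list(stft = X, power = Mod(X)^2, sample_rate = fs, grid = grid),
            class = "spectrum")
}

# One-sided bin frequencies of a spectrum.
spectrum_freqs <- function(spec) {
  N <- nrow(spec$stft)
  (0:floor(N / 2)) * spec$sample_rate / N
}

# One-sided power matrix (bins x frames).
spectrum_power_onesided <- function(spec) {
  N <- nrow(spec$power)
  spec$power[1:(floor(N / 2) + 1), , drop = FALSE]
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel triangular filter bank
#'
#' `M` triangular filters with centers equally spaced on the Mel scale
#' between `fmin` and `fmax`, evaluated on the one-sided FFT bin frequencies.
#'
#' @param freqs FFT bin frequencies (Hz).
#' @param M Number of filters.
#' @param fmin,fmax Band edges in Hz.
#' @return Matrix M x length(freqs) of non-negative filter responses.
#' @export
mel_filter_bank <- function(freqs, M = 128, fmin = 0, fmax = max(freqs)) {
  stopifnot(M >= 1, fmax > fmin)
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = M + 2))
  H <- matrix(0, M, length(freqs))
  for (m in seq_len(M)) {
    lo <- pts[m]; cen <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (cen - lo)
    dn <- (hi - freqs) / (hi - cen)
    H[m, ] <- pmax(0, pmin(up, dn))
  }
  H
}

new_filter_bank_response <- function(bank_kind, H, energies, sample_rate,
                                     meta = list()) {
  stopifnot(all(H >= 0), all(is.finite(energies)), all(energies >= -1e-12))
  structure(list(bank_kind = bank_kind, H = H, energies = energies,
                 sample_rate = sample_rate, enhanced = FALSE, meta = meta),
            class = "filter_bank_response")
}

#' Mel spectrogram of a segment
#'
#' Applies a Mel triangular filter bank to the one-sided STFT power spectrum;
#' the log map is the natural log of the filter-bank energies with a small
#' floor so silent frames stay finite.
#'
#' @param spec A `spectrum` from [stft_frames()], or a segment (converted).
#' @param M Number of Mel filters (default 128).
#' @param fmin,fmax Filter-bank band edges in Hz.
#' @return A `filter_bank_response` with `bank_kind = "mel"`; use
#'   [log_energies()] for the log map.
#' @export
mel_spectrogram <- function(spec, M = 128, fmin = 0, fmax = NULL) {
  if (!inherits(spec, "spectrum")) spec <- stft_frames(spec)
  freqs <- spectrum_freqs(spec)
  if (is.null(fmax)) fmax <- max(freqs)
  if (M > length(freqs)) stop("more filters than usable FFT bins")
  H <- mel_filter_bank(freqs, M, fmin, fmax)
  P <- spectrum_power_onesided(spec)
  E <- H %*% P
  new_filter_bank_response("mel", H, E, spec$sample_rate,
                           meta = list(M = M, fmin = fmin, fmax = fmax))
}

#' Log map of filter-bank energies
#'
#' @param resp A `filter_bank_response` (or a plain energy matrix).
#' @param floor_eps Energy floor applied before the natural log.
#' @return Matrix of `log(pmax(E, floor_eps))`.
#' @export
log_energies <- function(resp, floor_eps = 1e-10) {
  E <- if (inherits(resp, "filter_bank_response")) resp$energies else resp
  log(pmax(E, floor_eps))
}

#' Mel-frequency cepstral coefficients
#'
#' Cosine transform of the log Mel energies:
#' `C(l) = sum_m s(m) * cos(pi * l * (m - 0.5) / M)`, for `l = 1..L` over the
#' `M` filters.
#'
#' @param s Log Mel energy matrix (M x frames) or vector.
#' @param L Number of coefficients (default 13).
#' @return Matrix L x frames of coefficients.
#' @export
mfcc <- function(s, L = 13) {
  if (is.vector(s)) s <- matrix(s, ncol = 1)
  M <- nrow(s)
  if (L > M) stop("requested more coefficients than filters")
  m <- seq_len(M)
  D <- t(vapply(seq_len(L), function(l) cos(pi * l * (m - 0.5) / M),
                numeric(M)))
  D %*% s
}

#' Constant-Q analysis parameters
#'
#' Center frequencies follow `f_k = f1 * 2^((k - 1) / B)`; the quality factor
#' `Q = f_k / delta_f_k = 1 / (2^(1/B) - 1)` is constant across bins.
#'
#' @param f1 Center frequency of the lowest bin (Hz); default C1 = 32.7 Hz.
#' @param bins_per_octave Bins per octave (default 12).
#' @param n_bins Total number of bins (default 84 = 7 octaves).
#' @return Object of class `cqt_params` with the fields plus `Q` and
#'   `center_freqs`.
#' @export
cqt_params <- function(f1 = 32.70320, bins_per_octave = 12, n_bins = 84) {
  stopifnot(f1 > 0, bins_per_octave >= 1, n_bins >= 1)
  Q <- 1 / (2^(1 / bins_per_octave) - 1)
  fk <- f1 * 2^((seq_len(n_bins) - 1) / bins_per_octave)
  structure(list(f1 = f1, bins_per_octave = bins_per_octave, n_bins = n_bins,
                 Q = Q, center_freqs = fk), class = "cqt_params")
}

#' Constant-Q spectrogram of a segment
#'
#' Geometrically spaced bins with constant center-frequency-to-bandwidth
#' ratio, realized as a spectral-domain filter bank: each bin is a
#' raised-cosine window of width `f_k / Q` centered on `f_k`, applied to the
#' one-sided STFT power spectrum. Bins narrower than the FFT resolution take
#' their nearest FFT bin.
#'
#' @param segment Segment or `spectrum`.
#' @param params A [cqt_params()].
#' @return A `filter_bank_response` with `bank_kind = "cqt_bins"` and the
#'   params in `meta`.
#' @export
cqt_spectrogram <- function(segment, params = cqt_params()) {
  stopifnot(inherits(params, "cqt_params"))
  spec <- if (inherits(segment, "spectrum")) segment else stft_frames(segment)
  freqs <- spectrum_freqs(spec)
  nyq <- spec$sample_rate / 2
  if (max(params$center_freqs) >= nyq) {
    stop("highest CQT bin (", round(max(params$center_freqs), 1),
         " Hz) reaches or exceeds Nyquist (", nyq, " Hz)")
  }
  H <- matrix(0, params$n_bins, length(freqs))
  for (k in seq_len(params$n_bins)) {
    fk <- params$center_freqs[k]
    bw <- fk / params$Q
    u <- (freqs - fk) / bw
    w <- ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
    if (sum(w) == 0) w[which.min(abs(freqs - fk))] <- 1
    H[k, ] <- w / sum(w)
  }
  E <- H %*% spectrum_power_onesided(spec)
  new_filter_bank_response("cqt_bins", H, E, spec$sample_rate,
                           meta = list(params = params))
}

#' CENS chroma features of a segment
#'
#' 12-dimensional pitch-class energies per frame (chroma filter bank over the
#' STFT bins), short-time-statistics style: per-frame L1 normalization,
#' step-function quantization, temporal smoothing with a Hann window, time
#' downsampling, and final per-frame unit (L2) normalization. Frames with
#' total energy below the floor map to the uniform chroma vector.
#'
#' @param segment Segment or `spectrum`. Raw segments are analyzed with
#'   longer frames (2048 samples, hop 512 at 22.05 kHz) than the default
#'   grid so that adjacent semitones resolve to distinct FFT bins.
#' @param smooth_frames Smoothing window length in frames (default 41).
#' @param downsample Time downsampling factor (default 10).
#' @param fmin,fmax Frequency range mapped to pitch classes.
#' @param floor_eps Silence floor on per-frame total energy.
#' @return A `filter_bank_response` with `bank_kind = "chroma"`; rows are
#'   pitch classes C, C#, ..., B.
#' @export
cens <- function(segment, smooth_frames = 41, downsample = 10,
                 fmin = 65, fmax = 2000, floor_eps = 1e-10) {
  spec <- if (inherits(segment, "spectrum")) {
    segment
  } else {
    fs <- if (is.list(segment)) segment$sample_rate else SNORE_SR
    grid <- frame_grid(fs, frame_length_ms = 2048 / fs * 1000,
                       hop_ms = 512 / fs * 1000)
    stft_frames(segment, grid)
  }
  freqs <- spectrum_freqs(spec)
  classes <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  H <- matrix(0, 12, length(freqs))
  sel <- which(freqs >= fmin & freqs <= fmax)
  # MIDI pitch class: A4 = 440 Hz = class A (index 10)
  pc <- (round(69 + 12 * log2(freqs[sel] / 440)) %% 12 + 12) %% 12
  # map MIDI class 0 = C
  for (i in seq_along(sel)) H[pc[i] + 1, sel[i]] <- 1
  E <- H %*% spectrum_power_onesided(spec)
  # per-frame L1 normalization with silence -> uniform
  tot <- colSums(E)
  Cn <- sweep(E, 2, pmax(tot, floor_eps), "/")
  Cn[, tot < floor_eps] <- 1 / 12
  # CENS step quantization
  quant <- function(v) {
    q <- numeric(length(v))
    q[v > 0.05] <- 1; q[v > 0.1] <- 2; q[v > 0.2] <- 3; q[v > 0.4] <- 4
    q
  }
  Q <- apply(Cn, 2, quant)
  # Hann smoothing along time, then downsample
  w <- 0.5 * (1 - cos(2 * pi * (0:(smooth_frames - 1)) / (smooth_frames - 1)))
  w <- w / sum(w)
  S <- t(apply(Q, 1, function(row) {
    stats::filter(c(rep(row[1], smooth_frames), row, rep(row[length(row)], smooth_frames)),
                  w, sides = 2)[(smooth_frames + 1):(smooth_frames + length(row))]
  }))
  keep <- seq(1, ncol(S), by = downsample)
  S <- S[, keep, drop = FALSE]
  # unit L2 norm per frame, uniform on degenerate frames
  nrm <- sqrt(colSums(S^2))
  S <- sweep(S, 2, pmax(nrm, floor_eps), "/")
  S[, nrm < floor_eps] <- 1 / sqrt(12)
  resp <- new_filter_bank_response("chroma", H, S, spec$sample_rate,
                                   meta = list(classes = classes,
                                               smooth_frames = smooth_frames,
                                               downsample = downsample))
  resp
}

#' Enhancement configuration
#'
#' @param beta Gain applied to selected filters (>= 1; default 1.5, the
#'   validation-set optimum of the grid search).
#' @param percentile Per-frame energy percentile above which a filter is
#'   enhanced (strict comparison; default 80).
#' @return Object of class `enhancement_config`.
#' @export
enhancement_config <- function(beta = 1.5, percentile = 80) {
  stopifnot(beta >= 1, percentile > 0, percentile < 100)
  structure(list(beta = beta, percentile = percentile,
                 comparison = "strict-greater"),
            class = "enhancement_config")
}

#' Adaptive filter-bank enhancement
#'
#' For each frame, filters whose energy strictly exceeds the frame's
#' `percentile`-th energy percentile (sorted linear interpolation) are scaled
#' by `beta`; all other filters pass through unchanged. The selection mask
#' depends only on the pre-enhancement energies. A single-filter bank has a
#' degenerate percentile and is returned unchanged.
#'
#' @param resp A `filter_bank_response` (or plain energy matrix).
#' @param cfg An [enhancement_config()].
#' @return Same type as the input with enhanced energies; a
#'   `filter_bank_response` additionally carries `gains` and `enhanced=TRUE`.
#' @export
enhance <- function(resp, cfg = enhancement_config()) {
  stopifnot(inherits(cfg, "enhancement_config"))
  E <- if (inherits(resp, "filter_bank_response")) resp$energies else resp
  if (is.vector(E)) E <- matrix(E, ncol = 1)
  gains <- matrix(1, nrow(E), ncol(E))
  if (nrow(E) > 1) {
    for (t in seq_len(ncol(E))) {
      q <- stats::quantile(E[, t], cfg$percentile / 100, type = 7, names = FALSE)
      gains[E[, t] > q, t] <- cfg$beta
    }
  }
  E2 <- E * gains
  if (inherits(resp, "filter_bank_response")) {
    resp$energies <- E2
    resp$gains <- gains
    resp$enhanced <- TRUE
    resp
  } else {
    attr(E2, "gains") <- gains
    E2
  }
}

#' Grid search for the enhancement gain
#'
#' Evaluates `eval_fn` on each candidate gain and returns the argmax of the
#' validation metric; ties are broken toward the smallest gain.
#'
#' @param eval_fn Function of one numeric argument (beta) returning a scalar
#'   validation metric (higher is better).
#' @param candidates Candidate gains (default 1.1 to 2.0, step 0.1).
#' @return List with `beta` (best candidate) and `scores` (named vector).
#' @export
grid_search_beta <- function(eval_fn, candidates = seq(1.1, 2.0, by = 0.1)) {
  scores <- vapply(candidates, eval_fn, numeric(1))
  best <- candidates[which.max(scores)]  # which.max takes the first maximum
  list(beta = best, scores = stats::setNames(scores, candidates))
}

#' Render a feature map as a fixed-size image
#'
#' Optional log compression, per-image min-max normalization to \[0, 1\]
#' (a constant map renders as zeros), bilinear resize, and replication to
#' three channels.
#'
#' @param map Numeric matrix (filters/coefficients x frames) or a
#'   `filter_bank_response` (its energies are used).
#' @param log_compress Apply `log(pmax(map, 1e-10))` first (used for power-
#'   like maps; MFCC and CENS maps are rendered as-is).
#' @param size Output height and width in pixels (default 224).
#' @return Object of class `feature_image`: `pixels` is a `size x size x 3`
#'   array in \[0, 1\].
#' @export
render_image <- function(map, log_compress = TRUE, size = 224) {
  if (inherits(map, "filter_bank_response")) map <- map$energies
  stopifnot(is.matrix(map), all(is.finite(map)))
  if (log_compress) map <- log(pmax(map, 1e-10))
  rng <- range(map)
  z <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1]) else map * 0
  # display convention: first filter (lowest frequency) at the bottom row
  z <- z[rev(seq_len(nrow(z))), , drop = FALSE]
  r <- resize_bilinear(z, size, size)
  px <- array(rep(r, 3), dim = c(size, size, 3))
  structure(list(pixels = px, size = size), class = "feature_image")
}

#' Compute one of the four feature images for a segment
#'
#' End-to-end helper: STFT, the chosen filter bank, optional adaptive
#' enhancement (applied to the filter-bank energies before any log or cosine
#' transform), then image rendering.
#'
#' @param segment Segment-like input for [stft_frames()].
#' @param kind `"mel"`, `"mfcc"`, `"cqt"` or `"cens"`.
#' @param enhanced Apply the adaptive enhancement (default TRUE).
#' @param beta Enhancement gain (default 1.5).
#' @param size Image size (default 224).
#' @param M Mel filter count for mel/mfcc.
#' @return A `feature_image` with `kind` and `enhanced` recorded.
#' @export
feature_image <- function(segment, kind = c("mel", "mfcc", "cqt", "cens"),
                          enhanced = TRUE, beta = 1.5, size = 224, M = 128) {
  kind <- match.arg(kind)
  cfg <- enhancement_config(beta = beta)
  img <- switch(kind,
    mel = {
      r <- mel_spectrogram(stft_frames(segment), M = M)
      if (enhanced) r <- enhance(r, cfg)
      render_image(log_energies(r), log_compress = FALSE, size = size)
    },
    mfcc = {
      r <- mel_spectrogram(stft_frames(segment), M = M)
      if (enhanced) r <- enhance(r, cfg)
      render_image(mfcc(log_energies(r), L = 13), log_compress = FALSE,
                   size = size)
    },
    cqt = {
      r <- cqt_spectrogram(segment)
      if (enhanced) r <- enhance(r, cfg)
      render_image(log_energies(r), log_compress = FALSE, size = size)
    },
    cens = {
      r <- cens(segment)
      if (enhanced) r <- enhance(r, cfg)
      render_image(r$energies, log_compress = FALSE, size = size)
    })
  img$kind <- kind
  img$enhanced <- enhanced
  img
}
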