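# Feature representations and the adaptive enhancement.

test_that("framed transform equals the direct DFT summation", {
  g64 <- structure(list(sample_rate = 22050, frame_length = 64L, hop = 32L,
                        window = snoreacoustics:::hamming_window(64)),
                   class = "frame_grid")
  set.seed(1)
  for (rep in 1:5) {
    x <- stats::rnorm(64)
    sp <- stft_frames(c(x, numeric(32)), g64)
    direct <- oracle_dft(x, g64$window)
    expect_lt(max(Mod(sp$stft[, 1] - direct)) / max(Mod(direct)), 1e-8)
  }
  # pure tone at a bin frequency peaks at that bin
  k0 <- 8
  tone <- sin(2 * pi * k0 * (0:63) / 64)
  sp <- stft_frames(c(tone, numeric(32)), g64)
  expect_equal(which.max(Mod(sp$stft[1:33, 1])) - 1L, k0)
  # all-zero input gives an all-zero spectrum
  spz <- stft_frames(numeric(200), g64)
  expect_true(all(spz$power == 0))
  expect_error(stft_frames(numeric(10), g64), "frame longer")
})

test_that("Mel filter-bank energies match direct summation on flat spectra", {
  g <- frame_grid(22050)
  N <- g$frame_length
  flat <- structure(list(stft = matrix(1 + 0i, N, 2), power = matrix(1, N, 2),
                         sample_rate = 22050, grid = g), class = "spectrum")
  r <- mel_spectrogram(flat, M = 24)
  expect_equal(unname(r$energies[, 1]), unname(rowSums(r$H)), tolerance = 1e-12)
  # zero power floors at ln(eps)
  zero <- flat; zero$power[] <- 0
  rz <- mel_spectrogram(zero, M = 24)
  expect_true(all(log_energies(rz) == log(1e-10)))
  # a tone on filter m0's peak maximizes s(m) at m0
  freqs <- snoreacoustics:::spectrum_freqs(flat)
  H <- mel_filter_bank(freqs, 24)
  m0 <- 10
  peak_bin <- which.max(H[m0, ])
  tone <- flat; tone$power[] <- 0; tone$power[peak_bin, ] <- 1
  rt <- mel_spectrogram(tone, M = 24)
  expect_equal(unname(which.max(rt$energies[, 1])), m0)
  expect_error(mel_spectrogram(flat, M = 10000), "more filters")
})

test_that("cepstral transform obeys its cosine-orthogonality structure", {
  expect_lt(max(abs(mfcc(matrix(7, 32, 4)))), 1e-9 * 32 * 7)
  # hand 4-term evaluation at M = 4, l = 1
  s <- c(1, 2, 3, 4)
  hand <- sum(s * cos(pi * 1 * ((1:4) - 0.5) / 4))
  expect_equal(mfcc(s, L = 1)[1, 1], hand, tolerance = 1e-12)
  # a pure cosine in m projects onto exactly one coefficient
  M <- 16
  s2 <- cos(pi * 2 * ((1:M) - 0.5) / M)
  cc <- mfcc(s2, L = 6)
  expect_equal(cc[2, 1], M / 2, tolerance = 1e-9)
  expect_lt(max(abs(cc[-2, 1])), 1e-9)
  expect_error(mfcc(s, L = 10), "more coefficients")
})

test_that("constant-Q bins are geometric with constant Q", {
  p <- cqt_params(f1 = 32.7, bins_per_octave = 12, n_bins = 84)
  expect_equal(p$center_freqs[1], 32.7)
  expect_equal(p$center_freqs[13], 65.4, tolerance = 1e-9)  # one octave up
  # Q measured from adjacent spacing is constant across bins
  dfk <- diff(p$center_freqs)
  q_meas <- p$center_freqs[-length(p$center_freqs)] / dfk
  expect_lt(diff(range(q_meas)) / mean(q_meas), 0.01)
  expect_error(cqt_spectrogram(make_tone(200),
                               cqt_params(f1 = 1000, n_bins = 60)),
               "Nyquist")
  r <- cqt_spectrogram(make_tone(200))
  expect_equal(nrow(r$energies), 84)
  expect_true(all(r$H >= 0))
})

test_that("chroma statistics map pitch classes and degrade gracefully", {
  ce <- cens(make_tone(440))
  cls <- ce$meta$classes[which.max(rowMeans(ce$energies))]
  expect_equal(cls, "A")
  # octave transposition leaves the dominant chroma class unchanged
  ce2 <- cens(make_tone(880))
  expect_equal(ce$meta$classes[which.max(rowMeans(ce2$energies))], "A")
  # silence maps to the uniform chroma vector
  cs <- cens(numeric(66150))
  expect_true(all(abs(cs$energies - 1 / sqrt(12)) < 1e-12))
  # frames are unit-norm
  expect_equal(unname(colSums(ce$energies^2)), rep(1, ncol(ce$energies)),
               tolerance = 1e-9)
})

test_that("enhancement scales only the strict top-percentile filters", {
  e <- enhance(matrix(c(1, 2, 3, 4, 10), ncol = 1))
  expect_equal(as.numeric(attr(e, "gains")), c(1, 1, 1, 1, 1.5))
  expect_equal(as.numeric(e), c(1, 2, 3, 4, 15))
  # uniform energies: percentile equals every value, strict > fails
  u <- enhance(matrix(5, 8, 1))
  expect_equal(as.numeric(u), rep(5, 8))
  # single filter: degenerate percentile, pass-through
  s1 <- enhance(matrix(3, 1, 4))
  expect_equal(as.numeric(s1), rep(3, 4))
})

test_that("enhancement matches the hand-coded oracle on random frames", {
  set.seed(7)
  cfg <- enhancement_config(beta = 1.5, percentile = 80)
  for (rep in 1:100) {
    n <- sample(5:64, 1)
    e <- stats::rexp(n)
    out <- enhance(matrix(e, ncol = 1), cfg)
    orc <- oracle_enhance_frame(e, 1.5, 80)
    expect_identical(as.logical(attr(out, "gains") > 1), orc$mask)
    expect_lt(max(abs(as.numeric(out) - orc$e)), 1e-12)
    # untouched filters bit-identical; touched exactly beta-fold
    expect_identical(as.numeric(out)[!orc$mask], e[!orc$mask])
    expect_identical(as.numeric(out)[orc$mask], 1.5 * e[orc$mask])
    # no more than ~20% of filters enhanced (plus tie slack)
    expect_lte(sum(orc$mask), ceiling(0.2 * n) + 1)
  }
})

test_that("the selection mask depends only on pre-enhancement energies", {
  set.seed(8)
  E <- matrix(stats::rexp(40 * 6), 40, 6)
  r1 <- enhance(E)
  g1 <- attr(r1, "gains")
  # recompute the mask from the original energies: identical
  r2 <- enhance(E)
  expect_identical(g1, attr(r2, "gains"))
  # filter-bank response objects carry gains and the enhanced flag
  g <- frame_grid(22050)
  sp <- stft_frames(make_tone(300), g)
  mel <- mel_spectrogram(sp, M = 32)
  en <- enhance(mel)
  expect_true(en$enhanced)
  expect_equal(dim(en$gains), dim(mel$energies))
})

test_that("the gain grid search returns the argmax with smallest-tie rule", {
  peak15 <- function(b) -(b - 1.5)^2
  expect_equal(grid_search_beta(peak15)$beta, 1.5)
  expect_equal(grid_search_beta(function(b) 1)$beta, 1.1)
  expect_equal(grid_search_beta(function(b) b)$beta, 2.0)
})

test_that("rendered images are fixed-shape, bounded and affine-invariant", {
  set.seed(2)
  m <- matrix(stats::rexp(32 * 50), 32, 50)
  img <- render_image(m, log_compress = TRUE, size = 224)
  expect_equal(dim(img$pixels), c(224, 224, 3))
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 1)
  # constant map renders as zeros (documented min-max convention)
  expect_true(all(render_image(matrix(4, 10, 10), FALSE, 32)$pixels == 0))
  # doubling contrast before min-max leaves the image unchanged
  a <- render_image(m, log_compress = FALSE, size = 64)
  b <- render_image(2 * m + 5, log_compress = FALSE, size = 64)
  expect_equal(a$pixels, b$pixels, tolerance = 1e-12)
})

test_that("feature images are computed end to end for all four kinds", {
  seg <- list(samples = synth_snore(snore_event_spec(duration_s = 3), seed = 4),
              sample_rate = 22050)
  for (kind in c("mel", "mfcc", "cqt", "cens")) {
    fi <- feature_image(seg, kind, size = 32, M = 32)
    expect_equal(dim(fi$pixels), c(32, 32, 3))
    expect_true(all(is.finite(fi$pixels)))
    expect_equal(fi$kind, kind)
    expect_true(fi$enhanced)
  }
})
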