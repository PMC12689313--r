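# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with naive loops or closed forms, never by calling
# the implementation under test.

# Direct O(N^2) windowed DFT of one frame.
oracle_dft <- function(x, window) {
  N <- length(x)
  xw <- x * window
  vapply(0:(N - 1), function(k) {
    sum(xw * exp(-1i * 2 * pi * k * (0:(N - 1)) / N))
  }, complex(1))
}

# Hand-coded percentile (sorted linear interpolation, the common default).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (if (lo < length(s)) s[lo + 1] - s[lo] else 0)
}

# Hand-coded enhancement of one frame of filter energies.
oracle_enhance_frame <- function(e, beta, pct) {
  if (length(e) == 1) return(list(e = e, mask = FALSE))
  q <- oracle_percentile(e, pct / 100)
  mask <- e > q
  list(e = ifelse(mask, beta * e, e), mask = mask)
}

# Bilinear read of img (H x W) at zero-based (y, x); out of bounds reads 0.
oracle_bilinear <- function(img, y, x) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  g <- function(r, c) {
    if (r >= 0 && r <= H - 1 && c >= 0 && c <= W - 1) img[r + 1, c + 1] else 0
  }
  (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x0 + 1)) +
    fy * ((1 - fx) * g(y0 + 1, x0) + fx * g(y0 + 1, x0 + 1))
}

# Plain 2-D convolution of a (C,H,W) array with weights (cout,cin,k,k),
# loop transcription.
oracle_conv2d <- function(x, w, b, stride = 1, pad = 0) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  dw <- dim(w); cout <- dw[1]; k <- dw[3]
  xp <- array(0, c(C, H + 2 * pad, W + 2 * pad))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(cout, Ho, Wo))
  for (o in seq_len(cout)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- 0
    for (ci in seq_len(C)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      acc <- acc + w[o, ci, ki, kj] *
        xp[ci, (i - 1) * stride + ki, (j - 1) * stride + kj]
    }
    y[o, i, j] <- acc + (if (is.null(b)) 0 else b[o])
  }
  y
}

# Depthwise convolution loop transcription; stride 1.
oracle_dwconv <- function(x, w, b, pad) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  k <- dim(w)[2]
  xp <- array(0, c(C, H + 2 * pad, W + 2 * pad))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  y <- array(0, c(C, H, W))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      acc <- acc + w[c, ki, kj] * xp[c, i + ki - 1, j + kj - 1]
    }
    y[c, i, j] <- acc + (if (is.null(b)) 0 else b[c])
  }
  y
}

# CBAM as a direct transcription of its defining equations.
oracle_cbam <- function(x, w0, w1, w_sp, spatial_kernel) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  sig <- function(v) 1 / (1 + exp(-v))
  f_avg <- apply(x, 1, mean)
  f_max <- apply(x, 1, max)
  mlp <- function(v) w1 %*% pmax(w0 %*% v, 0)
  mc <- sig(mlp(f_avg) + mlp(f_max))
  f1 <- x
  for (c in seq_len(C)) f1[c, , ] <- x[c, , ] * mc[c]
  s_avg <- apply(f1, c(2, 3), mean)
  s_max <- apply(f1, c(2, 3), max)
  stack <- array(0, c(2, H, W))
  stack[1, , ] <- s_avg; stack[2, , ] <- s_max
  s <- oracle_conv2d(stack, w_sp, NULL, stride = 1,
                     pad = (spatial_kernel - 1) %/% 2)
  ms <- sig(s[1, , ])
  f2 <- f1
  for (c in seq_len(C)) f2[c, , ] <- f1[c, , ] * ms
  f2
}

# AKConv as a per-pixel gather-and-weight loop.
oracle_akconv <- function(x, cfg, w) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  N <- cfg$num_param
  coords <- akconv_init_coords(N)
  pad_off <- (cfg$offset_kernel - 1) %/% 2
  off <- oracle_conv2d(x, w$w_off, w$b_off, stride = 1, pad = pad_off)
  cout <- nrow(w$w_pw)
  y <- array(0, c(cout, H, W))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    g <- numeric(C * N)
    for (n in seq_len(N)) {
      yy <- (i - 1) + coords[n, 1] + off[n, i, j]
      xx <- (j - 1) + coords[n, 2] + off[N + n, i, j]
      for (c in seq_len(C)) {
        g[(n - 1) * C + c] <- oracle_bilinear(x[c, , ], yy, xx)
      }
    }
    y[, i, j] <- w$w_pw %*% g + w$b_pw
  }
  if (isTRUE(cfg$include_norm)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      v <- y[, i, j]
      mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-6)
      y[, i, j] <- w$ln_g * (v - mu) / s + w$ln_b
    }
  }
  if (isTRUE(cfg$include_act)) y <- y / (1 + exp(-y))
  y
}

# ConvMod as hand-composed branch computation.
oracle_convmod <- function(x, cfg, w) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  xn <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- x[, i, j]
    mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-6)
    xn[, i, j] <- w$ln_g * (v - mu) / s + w$ln_b
  }
  a <- array(0, dim(x)); vv <- array(0, dim(x))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    a[, i, j] <- w$wa %*% xn[, i, j] + w$ba
    vv[, i, j] <- w$wv %*% xn[, i, j] + w$bv
  }
  a <- a * pnorm(a)  # GELU
  a <- oracle_dwconv(a, w$wdw, w$bdw, pad = cfg$dw_padding)
  m <- a * vv
  y <- array(0, dim(x))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    y[, i, j] <- w$wp %*% m[, i, j]
  }
  x + y
}

# Random weight set for an AKConv layer at given sizes.
rand_akconv_weights <- function(C, N, cout = C, ko = 3, seed = 1) {
  set.seed(seed)
  list(w_off = array(rnorm(2 * N * C * ko * ko, 0, 0.1), c(2 * N, C, ko, ko)),
       b_off = runif(2 * N, -0.3, 0.3),
       w_pw = matrix(rnorm(cout * C * N, 0, 0.2), cout, C * N),
       b_pw = rnorm(cout, 0, 0.1),
       ln_g = runif(cout, 0.5, 1.5), ln_b = rnorm(cout, 0, 0.1))
}

rand_convmod_weights <- function(d, k = 11, seed = 1) {
  set.seed(seed)
  list(ln_g = runif(d, 0.5, 1.5), ln_b = rnorm(d, 0, 0.1),
       wa = matrix(rnorm(d * d, 0, 0.2), d, d), ba = rnorm(d, 0, 0.1),
       wdw = array(rnorm(d * k * k, 0, 0.1), c(d, k, k)), bdw = rnorm(d, 0, 0.1),
       wv = matrix(rnorm(d * d, 0, 0.2), d, d), bv = rnorm(d, 0, 0.1),
       wp = matrix(rnorm(d * d, 0, 0.2), d, d))
}

# 3-second tone segment helper.
make_tone <- function(freq, duration_s = 3, fs = 22050, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(duration_s * fs) - 1)) / fs)
}
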