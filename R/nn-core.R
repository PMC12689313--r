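# Numerical core for the classifier: feature maps are C x (H*W) matrices
# (row = channel, column = spatial position, height index fastest), and every
# primitive provides a hand-derived backward pass so the network trains on
# CPU without an autodiff framework. Backward passes are validated against
# numerical gradients in the test suite.

conv_out_size <- function(n, pad, k, stride) (n + 2 * pad - k) %/% stride + 1L

# Zero-pad a C x (H*W) map by `pad` on all sides.
pad_map <- function(x, H, W, pad) {
  if (pad == 0) {
    return(list(x = x, H = H, W = W, inner = seq_len(H * W)))
  }
  C <- nrow(x)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- matrix(0, C, Hp * Wp)
  inner <- as.vector(outer((pad + 1):(pad + H), (pad + 1):(pad + W),
                           function(i, j) (j - 1L) * Hp + i))
  xp[, inner] <- x
  list(x = xp, H = Hp, W = Wp, inner = inner)
}

# For each of the k*k kernel taps, the flat indices (into the padded map)
# read by every output position. Tap order: (ki, kj) with ki fastest.
tap_indices <- function(Hp, Wp, k, stride, Ho, Wo) {
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  out <- vector("list", k * k)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      ip <- (io - 1L) * stride + ki
      jp <- (jo - 1L) * stride + kj
      out[[(kj - 1L) * k + ki]] <- (jp - 1L) * Hp + ip
    }
  }
  out
}

# Flatten a (cout, cin, k, k) weight array to the im2col matrix layout.
conv_weight_mat <- function(Wt) {
  d <- dim(Wt)
  cout <- d[1]; cin <- d[2]; k <- d[3]
  Wm <- matrix(0, cout, cin * k * k)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      t <- (kj - 1L) * k + ki
      Wm[, (t - 1L) * cin + seq_len(cin)] <- Wt[, , ki, kj]
    }
  }
  Wm
}

conv_weight_unmat <- function(Wm, cout, cin, k) {
  Wt <- array(0, c(cout, cin, k, k))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      t <- (kj - 1L) * k + ki
      Wt[, , ki, kj] <- Wm[, (t - 1L) * cin + seq_len(cin), drop = FALSE]
    }
  }
  Wt
}

# Standard convolution via im2col. Wt: (cout, cin, k, k); b: cout or NULL.
conv2d_fwd <- function(x, H, W, Wt, b, stride = 1L, pad = 0L) {
  d <- dim(Wt); cout <- d[1]; cin <- d[2]; k <- d[3]
  stopifnot(nrow(x) == cin)
  pp <- pad_map(x, H, W, pad)
  Ho <- conv_out_size(H, pad, k, stride); Wo <- conv_out_size(W, pad, k, stride)
  taps <- tap_indices(pp$H, pp$W, k, stride, Ho, Wo)
  cols <- matrix(0, cin * k * k, Ho * Wo)
  for (t in seq_along(taps)) {
    cols[(t - 1L) * cin + seq_len(cin), ] <- pp$x[, taps[[t]], drop = FALSE]
  }
  Wm <- conv_weight_mat(Wt)
  y <- Wm %*% cols
  if (!is.null(b)) y <- y + b
  list(y = y, H = Ho, W = Wo,
       cache = list(cols = cols, taps = taps, Wm = Wm, cin = cin, k = k,
                    Hp = pp$H, Wp = pp$W, inner = pp$inner, pad = pad,
                    cout = cout))
}

conv2d_bwd <- function(dy, cache) {
  cin <- cache$cin; k <- cache$k
  dWm <- dy %*% t(cache$cols)
  db <- rowSums(dy)
  dcols <- t(cache$Wm) %*% dy
  dxp <- matrix(0, cin, cache$Hp * cache$Wp)
  for (t in seq_along(cache$taps)) {
    rows <- (t - 1L) * cin + seq_len(cin)
    idx <- cache$taps[[t]]
    dxp[, idx] <- dxp[, idx] + dcols[rows, , drop = FALSE]
  }
  list(dx = dxp[, cache$inner, drop = FALSE],
       dW = conv_weight_unmat(dWm, cache$cout, cin, k), db = db)
}

# Depthwise convolution. Wt: (C, k, k); b: C or NULL. Stride 1 only.
dwconv_fwd <- function(x, H, W, Wt, b, pad) {
  C <- nrow(x); k <- dim(Wt)[2]
  pp <- pad_map(x, H, W, pad)
  Ho <- conv_out_size(H, pad, k, 1L); Wo <- conv_out_size(W, pad, k, 1L)
  taps <- tap_indices(pp$H, pp$W, k, 1L, Ho, Wo)
  Wm <- matrix(Wt, C, k * k)  # column t = tap (ki fastest) matches tap order
  y <- matrix(0, C, Ho * Wo)
  for (t in seq_along(taps)) {
    y <- y + Wm[, t] * pp$x[, taps[[t]], drop = FALSE]
  }
  if (!is.null(b)) y <- y + b
  list(y = y, H = Ho, W = Wo,
       cache = list(xp = pp$x, taps = taps, Wm = Wm, k = k,
                    Hp = pp$H, Wp = pp$W, inner = pp$inner))
}

dwconv_bwd <- function(dy, cache) {
  C <- nrow(dy); k <- cache$k
  dWm <- matrix(0, C, k * k)
  dxp <- matrix(0, C, cache$Hp * cache$Wp)
  for (t in seq_along(cache$taps)) {
    idx <- cache$taps[[t]]
    dWm[, t] <- rowSums(dy * cache$xp[, idx, drop = FALSE])
    dxp[, idx] <- dxp[, idx] + cache$Wm[, t] * dy
  }
  list(dx = dxp[, cache$inner, drop = FALSE],
       dW = array(dWm, c(C, k, k)), db = rowSums(dy))
}

bcast_cols <- function(v, C) matrix(v, C, length(v), byrow = TRUE)

# Layer norm across channels, independently at each spatial position.
ln_fwd <- function(x, g, b, eps = 1e-6) {
  C <- nrow(x)
  mu <- colMeans(x)
  xc <- x - bcast_cols(mu, C)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * bcast_cols(inv, C)
  list(y = g * xhat + b, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  C <- nrow(dy)
  xhat <- cache$xhat
  dxhat <- dy * cache$g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - bcast_cols(m1, C) - xhat * bcast_cols(m2, C)) *
    bcast_cols(cache$inv, C)
  list(dx = dx, dg = rowSums(dy * xhat), db = rowSums(dy))
}

gelu_fwd <- function(x) list(y = x * stats::pnorm(x), cache = x)
gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}
silu_bwd <- function(dy, cache) {
  dy * (cache$s * (1 + cache$x * (1 - cache$s)))
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, mask) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# Truncated-normal-ish initializer (normal clipped at 2 sd), sd 0.02.
init_trunc_normal <- function(dims, sd = 0.02) {
  n <- prod(dims)
  v <- stats::rnorm(n, 0, sd)
  v <- pmax(pmin(v, 2 * sd), -2 * sd)
  array(v, dims)
}
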