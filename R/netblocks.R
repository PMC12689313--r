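# Improved ConvNeXt-style classifier: backbone blocks plus the three added
# modules — alterable-kernel convolution (AKConv, offset-sampled), CBAM
# channel-spatial attention, and convolutional modulation (ConvMod). Exported
# *_forward functions are functional (array in, array out) so they can be
# checked against brute-force oracles; the trainable network reuses the same
# internals with cached backward passes.

as_cmap <- function(x) {
  # accept (C,H,W) array or C x (H*W) matrix with H/W attributes
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    list(x = matrix(x, d[1], d[2] * d[3]), H = d[2], W = d[3])
  } else stop("expected a (C, H, W) array")
}

cmap_to_array <- function(x, H, W) array(x, c(nrow(x), H, W))

#' AKConv configuration
#'
#' @param num_param Number of sampled kernel points N (default 3).
#' @param stride Convolution stride (fixed at 1 to preserve resolution).
#' @param offset_kernel Kernel size of the offset-predicting convolution.
#' @param offset_lr_scale Learning-rate multiplier for the offset predictor
#'   (default 0.1); its weights initialize to zero.
#' @param include_norm,include_act Apply the channelwise layer norm and SiLU
#'   activation after the pointwise projection (defaults TRUE).
#' @return Object of class `akconv_config`.
#' @export
akconv_config <- function(num_param = 3, stride = 1, offset_kernel = 3,
                          offset_lr_scale = 0.1, include_norm = TRUE,
                          include_act = TRUE) {
  stopifnot(num_param >= 1, stride == 1)
  structure(list(num_param = num_param, stride = stride,
                 offset_kernel = offset_kernel,
                 offset_lr_scale = offset_lr_scale,
                 include_norm = include_norm, include_act = include_act),
            class = "akconv_config")
}

#' Initial sampling coordinates of the alterable kernel
#'
#' Deterministic layout for `num_param` points anchored at the upper-left
#' corner (0,0): a regular grid of `floor(sqrt(n))` columns filled row by
#' row, with any remainder appended as a final partial row.
#'
#' @param num_param Number of kernel points (>= 1).
#' @return Integer matrix `num_param` x 2 with columns `dy`, `dx`
#'   (zero-based offsets from the anchor).
#' @export
akconv_init_coords <- function(num_param) {
  if (num_param < 1) stop("num_param must be >= 1")
  base <- floor(sqrt(num_param))
  rows <- num_param %/% base
  rem <- num_param %% base
  dy <- integer(0); dx <- integer(0)
  for (r in seq_len(rows) - 1L) {
    dy <- c(dy, rep(r, base)); dx <- c(dx, seq_len(base) - 1L)
  }
  if (rem > 0) {
    dy <- c(dy, rep(rows, rem)); dx <- c(dx, seq_len(rem) - 1L)
  }
  m <- cbind(dy = dy, dx = dx)
  stopifnot(nrow(m) == num_param, all(m[1, ] == c(0, 0)))
  m
}

# Core offset sampling: gather N bilinear samples per output position.
# offsets: (2N) x P matrix, rows 1..N = dy, N+1..2N = dx.
# Returns gathered (C*N) x P matrix (rows (n-1)*C + 1:C per point) + cache.
akconv_sample <- function(x, H, W, coords, offsets) {
  C <- nrow(x); N <- nrow(coords); P <- H * W
  img <- array(x, c(C, H, W))
  i0 <- rep(seq_len(H) - 1L, times = W)   # zero-based anchor rows
  j0 <- rep(seq_len(W) - 1L, each = H)
  g <- matrix(0, C * N, P)
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    ys <- i0 + coords[n, 1] + offsets[n, ]
    xs <- j0 + coords[n, 2] + offsets[N + n, ]
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    corner <- function(yy, xx) {
      ok <- yy >= 0 & yy <= (H - 1) & xx >= 0 & xx <= (W - 1)
      pos <- ifelse(ok, xx * H + yy + 1L, NA_integer_)
      v <- matrix(0, C, P)
      v[, ok] <- x[, pos[ok], drop = FALSE]
      list(v = v, pos = pos, ok = ok)
    }
    c00 <- corner(y0, x0); c01 <- corner(y0, x0 + 1)
    c10 <- corner(y0 + 1, x0); c11 <- corner(y0 + 1, x0 + 1)
    wy <- bcast_cols(fy, C); wx <- bcast_cols(fx, C)
    g[(n - 1L) * C + seq_len(C), ] <-
      (1 - wy) * ((1 - wx) * c00$v + wx * c01$v) +
      wy * ((1 - wx) * c10$v + wx * c11$v)
    cache[[n]] <- list(c00 = c00, c01 = c01, c10 = c10, c11 = c11,
                       fy = fy, fx = fx)
  }
  list(g = g, cache = cache)
}

# Backward of akconv_sample: gradients w.r.t. the input map and the offsets.
akconv_sample_bwd <- function(dg, x, H, W, coords, cache) {
  C <- nrow(x); N <- length(cache); P <- H * W
  dx <- matrix(0, C, P)
  doff <- matrix(0, 2L * N, P)
  for (n in seq_len(N)) {
    cc <- cache[[n]]
    dgn <- dg[(n - 1L) * C + seq_len(C), , drop = FALSE]
    fy <- cc$fy; fx <- cc$fx
    ww <- list(c00 = (1 - fy) * (1 - fx), c01 = (1 - fy) * fx,
               c10 = fy * (1 - fx), c11 = fy * fx)
    for (nm in names(ww)) {
      cn <- cc[[nm]]
      ok <- cn$ok
      if (!any(ok)) next
      contrib <- dgn[, ok, drop = FALSE] * bcast_cols(ww[[nm]][ok], C)
      acc <- rowsum(t(contrib), group = cn$pos[ok])
      tgt <- as.integer(rownames(acc))
      dx[, tgt] <- dx[, tgt] + t(acc)
    }
    ddy_val <- bcast_cols(1 - fx, C) * (cc$c10$v - cc$c00$v) +
      bcast_cols(fx, C) * (cc$c11$v - cc$c01$v)
    ddx_val <- bcast_cols(1 - fy, C) * (cc$c01$v - cc$c00$v) +
      bcast_cols(fy, C) * (cc$c11$v - cc$c10$v)
    doff[n, ] <- colSums(dgn * ddy_val)
    doff[N + n, ] <- colSums(dgn * ddx_val)
  }
  list(dx = dx, doffsets = doff)
}

akconv_core_fwd <- function(x, H, W, cfg, w) {
  C <- nrow(x); N <- cfg$num_param
  coords <- akconv_init_coords(N)
  off <- conv2d_fwd(x, H, W, w$w_off, w$b_off, stride = 1L,
                    pad = (cfg$offset_kernel - 1L) %/% 2L)
  smp <- akconv_sample(x, H, W, coords, off$y)
  y <- w$w_pw %*% smp$g + w$b_pw
  ln <- NULL
  if (cfg$include_norm) {
    ln <- ln_fwd(y, w$ln_g, w$ln_b)
    y <- ln$y
  }
  act <- NULL
  if (cfg$include_act) {
    act <- silu_fwd(y)
    y <- act$y
  }
  list(y = y, H = H, W = W,
       cache = list(off = off, smp = smp, coords = coords, x = x,
                    ln = ln, act = act, g = smp$g))
}

akconv_core_bwd <- function(dy, cfg, w, cache, H, W) {
  if (cfg$include_act) dy <- silu_bwd(dy, cache$act$cache)
  dln_g <- NULL; dln_b <- NULL
  if (cfg$include_norm) {
    lb <- ln_bwd(dy, cache$ln$cache)
    dy <- lb$dx; dln_g <- lb$dg; dln_b <- lb$db
  }
  dW_pw <- dy %*% t(cache$g)
  db_pw <- rowSums(dy)
  dg <- t(w$w_pw) %*% dy
  sb <- akconv_sample_bwd(dg, cache$x, H, W, cache$coords, cache$smp$cache)
  ob <- conv2d_bwd(sb$doffsets, cache$off$cache)
  dx <- sb$dx + ob$dx
  grads <- list(w_off = ob$dW, b_off = ob$db, w_pw = dW_pw, b_pw = db_pw)
  if (cfg$include_norm) { grads$ln_g <- dln_g; grads$ln_b <- dln_b }
  list(dx = dx, grads = grads)
}

#' AKConv forward pass
#'
#' Offset-sampled convolution: a small convolution predicts per-position 2N
#' offsets (rows 1..N vertical, N+1..2N horizontal), the input is resampled
#' bilinearly at the N initial coordinates plus offsets (out-of-bounds reads
#' zero), the gathered C*N features are mixed by a pointwise projection, then
#' (optionally) layer-normalized and passed through SiLU. With the offset
#' predictor at its zero initialization, sampling lands exactly on the
#' initial integer coordinates.
#'
#' @param x Input array (C, H, W).
#' @param cfg An [akconv_config()].
#' @param weights List with `w_off` (2N, C, k_off, k_off), `b_off` (2N),
#'   `w_pw` (C_out, C*N), `b_pw` (C_out), and if `include_norm` `ln_g`,
#'   `ln_b` (C_out).
#' @return Output array (C_out, H, W).
#' @export
akconv_forward <- function(x, cfg, weights) {
  m <- as_cmap(x)
  r <- akconv_core_fwd(m$x, m$H, m$W, cfg, weights)
  cmap_to_array(r$y, m$H, m$W)
}

#' CBAM configuration
#'
#' @param reduction Channel-MLP reduction ratio (default 16); the channel
#'   count must be divisible by it.
#' @param spatial_kernel Spatial-attention convolution kernel (default 7).
#' @return Object of class `cbam_config`.
#' @export
cbam_config <- function(reduction = 16, spatial_kernel = 7) {
  stopifnot(reduction >= 1, spatial_kernel %% 2 == 1)
  structure(list(reduction = reduction, spatial_kernel = spatial_kernel),
            class = "cbam_config")
}

cbam_core_fwd <- function(x, H, W, cfg, w) {
  C <- nrow(x)
  if (C %% cfg$reduction != 0) {
    stop("channels (", C, ") not divisible by reduction (", cfg$reduction, ")")
  }
  # channel attention: shared MLP over global average and max pools
  avg <- rowMeans(x)
  imax <- max.col(x, ties.method = "first")   # argmax position per channel
  mx <- x[cbind(seq_len(C), imax)]
  h_avg <- relu_fwd(w$w0 %*% avg)
  h_max <- relu_fwd(w$w0 %*% mx)
  a <- w$w1 %*% h_avg$y + w$w1 %*% h_max$y
  mc <- sigmoid(a)
  f1 <- x * as.numeric(mc)
  # spatial attention over channel-wise mean and max
  s_avg <- colMeans(f1)
  jmax <- max.col(t(f1), ties.method = "first")  # argmax channel per position
  s_max <- f1[cbind(jmax, seq_len(ncol(f1)))]
  stack <- rbind(s_avg, s_max)
  sp <- conv2d_fwd(stack, H, W, w$w_sp, NULL, stride = 1L,
                   pad = (cfg$spatial_kernel - 1L) %/% 2L)
  ms <- sigmoid(sp$y)
  f2 <- f1 * bcast_cols(as.numeric(ms), C)
  list(y = f2, H = H, W = W,
       cache = list(x = x, avg = avg, mx = mx, imax = imax, h_avg = h_avg,
                    h_max = h_max, mc = mc, f1 = f1, jmax = jmax, sp = sp,
                    ms = ms))
}

cbam_core_bwd <- function(dy, cfg, w, cache, H, W) {
  C <- nrow(dy); P <- ncol(dy)
  ms_v <- as.numeric(cache$ms)
  dms <- colSums(dy * cache$f1)
  df1 <- dy * bcast_cols(ms_v, C)
  dsp <- matrix(dms * ms_v * (1 - ms_v), 1, P)
  cb <- conv2d_bwd(dsp, cache$sp$cache)
  dstack <- cb$dx
  df1 <- df1 + bcast_cols(dstack[1, ], C) / C
  idx_max <- cbind(cache$jmax, seq_len(P))
  df1[idx_max] <- df1[idx_max] + dstack[2, ]
  mc_v <- as.numeric(cache$mc)
  dmc <- rowSums(df1 * cache$x)
  dx <- df1 * mc_v
  da <- dmc * mc_v * (1 - mc_v)
  dw1 <- da %*% t(cache$h_avg$y) + da %*% t(cache$h_max$y)
  dh_avg <- relu_bwd(t(w$w1) %*% da, cache$h_avg$cache)
  dh_max <- relu_bwd(t(w$w1) %*% da, cache$h_max$cache)
  dw0 <- dh_avg %*% t(matrix(cache$avg)) + dh_max %*% t(matrix(cache$mx))
  davg <- as.numeric(t(w$w0) %*% dh_avg)
  dmx <- as.numeric(t(w$w0) %*% dh_max)
  dx <- dx + matrix(davg, C, P) / P
  idx_cmax <- cbind(seq_len(C), cache$imax)
  dx[idx_cmax] <- dx[idx_cmax] + dmx
  list(dx = dx, grads = list(w0 = dw0, w1 = dw1, w_sp = cb$dW))
}

#' CBAM forward pass
#'
#' Sequential channel and spatial attention: channel weights are the sigmoid
#' of a shared two-layer MLP (reduction ratio `cfg$reduction`, ReLU in the
#' middle, no biases) applied to the global average- and max-pooled channel
#' descriptors and summed; spatial weights are the sigmoid of a
#' `spatial_kernel` convolution over the channel-wise mean and max maps of
#' the channel-reweighted features.
#'
#' @param x Input array (C, H, W); C must be divisible by the reduction.
#' @param cfg A [cbam_config()].
#' @param weights List with `w0` (C/r, C), `w1` (C, C/r), `w_sp`
#'   (1, 2, k, k).
#' @return Output array (C, H, W).
#' @export
cbam_forward <- function(x, cfg, weights) {
  m <- as_cmap(x)
  r <- cbam_core_fwd(m$x, m$H, m$W, cfg, weights)
  cmap_to_array(r$y, m$H, m$W)
}

#' ConvMod configuration
#'
#' @param dim Channel dimension of the block.
#' @param dw_kernel Depthwise kernel size (default 11).
#' @param dw_padding Depthwise padding (default 5, preserving resolution).
#' @return Object of class `convmod_config`.
#' @export
convmod_config <- function(dim = 768, dw_kernel = 11, dw_padding = 5) {
  stopifnot(dim >= 1, dw_padding == (dw_kernel - 1) %/% 2)
  structure(list(dim = dim, dw_kernel = dw_kernel, dw_padding = dw_padding),
            class = "convmod_config")
}

convmod_core_fwd <- function(x, H, W, cfg, w) {
  if (nrow(x) != cfg$dim) {
    stop("input dim ", nrow(x), " does not match ConvMod dim ", cfg$dim)
  }
  ln <- ln_fwd(x, w$ln_g, w$ln_b)
  a1 <- w$wa %*% ln$y + w$ba
  ag <- gelu_fwd(a1)
  dw <- dwconv_fwd(ag$y, H, W, w$wdw, w$bdw, pad = cfg$dw_padding)
  v <- w$wv %*% ln$y + w$bv
  m <- dw$y * v
  y <- w$wp %*% m   # no projection bias: a silent gate leaves the identity
  list(y = x + y, H = H, W = W,
       cache = list(ln = ln, a1 = a1, ag = ag, dw = dw, v = v, m = m))
}

convmod_core_bwd <- function(dy, cfg, w, cache, H, W) {
  dwp <- dy %*% t(cache$m)
  dm <- t(w$wp) %*% dy
  ddw_out <- dm * cache$v
  dv <- dm * cache$dw$y
  dwv <- dv %*% t(cache$ln$y)
  dbv <- rowSums(dv)
  dln_from_v <- t(w$wv) %*% dv
  db <- dwconv_bwd(ddw_out, cache$dw$cache)
  da1 <- gelu_bwd(db$dx, cache$ag$cache)
  dwa <- da1 %*% t(cache$ln$y)
  dba <- rowSums(da1)
  dln_from_a <- t(w$wa) %*% da1
  lb <- ln_bwd(dln_from_a + dln_from_v, cache$ln$cache)
  list(dx = dy + lb$dx,
       grads = list(ln_g = lb$dg, ln_b = lb$db, wa = dwa, ba = dba,
                    wdw = db$dW, bdw = db$db, wv = dwv, bv = dbv,
                    wp = dwp))
}

#' ConvMod (convolutional modulation) forward pass
#'
#' Self-attention replacement: after layer norm, a gating branch (pointwise
#' linear, GELU, large-kernel depthwise convolution) multiplicatively
#' modulates a value branch (pointwise linear); a final bias-free pointwise
#' projection feeds a residual connection around the block, so zero
#' value-branch weights reduce the block exactly to the identity.
#'
#' @param x Input array (dim, H, W).
#' @param cfg A [convmod_config()].
#' @param weights List with `ln_g`, `ln_b`, `wa`, `ba`, `wdw`
#'   (dim, k, k), `bdw`, `wv`, `bv`, `wp`.
#' @return Output array (dim, H, W).
#' @export
convmod_forward <- function(x, cfg, weights) {
  m <- as_cmap(x)
  r <- convmod_core_fwd(m$x, m$H, m$W, cfg, weights)
  cmap_to_array(r$y, m$H, m$W)
}
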