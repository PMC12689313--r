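# Model assembly: ConvNeXt-style backbone with configurable placements of
# the three added modules, a trainable network object, and a parameter table
# consistent with the trainable allocation.

#' Model specification
#'
#' Describes the backbone (stage depths and widths, 4x4/stride-4 stem, 2-way
#' linear head) and the placement of the added modules: AKConv replaces the
#' depthwise convolution inside every stage-2 block, CBAM is inserted on the
#' stage-3 output, and one ConvMod block is appended after stage 4. The
#' default configuration is ConvNeXt-Tiny sized; reduced `dims`/`depths`
#' give a small model trainable on CPU.
#'
#' @param depths Blocks per stage (default `c(3, 3, 9, 3)`).
#' @param dims Channels per stage (default `c(96, 192, 384, 768)`).
#' @param n_classes Output classes (default 2).
#' @param use_akconv,use_cbam,use_convmod Enable each added module.
#' @param akconv An [akconv_config()].
#' @param cbam A [cbam_config()].
#' @param convmod A [convmod_config()]; its `dim` must equal `dims[4]`
#'   (defaults to it).
#' @param input_channels Input image channels (default 3).
#' @param layer_scale_init Initial value of the per-block residual scaling
#'   (default 0.01).
#' @return Object of class `snore_model_spec`.
#' @export
model_spec <- function(depths = c(3, 3, 9, 3), dims = c(96, 192, 384, 768),
                       n_classes = 2, use_akconv = TRUE, use_cbam = TRUE,
                       use_convmod = TRUE, akconv = akconv_config(),
                       cbam = cbam_config(), convmod = NULL,
                       input_channels = 3, layer_scale_init = 1e-2) {
  stopifnot(length(depths) == 4, length(dims) == 4, all(depths >= 1),
            all(dims >= 1), n_classes >= 2)
  if (is.null(convmod)) convmod <- convmod_config(dim = dims[4])
  if (use_convmod && convmod$dim != dims[4]) {
    stop("ConvMod dim (", convmod$dim, ") must match stage-4 width (",
         dims[4], ")")
  }
  if (use_cbam && dims[3] %% cbam$reduction != 0) {
    stop("stage-3 width (", dims[3], ") not divisible by CBAM reduction (",
         cbam$reduction, ")")
  }
  structure(list(depths = depths, dims = dims, n_classes = n_classes,
                 use_akconv = use_akconv, use_cbam = use_cbam,
                 use_convmod = use_convmod, akconv = akconv, cbam = cbam,
                 convmod = convmod, input_channels = input_channels,
                 layer_scale_init = layer_scale_init),
            class = "snore_model_spec")
}

#' Baseline (unmodified backbone) version of a model spec
#' @param spec A `snore_model_spec`.
#' @return The spec with all added modules disabled.
#' @export
baseline_spec <- function(spec = model_spec()) {
  spec$use_akconv <- FALSE; spec$use_cbam <- FALSE; spec$use_convmod <- FALSE
  spec
}

# ---- block constructors (parameters + metadata) ----

new_block <- function(type, params, meta = list(), lr_scale = NULL) {
  list(type = type, params = params, meta = meta, lr_scale = lr_scale)
}

mk_stem <- function(cin, d) {
  new_block("stem",
            list(w = init_trunc_normal(c(d, cin, 4, 4)), b = numeric(d),
                 ln_g = rep(1, d), ln_b = numeric(d)),
            meta = list(stride = 4L, k = 4L))
}

mk_downsample <- function(din, dout) {
  new_block("downsample",
            list(ln_g = rep(1, din), ln_b = numeric(din),
                 w = init_trunc_normal(c(dout, din, 2, 2)), b = numeric(dout)),
            meta = list(stride = 2L, k = 2L))
}

mk_convnext_block <- function(d, ls_init, akconv = NULL) {
  p <- list(ln_g = rep(1, d), ln_b = numeric(d),
            w1 = init_trunc_normal(c(4 * d, d)), b1 = numeric(4 * d),
            w2 = init_trunc_normal(c(d, 4 * d)), b2 = numeric(d),
            gamma = rep(ls_init, d))
  if (is.null(akconv)) {
    p$dw_w <- init_trunc_normal(c(d, 7, 7))
    p$dw_b <- numeric(d)
    new_block("convnext", p)
  } else {
    N <- akconv$num_param; ko <- akconv$offset_kernel
    p$ak_w_off <- array(0, c(2 * N, d, ko, ko))   # zero offset init
    p$ak_b_off <- numeric(2 * N)
    p$ak_w_pw <- init_trunc_normal(c(d, d * N))
    p$ak_b_pw <- numeric(d)
    p$ak_ln_g <- rep(1, d)
    p$ak_ln_b <- numeric(d)
    new_block("convnext_ak", p, meta = list(akconv = akconv),
              lr_scale = c(ak_w_off = akconv$offset_lr_scale,
                           ak_b_off = akconv$offset_lr_scale))
  }
}

mk_cbam <- function(d, cfg) {
  r <- cfg$reduction; k <- cfg$spatial_kernel
  new_block("cbam",
            list(w0 = init_trunc_normal(c(d %/% r, d)),
                 w1 = init_trunc_normal(c(d, d %/% r)),
                 w_sp = init_trunc_normal(c(1, 2, k, k))),
            meta = list(cfg = cfg))
}

mk_convmod <- function(cfg) {
  d <- cfg$dim; k <- cfg$dw_kernel
  new_block("convmod",
            list(ln_g = rep(1, d), ln_b = numeric(d),
                 wa = init_trunc_normal(c(d, d)), ba = numeric(d),
                 wdw = init_trunc_normal(c(d, k, k)), bdw = numeric(d),
                 wv = init_trunc_normal(c(d, d)), bv = numeric(d),
                 wp = init_trunc_normal(c(d, d))),
            meta = list(cfg = cfg))
}

mk_head <- function(d, n_classes) {
  new_block("head",
            list(ln_g = rep(1, d), ln_b = numeric(d),
                 w = init_trunc_normal(c(n_classes, d)),
                 b = numeric(n_classes)))
}

#' Build a classifier network from a model spec
#'
#' Allocates all trainable parameters (seeded, deterministic) and returns a
#' network whose forward pass maps a (input_channels, S, S) image to
#' `n_classes` logits. With every added module disabled the layout is the
#' standard ConvNeXt backbone.
#'
#' @param spec A [model_spec()].
#' @param seed Seed for weight initialization.
#' @return Object of class `snore_net`.
#' @export
build_model <- function(spec = model_spec(), seed = 1) {
  stopifnot(inherits(spec, "snore_model_spec"))
  with_seed(seed, {
    blocks <- list(mk_stem(spec$input_channels, spec$dims[1]))
    for (s in 1:4) {
      if (s > 1) {
        blocks <- c(blocks, list(mk_downsample(spec$dims[s - 1], spec$dims[s])))
      }
      for (b in seq_len(spec$depths[s])) {
        ak <- if (spec$use_akconv && s == 2) spec$akconv else NULL
        blocks <- c(blocks, list(mk_convnext_block(spec$dims[s],
                                                   spec$layer_scale_init, ak)))
      }
      if (s == 3 && spec$use_cbam) {
        blocks <- c(blocks, list(mk_cbam(spec$dims[3], spec$cbam)))
      }
      if (s == 4 && spec$use_convmod) {
        blocks <- c(blocks, list(mk_convmod(spec$convmod)))
      }
    }
    blocks <- c(blocks, list(mk_head(spec$dims[4], spec$n_classes)))
    structure(list(spec = spec, blocks = blocks), class = "snore_net")
  })
}

#' Flat named list of a network's parameter arrays
#' @param net A `snore_net`.
#' @return Named list of numeric arrays.
#' @export
net_parameters <- function(net) {
  out <- list()
  for (i in seq_along(net$blocks)) {
    for (nm in names(net$blocks[[i]]$params)) {
      out[[sprintf("b%02d.%s", i, nm)]] <- net$blocks[[i]]$params[[nm]]
    }
  }
  out
}

#' Parameter table matching [build_model()]'s allocation
#'
#' Enumerates exactly the tensors a built network owns, so
#' `count_params(net_param_table(spec)) == count_params(build_model(spec))`
#' for any spec; the baseline full-size spec reproduces the standard
#' backbone count.
#'
#' @param spec A [model_spec()].
#' @return Parameter table data frame.
#' @export
net_param_table <- function(spec = model_spec()) {
  net <- build_model(spec, seed = 1)
  rows <- list()
  for (i in seq_along(net$blocks)) {
    bl <- net$blocks[[i]]
    for (nm in names(bl$params)) {
      d <- dim(bl$params[[nm]])
      if (is.null(d)) d <- length(bl$params[[nm]])
      rows[[length(rows) + 1]] <-
        ptab_row(sprintf("b%02d.%s", i, bl$type), nm, d)
    }
  }
  do.call(rbind, rows)
}

# ---- forward / backward over blocks ----

block_fwd <- function(bl, x, H, W) {
  p <- bl$params
  switch(bl$type,
    stem = {
      cv <- conv2d_fwd(x, H, W, p$w, p$b, stride = bl$meta$stride, pad = 0L)
      ln <- ln_fwd(cv$y, p$ln_g, p$ln_b)
      list(y = ln$y, H = cv$H, W = cv$W, cache = list(cv = cv, ln = ln))
    },
    downsample = {
      ln <- ln_fwd(x, p$ln_g, p$ln_b)
      cv <- conv2d_fwd(ln$y, H, W, p$w, p$b, stride = bl$meta$stride, pad = 0L)
      list(y = cv$y, H = cv$H, W = cv$W, cache = list(cv = cv, ln = ln))
    },
    convnext = {
      dw <- dwconv_fwd(x, H, W, p$dw_w, p$dw_b, pad = 3L)
      convnext_tail_fwd(bl, x, dw$y, H, W, list(dw = dw))
    },
    convnext_ak = {
      ak <- akconv_core_fwd(x, H, W, bl$meta$akconv,
                            list(w_off = p$ak_w_off, b_off = p$ak_b_off,
                                 w_pw = p$ak_w_pw, b_pw = p$ak_b_pw,
                                 ln_g = p$ak_ln_g, ln_b = p$ak_ln_b))
      convnext_tail_fwd(bl, x, ak$y, H, W, list(ak = ak))
    },
    cbam = {
      r <- cbam_core_fwd(x, H, W, bl$meta$cfg,
                         list(w0 = p$w0, w1 = p$w1, w_sp = p$w_sp))
      list(y = r$y, H = H, W = W, cache = r$cache)
    },
    convmod = {
      r <- convmod_core_fwd(x, H, W, bl$meta$cfg, p)
      list(y = r$y, H = H, W = W, cache = r$cache)
    },
    head = {
      g <- rowMeans(x)
      ln <- ln_fwd(matrix(g, ncol = 1), p$ln_g, p$ln_b)
      logits <- as.numeric(p$w %*% ln$y + p$b)
      list(y = logits, H = 1L, W = 1L,
           cache = list(ln = ln, g = g, P = ncol(x), C = nrow(x)))
    },
    stop("unknown block type ", bl$type))
}

convnext_tail_fwd <- function(bl, x, t1, H, W, cache) {
  p <- bl$params
  ln <- ln_fwd(t1, p$ln_g, p$ln_b)
  t3 <- p$w1 %*% ln$y + p$b1
  ge <- gelu_fwd(t3)
  t5 <- p$w2 %*% ge$y + p$b2
  y <- x + p$gamma * t5
  cache$ln <- ln; cache$ge <- ge; cache$t5 <- t5
  list(y = y, H = H, W = W, cache = cache)
}

convnext_tail_bwd <- function(bl, dy, cache) {
  p <- bl$params
  dgamma <- rowSums(dy * cache$t5)
  dt5 <- dy * p$gamma
  dw2 <- dt5 %*% t(cache$ge$y)
  db2 <- rowSums(dt5)
  dt4 <- t(p$w2) %*% dt5
  dt3 <- gelu_bwd(dt4, cache$ge$cache)
  dw1 <- dt3 %*% t(cache$ln$y)
  db1 <- rowSums(dt3)
  dln <- t(p$w1) %*% dt3
  lb <- ln_bwd(dln, cache$ln$cache)
  list(dt1 = lb$dx, dres = dy,
       grads = list(ln_g = lb$dg, ln_b = lb$db, w1 = dw1, b1 = db1,
                    w2 = dw2, b2 = db2, gamma = dgamma))
}

block_bwd <- function(bl, dy, cache, H, W) {
  p <- bl$params
  switch(bl$type,
    stem = {
      lb <- ln_bwd(dy, cache$ln$cache)
      cb <- conv2d_bwd(lb$dx, cache$cv$cache)
      list(dx = cb$dx,
           grads = list(w = cb$dW, b = cb$db, ln_g = lb$dg, ln_b = lb$db))
    },
    downsample = {
      cb <- conv2d_bwd(dy, cache$cv$cache)
      lb <- ln_bwd(cb$dx, cache$ln$cache)
      list(dx = lb$dx,
           grads = list(ln_g = lb$dg, ln_b = lb$db, w = cb$dW, b = cb$db))
    },
    convnext = {
      tb <- convnext_tail_bwd(bl, dy, cache)
      db <- dwconv_bwd(tb$dt1, cache$dw$cache)
      grads <- tb$grads
      grads$dw_w <- db$dW; grads$dw_b <- db$db
      list(dx = tb$dres + db$dx, grads = grads)
    },
    convnext_ak = {
      tb <- convnext_tail_bwd(bl, dy, cache)
      ab <- akconv_core_bwd(tb$dt1, bl$meta$akconv,
                            list(w_off = p$ak_w_off, b_off = p$ak_b_off,
                                 w_pw = p$ak_w_pw, b_pw = p$ak_b_pw,
                                 ln_g = p$ak_ln_g, ln_b = p$ak_ln_b),
                            cache$ak$cache, H, W)
      grads <- tb$grads
      grads$ak_w_off <- ab$grads$w_off; grads$ak_b_off <- ab$grads$b_off
      grads$ak_w_pw <- ab$grads$w_pw; grads$ak_b_pw <- ab$grads$b_pw
      grads$ak_ln_g <- ab$grads$ln_g; grads$ak_ln_b <- ab$grads$ln_b
      list(dx = tb$dres + ab$dx, grads = grads)
    },
    cbam = {
      r <- cbam_core_bwd(dy, bl$meta$cfg,
                         list(w0 = p$w0, w1 = p$w1, w_sp = p$w_sp), cache, H, W)
      list(dx = r$dx, grads = r$grads)
    },
    convmod = {
      r <- convmod_core_bwd(dy, bl$meta$cfg, p, cache, H, W)
      list(dx = r$dx, grads = r$grads)
    },
    head = {
      dlogits <- matrix(dy, ncol = 1)
      dw <- dlogits %*% t(cache$ln$y)
      db <- as.numeric(dlogits)
      dlny <- t(p$w) %*% dlogits
      lb <- ln_bwd(dlny, cache$ln$cache)
      dx <- matrix(lb$dx, cache$C, cache$P) / cache$P
      list(dx = dx,
           grads = list(ln_g = lb$dg, ln_b = lb$db, w = dw, b = db))
    },
    stop("unknown block type ", bl$type))
}

#' Forward pass of a network on one image
#'
#' @param net A `snore_net`.
#' @param img Input array (C, H, W) or (H, W, C) (auto-detected from the
#'   spec's `input_channels`), or a `feature_image`.
#' @param train Keep caches for a backward pass.
#' @return If `train = FALSE`, the logits vector; otherwise a list with
#'   `logits` and `caches`.
#' @export
net_forward <- function(net, img, train = FALSE) {
  x <- net_input(net, img)
  H <- attr(x, "H"); W <- attr(x, "W")
  caches <- if (train) vector("list", length(net$blocks)) else NULL
  dims <- vector("list", length(net$blocks))
  for (i in seq_along(net$blocks)) {
    dims[[i]] <- c(H, W)
    r <- block_fwd(net$blocks[[i]], x, H, W)
    if (train) caches[[i]] <- r$cache
    x <- r$y; H <- r$H; W <- r$W
  }
  if (train) list(logits = x, caches = caches, dims = dims) else x
}

# Convert supported image formats to the internal C x (H*W) layout.
net_input <- function(net, img) {
  if (inherits(img, "feature_image")) img <- img$pixels
  stopifnot(is.array(img), length(dim(img)) == 3)
  d <- dim(img)
  cin <- net$spec$input_channels
  if (d[1] == cin) {
    x <- matrix(img, d[1], d[2] * d[3]); H <- d[2]; W <- d[3]
  } else if (d[3] == cin) {
    x <- t(matrix(img, d[1] * d[2], d[3])); H <- d[1]; W <- d[2]
  } else {
    stop("cannot match input channels (", cin, ") to image dims ",
         paste(d, collapse = "x"))
  }
  attr(x, "H") <- H; attr(x, "W") <- W
  x
}

# Backward pass from dlogits; returns per-block gradient lists.
net_backward <- function(net, fwd, dlogits) {
  n <- length(net$blocks)
  grads <- vector("list", n)
  dy <- dlogits
  for (i in rev(seq_len(n))) {
    hw <- fwd$dims[[i]]
    r <- block_bwd(net$blocks[[i]], dy, fwd$caches[[i]], hw[1], hw[2])
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

#' Class probabilities / predictions for a batch of images
#'
#' @param net A `snore_net`.
#' @param imgs List of images accepted by [net_forward()].
#' @return Matrix (n x n_classes) of softmax probabilities.
#' @export
net_predict <- function(net, imgs) {
  t(vapply(imgs, function(im) {
    z <- net_forward(net, im)
    e <- exp(z - max(z))
    e / sum(e)
  }, numeric(net$spec$n_classes)))
}
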