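# Exact parameter accounting. Each builder lays out an architecture as a
# table of named parameter tensors with their shapes; counts are the product
# of each shape. Totals for the reference backbones with a 2-class head
# reproduce the published per-model parameter counts.

ptab_row <- function(module, param, shape) {
  data.frame(module = module, param = param,
             shape = paste(shape, collapse = "x"),
             count = prod(shape), stringsAsFactors = FALSE)
}

ptab <- function(...) do.call(rbind, list(...))

# conv with optional bias
p_conv <- function(name, cin, cout, k, bias = TRUE) {
  rows <- ptab_row(name, "weight", c(cout, cin, k, k))
  if (bias) rows <- rbind(rows, ptab_row(name, "bias", cout))
  rows
}
# depthwise conv
p_dwconv <- function(name, c, k, bias = TRUE) {
  rows <- ptab_row(name, "weight", c(c, 1, k, k))
  if (bias) rows <- rbind(rows, ptab_row(name, "bias", c))
  rows
}
p_linear <- function(name, cin, cout, bias = TRUE) {
  rows <- ptab_row(name, "weight", c(cout, cin))
  if (bias) rows <- rbind(rows, ptab_row(name, "bias", cout))
  rows
}
p_norm <- function(name, c) {  # LN or BN: weight + bias
  rbind(ptab_row(name, "weight", c), ptab_row(name, "bias", c))
}

#' Parameter table of a ConvNeXt backbone with classification head
#'
#' Standard layout: 4x4 stride-4 stem to `dims[1]` channels with layer norm;
#' four stages of blocks (7x7 depthwise conv + LN + pointwise MLP with 4x
#' expansion + layer-scale), 2x2 stride-2 downsampling between stages; final
#' LN and a linear head. The Tiny configuration (depths 3,3,9,3 and dims
#' 96,192,384,768) with a 2-class head totals 27,821,666 parameters.
#'
#' @param depths Blocks per stage (default Tiny: `c(3, 3, 9, 3)`).
#' @param dims Channels per stage (default Tiny: `c(96, 192, 384, 768)`).
#' @param n_classes Head output dimension (default 2).
#' @return Data frame with columns `module`, `param`, `shape`, `count`.
#' @export
convnext_param_table <- function(depths = c(3, 3, 9, 3),
                                 dims = c(96, 192, 384, 768), n_classes = 2) {
  rows <- list(p_conv("stem.conv", 3, dims[1], 4), p_norm("stem.norm", dims[1]))
  block <- function(name, d) {
    ptab(p_dwconv(paste0(name, ".dwconv"), d, 7),
         p_norm(paste0(name, ".norm"), d),
         p_linear(paste0(name, ".pwconv1"), d, 4 * d),
         p_linear(paste0(name, ".pwconv2"), 4 * d, d),
         ptab_row(paste0(name, ".gamma"), "scale", d))
  }
  for (s in seq_along(depths)) {
    if (s > 1) {
      rows <- c(rows, list(
        p_norm(sprintf("downsample%d.norm", s - 1), dims[s - 1]),
        p_conv(sprintf("downsample%d.conv", s - 1), dims[s - 1], dims[s], 2)))
    }
    for (b in seq_len(depths[s])) {
      rows <- c(rows, list(block(sprintf("stage%d.block%d", s, b), dims[s])))
    }
  }
  rows <- c(rows, list(p_norm("head.norm", dims[length(dims)]),
                       p_linear("head.fc", dims[length(dims)], n_classes)))
  do.call(rbind, rows)
}

#' Parameter table of ResNet50 with classification head
#'
#' Standard bottleneck layout: 7x7 stem, stages of \[3, 4, 6, 3\] bottleneck
#' blocks (1x1 reduce, 3x3, 1x1 expand x4, batch norm after each conv, 1x1
#' projection shortcut on the first block of each stage), global pooling and
#' a linear head. With a 2-class head: 23,512,130 parameters.
#'
#' @param n_classes Head output dimension (default 2).
#' @return Parameter table data frame.
#' @export
resnet50_param_table <- function(n_classes = 2) {
  rows <- list(p_conv("stem.conv", 3, 64, 7, bias = FALSE),
               p_norm("stem.bn", 64))
  widths <- c(64, 128, 256, 512)
  blocks <- c(3, 4, 6, 3)
  cin <- 64
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (b in seq_len(blocks[s])) {
      name <- sprintf("layer%d.block%d", s, b)
      rows <- c(rows, list(
        p_conv(paste0(name, ".conv1"), cin, w, 1, bias = FALSE),
        p_norm(paste0(name, ".bn1"), w),
        p_conv(paste0(name, ".conv2"), w, w, 3, bias = FALSE),
        p_norm(paste0(name, ".bn2"), w),
        p_conv(paste0(name, ".conv3"), w, 4 * w, 1, bias = FALSE),
        p_norm(paste0(name, ".bn3"), 4 * w)))
      if (b == 1) {
        rows <- c(rows, list(
          p_conv(paste0(name, ".downsample.conv"), cin, 4 * w, 1, bias = FALSE),
          p_norm(paste0(name, ".downsample.bn"), 4 * w)))
      }
      cin <- 4 * w
    }
  }
  rows <- c(rows, list(p_linear("head.fc", 2048, n_classes)))
  do.call(rbind, rows)
}

#' Parameter table of Swin-Tiny with classification head
#'
#' Shifted-window transformer, Tiny configuration: 4x4 patch embedding to 96
#' channels; stages of depths \[2, 2, 6, 2\] with heads \[3, 6, 12, 24\] and
#' window 7 (each block: LN, windowed attention with qkv and output
#' projections plus a (2*7-1)^2-entry relative position bias table per head,
#' LN, 4x MLP); patch-merging (LN + 4d->2d linear) between stages; final LN
#' and linear head. With a 2-class head: 27,520,892 parameters.
#'
#' @param n_classes Head output dimension (default 2).
#' @return Parameter table data frame.
#' @export
swin_t_param_table <- function(n_classes = 2) {
  depths <- c(2, 2, 6, 2); heads <- c(3, 6, 12, 24)
  dims <- 96 * 2^(0:3); window <- 7
  rows <- list(p_conv("patch_embed.proj", 3, dims[1], 4),
               p_norm("patch_embed.norm", dims[1]))
  for (s in seq_along(depths)) {
    d <- dims[s]
    for (b in seq_len(depths[s])) {
      name <- sprintf("stage%d.block%d", s, b)
      rows <- c(rows, list(
        p_norm(paste0(name, ".norm1"), d),
        p_linear(paste0(name, ".attn.qkv"), d, 3 * d),
        ptab_row(paste0(name, ".attn.rel_pos_bias"),
                 "table", c((2 * window - 1)^2, heads[s])),
        p_linear(paste0(name, ".attn.proj"), d, d),
        p_norm(paste0(name, ".norm2"), d),
        p_linear(paste0(name, ".mlp.fc1"), d, 4 * d),
        p_linear(paste0(name, ".mlp.fc2"), 4 * d, d)))
    }
    if (s < length(depths)) {
      rows <- c(rows, list(
        p_norm(sprintf("merge%d.norm", s), 4 * d),
        p_linear(sprintf("merge%d.reduction", s), 4 * d, 2 * d, bias = FALSE)))
    }
  }
  rows <- c(rows, list(p_norm("head.norm", dims[4]),
                       p_linear("head.fc", dims[4], n_classes)))
  do.call(rbind, rows)
}

# channel rounding rule used by the MobileNetV3 reference implementation
make_divisible <- function(v, divisor = 8) {
  new_v <- max(divisor, (as.integer(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  new_v
}

#' Parameter table of MobileNetV3-Large with classification head
#'
#' Standard large configuration: 16-channel stem, fifteen inverted-residual
#' blocks (optional 1x1 expansion, depthwise conv, optional squeeze-excite
#' with channels rounded to multiples of 8, 1x1 projection; batch norm after
#' each conv), 960-channel final conv, then a 1280-unit hidden linear layer
#' and the class head. With a 2-class head: 4,204,594 parameters.
#'
#' @param n_classes Head output dimension (default 2).
#' @return Parameter table data frame.
#' @export
mobilenet_v3_large_param_table <- function(n_classes = 2) {
  # kernel, expanded, out, squeeze-excite, stride
  cfg <- list(
    c(3,  16,  16, 0, 1), c(3,  64,  24, 0, 2), c(3,  72,  24, 0, 1),
    c(5,  72,  40, 1, 2), c(5, 120,  40, 1, 1), c(5, 120,  40, 1, 1),
    c(3, 240,  80, 0, 2), c(3, 200,  80, 0, 1), c(3, 184,  80, 0, 1),
    c(3, 184,  80, 0, 1), c(3, 480, 112, 1, 1), c(3, 672, 112, 1, 1),
    c(5, 672, 160, 1, 2), c(5, 960, 160, 1, 1), c(5, 960, 160, 1, 1))
  rows <- list(p_conv("stem.conv", 3, 16, 3, bias = FALSE), p_norm("stem.bn", 16))
  cin <- 16
  for (i in seq_along(cfg)) {
    k <- cfg[[i]][1]; exp <- cfg[[i]][2]; out <- cfg[[i]][3]; se <- cfg[[i]][4]
    name <- sprintf("block%02d", i)
    if (exp != cin) {
      rows <- c(rows, list(p_conv(paste0(name, ".expand"), cin, exp, 1, bias = FALSE),
                           p_norm(paste0(name, ".expand_bn"), exp)))
    }
    rows <- c(rows, list(p_dwconv(paste0(name, ".dw"), exp, k, bias = FALSE),
                         p_norm(paste0(name, ".dw_bn"), exp)))
    if (se == 1) {
      sq <- make_divisible(exp %/% 4)
      rows <- c(rows, list(p_conv(paste0(name, ".se.fc1"), exp, sq, 1),
                           p_conv(paste0(name, ".se.fc2"), sq, exp, 1)))
    }
    rows <- c(rows, list(p_conv(paste0(name, ".project"), exp, out, 1, bias = FALSE),
                         p_norm(paste0(name, ".project_bn"), out)))
    cin <- out
  }
  rows <- c(rows, list(p_conv("last_conv", cin, 960, 1, bias = FALSE),
                       p_norm("last_conv_bn", 960),
                       p_linear("classifier.hidden", 960, 1280),
                       p_linear("classifier.fc", 1280, n_classes)))
  do.call(rbind, rows)
}

#' Count trainable parameters
#'
#' Counts all trainable scalars in a parameter table (data frame with a
#' `count` column), a fitted/built network (`snore_net`), or any nested list
#' of numeric arrays.
#'
#' @param x Parameter table, `snore_net`, or nested list of arrays.
#' @return Integer-valued total count.
#' @export
count_params <- function(x) {
  if (is.data.frame(x)) return(sum(x$count))
  if (inherits(x, "snore_net")) {
    return(sum(vapply(net_parameters(x), length, numeric(1))))
  }
  if (is.list(x)) {
    return(sum(vapply(x, function(e) {
      if (is.numeric(e)) length(e) else count_params(e)
    }, numeric(1))))
  }
  if (is.numeric(x)) return(length(x))
  stop("cannot count parameters of ", class(x)[1])
}

#' Parameter counts of the reference model zoo, in millions
#'
#' @param n_classes Head output dimension (default 2).
#' @param digits Rounding for the `params_m` column (default 2).
#' @return Data frame with `model`, `params`, `params_m`.
#' @export
model_zoo_params <- function(n_classes = 2, digits = 2) {
  tabs <- list(
    `ConvNeXt-T` = convnext_param_table(n_classes = n_classes),
    ResNet50 = resnet50_param_table(n_classes = n_classes),
    `Swin-T` = swin_t_param_table(n_classes = n_classes),
    `MobileNetV3-L` = mobilenet_v3_large_param_table(n_classes = n_classes))
  data.frame(model = names(tabs),
             params = vapply(tabs, count_params, numeric(1)),
             params_m = round(vapply(tabs, count_params, numeric(1)) / 1e6,
                              digits),
             row.names = NULL)
}
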