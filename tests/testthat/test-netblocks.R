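# Network blocks, parameter accounting, and the trainable model.

test_that("alterable-kernel initial coordinates follow the grid-plus-remainder rule", {
  expect_equal(unname(akconv_init_coords(1)), cbind(0L, 0L))
  c4 <- akconv_init_coords(4)
  expect_equal(unname(c4), cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
  # n = 3: base floor(sqrt(3)) = 1 column, three full rows, no remainder
  c3 <- akconv_init_coords(3)
  expect_equal(unname(c3), cbind(0:2, c(0L, 0L, 0L)))
  # n = 5: 2x2 base grid plus one remainder point on the next row
  c5 <- akconv_init_coords(5)
  expect_equal(unname(c5), cbind(c(0L, 0L, 1L, 1L, 2L), c(0L, 1L, 0L, 1L, 0L)))
  expect_equal(unname(c5[1, ]), c(0L, 0L))  # anchored at the origin
  expect_error(akconv_init_coords(0), "num_param")
})

test_that("bilinear sampling interpolates midpoints and zeros out of bounds", {
  img <- matrix(c(0, 1), 1, 2)        # two pixels, values 0 and 1
  expect_equal(bilinear_sample(img, 0, 0.5), 0.5)
  expect_equal(bilinear_sample(img, 0, 0), 0)
  expect_equal(bilinear_sample(img, 0, 1), 1)
  expect_equal(bilinear_sample(img, 5, 5), 0)  # outside reads zero
})

test_that("zero offsets reduce AKConv to a fixed-coordinate gather", {
  set.seed(3)
  C <- 3; N <- 3; H <- 5; W <- 6
  x <- array(stats::rnorm(C * H * W), c(C, H, W))
  cfg <- akconv_config(num_param = N, include_norm = FALSE,
                       include_act = FALSE)
  w <- list(w_off = array(0, c(2 * N, C, 3, 3)), b_off = numeric(2 * N),
            w_pw = diag(C * N), b_pw = numeric(C * N))
  y <- akconv_forward(x, cfg, w)
  coords <- akconv_init_coords(N)
  for (n in seq_len(N)) for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- i + coords[n, 1]; jj <- j + coords[n, 2]
    expected <- if (ii <= H && jj <= W) x[, ii, jj] else numeric(C)
    expect_equal(unname(y[(n - 1) * C + seq_len(C), i, j]), expected,
                 tolerance = 1e-12)
  }
})

test_that("AKConv matches the per-pixel gather-and-weight loop oracle", {
  set.seed(5)
  x <- array(stats::rnorm(4 * 6 * 6), c(4, 6, 6))
  cfg <- akconv_config(num_param = 3)
  w <- rand_akconv_weights(C = 4, N = 3, seed = 9)
  y <- akconv_forward(x, cfg, w)
  yo <- oracle_akconv(x, cfg, w)
  expect_lt(max(abs(y - yo)), 1e-6)
})

test_that("zero-weight CBAM forces both attentions to one half", {
  set.seed(1)
  x <- array(stats::rnorm(16 * 5 * 5), c(16, 5, 5))
  cfg <- cbam_config(reduction = 16, spatial_kernel = 7)
  w <- list(w0 = matrix(0, 1, 16), w1 = matrix(0, 16, 1),
            w_sp = array(0, c(1, 2, 7, 7)))
  y <- cbam_forward(x, cfg, w)
  expect_equal(y, 0.25 * x, tolerance = 1e-12)
})

test_that("single-channel constant input collapses the pooled paths", {
  # with a constant map, average and max pooling coincide, so the channel
  # attention is sigmoid(2 * MLP(c)); a zero spatial conv fixes M_S = 0.5
  x <- array(2, c(1, 4, 4))
  cfg <- cbam_config(reduction = 1, spatial_kernel = 3)
  w <- list(w0 = matrix(0.7, 1, 1), w1 = matrix(-0.4, 1, 1),
            w_sp = array(0, c(1, 2, 3, 3)))
  y <- cbam_forward(x, cfg, w)
  mc <- 1 / (1 + exp(-2 * (-0.4) * max(0.7 * 2, 0)))
  expect_equal(as.numeric(y), rep(2 * mc * 0.5, 16), tolerance = 1e-12)
})

test_that("CBAM matches a direct transcription of its equations", {
  set.seed(11)
  x <- array(stats::rnorm(16 * 5 * 5), c(16, 5, 5))
  cfg <- cbam_config(reduction = 4, spatial_kernel = 7)
  w <- list(w0 = matrix(stats::rnorm(4 * 16, 0, 0.3), 4, 16),
            w1 = matrix(stats::rnorm(16 * 4, 0, 0.3), 16, 4),
            w_sp = array(stats::rnorm(2 * 49, 0, 0.2), c(1, 2, 7, 7)))
  y <- cbam_forward(x, cfg, w)
  yo <- oracle_cbam(x, w$w0, w$w1, w$w_sp, 7)
  expect_lt(max(abs(y - yo)), 1e-6)
  expect_error(cbam_forward(x, cbam_config(reduction = 5), w), "divisible")
})

test_that("zero value-branch weights make ConvMod the identity", {
  set.seed(4)
  d <- 8
  x <- array(stats::rnorm(d * 4 * 4), c(d, 4, 4))
  cfg <- convmod_config(dim = d, dw_kernel = 11, dw_padding = 5)
  w <- rand_convmod_weights(d, seed = 3)
  w$wv[] <- 0; w$bv[] <- 0
  expect_equal(convmod_forward(x, cfg, w), x, tolerance = 1e-12)
})

test_that("ConvMod handles degenerate 1x1 maps and matches composition", {
  d <- 8
  cfg <- convmod_config(dim = d, dw_kernel = 11, dw_padding = 5)
  w <- rand_convmod_weights(d, seed = 6)
  x1 <- array(stats::rnorm(d), c(d, 1, 1))
  y1 <- convmod_forward(x1, cfg, w)
  expect_equal(dim(y1), c(d, 1, 1))
  expect_true(all(is.finite(y1)))
  set.seed(8)
  x <- array(stats::rnorm(d * 7 * 7), c(d, 7, 7))
  expect_lt(max(abs(convmod_forward(x, cfg, w) - oracle_convmod(x, cfg, w))),
            1e-6)
  expect_error(convmod_forward(array(0, c(4, 3, 3)), cfg, w), "dim")
})

test_that("parameter accounting reproduces the published backbone counts", {
  zoo <- model_zoo_params(n_classes = 2)
  expect_equal(zoo$params_m[zoo$model == "ConvNeXt-T"], 27.82)
  expect_equal(zoo$params_m[zoo$model == "ResNet50"], 23.51)
  expect_equal(zoo$params_m[zoo$model == "Swin-T"], 27.52)
  expect_equal(zoo$params_m[zoo$model == "MobileNetV3-L"], 4.20)
  expect_equal(count_params(convnext_param_table()), 27821666)
})

test_that("counting covers plain parameter lists", {
  lin <- list(w = matrix(0, 2, 10), b = numeric(2))
  expect_equal(count_params(lin), 22)
})

test_that("the trainable allocation agrees with its parameter table", {
  spec <- model_spec(depths = c(1, 1, 1, 1), dims = c(4, 6, 8, 8),
                     cbam = cbam_config(reduction = 4))
  expect_equal(count_params(build_model(spec, seed = 2)),
               count_params(net_param_table(spec)))
  # full-size baseline spec reproduces the standard backbone count
  expect_equal(count_params(net_param_table(baseline_spec())), 27821666)
  # the improved full-size model is strictly larger than the baseline
  expect_gt(count_params(net_param_table(model_spec())), 27821666)
})

test_that("a reduced model maps images to two logits", {
  spec <- model_spec(depths = c(1, 1, 1, 1), dims = c(4, 6, 8, 8),
                     cbam = cbam_config(reduction = 4))
  net <- build_model(spec, seed = 1)
  img <- array(stats::runif(3 * 32 * 32), c(3, 32, 32))
  z <- net_forward(net, img)
  expect_length(z, 2)
  probs <- net_predict(net, replicate(4, img, simplify = FALSE))
  expect_equal(dim(probs), c(4, 2))
  expect_equal(unname(rowSums(probs)), rep(1, 4), tolerance = 1e-9)
  # HWC input layout is accepted too
  img_hwc <- aperm(array(img, c(3, 32, 32)), c(2, 3, 1))
  expect_equal(net_forward(net, img_hwc), z, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  spec <- model_spec(depths = c(1, 1, 1, 1), dims = c(4, 6, 8, 8),
                     cbam = cbam_config(reduction = 4))
  net <- build_model(spec, seed = 3)
  # move the offset predictor off the integer lattice, where bilinear
  # sampling is differentiable
  for (i in seq_along(net$blocks)) {
    if (net$blocks[[i]]$type == "convnext_ak") {
      set.seed(5)
      net$blocks[[i]]$params$ak_b_off[] <-
        stats::runif(length(net$blocks[[i]]$params$ak_b_off), 0.1, 0.3)
    }
  }
  set.seed(11)
  img <- array(stats::runif(3 * 32 * 32), c(3, 32, 32))
  loss_fn <- function(nn) {
    z <- net_forward(nn, img)
    m <- max(z)
    -(z[1] - m - log(sum(exp(z - m))))
  }
  fw <- net_forward(net, img, train = TRUE)
  p <- exp(fw$logits - max(fw$logits)); p <- p / sum(p)
  grads <- snoreacoustics:::net_backward(net, fw, p - c(1, 0))
  eps <- 1e-5
  set.seed(42)
  for (i in seq_along(net$blocks)) {
    for (nm in names(net$blocks[[i]]$params)) {
      pv <- net$blocks[[i]]$params[[nm]]
      ix <- sample(length(pv), 1)
      n2 <- net
      n2$blocks[[i]]$params[[nm]][ix] <- pv[ix] + eps
      lp <- loss_fn(n2)
      n2$blocks[[i]]$params[[nm]][ix] <- pv[ix] - eps
      lm <- loss_fn(n2)
      num <- (lp - lm) / (2 * eps)
      ana <- grads[[i]][[nm]][ix]
      expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-3)
    }
  }
})
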