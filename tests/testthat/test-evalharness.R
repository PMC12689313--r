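# Metrics, bootstrap, voting, SNR mixing, training, cross-validation.

test_that("confusion-matrix metrics match hand-evaluated formulas", {
  perfect <- compute_metrics(50, 50, 0, 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$f1), rep(100, 5))

  m <- compute_metrics(90, 80, 20, 10)
  expect_equal(m$accuracy, 85.00, tolerance = 1e-9)
  expect_equal(m$sensitivity, 90.00, tolerance = 1e-9)
  expect_equal(m$specificity, 80.00, tolerance = 1e-9)
  expect_equal(m$ppv, 81.82, tolerance = 0.005)
  expect_equal(m$f1, 85.71, tolerance = 0.005)
  expect_length(m$undefined, 0)

  deg <- compute_metrics(0, 10, 0, 10)
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$specificity, 100)
  expect_true(is.na(deg$ppv))
  expect_true("ppv" %in% deg$undefined)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(3)
  for (rep in 1:200) {
    cts <- stats::rpois(4, 20) + c(1, 1, 0, 0)  # ensure both classes present
    m <- compute_metrics(cts[1], cts[2], cts[3], cts[4])
    pos <- cts[1] + cts[4]; neg <- cts[2] + cts[3]
    expect_equal(m$accuracy,
                 (m$sensitivity * pos + m$specificity * neg) / (pos + neg),
                 tolerance = 1e-10)
    if (!is.na(m$ppv) && !is.na(m$f1)) {
      expect_equal(m$f1, 2 / (1 / m$ppv + 1 / m$sensitivity), tolerance = 1e-10)
    }
  }
})

test_that("patient bootstrap is deterministic with sensible degenerate cases", {
  all_right <- data.frame(patient_id = rep(c("A", "B", "C"), each = 4),
                          correct = 1)
  ci <- bootstrap_ci(all_right, B = 200, seed = 42)
  expect_equal(c(ci$low, ci$high), c(100, 100))

  two <- data.frame(patient_id = rep(c("A", "B"), each = 5),
                    correct = rep(c(0, 1), each = 5))
  ci2 <- bootstrap_ci(two, B = 500, seed = 42)
  # resample means can only be 0, 50 or 100
  expect_true(all(c(ci2$low, ci2$high) %in% c(0, 50, 100)))
  expect_identical(bootstrap_ci(two, B = 500, seed = 42),
                   bootstrap_ci(two, B = 500, seed = 42))
  expect_error(bootstrap_ci(data.frame(patient_id = "A", correct = 1)),
               "at least 2 patients")
})

test_that("bootstrap intervals cover the true mean at near-nominal rate", {
  set.seed(9)
  true_mean <- 0.8
  covered <- 0
  reps <- 300
  for (r in seq_len(reps)) {
    acc <- stats::rbeta(25, 8, 2)          # E = 0.8 across patients
    df <- data.frame(patient_id = seq_len(25), correct = acc)
    ci <- bootstrap_ci(df, B = 300, seed = r)
    covered <- covered + (ci$low <= 100 * true_mean &&
                            100 * true_mean <= ci$high)
  }
  expect_gte(covered / reps, 0.90)
  expect_lte(covered / reps, 0.99)
})

test_that("majority voting aggregates segments with a positive tie rule", {
  df <- data.frame(patient_id = rep("A", 5), pred = c(1, 1, 1, 0, 0))
  expect_equal(unname(majority_vote(df)), 1L)
  tie <- data.frame(patient_id = rep("B", 4), pred = c(1, 1, 0, 0))
  expect_equal(unname(majority_vote(tie)), 1L)
  # six patients, all segment majorities correct -> 100% patient accuracy
  set.seed(2)
  six <- do.call(rbind, lapply(1:6, function(i) {
    lab <- i %% 2
    data.frame(patient_id = sprintf("P%d", i),
               pred = c(lab, lab, lab, 1 - lab), label = lab)
  }))
  pl <- patient_level_accuracy(six)
  expect_equal(pl$patient_accuracy, 100)
})

test_that("noise mixing hits the target SNR exactly", {
  s <- synth_noise(noise_spec("white", 1, seed = 1))
  n <- synth_noise(noise_spec("pink", 1, seed = 2))
  # equal unit powers at 0 dB: scale factor 1
  expect_equal(mix_at_snr(s, n, 0)$scale, 1, tolerance = 1e-9)
  # +20 dB: scaled noise power is P_signal / 100
  m20 <- mix_at_snr(s, n, 20)
  expect_equal(mean(m20$scaled_noise^2), mean(s^2) / 100, tolerance = 1e-9)
  # random pair at -5 dB measured post hoc
  m5 <- mix_at_snr(s, n, -5)
  snr_meas <- 10 * log10(mean(s^2) / mean(m5$scaled_noise^2))
  expect_equal(snr_meas, -5, tolerance = 0.01)
  # shorter noise is looped deterministically
  short <- n[1:5000]
  mx <- mix_at_snr(s, short, 10, seed = 3)
  expect_length(mx$mix, length(s))
  expect_identical(mx$mix, mix_at_snr(s, short, 10, seed = 3)$mix)
  expect_error(mix_at_snr(numeric(100), n[1:100], 0), "silent signal")
  expect_error(mix_at_snr(s[1:100], numeric(100), 0), "silent noise")
})

test_that("training is inert at zero learning rate and learns at toy scale", {
  spec <- model_spec(depths = c(1, 1, 1, 1), dims = c(2, 4, 4, 4),
                     use_akconv = FALSE, use_cbam = FALSE, use_convmod = FALSE)
  net <- build_model(spec, seed = 1)
  set.seed(4)
  mk <- function(level, label) list(
    image = array(level + stats::rnorm(3 * 32 * 32, 0, 0.02), c(3, 32, 32)),
    label = label)
  ds <- c(lapply(1:6, function(i) mk(0.1, 0L)),
          lapply(1:6, function(i) mk(0.9, 1L)))
  frozen <- train(net, ds, train_config(batch_size = 4, lr = 0, epochs = 1,
                                        seed = 1))
  expect_equal(net_parameters(frozen$net), net_parameters(net),
               tolerance = 1e-14)
  fit <- train(net, ds, train_config(batch_size = 4, lr = 5e-3, epochs = 3,
                                     seed = 1))
  expect_true(all(diff(fit$history$train_loss) < 0))
  expect_error(train(net, list(), train_config()), "empty")
})

test_that("fold scores aggregate and compare as paired samples", {
  recs <- rep(lapply(1:10, function(i) list(patient_id = paste0("P", i),
                                            label = i %% 2)), each = 2)
  cv <- crossval_kfold(recs, fit_fns = list(
    A = function(tr, va) length(va),
    B = function(tr, va) length(va) + 1), k = 5, seed = 1)
  expect_equal(dim(cv$scores), c(5, 2))
  expect_equal(cv$summary$mean[cv$summary$variant == "B"] -
                 cv$summary$mean[cv$summary$variant == "A"], 1)
  # identical variants: all differences zero, cannot reject
  same <- compare_folds(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$p, 1)
  expect_equal(same$n_effective, 0L)
  # five uniformly signed differences: exact two-sided p = 2/32
  pos <- compare_folds(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(pos$p, 0.0625, tolerance = 1e-12)
})
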