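# Training loop, confusion-matrix metrics, patient-level bootstrap CIs,
# majority voting, SNR-controlled noise mixing, and patient-level k-fold
# cross-validation with paired Wilcoxon comparison of model variants.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 32, AdamW with initial
#' learning rate 2e-4 and weight decay 0.05, 100 epochs, cross-entropy loss.
#'
#' @param batch_size Minibatch size.
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight-decay coefficient (applied to weight
#'   matrices/tensors, not to biases, norms or residual scales).
#' @param epochs Training epochs.
#' @param seed RNG seed controlling initialization-independent shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, lr = 2e-4, weight_decay = 0.05,
                         epochs = 100, seed = 1) {
  stopifnot(batch_size >= 1, lr >= 0, weight_decay >= 0, epochs >= 1)
  structure(list(batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, epochs = epochs,
                 optimizer = "adamw", loss = "cross-entropy", seed = seed),
            class = "train_config")
}

softmax_ce <- function(logits, label01) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  target <- if (label01 == 1) c(0, 1) else c(1, 0)
  list(loss = -sum(target * (z - log(sum(exp(z))))), dlogits = p - target)
}

#' Train a network with AdamW and cross-entropy loss
#'
#' `dataset` entries are lists with `image` (array accepted by
#' [net_forward()]) and `label` (0/1). Per-epoch mean training loss (and
#' validation loss/accuracy if a validation set is given) is logged. The
#' offset-predictor parameters of AKConv blocks use the configured
#' learning-rate multiplier. Deterministic given `cfg$seed` and data order.
#'
#' @param net A `snore_net` from [build_model()].
#' @param dataset Training samples.
#' @param cfg A [train_config()].
#' @param validation Optional validation samples in the same format.
#' @return List with `net` (fitted), `history` (data frame: `epoch`,
#'   `train_loss`, `val_loss`, `val_accuracy`).
#' @export
train <- function(net, dataset, cfg = train_config(), validation = NULL) {
  stopifnot(inherits(net, "snore_net"), inherits(cfg, "train_config"))
  if (length(dataset) == 0) stop("empty training dataset")
  n <- length(dataset)
  # AdamW state per block/param
  state <- lapply(net$blocks, function(bl) {
    lapply(bl$params, function(p) list(m = p * 0, v = p * 0))
  })
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        gacc <- NULL
        bloss <- 0
        for (i in idx) {
          fw <- net_forward(net, dataset[[i]]$image, train = TRUE)
          ce <- softmax_ce(fw$logits, dataset[[i]]$label)
          bloss <- bloss + ce$loss
          g <- net_backward(net, fw, ce$dlogits)
          if (is.null(gacc)) gacc <- g
          else for (j in seq_along(g)) for (nm in names(g[[j]])) {
            gacc[[j]][[nm]] <- gacc[[j]][[nm]] + g[[j]][[nm]]
          }
        }
        ep_loss <- ep_loss + bloss
        step <- step + 1L
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        for (j in seq_along(net$blocks)) {
          bl <- net$blocks[[j]]
          for (nm in names(bl$params)) {
            g <- gacc[[j]][[nm]] / length(idx)
            st <- state[[j]][[nm]]
            st$m <- beta1 * st$m + (1 - beta1) * g
            st$v <- beta2 * st$v + (1 - beta2) * g^2
            state[[j]][[nm]] <- st
            lr_eff <- cfg$lr
            if (!is.null(bl$lr_scale) && nm %in% names(bl$lr_scale)) {
              lr_eff <- lr_eff * bl$lr_scale[[nm]]
            }
            upd <- lr_eff * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
            p <- bl$params[[nm]]
            # decouple weight decay; skip 1-D params (biases, norms, scales)
            if (!is.null(dim(p))) upd <- upd + lr_eff * cfg$weight_decay * p
            net$blocks[[j]]$params[[nm]] <- p - upd
          }
        }
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(validation) && length(validation) > 0) {
        vl <- 0; correct <- 0
        for (s in validation) {
          z <- net_forward(net, s$image)
          vl <- vl + softmax_ce(z, s$label)$loss
          correct <- correct + as.integer(which.max(z) - 1L == s$label)
        }
        val_loss <- vl / length(validation)
        val_acc <- 100 * correct / length(validation)
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / n, val_loss = val_loss,
        val_accuracy = val_acc))
    }
  })
  list(net = net, history = history)
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity, positive predictive value and
#' F1-score, as percentages. Metrics with an empty denominator are returned
#' as `NA` and named in `undefined` rather than silently zeroed.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (total > 0).
#' @return Object of class `metric_report`: list with the five metrics (in
#'   percent), the counts, and `undefined`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- pct(tp + tn, tp + tn + fp + fn)
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  vals <- c(accuracy = acc, sensitivity = sens, specificity = spec,
            ppv = ppv, f1 = f1)
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 ppv = ppv, f1 = f1,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 undefined = names(vals)[is.na(vals)]),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("accuracy ", fmt_pct(x$accuracy), "  sensitivity ", fmt_pct(x$sensitivity),
      "  specificity ", fmt_pct(x$specificity), "  PPV ", fmt_pct(x$ppv),
      "  F1 ", fmt_pct(x$f1), "\n", sep = "")
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
fmt_pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)

#' Patient-level bootstrap confidence interval for accuracy
#'
#' Patients are the resampling unit: per-patient segment accuracies are
#' computed once, then `B` bootstrap resamples of patients (with
#' replacement) give a distribution of mean patient accuracy whose 2.5th and
#' 97.5th percentiles form the interval. Deterministic given `seed`.
#'
#' @param predictions Data frame with columns `patient_id` and `correct`
#'   (logical or 0/1), one row per segment.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed RNG seed (default 42).
#' @param conf Confidence level (default 0.95).
#' @return List with `low`, `high`, `point` (percent).
#' @export
bootstrap_ci <- function(predictions, B = 1000, seed = 42, conf = 0.95) {
  stopifnot(all(c("patient_id", "correct") %in% names(predictions)))
  acc <- tapply(as.numeric(predictions$correct), predictions$patient_id, mean)
  np <- length(acc)
  if (np < 2) stop("need at least 2 patients for a patient-level bootstrap")
  stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) mean(acc[sample.int(np, np, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stats, c(alpha, 1 - alpha), type = 7, names = FALSE)
  list(low = 100 * q[1], high = 100 * q[2], point = 100 * mean(acc))
}

#' Patient-level labels by majority vote over segments
#'
#' @param predictions Data frame with `patient_id` and `pred` (0/1 segment
#'   predictions). Ties go to the positive class.
#' @return Named integer vector of per-patient labels.
#' @export
majority_vote <- function(predictions) {
  stopifnot(all(c("patient_id", "pred") %in% names(predictions)))
  votes <- tapply(as.numeric(predictions$pred), predictions$patient_id, mean)
  out <- as.integer(votes >= 0.5)
  names(out) <- names(votes)
  out
}

#' Mix noise into a signal at a target SNR
#'
#' The noise is cropped, or looped from a seeded random phase offset when
#' shorter than the signal, then scaled so that
#' `10*log10(P_signal / P_noise) = snr_db` and added.
#'
#' @param signal Numeric waveform (non-silent).
#' @param noise Numeric waveform (non-silent).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Seed for the loop phase offset.
#' @return List with `mix`, `scaled_noise`, `scale`.
#' @export
mix_at_snr <- function(signal, noise, snr_db, seed = 1) {
  stopifnot(is.finite(snr_db))
  ps <- mean(signal^2)
  if (ps <= 0) stop("silent signal: SNR undefined")
  if (mean(noise^2) <= 0) stop("silent noise: SNR undefined")
  n <- length(signal)
  if (length(noise) < n) {
    off <- with_seed(seed, sample.int(length(noise), 1))
    noise <- rep(c(noise[off:length(noise)], noise[seq_len(off - 1)]),
                 length.out = n)
  } else {
    noise <- noise[seq_len(n)]
  }
  pn <- mean(noise^2)
  if (pn <= 0) stop("silent noise after cropping: SNR undefined")
  scale <- sqrt(ps / (pn * 10^(snr_db / 10)))
  list(mix = signal + scale * noise, scaled_noise = scale * noise,
       scale = scale)
}

#' Patient-level k-fold cross-validation of model variants
#'
#' Splits records into patient-level folds, applies each variant's fit
#' function to every fold, and summarizes per-fold scores as mean and SD.
#' Variants are compared pairwise with [compare_folds()].
#'
#' @param records Segment records with `patient_id` (see [make_cv_folds()]).
#' @param fit_fns Named list of functions `f(train_records, val_records)`
#'   returning a scalar validation score (e.g. accuracy in percent).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List with `scores` (k x variants matrix), `summary` (mean, sd per
#'   variant), `folds`.
#' @export
crossval_kfold <- function(records, fit_fns, k = 5, seed = 1) {
  stopifnot(length(fit_fns) >= 1, !is.null(names(fit_fns)))
  folds <- make_cv_folds(records, k = k, seed = seed)
  scores <- sapply(fit_fns, function(f) {
    vapply(folds, function(fd) f(fd$train, fd$validation), numeric(1))
  })
  scores <- matrix(scores, nrow = k,
                   dimnames = list(paste0("fold", seq_len(k)), names(fit_fns)))
  summ <- data.frame(variant = colnames(scores),
                     mean = colMeans(scores),
                     sd = apply(scores, 2, stats::sd), row.names = NULL)
  list(scores = scores, summary = summ,
       folds = lapply(folds, `[[`, "patients"))
}

#' Paired Wilcoxon signed-rank comparison of per-fold scores
#'
#' Two-sided test on the paired fold differences; zero differences are
#' dropped (the convention used by common statistics packages). With up to
#' 14 non-zero differences the exact null distribution is enumerated over
#' all sign assignments (valid under tied mid-ranks too); beyond that the
#' normal approximation is used. With all differences zero the test cannot
#' reject and p = 1 is returned.
#'
#' @param a,b Numeric vectors of per-fold scores (same length).
#' @return List with `p`, `statistic` (V, the positive-rank sum),
#'   `n_effective`, `method`.
#' @export
compare_folds <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  M <- sum(r)
  if (n <= 14) {
    # enumerate all 2^n sign assignments of the (mid-)ranks
    vs <- 0
    for (i in seq_len(n)) vs <- c(vs, vs + r[i])
    lo <- min(v, M - v); hi <- max(v, M - v)
    p <- (sum(vs <= lo) + sum(vs >= hi)) / length(vs)
    method <- "exact enumeration"
  } else {
    mu <- M / 2
    sg <- sqrt(sum(r^2) / 4)
    p <- min(1, 2 * stats::pnorm(-abs(v - mu) / sg))
    method <- "normal approximation"
  }
  list(p = min(1, p), statistic = v, n_effective = n, method = method)
}
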