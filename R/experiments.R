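# Reusable end-to-end experiment drivers: synthetic cohort -> features ->
# classifier -> patient-level evaluation, and the Monte-Carlo group-
# comparison study.

#' Patient-level accuracy by majority vote of segment correctness
#'
#' A patient is counted correct when the majority of that patient's segments
#' are classified correctly (ties count as correct, mirroring the positive
#' tie rule of [majority_vote()]).
#'
#' @param predictions Data frame with `patient_id`, `pred`, `label`.
#' @return List with `patient_accuracy` (percent), `per_patient` (named
#'   fraction-correct vector), `segment_accuracy` (percent).
#' @export
patient_level_accuracy <- function(predictions) {
  stopifnot(all(c("patient_id", "pred", "label") %in% names(predictions)))
  correct <- as.numeric(predictions$pred == predictions$label)
  per_patient <- tapply(correct, predictions$patient_id, mean)
  list(patient_accuracy = 100 * mean(per_patient >= 0.5),
       per_patient = per_patient,
       segment_accuracy = 100 * mean(correct))
}

#' Train and evaluate the classifier on a synthetic cohort
#'
#' Generates a spectrally separable snore/non-snore cohort, computes
#' enhanced Mel-spectrogram feature images, performs a patient-level 8:2
#' split, trains a reduced improved model, and evaluates held-out segment
#' and patient-level accuracy. All sub-seeds derive from `seed`.
#'
#' @param seed Master seed.
#' @param n_per_group Patients per group (default 5, i.e. 10 patients).
#' @param segments_per_patient Snore (and equally non-snore) segments per
#'   patient (default 6).
#' @param epochs Training epochs (default 10).
#' @param image_size Feature-image side length fed to the model (default 32).
#' @param n_mel Mel filters for the feature map (default 32).
#' @param dims Model stage widths (default `c(4, 8, 16, 16)`).
#' @param lr Learning rate (default 3e-3, suited to the short schedule).
#' @param batch_size Minibatch size (default 16).
#' @param improved Use the improved model (AKConv + CBAM + ConvMod); `FALSE`
#'   gives the plain reduced backbone.
#' @param enhanced Apply the adaptive filter-bank enhancement to features.
#' @return List with `history`, `patient_accuracy`, `segment_accuracy`,
#'   `per_patient`, `split` (patient ID partition), `net`, `n_segments`.
#' @export
run_synthetic_experiment <- function(seed = 1, n_per_group = 5,
                                     segments_per_patient = 6, epochs = 10,
                                     image_size = 32, n_mel = 32,
                                     dims = c(4, 8, 16, 16), lr = 3e-3,
                                     batch_size = 16, improved = TRUE,
                                     enhanced = TRUE) {
  seeds <- with_seed(seed, sample.int(2^30, 4))
  cohort <- synth_cohort(cohort_spec(
    n_stenotic = n_per_group, n_non_stenotic = n_per_group,
    segments_per_patient = segments_per_patient,
    nonsnore_segments_per_patient = segments_per_patient, seed = seeds[1]))
  recs <- cohort_segments(cohort)
  ds <- lapply(recs, function(r) {
    img <- feature_image(list(samples = r$wave, sample_rate = SNORE_SR),
                         "mel", enhanced = enhanced, size = image_size,
                         M = n_mel)
    list(image = img$pixels, label = r$label, patient_id = r$patient_id)
  })
  sp <- patient_split(ds, ratio = 0.8, seed = seeds[2])
  spec <- model_spec(depths = c(1, 1, 1, 1), dims = dims,
                     use_akconv = improved, use_cbam = improved,
                     use_convmod = improved,
                     cbam = cbam_config(reduction = 4),
                     layer_scale_init = 1e-2)
  net <- build_model(spec, seed = seeds[3])
  fit <- train(net, sp$train,
               train_config(batch_size = batch_size, lr = lr, epochs = epochs,
                            seed = seeds[4]),
               validation = sp$validation)
  probs <- net_predict(fit$net, lapply(sp$validation, `[[`, "image"))
  preds <- max.col(probs, ties.method = "first") - 1L
  df <- data.frame(
    patient_id = vapply(sp$validation, `[[`, character(1), "patient_id"),
    pred = preds,
    label = vapply(sp$validation, function(s) as.integer(s$label), integer(1)))
  pa <- patient_level_accuracy(df)
  list(history = fit$history, patient_accuracy = pa$patient_accuracy,
       segment_accuracy = pa$segment_accuracy, per_patient = pa$per_patient,
       split = list(train = sp$train_patients,
                    validation = sp$validation_patients),
       net = fit$net, n_segments = length(ds))
}

#' Monte-Carlo group-comparison study on synthetic cohorts
#'
#' Repeats, over `n_seeds` generator seeds, the pipeline: synthesize a
#' cohort at the default group medians (patient parameters only, no audio),
#' summarize patients, and run the three Mann-Whitney comparisons. Reports
#' the rejection rate at alpha = 0.05 per indicator.
#'
#' @param n_seeds Number of Monte-Carlo replicates (default 100).
#' @param base_seed Seed offset; replicate s uses seed `base_seed + s`.
#' @param spec_fn Function of one argument (seed) returning a
#'   [cohort_spec()]; defaults to the standard cohort without audio.
#' @return List with `rejection_rate` (fractions per indicator) and `detail`
#'   (logical matrix n_seeds x 3).
#' @export
mc_group_comparison <- function(n_seeds = 100, base_seed = 0, spec_fn = NULL) {
  if (is.null(spec_fn)) {
    spec_fn <- function(s) cohort_spec(segments_per_patient = 0,
                                       nonsnore_segments_per_patient = 0,
                                       seed = s)
  }
  detail <- matrix(NA, n_seeds, 3,
                   dimnames = list(NULL, c("lfer", "frequency", "duration")))
  for (s in seq_len(n_seeds)) {
    cohort <- synth_cohort(spec_fn(base_seed + s))
    g <- group_comparison(cohort_acoustic_summaries(cohort))
    detail[s, ] <- c(g$lfer$significant, g$frequency$significant,
                     g$duration$significant)
  }
  list(rejection_rate = colMeans(detail), detail = detail)
}
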