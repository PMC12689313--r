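# Audio I/O, resampling, normalization, endpoint detection, fixed-length
# segmentation and patient-level dataset splitting.

#' Target sample rate for all analysis
#' @keywords internal
SNORE_SR <- 22050L

#' Analysis frame grid
#'
#' 20 ms Hamming-windowed frames with a 10 ms hop; the frame length in
#' samples is `round(0.020 * sample_rate)`.
#'
#' @param sample_rate Sample rate in Hz.
#' @param frame_length_ms,hop_ms Frame length and hop in milliseconds.
#' @return Object of class `frame_grid` with `frame_length`, `hop` (samples),
#'   `window` (numeric vector) and the input fields.
#' @export
frame_grid <- function(sample_rate = SNORE_SR, frame_length_ms = 20, hop_ms = 10) {
  stopifnot(frame_length_ms > hop_ms, hop_ms > 0)
  n <- round(frame_length_ms * sample_rate / 1000)
  hop <- round(hop_ms * sample_rate / 1000)
  structure(list(sample_rate = sample_rate, frame_length_ms = frame_length_ms,
                 hop_ms = hop_ms, frame_length = n, hop = hop,
                 window = hamming_window(n)),
            class = "frame_grid")
}

#' Load a WAV file and normalize it for analysis
#'
#' Stereo input is averaged to mono, the waveform is resampled to 22.05 kHz
#' with a polyphase band-limited resampler, and the mean is removed.
#'
#' @param path Path to a WAV file.
#' @param patient_id,group Optional metadata carried on the signal.
#' @param target_rate Output sample rate (default 22050 Hz).
#' @return Object of class `audio_signal`: list with `samples`,
#'   `sample_rate`, `patient_id`, `group`.
#' @export
load_and_normalize <- function(path, patient_id = NA_character_,
                               group = NA_character_, target_rate = SNORE_SR) {
  wav <- read_wav(path)
  x <- rowMeans(wav$samples)
  if (length(x) == 0) stop("empty audio in ", path)
  if (wav$sample_rate != target_rate) {
    g <- gcd_int(target_rate, wav$sample_rate)
    x <- as.numeric(signal::resample(x, target_rate / g, wav$sample_rate / g))
    n_expect <- round(length(rowMeans(wav$samples)) * target_rate / wav$sample_rate)
    x <- pad_to_length(x, n_expect)
  }
  x <- x - mean(x)
  audio_signal(x, target_rate, patient_id, group)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Construct an audio signal object
#' @param samples Numeric mono waveform.
#' @param sample_rate Sample rate in Hz.
#' @param patient_id,group Optional metadata.
#' @return Object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate = SNORE_SR,
                         patient_id = NA_character_, group = NA_character_) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 patient_id = patient_id, group = group),
            class = "audio_signal")
}

#' Detect active acoustic regions by short-time energy
#'
#' Classical double-threshold voice-activity detection: frame energies are
#' compared against thresholds set from the signal's noise floor (median
#' frame energy); regions exceeding the high threshold are grown outward
#' while the energy stays above the low threshold or the zero-crossing rate
#' indicates continued activity. Nearby regions are merged and very short
#' ones dropped.
#'
#' @param sig An `audio_signal` (or numeric vector at 22.05 kHz).
#' @param factor_high,factor_low Multiples of the noise-floor energy for the
#'   two thresholds.
#' @param min_duration_s Minimum event duration kept.
#' @param merge_gap_s Regions closer than this are merged.
#' @param zcr_factor Zero-crossing-rate multiple of the median ZCR above
#'   which low-energy frames still extend a region.
#' @return Data frame with `start_s`, `end_s`, sorted and non-overlapping;
#'   zero rows for silence.
#' @export
detect_endpoints <- function(sig, factor_high = 10, factor_low = 3,
                             min_duration_s = 0.1, merge_gap_s = 0.15,
                             zcr_factor = 4) {
  if (inherits(sig, "audio_signal")) {
    x <- sig$samples; fs <- sig$sample_rate
  } else {
    x <- as.numeric(sig); fs <- SNORE_SR
  }
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  g <- frame_grid(fs)
  if (length(x) < g$frame_length) return(empty)
  starts <- seq(1L, length(x) - g$frame_length + 1L, by = g$hop)
  energy <- vapply(starts, function(s) {
    fr <- x[s:(s + g$frame_length - 1L)]
    mean(fr^2)
  }, numeric(1))
  zcr <- vapply(starts, function(s) {
    fr <- x[s:(s + g$frame_length - 1L)]
    mean(abs(diff(sign(fr))) > 0)
  }, numeric(1))
  floor_e <- stats::median(energy)
  if (floor_e <= 0 || max(energy) <= 0) return(empty)
  thr_hi <- floor_e * factor_high
  thr_lo <- floor_e * factor_low
  zcr_thr <- stats::median(zcr) * zcr_factor
  active <- energy > thr_hi
  if (!any(active)) return(empty)
  extendable <- energy > thr_lo | zcr > zcr_thr
  lab <- which(active)
  # grow each active run outward through extendable frames
  keep <- logical(length(energy))
  keep[lab] <- TRUE
  for (i in lab) {
    j <- i - 1L
    while (j >= 1L && extendable[j] && !keep[j]) { keep[j] <- TRUE; j <- j - 1L }
    j <- i + 1L
    while (j <= length(keep) && extendable[j] && !keep[j]) { keep[j] <- TRUE; j <- j + 1L }
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  iv <- cbind(begs[r$values], ends[r$values])
  t0 <- (starts[iv[, 1]] - 1) / fs
  t1 <- (starts[iv[, 2]] - 1 + g$frame_length) / fs
  # merge close intervals
  out <- list()
  cs <- t0[1]; ce <- t1[1]
  for (k in seq_along(t0)[-1]) {
    if (t0[k] - ce <= merge_gap_s) ce <- t1[k]
    else { out[[length(out) + 1]] <- c(cs, ce); cs <- t0[k]; ce <- t1[k] }
  }
  out[[length(out) + 1]] <- c(cs, ce)
  m <- do.call(rbind, out)
  res <- data.frame(start_s = m[, 1], end_s = m[, 2])
  res[res$end_s - res$start_s >= min_duration_s, , drop = FALSE]
}

#' Cut labeled events into fixed 3-second segments
#'
#' An event shorter than 3 s yields one zero-padded segment; an event of
#' length L >= 3 s is tiled into `ceiling(L / 3)` consecutive clips with the
#' last zero-padded. Tiling does not overlap.
#'
#' @param sig An `audio_signal`.
#' @param events Data frame with `start_s`, `end_s` (within signal bounds).
#' @param labels Integer vector (0 non-snoring / 1 snoring), one per event.
#' @param segment_s Segment length in seconds (default 3).
#' @return List of `audio_segment` objects: `samples` (exactly
#'   `segment_s * sample_rate` long), `sample_rate`, `label`, `pad_length`
#'   (trailing zeros in samples), `patient_id`, `group`, `event_index`.
#' @export
segment_3s <- function(sig, events, labels, segment_s = 3) {
  stopifnot(inherits(sig, "audio_signal"))
  if (nrow(events) != length(labels)) stop("label missing for an event")
  if (any(is.na(labels))) stop("label missing for an event")
  fs <- sig$sample_rate
  seg_n <- round(segment_s * fs)
  n <- length(sig$samples)
  out <- list()
  for (e in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$start_s[e] * fs) + 1L)
    i1 <- min(n, ceiling(events$end_s[e] * fs))
    if (i1 > n || i0 < 1 || i1 < i0) stop("event outside signal bounds")
    ev <- sig$samples[i0:i1]
    n_clips <- max(1L, ceiling(length(ev) / seg_n))
    for (k in seq_len(n_clips)) {
      a <- (k - 1L) * seg_n + 1L
      b <- min(length(ev), k * seg_n)
      clip <- ev[a:b]
      pad <- seg_n - length(clip)
      out[[length(out) + 1]] <- structure(list(
        samples = c(clip, numeric(pad)), sample_rate = fs,
        label = as.integer(labels[e]), pad_length = pad,
        patient_id = sig$patient_id, group = sig$group,
        event_index = e, part = k), class = "audio_segment")
    }
  }
  out
}

segment_patient_ids <- function(records) {
  vapply(records, function(r) as.character(r$patient_id), character(1))
}

#' Patient-level train/validation split
#'
#' Patients (not segments) are partitioned so that no patient contributes to
#' both sets; with the default 8:2 ratio, 31 patients split as 25 train /
#' 6 validation.
#'
#' @param records List of segment-like records each carrying a `patient_id`.
#' @param ratio Fraction of patients assigned to training (default 0.8).
#' @param seed Integer seed (shuffling is deterministic given the seed).
#' @return List with `train`, `validation` (record sublists) and
#'   `train_patients`, `validation_patients`.
#' @export
patient_split <- function(records, ratio = 0.8, seed = 1) {
  ids <- segment_patient_ids(records)
  patients <- unique(ids)
  if (length(patients) < 2) stop("need at least 2 patients to split")
  perm <- with_seed(seed, sample(patients))
  n_train <- round(ratio * length(patients))
  n_train <- min(max(n_train, 1L), length(patients) - 1L)
  tr <- perm[seq_len(n_train)]
  va <- setdiff(patients, tr)
  list(train = records[ids %in% tr], validation = records[ids %in% va],
       train_patients = sort(tr), validation_patients = sort(va))
}

#' Patient-level k-fold partition
#'
#' Every patient lands in exactly one fold; folds are as equal in patient
#' count as possible.
#'
#' @param records List of segment-like records each carrying a `patient_id`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of folds; each fold is a list with `patients`,
#'   `validation` (records of those patients) and `train` (all others).
#' @export
make_cv_folds <- function(records, k = 5, seed = 1) {
  ids <- segment_patient_ids(records)
  patients <- unique(ids)
  if (length(patients) < k) stop("fewer patients than folds")
  perm <- with_seed(seed, sample(patients))
  assign_fold <- rep(seq_len(k), length.out = length(perm))
  lapply(seq_len(k), function(f) {
    va <- perm[assign_fold == f]
    list(patients = sort(va),
         validation = records[ids %in% va],
         train = records[!(ids %in% va)])
  })
}

#' Flatten a synthetic cohort into a segment record list
#'
#' @param cohort A `snore_cohort`.
#' @return List of records: `wave`, `label`, `patient_id`, `group`.
#' @export
cohort_segments <- function(cohort) {
  stopifnot(inherits(cohort, "snore_cohort"))
  out <- list()
  for (p in cohort$patients) {
    for (seg in p$segments) {
      out[[length(out) + 1]] <- list(wave = seg$wave, label = seg$label,
                                     patient_id = p$patient_id,
                                     group = p$group)
    }
  }
  out
}
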