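# Synthetic snore/non-snore audio and patient cohorts. The generator's
# defaults encode the study conditions the statistics pipeline targets:
# two patient groups whose low-frequency energy ratio (LFER), nightly event
# counts and event durations differ at the group-median level.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, making generators pure functions of (spec, seed).
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic snore event
#'
#' A snore is modeled as a quasi-periodic harmonic stack (fundamental
#' typically 40-200 Hz) with exponential harmonic roll-off, slow amplitude
#' modulation (2-8 Hz), a raised-cosine onset/offset, and a pink-noise floor.
#' The fraction of energy below 650 Hz is tuned to `target_lfer` by rescaling
#' the spectral content on either side of the band edge.
#'
#' @param fundamental_hz Fundamental frequency in Hz (> 0).
#' @param n_harmonics Number of harmonic partials (>= 1).
#' @param harmonic_rolloff Amplitude decay factor per harmonic in (0, 1\].
#' @param duration_s Event duration in seconds (> 0).
#' @param am_rate_hz Amplitude-modulation rate in Hz.
#' @param target_lfer Desired low-frequency (< 650 Hz) energy ratio in \[0, 1\].
#' @param snr_db_floor SNR of the harmonic stack over the added pink-noise
#'   floor, in dB.
#' @return An object of class `snore_event_spec`.
#' @export
snore_event_spec <- function(fundamental_hz = 120, n_harmonics = 8,
                             harmonic_rolloff = 0.75, duration_s = 1.6,
                             am_rate_hz = 4, target_lfer = 0.6,
                             snr_db_floor = 25) {
  stopifnot(fundamental_hz > 0, n_harmonics >= 1,
            harmonic_rolloff > 0, harmonic_rolloff <= 1,
            duration_s > 0, am_rate_hz >= 0,
            target_lfer >= 0, target_lfer <= 1, snr_db_floor > 0)
  structure(list(fundamental_hz = fundamental_hz, n_harmonics = n_harmonics,
                 harmonic_rolloff = harmonic_rolloff, duration_s = duration_s,
                 am_rate_hz = am_rate_hz, target_lfer = target_lfer,
                 snr_db_floor = snr_db_floor),
            class = "snore_event_spec")
}

#' Synthesize one snore event
#'
#' Deterministic given `seed`. The returned waveform has unit RMS and its
#' measured low-frequency energy ratio (Welch PSD, 650 Hz band edge) is within
#' about 0.05 of `spec$target_lfer`.
#'
#' @param spec A [snore_event_spec()].
#' @param sample_rate Sample rate in Hz; must satisfy the Nyquist condition
#'   for the highest harmonic.
#' @param seed Integer seed.
#' @return Numeric waveform of `round(duration_s * sample_rate)` samples.
#' @export
synth_snore <- function(spec, sample_rate = 22050, seed = 1) {
  stopifnot(inherits(spec, "snore_event_spec"))
  f_top <- spec$fundamental_hz * spec$n_harmonics
  if (sample_rate < 2 * f_top) {
    stop("aliasing: highest harmonic ", f_top, " Hz exceeds Nyquist for fs = ",
         sample_rate, " Hz")
  }
  n <- round(spec$duration_s * sample_rate)
  with_seed(seed, {
    t <- (0:(n - 1)) / sample_rate
    s <- numeric(n)
    for (h in seq_len(spec$n_harmonics)) {
      amp <- spec$harmonic_rolloff^(h - 1)
      s <- s + amp * sin(2 * pi * h * spec$fundamental_hz * t +
                           stats::runif(1, 0, 2 * pi))
    }
    if (spec$am_rate_hz > 0) {
      s <- s * (1 + 0.5 * sin(2 * pi * spec$am_rate_hz * t +
                                stats::runif(1, 0, 2 * pi)))
    }
    ramp_n <- min(floor(n / 4), round(0.05 * sample_rate))
    if (ramp_n > 1) {
      ramp <- 0.5 * (1 - cos(pi * (0:(ramp_n - 1)) / (ramp_n - 1)))
      s[1:ramp_n] <- s[1:ramp_n] * ramp
      s[(n - ramp_n + 1):n] <- s[(n - ramp_n + 1):n] * rev(ramp)
    }
    noise <- pink_noise(n)
    noise <- noise * rms(s) / rms(noise) * 10^(-spec$snr_db_floor / 20)
    s <- s + noise
    s <- tune_lfer(s, sample_rate, spec$target_lfer)
    unit_rms(s)
  })
}

# Rescale the spectral halves of a waveform about the 650 Hz edge so the
# low-band energy fraction equals `target`.
tune_lfer <- function(x, fs, target, cutoff_hz = 650) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f, fs - f)  # two-sided spectrum folded to [0, fs/2]
  low_mask <- f_fold < cutoff_hz
  X_low <- X * low_mask
  x_low <- Re(stats::fft(X_low, inverse = TRUE)) / n
  x_high <- x - x_low
  e_low <- sum(x_low^2)
  e_high <- sum(x_high^2)
  if (target > 0 && e_low <= 0) stop("no low-band content to scale toward target LFER")
  if (target < 1 && e_high <= 0) stop("no high-band content to scale toward target LFER")
  a <- if (target > 0) sqrt(target / e_low) else 0
  b <- if (target < 1) sqrt((1 - target) / e_high) else 0
  a * x_low + b * x_high
}

# Pink (1/f) noise via spectral shaping of white noise; zero-mean, non-unit
# scale (callers rescale).
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)
  g <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  x - mean(x)
}

#' Specification of a synthetic noise waveform
#'
#' Stands in for external ward/background noise corpora in the SNR mixing
#' protocol.
#'
#' @param kind One of `"white"`, `"pink"`, `"speech_band"` (300-3400 Hz band
#'   noise), `"transient_train"` (footstep-like impulses).
#' @param duration_s Duration in seconds (> 0).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("white", "pink", "speech_band", "transient_train"),
                       duration_s = 3, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0)
  structure(list(kind = kind, duration_s = duration_s, seed = seed),
            class = "noise_spec")
}

#' Synthesize a noise waveform
#'
#' Deterministic given the spec's seed; output has unit RMS.
#'
#' @param spec A [noise_spec()].
#' @param sample_rate Sample rate in Hz.
#' @return Numeric waveform.
#' @export
synth_noise <- function(spec, sample_rate = 22050) {
  stopifnot(inherits(spec, "noise_spec"))
  n <- round(spec$duration_s * sample_rate)
  with_seed(spec$seed, {
    x <- switch(spec$kind,
      white = stats::rnorm(n),
      pink = pink_noise(n),
      speech_band = band_noise(n, sample_rate, 300, 3400),
      transient_train = transient_train(n, sample_rate)
    )
    unit_rms(x)
  })
}

# Brick-wall band-limited white noise via FFT masking.
band_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  mask <- f >= f_lo & f <= f_hi
  Re(stats::fft(X * mask, inverse = TRUE)) / n
}

# Footstep-like impulsive noise: sparse impulses convolved with a short
# decaying noise burst.
transient_train <- function(n, fs) {
  x <- numeric(n)
  burst_n <- round(0.03 * fs)
  burst <- stats::rnorm(burst_n) * exp(-6 * (0:(burst_n - 1)) / burst_n)
  pos <- 1
  while (pos < n - burst_n) {
    x[pos:(pos + burst_n - 1)] <- x[pos:(pos + burst_n - 1)] +
      burst * stats::runif(1, 0.5, 1.5)
    pos <- pos + round(fs * stats::runif(1, 0.2, 0.5))
  }
  if (all(x == 0)) x[1:burst_n] <- burst
  x
}

# Breath-like noise: 100-1000 Hz band noise with slow amplitude modulation.
breath_noise <- function(n, fs) {
  x <- band_noise(n, fs, 100, 1000)
  t <- (0:(n - 1)) / fs
  x * (0.6 + 0.4 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi)))
}

#' Synthesize a non-snore sound segment
#'
#' Draws one of three ward-sound classes: breath-band filtered noise,
#' impulsive transients (footstep-like) or 300-3400 Hz speech-band noise.
#'
#' @param kind `"breath"`, `"transient"` or `"speech"`.
#' @param duration_s Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param seed Integer seed.
#' @return Unit-RMS numeric waveform.
#' @export
synth_nonsnore <- function(kind = c("breath", "transient", "speech"),
                           duration_s = 3, sample_rate = 22050, seed = 1) {
  kind <- match.arg(kind)
  n <- round(duration_s * sample_rate)
  with_seed(seed, {
    x <- switch(kind,
      breath = breath_noise(n, sample_rate),
      transient = transient_train(n, sample_rate),
      speech = band_noise(n, sample_rate, 300, 3400)
    )
    unit_rms(x)
  })
}

#' Specification of a synthetic two-group patient cohort
#'
#' Group-level defaults are the study conditions of the statistics pipeline:
#' stenotic vs non-stenotic group medians for the low-frequency energy ratio
#' (0.52 vs 0.69), nightly snore events per 8 h (835.5 vs 649) and median
#' event duration (1.60 vs 1.51 s). Patient values are drawn from
#' logit-normal (LFER) or log-normal (counts, durations) distributions around
#' those medians; medians are preserved exactly by construction, so a
#' zero-dispersion cohort degenerates to the group medians.
#'
#' @param n_stenotic,n_non_stenotic Group sizes (>= 1).
#' @param lfer_median_by_group Length-2 vector (stenotic, non-stenotic) of
#'   LFER medians in \[0, 1\].
#' @param events_per_8h_median_by_group Length-2 vector of median event
#'   counts per 8 h (> 0).
#' @param duration_median_by_group_s Length-2 vector of median event
#'   durations in seconds (> 0).
#' @param dispersion List of between-patient spread parameters:
#'   `lfer_logit_sd`, `events_log_sd`, `duration_log_sd` (each length 2,
#'   stenotic then non-stenotic) and within-patient spreads
#'   `within_lfer_logit_sd`, `within_duration_log_sd`.
#' @param segments_per_patient Snore audio segments synthesized per patient.
#' @param nonsnore_segments_per_patient Non-snore audio segments per patient.
#' @param recording_hours Nominal recording length used to scale event counts.
#' @param sample_rate Audio sample rate in Hz.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stenotic = 16, n_non_stenotic = 15,
                        lfer_median_by_group = c(stenotic = 0.52, non_stenotic = 0.69),
                        events_per_8h_median_by_group = c(stenotic = 835.5, non_stenotic = 649),
                        duration_median_by_group_s = c(stenotic = 1.60, non_stenotic = 1.51),
                        dispersion = list(
                          lfer_logit_sd = c(0.40, 0.66),
                          events_log_sd = c(0.20, 0.20),
                          duration_log_sd = c(0.153, 0.138),
                          within_lfer_logit_sd = 0.15,
                          within_duration_log_sd = 0.10),
                        segments_per_patient = 4,
                        nonsnore_segments_per_patient = 4,
                        recording_hours = 8,
                        sample_rate = 22050,
                        seed = 1) {
  stopifnot(n_stenotic >= 1, n_non_stenotic >= 1,
            all(lfer_median_by_group >= 0), all(lfer_median_by_group <= 1),
            all(events_per_8h_median_by_group > 0),
            all(duration_median_by_group_s > 0),
            recording_hours > 0, segments_per_patient >= 0,
            nonsnore_segments_per_patient >= 0)
  structure(list(n_stenotic = n_stenotic, n_non_stenotic = n_non_stenotic,
                 lfer_median_by_group = lfer_median_by_group,
                 events_per_8h_median_by_group = events_per_8h_median_by_group,
                 duration_median_by_group_s = duration_median_by_group_s,
                 dispersion = dispersion,
                 segments_per_patient = segments_per_patient,
                 nonsnore_segments_per_patient = nonsnore_segments_per_patient,
                 recording_hours = recording_hours,
                 sample_rate = sample_rate, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Produces, per patient: true acoustic parameters (LFER, events per 8 h,
#' median event duration), an event table with start/end times, labeled
#' 3-second audio segments (snore label 1, non-snore label 0), and the
#' per-segment target LFER values. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `snore_cohort`: list with `spec` and `patients`
#'   (each patient a list with `patient_id`, `group`, `lfer`, `events_per_8h`,
#'   `duration_median_s`, `events` data frame, `segments` list,
#'   `segment_lfer`).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$dispersion
  groups <- c(rep("stenotic", spec$n_stenotic),
              rep("non_stenotic", spec$n_non_stenotic))
  with_seed(spec$seed, {
    patients <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      g <- if (groups[i] == "stenotic") 1L else 2L
      lfer_p <- stats::plogis(stats::rnorm(1, stats::qlogis(spec$lfer_median_by_group[g]),
                                           d$lfer_logit_sd[g]))
      events_p <- max(1, round(exp(stats::rnorm(1, log(spec$events_per_8h_median_by_group[g]),
                                                d$events_log_sd[g]))))
      dur_p <- exp(stats::rnorm(1, log(spec$duration_median_by_group_s[g]),
                                d$duration_log_sd[g]))
      durations <- exp(stats::rnorm(events_p, log(dur_p), d$within_duration_log_sd))
      total_s <- spec$recording_hours * 3600
      gaps <- stats::runif(events_p)
      gaps <- gaps / sum(gaps) * max(0, total_s - sum(durations))
      starts <- cumsum(gaps) + cumsum(c(0, utils::head(durations, -1)))
      events <- data.frame(start_s = starts, end_s = starts + durations,
                           duration_s = durations)
      seg_lfer <- stats::plogis(stats::rnorm(spec$segments_per_patient,
                                             stats::qlogis(lfer_p),
                                             d$within_lfer_logit_sd))
      segments <- list()
      if (spec$segments_per_patient > 0) {
        for (k in seq_len(spec$segments_per_patient)) {
          ev_spec <- snore_event_spec(
            fundamental_hz = stats::runif(1, 60, 180),
            n_harmonics = sample(6:12, 1),
            duration_s = min(3, durations[min(k, length(durations))]),
            am_rate_hz = stats::runif(1, 2, 8),
            target_lfer = seg_lfer[k])
          wav <- synth_snore(ev_spec, spec$sample_rate,
                             seed = sample.int(.Machine$integer.max, 1))
          segments[[length(segments) + 1]] <- list(
            wave = pad_to_length(wav, 3 * spec$sample_rate), label = 1L,
            lfer_target = seg_lfer[k])
        }
      }
      if (spec$nonsnore_segments_per_patient > 0) {
        kinds <- c("breath", "transient", "speech")
        for (k in seq_len(spec$nonsnore_segments_per_patient)) {
          wav <- synth_nonsnore(kinds[1 + (k - 1) %% 3], 3, spec$sample_rate,
                                seed = sample.int(.Machine$integer.max, 1))
          segments[[length(segments) + 1]] <- list(
            wave = wav, label = 0L, lfer_target = NA_real_)
        }
      }
      patients[[i]] <- list(
        patient_id = sprintf("P%03d", i), group = groups[i],
        lfer = unname(lfer_p), events_per_8h = unname(events_p),
        duration_median_s = unname(stats::median(durations)),
        events = events, segments = segments, segment_lfer = seg_lfer)
    }
    structure(list(spec = spec, patients = patients), class = "snore_cohort")
  })
}

pad_to_length <- function(x, n) {
  if (length(x) >= n) x[1:n] else c(x, numeric(n - length(x)))
}

#' Per-patient true parameter table of a synthetic cohort
#'
#' @param cohort A `snore_cohort`.
#' @return Data frame with `patient_id`, `group`, `lfer`, `events_per_8h`,
#'   `duration_median_s`.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "snore_cohort"))
  do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, group = p$group, lfer = p$lfer,
               events_per_8h = p$events_per_8h,
               duration_median_s = p$duration_median_s)
  }))
}

#' Write a cohort to WAV files plus an annotations CSV
#'
#' @param cohort A `snore_cohort`.
#' @param dir Output directory (created if missing).
#' @param bits WAV bit depth (16 or 32).
#' @return Path to the annotations CSV, invisibly. Columns: `patient_id`,
#'   `group`, `segment_path`, `label`, `event_start_s`, `event_end_s`.
#' @export
write_cohort <- function(cohort, dir, bits = 16) {
  stopifnot(inherits(cohort, "snore_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in cohort$patients) {
    for (k in seq_along(p$segments)) {
      seg <- p$segments[[k]]
      fn <- file.path(dir, sprintf("%s_seg%03d.wav", p$patient_id, k))
      write_wav(seg$wave, cohort$spec$sample_rate, fn, bits = bits)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p$patient_id, group = p$group, segment_path = fn,
        label = seg$label, event_start_s = 0,
        event_end_s = length(seg$wave) / cohort$spec$sample_rate)
    }
  }
  ann <- do.call(rbind, rows)
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, csv, row.names = FALSE)
  invisible(csv)
}
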