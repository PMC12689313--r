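# Low-frequency energy ratio, patient summaries and group statistics.

test_that("low-frequency energy ratio partitions spectral energy at 650 Hz", {
  expect_gte(lf_energy_ratio(make_tone(200)), 0.99)
  expect_lte(lf_energy_ratio(make_tone(2000)), 0.01)
  mix <- make_tone(200) + make_tone(2000)
  expect_equal(lf_energy_ratio(mix), 0.50, tolerance = 0.02)
  # invariant to amplitude scaling, bounded in [0, 1]
  expect_equal(lf_energy_ratio(0.01 * mix), lf_energy_ratio(100 * mix),
               tolerance = 1e-12)
  r <- lf_energy_ratio(synth_snore(snore_event_spec(target_lfer = 0.3), seed = 2))
  expect_gte(r, 0); expect_lte(r, 1)
  expect_warning(expect_true(is.na(lf_energy_ratio(numeric(66150)))),
                 "undefined")
})

test_that("patient summaries take medians and normalize to 8 hours", {
  s <- summarize_patient("P1", "stenotic", c(0.4, 0.5, 0.6),
                         data.frame(duration_s = 1.6), recording_hours = 8)
  expect_equal(s$lfer, 0.5)
  expect_equal(s$duration_median_s, 1.6)
  # 600 events in a 6-hour recording scale to 800 per 8 h
  s2 <- summarize_patient("P2", "stenotic", 0.5,
                          data.frame(duration_s = stats::runif(600)),
                          recording_hours = 6)
  expect_equal(s2$events_per_8h, 800)
  # missing indicators are flagged NA, not silently zero
  s3 <- summarize_patient("P3", "non_stenotic", numeric(0),
                          data.frame(duration_s = numeric(0)))
  expect_true(is.na(s3$lfer))
  expect_true(is.na(s3$events_per_8h))
})

test_that("summaries are robust to duplicating segments about the median", {
  v <- c(0.3, 0.5, 0.8)
  base <- summarize_patient("P", "stenotic", v, data.frame(duration_s = 1))
  dup <- summarize_patient("P", "stenotic", c(v, 0.3, 0.8),
                           data.frame(duration_s = 1))
  expect_equal(base$lfer, dup$lfer)
})

test_that("Mann-Whitney matches exact enumeration and is label-antisymmetric", {
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$U, 0)
  expect_equal(t1$p, 0.10, tolerance = 1e-12)
  expect_equal(t1$method, "exact")

  t2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t2$p, 1)

  set.seed(6)
  a <- stats::rnorm(12); b <- stats::rnorm(12, 1)
  fwd <- mann_whitney(a, b); rev <- mann_whitney(b, a)
  expect_equal(fwd$Z, -rev$Z, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), a), "empty")
})

test_that("the exact and approximate p agree closely at n = 8 vs 8", {
  set.seed(13)
  for (rep in 1:20) {
    a <- stats::rnorm(8); b <- stats::rnorm(8, 0.7)
    ex <- mann_whitney(a, b)     # exact path (no ties, min n <= 8)
    r <- rank(c(a, b))
    U1 <- sum(r[1:8]) - 36
    mu <- 32; sg <- sqrt(8 * 8 * 17 / 12)
    cc <- if (U1 > mu) 0.5 else if (U1 < mu) -0.5 else 0
    p_approx <- 2 * stats::pnorm(-abs((U1 - mu - cc) / sg))
    expect_lt(abs(ex$p - min(1, p_approx)), 0.02)
  }
})

test_that("exact p agrees with the base-R reference implementation", {
  set.seed(21)
  for (rep in 1:10) {
    a <- stats::rnorm(6); b <- stats::rnorm(7, 0.5)
    ours <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("a large standardized shift is detected in almost all replicates", {
  set.seed(31)
  hits <- 0
  for (r in 1:100) {
    a <- stats::rnorm(16, 0, 1); b <- stats::rnorm(15, 2, 1)  # d ~ 2
    hits <- hits + mann_whitney(a, b)$significant
  }
  expect_gte(hits / 100, 0.95)
})

test_that("group comparison tests the three indicators with IQRs reported", {
  su <- data.frame(
    patient_id = sprintf("P%02d", 1:10),
    group = rep(c("stenotic", "non_stenotic"), each = 5),
    lfer = c(rep(0.5, 5), rep(0.7, 5)),
    events_per_8h = c(900, 850, 820, 880, 860, 600, 640, 660, 620, 650),
    duration_median_s = stats::runif(10, 1.4, 1.7))
  g <- group_comparison(su)
  expect_named(g, c("lfer", "frequency", "duration"))
  # constant distinct groups: minimal attainable p for these sizes
  expect_lt(g$frequency$p, 0.05)
  expect_equal(g$lfer$median_a, 0.5)
  expect_equal(g$lfer$median_b, 0.7)
  # swapping group labels negates Z, keeps p
  su_sw <- su
  su_sw$group <- ifelse(su$group == "stenotic", "non_stenotic", "stenotic")
  g2 <- group_comparison(su_sw)
  expect_equal(g2$frequency$Z, -g$frequency$Z, tolerance = 1e-12)
  expect_equal(g2$frequency$p, g$frequency$p, tolerance = 1e-12)
})

test_that("sensitivity analysis drops flagged patients and reports sizes", {
  set.seed(41)
  co <- synth_cohort(cohort_spec(segments_per_patient = 0,
                                 nonsnore_segments_per_patient = 0, seed = 8))
  su <- cohort_acoustic_summaries(co)
  sten <- su$patient_id[su$group == "stenotic"]
  res <- sensitivity_excluding(su, exclude_ids = sten[1:4])
  expect_equal(unname(res$group_sizes), c(12, 15))
  # empty exclusion set reproduces the full-cohort tests
  res0 <- sensitivity_excluding(su, character(0))
  full <- group_comparison(su)
  expect_equal(res0$tests$lfer$p, full$lfer$p)
  expect_equal(res0$tests$frequency$Z, full$frequency$Z)
  expect_error(sensitivity_excluding(su, sten), "entire group")
})

test_that("demographic comparisons dispatch t, chi-square and Fisher tests", {
  set.seed(51)
  df <- data.frame(group = rep(c("a", "b"), each = 16),
                   age = c(stats::rnorm(16, 70, 8), stats::rnorm(16, 67, 9)),
                   sex = sample(c("F", "M"), 32, TRUE),
                   rare = c(rep("yes", 2), rep("no", 30)))
  out <- demographic_tests(df, continuous = "age",
                           categorical = c("sex", "rare"))
  expect_equal(out$test, c("t", "chisq", "fisher"))
  expect_true(all(out$p >= 0 & out$p <= 1))
})

test_that("large synthetic cohorts recover the generator group medians", {
  sp <- cohort_spec(n_stenotic = 200, n_non_stenotic = 200,
                    segments_per_patient = 0,
                    nonsnore_segments_per_patient = 0, seed = 77)
  su <- cohort_acoustic_summaries(synth_cohort(sp))
  med <- tapply(su$lfer, su$group, median)
  expect_equal(unname(med["stenotic"]), 0.52, tolerance = 0.05)
  expect_equal(unname(med["non_stenotic"]), 0.69, tolerance = 0.05)
  ev <- tapply(su$events_per_8h, su$group, median)
  expect_equal(unname(ev["stenotic"]), 835.5, tolerance = 0.1 * 835.5)
  expect_equal(unname(ev["non_stenotic"]), 649, tolerance = 0.1 * 649)
})
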