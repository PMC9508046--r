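test_that("configuration invariants are enforced", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(grade_attenuation = c("1" = 1, "2" = 0.5, "3" = 0.7,
                                                  "4" = 0.3, "5" = 0.1, "6" = 0)),
               "non-increasing")
  expect_error(synth_config(grade_attenuation = c("1" = 0.9, "2" = 0.7, "3" = 0.5,
                                                  "4" = 0.3, "5" = 0.1, "6" = 0)),
               "must equal 1")
  expect_error(synth_config(cohort_distribution = numeric(0)), "empty")
  expect_error(synth_config(cohort_distribution = c("1" = 1.5)), "integers")
  expect_error(synth_config(synkinesis_gain = 1), "synkinesis")
  expect_error(synth_config(tension_duration_s = 5, trace_duration_s = 4),
               "shorter")
  expect_error(synth_config(dropout = "smile"), "dropout_spec")
})

test_that("traces have the configured length and reject invalid grades", {
  cfg <- small_synth_config()
  tr <- withr::with_seed(5, simulate_trace("smile", "ipsi", 3, cfg))
  expect_length(tr$samples[[1]], 200 * 2)
  expect_error(simulate_trace("smile", "ipsi", 0, cfg), "HB grade")
  expect_error(simulate_trace("smile", "ipsi", 7, cfg), "HB grade")
  expect_error(simulate_trace("smile", "left", 2, cfg), "ipsi")
})

test_that("complete paralysis with zero baseline yields a silent ipsilateral trace", {
  cfg <- small_synth_config(baseline_noise_uv = 0, synkinesis_gain = 0,
                            repetition_cv = 0, subject_asymmetry_cv = 0)
  tr <- withr::with_seed(6, simulate_trace("smile", "ipsi", 6, cfg))
  expect_true(all(tr$samples[[1]] == 0))
  tr_c <- withr::with_seed(6, simulate_trace("smile", "contra", 6, cfg))
  expect_gt(max(abs(tr_c$samples[[1]])), 0)
})

test_that("a symmetric HB 1 session yields near-zero lateralization", {
  cfg <- small_synth_config(repetition_cv = 0, subject_asymmetry_cv = 0,
                            synkinesis_gain = 0,
                            cohort_distribution = c("1" = 2), n_unlabeled = 0,
                            n_patients = 1, seed = 8)
  traces <- simulate_cohort(cfg)
  f <- build_features(process_traces(traces), cohort_labels(traces))
  li <- as.matrix(f[, feature_cols(f)])
  expect_lt(max(abs(li)), 0.1)
})

test_that("expected lateralization decreases monotonically with grade", {
  cfg <- small_synth_config(repetition_cv = 0, subject_asymmetry_cv = 0,
                            synkinesis_gain = 0,
                            cohort_distribution = c("1" = 1, "2" = 1, "3" = 1,
                                                    "4" = 1, "5" = 1, "6" = 1),
                            n_unlabeled = 0, n_patients = 3, seed = 9)
  traces <- simulate_cohort(cfg)
  f <- build_features(process_traces(traces), cohort_labels(traces))
  mean_li <- tapply(rowMeans(as.matrix(f[, feature_cols(f)])), f$hb, mean)
  expect_true(all(diff(mean_li[as.character(1:6)]) < 0))
  expect_lt(abs(mean_li[["1"]]), 0.1)
})

test_that("cohort composition matches the configured distribution exactly", {
  cfg <- small_synth_config(cohort_distribution = c("1" = 3, "2" = 2, "4" = 1),
                            n_unlabeled = 1, unlabeled_truth_grades = 2,
                            n_patients = 3, seed = 10)
  traces <- simulate_cohort(cfg)
  labels <- cohort_labels(traces)
  expect_equal(nrow(labels), 7)
  expect_equal(unname(table(labels$hb)[c("1", "2", "4")]), c(3L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(sum(is.na(labels$hb)), 1)
  expect_false(any(is.na(labels$hb_true)))

  one <- simulate_cohort(small_synth_config(cohort_distribution = c("1" = 1),
                                            n_unlabeled = 0, n_patients = 1))
  expect_equal(dplyr::n_distinct(one$measurement_id), 1)
})

test_that("cohorts are deterministic in the seed and patients keep one operated side", {
  cfg <- small_synth_config(cohort_distribution = c("1" = 2, "3" = 2),
                            n_unlabeled = 0, n_patients = 2, seed = 12)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(cohort_labels(a), cohort_labels(b))

  other <- simulate_cohort(small_synth_config(
    cohort_distribution = c("1" = 2, "3" = 2), n_unlabeled = 0,
    n_patients = 2, seed = 13))
  expect_false(identical(a$samples, other$samples))

  sides <- dplyr::distinct(a[, c("patient_id", "operated_side")])
  expect_equal(nrow(sides), dplyr::n_distinct(a$patient_id))
})

test_that("sessions contain 126 traces unless dropouts fire, and dropouts are recorded", {
  traces <- cached_fixture("dropouts")
  counts <- table(traces$measurement_id)
  expect_equal(unname(counts[["M001"]]), 96)   # missing pose + single-rep pose
  expect_true(all(counts[c("M002", "M003", "M004")] == 126))
  drops <- attr(traces, "dropouts")
  expect_setequal(drops$rule, c("missing_pose", "single_repetition"))
  expect_true(all(drops$measurement_id == "M001"))
})

test_that("cohorts survive the long-CSV round trip", {
  cfg <- small_synth_config(cohort_distribution = c("1" = 1, "2" = 1),
                            n_unlabeled = 0, n_patients = 2, seed = 14)
  traces <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(traces, dir)
  back <- read_cohort_csv(dir)
  key <- c("measurement_id", "muscle", "side", "pose", "repetition")
  a <- dplyr::arrange(traces, dplyr::across(dplyr::all_of(key)))
  b <- dplyr::arrange(back, dplyr::across(dplyr::all_of(key)))
  expect_equal(b$samples, a$samples)
  expect_equal(b$hb, a$hb)
  expect_equal(b$patient_id, a$patient_id)
})
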