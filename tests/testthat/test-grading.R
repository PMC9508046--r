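# feature-table stub with a configurable HB label multiset; feature values
# carry a grade signal so classifiers have something to learn
stub_features <- function(hb, patients = NULL, noise = 0.05, seed = 100) {
  withr::with_seed(seed, {
    n <- length(hb)
    if (is.null(patients)) patients <- sprintf("P%02d", rep(seq_len(ceiling(n / 2)), each = 2))[1:n]
    li <- matrix(rep(-(hb - 1) / 5, 21), n, 21) +
      matrix(rnorm(n * 21, 0, noise), n, 21)
    li <- pmax(pmin(li, 1), -1)
    colnames(li) <- paste0("li_f", 1:21)
    out <- dplyr::bind_cols(
      tibble::tibble(measurement_id = sprintf("M%03d", seq_len(n)),
                     patient_id = patients, hb = as.integer(hb)),
      tibble::as_tibble(li)
    )
    attr(out, "li_cols") <- colnames(li)
    out
  })
}

clinic_hb <- c(rep(1, 30), rep(2, 17), rep(3, 5), rep(4, 3), rep(5, 2), NA, NA)

test_that("scenario datasets map grades to the documented classes and sizes", {
  f <- stub_features(clinic_hb)
  s1 <- make_scenario_dataset(f, 1)
  expect_equal(unname(table(s1$class)), c(30L, 27L), ignore_attr = TRUE)
  s2 <- make_scenario_dataset(f, 2)
  expect_equal(unname(table(s2$class)), c(47L, 10L), ignore_attr = TRUE)
  s3 <- make_scenario_dataset(f, 3)
  expect_equal(unname(table(s3$class)), c(30L, 17L, 5L), ignore_attr = TRUE)
  expect_false(any(s3$hb > 3))                    # HB 4-6 excluded
  expect_equal(nrow(s1), 57)                      # missing-HB rows dropped

  expect_error(make_scenario_dataset(stub_features(rep(1, 8)), 2), "no members")
  expect_error(scenario_spec(4), "must be 1, 2 or 3")
})

test_that("LOO folds partition the measurements by patient", {
  f <- stub_features(c(1, 1, 2, 2, 3, 3, 1, 2, 3),
                     patients = c("A", "A", "A", "B", "B", "C", "C", "D", "D"))
  ds <- make_scenario_dataset(f, 3)
  for (clf in c("logreg", "svm", "knn")) {
    preds <- loo_cross_validate(ds, clf)
    expect_setequal(preds$measurement_id, ds$measurement_id)
    expect_equal(nrow(preds), nrow(ds))           # each measurement exactly once
    expect_equal(anyDuplicated(preds$measurement_id), 0L)
  }
  expect_error(loo_cross_validate(make_scenario_dataset(
    stub_features(c(1, 2), patients = c("A", "A")), 1)), "at least 2 patients")
})

test_that("a patient's own measurements never reach its training fold", {
  # two patients with identical feature rows but opposite classes: with any
  # leakage the 5-NN would find the zero-distance self-match and be right;
  # proper LOO must predict each patient as the other's class and be wrong
  f <- stub_features(c(1, 1, 3, 3), patients = c("A", "A", "B", "B"), noise = 0)
  li_cols <- feature_cols(f)
  f[3:4, li_cols] <- f[1:2, li_cols]              # identical features, grades differ
  ds <- make_scenario_dataset(f, 2)
  # each patient carries only one class, so every fold also warns about the
  # class missing from training — expected in this adversarial miniature
  suppressWarnings(preds <- loo_cross_validate(ds, "knn"))
  expect_true(all(preds$predicted != preds$true))
})

test_that("class probabilities are normalized and predictions take the argmax", {
  f <- stub_features(clinic_hb, noise = 0.2)
  ds <- make_scenario_dataset(f, 3)
  for (clf in c("logreg", "svm", "knn")) {
    preds <- loo_cross_validate(ds, clf)
    prob <- as.matrix(preds[, paste0("p_", levels(ds$class))])
    expect_true(all(prob >= 0))
    expect_true(all(abs(rowSums(prob) - 1) < 1e-9))
    expect_equal(as.character(preds$predicted),
                 levels(ds$class)[apply(prob, 1, which.max)])
  }
})

test_that("tied probabilities resolve toward the better grade", {
  # equidistant training points of two classes give the 2-NN equal weights
  f <- stub_features(c(1, 3, 1, 3), patients = c("A", "A", "B", "B"), noise = 0)
  li_cols <- feature_cols(f)
  f[1, li_cols] <- 1; f[2, li_cols] <- -1
  f[3, li_cols] <- 1; f[4, li_cols] <- -1
  ds <- make_scenario_dataset(f, 2)
  probe <- ds; probe[probe$patient_id == "B", li_cols] <- 0  # exactly between
  preds <- loo_cross_validate(probe, "knn", standardize = FALSE)
  b <- preds[preds$patient_id == "B", ]
  expect_true(all(abs(b$`p_HB1-2` - 0.5) < 1e-9))
  expect_true(all(b$predicted == "HB1-2"))        # tie -> better grade
})

test_that("a training fold missing a class warns and fits on the rest", {
  # the only HB3 patient: its fold (and only its fold) trains without HB3
  f <- stub_features(c(1, 2, 1, 2, 3, 3),
                     patients = c("A", "A", "B", "B", "C", "C"))
  ds <- make_scenario_dataset(f, 3)
  expect_warning(preds <- loo_cross_validate(ds, "logreg"), "lacks class HB3")
  pc <- preds[preds$patient_id == "C", "p_HB3", drop = TRUE]
  expect_true(all(pc == 0))
})

test_that("all classifiers solve a cleanly separable synthetic cohort", {
  traces <- cached_fixture("tiny_separable")
  f <- build_features(process_traces(traces), cohort_labels(traces))
  ds <- make_scenario_dataset(f, 2)               # HB1 vs HB5 -> the two classes
  withr::with_seed(200, {
    for (clf in c("logreg", "svm", "knn")) {
      preds <- loo_cross_validate(ds, clf)
      expect_true(all(preds$predicted == preds$true), label = clf)
      expect_equal(binary_auc(preds), 1)
    }
  })
})

test_that("classifier hyperparameters are fixed as documented", {
  expect_equal(classifier_spec("knn")$hyperparameters$k, 5)
  expect_equal(classifier_spec("svm")$hyperparameters$C, 1)
  expect_equal(classifier_spec("svm")$hyperparameters$gamma, "1/n_features")
  expect_error(classifier_spec("rf"))
})
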