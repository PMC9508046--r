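# HB-grade classification: three clinical scenarios, three fixed classifiers,
# leave-one-patient-out cross-validation.

#' Classification scenario specifications
#'
#' Three clinically motivated groupings of the House--Brackmann scale:
#' \describe{
#'   \item{1}{normal vs. impaired — HB 1 vs. HB 2--6 (binary).}
#'   \item{2}{normal or slight vs. moderate impairment — HB 1--2 vs. HB 3--6
#'     (binary).}
#'   \item{3}{three-class HB 1 / 2 / 3; grades 4--6 are excluded because they
#'     are too rare for per-grade classification.}
#' }
#' Class levels are ordered from best to worst facial function; prediction
#' ties resolve toward the better grade.
#'
#' @param id Scenario id, 1, 2 or 3.
#' @return Object of class `scenario_spec`: `id`, `classes` (ordered levels),
#'   `included_grades`, and `map_grade()` mapping HB grades to class labels.
#' @export
scenario_spec <- function(id) {
  id <- as.integer(id)
  spec <- switch(as.character(id),
    "1" = list(classes = c("HB1", "HB2-6"), included = 1:6,
               map = function(hb) ifelse(hb == 1, "HB1", "HB2-6")),
    "2" = list(classes = c("HB1-2", "HB3-6"), included = 1:6,
               map = function(hb) ifelse(hb <= 2, "HB1-2", "HB3-6")),
    "3" = list(classes = c("HB1", "HB2", "HB3"), included = 1:3,
               map = function(hb) paste0("HB", hb)),
    stop("scenario id must be 1, 2 or 3", call. = FALSE)
  )
  structure(list(id = id, classes = spec$classes,
                 included_grades = spec$included, map_grade = spec$map),
            class = "scenario_spec")
}

#' Build the labeled dataset of one scenario
#'
#' Drops measurements without a clinical HB grade, restricts to the
#' scenario's grades (scenario 3 excludes HB 4--6) and maps grades to class
#' labels. Patient ids are retained for grouped cross-validation.
#'
#' @param features Feature tibble from [build_features()]; must carry `hb`
#'   and `patient_id`.
#' @param scenario A [scenario_spec()] or scenario id.
#' @return Tibble with `measurement_id`, `patient_id`, `hb`, `class` (factor
#'   with the scenario's levels) and the `li_` feature columns; attribute
#'   `"scenario"`.
#' @export
make_scenario_dataset <- function(features, scenario) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  cols <- feature_cols(features)
  ds <- dplyr::filter(features, !is.na(.data$hb),
                      .data$hb %in% scenario$included_grades)
  ds <- ds[, c("measurement_id", "patient_id", "hb", cols)]
  ds$class <- factor(scenario$map_grade(ds$hb), levels = scenario$classes)
  sizes <- table(ds$class)
  if (any(sizes == 0)) {
    stop("scenario ", scenario$id, ": class ",
         names(sizes)[sizes == 0][[1]], " has no members (AUC undefined)",
         call. = FALSE)
  }
  ds <- dplyr::relocate(ds, "class", .after = "hb")
  attr(ds, "scenario") <- scenario
  attr(ds, "li_cols") <- cols
  ds
}

#' Classifier specifications
#'
#' The three classifiers with fixed, untuned hyperparameters:
#' \describe{
#'   \item{logreg}{ridge-regularized logistic regression
#'     (`glmnet`, `alpha = 0`, `lambda = 1/n_train`); multinomial for
#'     scenario 3.}
#'   \item{svm}{support vector machine with RBF kernel,
#'     `gamma = 1/n_features`, `C = 1`, Platt-style probability calibration
#'     (`kernlab::ksvm`, `prob.model = TRUE`).}
#'   \item{knn}{k-nearest neighbours, `k = 5`, neighbour weights inversely
#'     proportional to distance (an exact match takes all the weight).}
#' }
#'
#' @param name `"logreg"`, `"svm"` or `"knn"`.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("logreg", "svm", "knn")) {
  name <- match.arg(name)
  hyper <- switch(name,
    logreg = list(alpha = 0, lambda = "1/n_train"),
    svm = list(kernel = "rbf", gamma = "1/n_features", C = 1, probability = TRUE),
    knn = list(k = 5, weights = "inverse_distance")
  )
  structure(list(name = name, hyperparameters = hyper), class = "classifier_spec")
}

# --- fit/predict backends ---------------------------------------------------
# All return an n_test x n_levels probability matrix over `lev` (the full
# level set); classes absent from training get probability 0.

# glmnet warns about classes with < 8 observations; folds that small are the
# study condition here, so that advisory is muffled
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

fit_predict_logreg <- function(x, y, xt, lev) {
  present <- levels(droplevels(y))
  prob <- matrix(0, nrow(xt), length(lev), dimnames = list(NULL, lev))
  if (length(present) == 1) {
    prob[, present] <- 1
    return(prob)
  }
  yd <- droplevels(y)
  lam <- 1 / length(y)
  # glmnet refuses classes with a single observation; duplicating that row
  # (= doubling its case weight) keeps such minute folds usable
  singletons <- names(which(table(yd) < 2))
  if (length(singletons) > 0) {
    idx <- which(yd %in% singletons)
    x <- rbind(x, x[idx, , drop = FALSE])
    yd <- factor(c(as.character(yd), as.character(yd[idx])), levels = levels(yd))
  }
  if (length(present) == 2) {
    fit <- quiet_small_class(
      glmnet::glmnet(x, yd, family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE)
    )
    p2 <- as.numeric(predict(fit, xt, type = "response"))
    prob[, present[2]] <- p2
    prob[, present[1]] <- 1 - p2
  } else {
    fit <- quiet_small_class(
      glmnet::glmnet(x, yd, family = "multinomial", alpha = 0, lambda = lam,
                     standardize = FALSE)
    )
    p <- predict(fit, xt, type = "response")[, , 1, drop = FALSE]
    prob[, colnames(p)] <- p[, , 1]
  }
  prob
}

fit_predict_svm <- function(x, y, xt, lev) {
  present <- levels(droplevels(y))
  prob <- matrix(0, nrow(xt), length(lev), dimnames = list(NULL, lev))
  if (length(present) == 1) {
    prob[, present] <- 1
    return(prob)
  }
  yd <- droplevels(y)
  kp <- list(sigma = 1 / ncol(x))
  fit <- tryCatch(
    kernlab::ksvm(x, yd, type = "C-svc", kernel = "rbfdot", kpar = kp, C = 1,
                  prob.model = TRUE, scaled = FALSE),
    error = function(e) NULL
  )
  p <- if (!is.null(fit)) {
    tryCatch(kernlab::predict(fit, xt, type = "probabilities"),
             error = function(e) NULL)
  }
  if (is.null(p) || any(!is.finite(p))) {
    # Platt calibration needs enough cases per class for kernlab's internal
    # cross-validation split; on minute folds fall back to the uncalibrated
    # decision and report hard class assignments
    hard <- kernlab::ksvm(x, yd, type = "C-svc", kernel = "rbfdot", kpar = kp,
                          C = 1, prob.model = FALSE, scaled = FALSE)
    cls <- as.character(kernlab::predict(hard, xt))
    p <- matrix(0, nrow(xt), length(present), dimnames = list(NULL, present))
    p[cbind(seq_len(nrow(xt)), match(cls, present))] <- 1
  }
  prob[, colnames(p)] <- p
  prob
}

fit_predict_knn <- function(x, y, xt, lev, k = 5) {
  present <- levels(droplevels(y))
  prob <- matrix(0, nrow(xt), length(lev), dimnames = list(NULL, lev))
  k <- min(k, nrow(x))
  for (i in seq_len(nrow(xt))) {
    d <- sqrt(colSums((t(x) - xt[i, ])^2))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (any(dn < 1e-12)) {
      exact <- nn[dn < 1e-12]
      w <- setNames(rep(1 / length(exact), length(exact)), NULL)
      cls <- y[exact]
    } else {
      w <- (1 / dn) / sum(1 / dn)
      cls <- y[nn]
    }
    for (j in seq_along(w)) {
      prob[i, as.character(cls[j])] <- prob[i, as.character(cls[j])] + w[j]
    }
  }
  prob
}

fit_predict <- function(x, y, xt, lev, spec) {
  prob <- switch(spec$name,
    logreg = fit_predict_logreg(x, y, xt, lev),
    svm = fit_predict_svm(x, y, xt, lev),
    knn = fit_predict_knn(x, y, xt, lev, k = spec$hyperparameters$k)
  )
  prob / rowSums(prob)
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: all of a patient's measurements are held out
#' together, so no measurement of a patient ever informs the model that
#' grades it (within-patient leakage across time points is excluded by
#' construction). Feature standardization statistics are computed on each
#' training fold only. Test-fold class probabilities are accumulated over
#' folds, covering every measurement exactly once.
#'
#' If a training fold lacks one of the scenario classes entirely (possible in
#' tiny cohorts), the classifier is fit on the remaining classes and a
#' warning is emitted; the absent class receives probability zero.
#'
#' @param dataset Scenario dataset from [make_scenario_dataset()].
#' @param classifier A [classifier_spec()] or its name.
#' @param standardize Standardize features with training-fold mean/sd
#'   (default `TRUE`; constant features get scale 1).
#' @return Tibble of accumulated test predictions: `measurement_id`,
#'   `patient_id`, `true`, `predicted` (argmax probability, ties toward the
#'   better grade) and one `p_<class>` column per scenario class.
#' @export
loo_cross_validate <- function(dataset, classifier = "logreg", standardize = TRUE) {
  if (!inherits(classifier, "classifier_spec")) classifier <- classifier_spec(classifier)
  cols <- attr(dataset, "li_cols")
  if (is.null(cols)) cols <- grep("^li_", names(dataset), value = TRUE)
  if (dplyr::n_distinct(dataset$patient_id) < 2) {
    stop("leave-one-patient-out needs at least 2 patients", call. = FALSE)
  }
  lev <- levels(dataset$class)
  X <- as.matrix(dataset[, cols])
  folds <- sort(unique(dataset$patient_id))

  out <- purrr::map(folds, function(pid) {
    te <- dataset$patient_id == pid
    xtr <- X[!te, , drop = FALSE]
    ytr <- dataset$class[!te]
    xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    absent <- setdiff(lev, as.character(unique(ytr)))
    if (length(absent) > 0) {
      warning("training fold for patient ", pid, " lacks class ",
              paste(absent, collapse = ", "),
              "; fitting on remaining classes", call. = FALSE)
    }
    prob <- fit_predict(xtr, ytr, xte, lev, classifier)
    pred <- lev[apply(prob, 1, which.max)]
    res <- tibble::tibble(
      measurement_id = dataset$measurement_id[te],
      patient_id = pid,
      true = dataset$class[te],
      predicted = factor(pred, levels = lev)
    )
    colnames(prob) <- paste0("p_", lev)
    dplyr::bind_cols(res, tibble::as_tibble(prob))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "classes") <- lev
  res
}
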