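# Evaluation metrics over accumulated cross-validation predictions:
# rank-based ROC-AUC, one-vs-one multiclass AUC, concordance breakdown.

# Mann-Whitney AUC: probability a random positive outscores a random
# negative, ties counting one half.
auc_rank <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pred_classes <- function(predictions) {
  lev <- attr(predictions, "classes")
  if (is.null(lev)) lev <- levels(predictions$true)
  lev
}

#' Binary ROC-AUC of accumulated predictions
#'
#' Rank-based (Mann--Whitney) area under the ROC curve of the positive-class
#' probability; ties contribute 1/2. Invariant under strictly monotone
#' transforms of the score.
#'
#' @param predictions Prediction tibble from [loo_cross_validate()] with a
#'   two-level `true` factor and `p_<class>` probability columns.
#' @param positive Positive class label; defaults to the worse (second)
#'   class.
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(predictions, positive = NULL) {
  lev <- pred_classes(predictions)
  if (length(lev) != 2) stop("binary_auc needs exactly 2 classes", call. = FALSE)
  if (is.null(positive)) positive <- lev[[2]]
  if (!positive %in% lev) stop("unknown positive class: ", positive, call. = FALSE)
  scores <- predictions[[paste0("p_", positive)]]
  auc_rank(scores, predictions$true == positive)
}

#' One-vs-one multiclass AUC
#'
#' For every unordered pair of classes, restricts the predictions to
#' measurements of those two classes and averages the two directed AUCs
#' (each direction scoring with its own class probability); the final value
#' is the unweighted mean over pairs. With exactly two classes this equals
#' [binary_auc()]. A pair with an empty class is skipped with a warning.
#'
#' @param predictions Prediction tibble from [loo_cross_validate()].
#' @return Macro-averaged one-vs-one AUC in `[0, 1]`.
#' @export
multiclass_ovo_auc <- function(predictions) {
  lev <- pred_classes(predictions)
  if (length(lev) < 2) stop("need at least 2 classes", call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  vals <- purrr::map_dbl(pairs, function(pr) {
    sub <- predictions[predictions$true %in% pr, ]
    if (!all(pr %in% sub$true)) {
      warning("pair ", pr[1], "/", pr[2], " has an empty class; skipped",
              call. = FALSE)
      return(NA_real_)
    }
    a1 <- auc_rank(sub[[paste0("p_", pr[1])]], sub$true == pr[1])
    a2 <- auc_rank(sub[[paste0("p_", pr[2])]], sub$true == pr[2])
    (a1 + a2) / 2
  })
  mean(vals, na.rm = TRUE)
}

#' Concordance / under- / overestimation breakdown
#'
#' Compares predicted with clinical grades on the ordinal class scale:
#' concordant (equal), underestimated (predicted a better grade than the
#' clinical one) and overestimated (worse), as percentages of all test
#' predictions.
#'
#' @param predictions Prediction tibble with ordinal `true` and `predicted`
#'   factors sharing levels ordered best to worst.
#' @return One-row tibble: `concordant_pct`, `under_pct`, `over_pct`, `n`.
#' @export
concordance_analysis <- function(predictions) {
  if (nrow(predictions) == 0) stop("no predictions", call. = FALSE)
  tr <- as.integer(predictions$true)
  pr <- as.integer(predictions$predicted)
  tibble::tibble(
    concordant_pct = 100 * mean(pr == tr),
    under_pct = 100 * mean(pr < tr),
    over_pct = 100 * mean(pr > tr),
    n = length(tr)
  )
}

# ROC curve points (for plotting): step coordinates over score thresholds
roc_points <- function(scores, is_pos) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  tibble::tibble(
    fpr = c(0, fp[keep] / sum(!is_pos)),
    tpr = c(0, tp[keep] / sum(is_pos))
  )
}
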