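# Lateralization indices: LI = (EMG_ipsi - EMG_contra) / (EMG_ipsi + EMG_contra)
# per muscle x pose x repetition, averaged over repetitions, with explicit
# imputation of incomplete movements.

#' Lateralization index
#'
#' `LI = (ipsi - contra) / (ipsi + contra)` of two envelope amplitudes.
#' +1 means activity only ipsilateral to the operated side, -1 only
#' contralateral, 0 symmetric. When both amplitudes are zero the index is
#' defined as 0 (no lateralization information). Vectorized.
#'
#' @param ipsi,contra Nonnegative envelope amplitudes (uV).
#' @return LI values in `[-1, 1]`.
#' @examples
#' lateralization_index(3, 1)   # 0.5
#' lateralization_index(0, 2)   # -1
#' @export
lateralization_index <- function(ipsi, contra) {
  if (any(is.na(ipsi)) || any(is.na(contra))) stop("amplitudes must not be NA", call. = FALSE)
  if (any(ipsi < 0) || any(contra < 0)) {
    stop("amplitudes must be nonnegative (rectified envelope)", call. = FALSE)
  }
  total <- ipsi + contra
  ifelse(total == 0, 0, (ipsi - contra) / total)
}

#' Impute missing movements in a lateralization table
#'
#' Completes per-movement gaps: a (muscle, pose) cell with no usable
#' repetitions at all receives the mean LI of that muscle's other poses in the
#' same measurement, and is flagged `"whole_movement"`. Cells that already
#' carry a repetition mean are untouched. A muscle with no observed pose at
#' all cannot be imputed and raises an error.
#'
#' @param li_long Tibble with columns `measurement_id`, `muscle`, `pose`,
#'   `li` (`NA` = movement fully missing) and `imputed`.
#' @return The completed tibble; every `li` finite, `imputed` updated.
#' @export
impute_missing <- function(li_long) {
  stopifnot(all(c("measurement_id", "muscle", "pose", "li", "imputed") %in% names(li_long)))
  grp <- dplyr::group_by(li_long, .data$measurement_id, .data$muscle)
  bad <- dplyr::filter(dplyr::summarise(grp, all_na = all(is.na(.data$li)), .groups = "drop"),
                       .data$all_na)
  if (nrow(bad) > 0) {
    stop("cannot impute: no observed pose for muscle ", bad$muscle[[1]],
         " in measurement ", bad$measurement_id[[1]], call. = FALSE)
  }
  out <- dplyr::mutate(
    grp,
    imputed = ifelse(is.na(.data$li), "whole_movement", .data$imputed),
    li = ifelse(is.na(.data$li), mean(.data$li, na.rm = TRUE), .data$li)
  )
  dplyr::ungroup(out)
}

#' Build lateralization feature vectors
#'
#' Pairs ipsi- and contralateral amplitudes per muscle x pose x repetition,
#' computes the LI of each repetition, averages over the available
#' repetitions, and imputes fully missing movements, yielding one fixed-length
#' feature vector (3 muscles x 7 poses = 21 indices) per measurement.
#' Repetitions with only one side recorded are dropped from the average; a
#' pose retaining fewer than `n_repetitions` usable repetitions is flagged
#' `"partial_repetitions"`, a fully absent pose is imputed and flagged
#' `"whole_movement"`.
#'
#' @param amplitudes Amplitude tibble from [process_traces()].
#' @param labels Session metadata with `measurement_id`, `patient_id`, `hb`
#'   (clinical HB grade, `NA` if missing), e.g. from [cohort_labels()].
#' @param poses Pose vocabulary defining the feature order; defaults to the
#'   poses present in `amplitudes`.
#' @param n_repetitions Protocol repetitions per pose (default 3).
#' @return Wide tibble, one row per measurement: `measurement_id`,
#'   `patient_id`, `hb`, 21 `li_<muscle>_<pose>` columns in `[-1, 1]` and 21
#'   matching `imp_<muscle>_<pose>` flag columns (`"none"`,
#'   `"partial_repetitions"` or `"whole_movement"`). Attribute `"li_cols"`
#'   names the feature columns in order.
#' @export
build_features <- function(amplitudes, labels, poses = NULL, n_repetitions = 3) {
  if (is.null(poses)) poses <- unique(amplitudes$pose)
  muscles <- semg_muscles()

  paired <- tidyr::pivot_wider(
    amplitudes[, c("measurement_id", "muscle", "pose", "repetition", "side",
                   "amplitude_uv")],
    names_from = "side", values_from = "amplitude_uv"
  )
  if (!"ipsi" %in% names(paired)) paired$ipsi <- NA_real_
  if (!"contra" %in% names(paired)) paired$contra <- NA_real_
  paired <- dplyr::filter(paired, !is.na(.data$ipsi) & !is.na(.data$contra))
  if (nrow(paired) > 0) {
    paired$li_rep <- lateralization_index(paired$ipsi, paired$contra)
  } else {
    paired$li_rep <- numeric(0)
  }

  per_cell <- dplyr::summarise(
    dplyr::group_by(paired, .data$measurement_id, .data$muscle, .data$pose),
    li = mean(.data$li_rep), n_reps = dplyr::n(), .groups = "drop"
  )

  usable <- dplyr::count(per_cell, .data$measurement_id)
  all_meas <- unique(amplitudes$measurement_id)
  dead <- setdiff(all_meas, usable$measurement_id)
  if (length(dead) > 0) {
    stop("measurement ", dead[[1]], " has no usable ipsi/contra pair", call. = FALSE)
  }

  grid <- tidyr::expand_grid(
    measurement_id = unique(per_cell$measurement_id),
    muscle = muscles, pose = poses
  )
  long <- dplyr::left_join(grid, per_cell,
                           by = c("measurement_id", "muscle", "pose"))
  long$imputed <- dplyr::case_when(
    is.na(long$li) ~ NA_character_,
    long$n_reps < n_repetitions ~ "partial_repetitions",
    TRUE ~ "none"
  )
  long <- impute_missing(long[, c("measurement_id", "muscle", "pose", "li", "imputed")])

  long$muscle <- factor(long$muscle, levels = muscles)
  long$pose <- factor(long$pose, levels = poses)
  long <- dplyr::arrange(long, .data$measurement_id, .data$muscle, .data$pose)

  li_wide <- tidyr::pivot_wider(
    long[, c("measurement_id", "muscle", "pose", "li")],
    names_from = c("muscle", "pose"), values_from = "li",
    names_prefix = "li_", names_sep = "_"
  )
  imp_wide <- tidyr::pivot_wider(
    long[, c("measurement_id", "muscle", "pose", "imputed")],
    names_from = c("muscle", "pose"), values_from = "imputed",
    names_prefix = "imp_", names_sep = "_"
  )
  out <- dplyr::left_join(li_wide, imp_wide, by = "measurement_id")

  meta_cols <- intersect(c("measurement_id", "patient_id", "hb"), names(labels))
  out <- dplyr::left_join(out, dplyr::distinct(labels[, meta_cols]),
                          by = "measurement_id")
  li_cols <- grep("^li_", names(out), value = TRUE)
  out <- dplyr::relocate(out, dplyr::any_of(c("measurement_id", "patient_id", "hb")))
  attr(out, "li_cols") <- li_cols
  out
}

#' Feature columns of a feature table
#'
#' @param features Tibble from [build_features()].
#' @return Character vector of the `li_` column names, in canonical order.
#' @export
feature_cols <- function(features) {
  cols <- attr(features, "li_cols")
  if (is.null(cols)) cols <- grep("^li_", names(features), value = TRUE)
  cols
}

#' Long view of a feature table
#'
#' Unpivots the 21 `li_` columns back to one row per measurement x muscle x
#' pose, convenient for plotting LI distributions by grade.
#'
#' @param features Tibble from [build_features()].
#' @return Long tibble with `muscle`, `pose`, `li` (and the metadata columns).
#' @export
li_long <- function(features) {
  muscles <- semg_muscles()
  long <- tidyr::pivot_longer(
    features[, c(intersect(c("measurement_id", "patient_id", "hb"), names(features)),
                 feature_cols(features))],
    dplyr::starts_with("li_"), names_to = "feature", values_to = "li"
  )
  feat <- sub("^li_", "", long$feature)
  m <- muscles[vapply(feat, function(f) which(startsWith(f, muscles))[1], 1L)]
  long$muscle <- m
  long$pose <- substring(feat, nchar(m) + 2L)
  long$feature <- NULL
  long
}

#' Write / read feature tables
#'
#' @param features Tibble from [build_features()].
#' @param path CSV path.
#' @return The path (write) or the feature tibble with its `li_cols`
#'   attribute restored (read).
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = "")
  out$hb <- suppressWarnings(as.integer(out$hb))
  attr(out, "li_cols") <- grep("^li_", names(out), value = TRUE)
  out
}
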