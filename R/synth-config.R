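# Configuration for the synthetic sEMG cohort generator.

#' Configure the synthetic sEMG cohort generator
#'
#' Builds the configuration object consumed by [simulate_trace()],
#' [simulate_session()] and [simulate_cohort()]. The defaults emulate the
#' perioperative recording protocol: seven facial poses, three
#' tension--relaxation repetitions per pose (about 1 s tension, 3 s
#' relaxation), three muscles recorded bilaterally, and a cohort of 59
#' measurements over 28 patients with the grade distribution
#' 30/17/5/3/2 for House--Brackmann (HB) grades 1--5 plus two measurements
#' whose clinical grade is missing.
#'
#' The signal model is band-limited Gaussian noise whose instantaneous
#' standard deviation follows a trapezoidal tension envelope. On the side
#' ipsilateral to the operated side the burst drive is attenuated by
#' `grade_attenuation[hb]`; a fraction `synkinesis_gain` of each side's drive
#' leaks to the other side (synkinetic crosstalk). Two further noise sources
#' make adjacent low grades overlap realistically: a per-repetition amplitude
#' jitter (`repetition_cv`) and a per-session, per-muscle ipsi/contra gain
#' mismatch (`subject_asymmetry_cv`) standing in for anatomical asymmetry and
#' electrode-placement differences.
#'
#' @param sampling_rate_hz Sampling rate in Hz. Default 1000.
#' @param trace_duration_s Length of one recorded repetition in seconds
#'   (one tension--relaxation cycle). Default 4.
#' @param tension_duration_s Duration of the tension phase in seconds.
#'   Default 1.
#' @param relaxation_duration_s Duration of the relaxation phase in seconds.
#'   Default 3. Kept for protocol bookkeeping; the tension onset is jittered
#'   within the trace.
#' @param baseline_noise_uv Resting-activity noise standard deviation, uV.
#' @param burst_amplitude_uv Unattenuated burst drive, uV (instantaneous
#'   standard deviation at full tension on a healthy side).
#' @param grade_attenuation Named numeric vector mapping HB grades 1--6 to the
#'   ipsilateral amplitude multiplier; must start at 1 and be non-increasing.
#' @param synkinesis_gain Fraction in `[0, 1)` of one side's drive leaking to
#'   the other side.
#' @param repetition_cv Coefficient of variation of the lognormal amplitude
#'   jitter across the three repetitions.
#' @param subject_asymmetry_cv Coefficient of variation of the lognormal
#'   ipsi/contra gain mismatch drawn once per session and muscle.
#' @param cohort_distribution Named integer vector `c("1" = n1, ...)` giving
#'   the number of labeled measurements per HB grade.
#' @param n_unlabeled Number of measurements emitted with a missing clinical
#'   grade (their assigned truth grade is still recorded).
#' @param unlabeled_truth_grades Truth grades for the unlabeled measurements.
#' @param n_patients Number of patients the measurements are spread over;
#'   sessions are allocated as evenly as possible so that some patients
#'   contribute two and some three sessions.
#' @param poses Character vector of the seven pose labels.
#' @param dropout Optional dropout specification created by
#'   [dropout_spec()]; `NULL` for complete sessions.
#' @param seed Integer seed; identical configurations (including the seed)
#'   generate identical cohorts.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [simulate_cohort()], [dropout_spec()]
#' @examples
#' cfg <- synth_config(seed = 7)
#' cfg$cohort_distribution
#' @export
synth_config <- function(sampling_rate_hz = 1000,
                         trace_duration_s = 4,
                         tension_duration_s = 1,
                         relaxation_duration_s = 3,
                         baseline_noise_uv = 2,
                         burst_amplitude_uv = 100,
                         grade_attenuation = c("1" = 1, "2" = 0.75, "3" = 0.5,
                                               "4" = 0.3, "5" = 0.15, "6" = 0),
                         synkinesis_gain = 0.05,
                         repetition_cv = 0.15,
                         subject_asymmetry_cv = 0.2,
                         cohort_distribution = c("1" = 30, "2" = 17, "3" = 5,
                                                 "4" = 3, "5" = 2, "6" = 0),
                         n_unlabeled = 2,
                         unlabeled_truth_grades = c(1, 2),
                         n_patients = 28,
                         poses = semg_default_poses(),
                         dropout = NULL,
                         seed = 1L) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    trace_duration_s = trace_duration_s,
    tension_duration_s = tension_duration_s,
    relaxation_duration_s = relaxation_duration_s,
    baseline_noise_uv = baseline_noise_uv,
    burst_amplitude_uv = burst_amplitude_uv,
    grade_attenuation = grade_attenuation,
    synkinesis_gain = synkinesis_gain,
    repetition_cv = repetition_cv,
    subject_asymmetry_cv = subject_asymmetry_cv,
    cohort_distribution = cohort_distribution,
    n_unlabeled = n_unlabeled,
    unlabeled_truth_grades = unlabeled_truth_grades,
    n_patients = n_patients,
    poses = poses,
    dropout = dropout,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  num_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  num_pos(cfg$sampling_rate_hz, "sampling_rate_hz")
  num_pos(cfg$trace_duration_s, "trace_duration_s")
  num_pos(cfg$tension_duration_s, "tension_duration_s")
  num_pos(cfg$relaxation_duration_s, "relaxation_duration_s")
  if (cfg$baseline_noise_uv < 0) stop("`baseline_noise_uv` must be >= 0", call. = FALSE)
  num_pos(cfg$burst_amplitude_uv, "burst_amplitude_uv")
  if (cfg$tension_duration_s >= cfg$trace_duration_s) {
    stop("`tension_duration_s` must be shorter than `trace_duration_s`", call. = FALSE)
  }

  ga <- cfg$grade_attenuation
  if (length(ga) != 6 || !identical(names(ga), as.character(1:6))) {
    stop("`grade_attenuation` must be named \"1\"..\"6\"", call. = FALSE)
  }
  if (any(ga < 0 | ga > 1)) stop("`grade_attenuation` values must lie in [0, 1]", call. = FALSE)
  if (ga[["1"]] != 1) stop("`grade_attenuation[\"1\"]` must equal 1 (HB 1 is normal)", call. = FALSE)
  if (any(diff(ga) > 0)) stop("`grade_attenuation` must be non-increasing in grade", call. = FALSE)

  if (cfg$synkinesis_gain < 0 || cfg$synkinesis_gain >= 1) {
    stop("`synkinesis_gain` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$repetition_cv < 0) stop("`repetition_cv` must be >= 0", call. = FALSE)
  if (cfg$subject_asymmetry_cv < 0) stop("`subject_asymmetry_cv` must be >= 0", call. = FALSE)

  cd <- cfg$cohort_distribution
  if (length(cd) == 0) stop("`cohort_distribution` must not be empty", call. = FALSE)
  if (is.null(names(cd)) || !all(names(cd) %in% as.character(1:6))) {
    stop("`cohort_distribution` must be named by HB grades \"1\"..\"6\"", call. = FALSE)
  }
  if (any(cd < 0) || any(cd != round(cd))) {
    stop("`cohort_distribution` counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(cd) + cfg$n_unlabeled < 1) stop("cohort would be empty", call. = FALSE)
  if (cfg$n_unlabeled < 0 || cfg$n_unlabeled != round(cfg$n_unlabeled)) {
    stop("`n_unlabeled` must be a nonnegative integer", call. = FALSE)
  }
  if (cfg$n_unlabeled > 0) {
    tg <- cfg$unlabeled_truth_grades
    if (length(tg) != cfg$n_unlabeled || !all(tg %in% 1:6)) {
      stop("`unlabeled_truth_grades` must supply one HB grade (1-6) per unlabeled measurement",
           call. = FALSE)
    }
  }
  if (cfg$n_patients < 1 || cfg$n_patients != round(cfg$n_patients)) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (length(cfg$poses) < 1 || anyDuplicated(cfg$poses)) {
    stop("`poses` must be a non-empty vector of unique labels", call. = FALSE)
  }
  if (!is.null(cfg$dropout) && !inherits(cfg$dropout, "semg_dropout")) {
    stop("`dropout` must be NULL or created by dropout_spec()", call. = FALSE)
  }
  cfg
}

#' Describe session dropouts
#'
#' Emulates incomplete sessions: poses a patient could not perform at all
#' (`missing_poses`: no repetitions recorded on either side) and poses
#' accomplished only once instead of three times (`single_rep_poses`).
#' Dropouts are applied to the configured sessions (all, or those named in
#' `measurement_ids`) and recorded explicitly in the trace table.
#'
#' @param missing_poses Character vector of pose labels fully absent.
#' @param single_rep_poses Character vector of pose labels with only the
#'   first repetition retained.
#' @param measurement_ids Optional measurement ids the rule applies to;
#'   `NULL` applies it to the first session of the cohort.
#' @return An object of class `semg_dropout`.
#' @export
dropout_spec <- function(missing_poses = character(),
                         single_rep_poses = character(),
                         measurement_ids = NULL) {
  structure(
    list(missing_poses = missing_poses,
         single_rep_poses = single_rep_poses,
         measurement_ids = measurement_ids),
    class = "semg_dropout"
  )
}

#' @method print synth_config
#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  sampling rate:", x$sampling_rate_hz, "Hz, trace", x$trace_duration_s,
      "s (tension", x$tension_duration_s, "s)\n")
  cat("  burst", x$burst_amplitude_uv, "uV over baseline", x$baseline_noise_uv, "uV\n")
  cat("  attenuation:", paste(sprintf("HB%s=%.2f", names(x$grade_attenuation),
                                      x$grade_attenuation), collapse = " "), "\n")
  cat("  noise: repetition CV", x$repetition_cv, ", asymmetry CV",
      x$subject_asymmetry_cv, ", synkinesis", x$synkinesis_gain, "\n")
  cat("  cohort:", sum(x$cohort_distribution), "labeled +", x$n_unlabeled,
      "unlabeled over", x$n_patients, "patients; seed", x$seed, "\n")
  invisible(x)
}
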