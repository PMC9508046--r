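# Synthetic bilateral facial sEMG cohorts.
#
# Signal model: unit-variance band-limited Gaussian noise whose instantaneous
# standard deviation follows sigma(t) = baseline + amplitude * trapezoid(t).
# The 95th-percentile envelope amplitude extracted downstream is then
# proportional to (baseline + amplitude), so grade attenuation of the burst
# drive propagates monotonically into the lateralization index.

# lognormal multiplier with unit mean and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# band-pass Butterworth carrier, cached per sampling rate
bandlimited_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  if (fs < 100 || n < 24) return(x / stats::sd(x))
  hi <- min(450, 0.45 * fs)
  bf <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
  z <- signal::filtfilt(bf, x)
  z / stats::sd(z)
}

# trapezoidal tension envelope in [0, 1]; ramps are 10% of the tension time
tension_envelope <- function(n, fs, onset_s, tension_s) {
  t <- (seq_len(n) - 1) / fs
  ramp <- 0.1 * tension_s
  up <- pmin(pmax((t - onset_s) / ramp, 0), 1)
  down <- pmin(pmax((onset_s + tension_s - t) / ramp, 0), 1)
  pmin(up, down)
}

check_hb <- function(hb) {
  if (length(hb) != 1 || is.na(hb) || !(hb %in% 1:6)) {
    stop("HB grade must be a single integer in 1..6, got: ",
         paste(hb, collapse = ","), call. = FALSE)
  }
  as.integer(hb)
}

# burst drive per side, uV: grade attenuation on the ipsilateral side plus
# synkinetic leakage of each side's drive onto the other
drive_amplitude <- function(side, hb, cfg, ipsi_gain = 1) {
  a <- unname(cfg$grade_attenuation[as.character(hb)])
  g <- cfg$synkinesis_gain
  A <- cfg$burst_amplitude_uv
  switch(side,
    ipsi   = ipsi_gain * (A * a + g * A),
    contra = A + g * A * a,
    stop("`side` must be \"ipsi\" or \"contra\"", call. = FALSE)
  )
}

#' Simulate one sEMG trace
#'
#' Generates one repetition of one channel: zero-mean band-limited noise with
#' a trapezoidal tension burst. On the ipsilateral side the burst drive is
#' multiplied by the configured grade attenuation; each side also receives the
#' synkinetic leakage fraction of the opposite drive. Consumes the global RNG
#' stream; seed at the call site (the cohort generator seeds once per cohort).
#'
#' @param pose Pose label.
#' @param side `"ipsi"` or `"contra"` (relative to the operated side).
#' @param hb HB grade 1--6 driving the attenuation.
#' @param cfg A [synth_config()].
#' @param muscle Muscle label (metadata only).
#' @param repetition Repetition number (metadata only).
#' @param ipsi_gain Multiplicative gain applied to the ipsilateral channel
#'   (per-session anatomical/electrode asymmetry); drawn by
#'   [simulate_session()].
#' @param onset_s Tension onset in seconds; `NULL` draws it uniformly so the
#'   burst lies fully inside the trace.
#' @return One-row tibble with columns `muscle`, `side`, `pose`, `repetition`,
#'   `fs` and a list-column `samples` (uV).
#' @examples
#' cfg <- synth_config(sampling_rate_hz = 250, trace_duration_s = 2,
#'                     tension_duration_s = 0.8, relaxation_duration_s = 1.2)
#' tr <- withr::with_seed(1, simulate_trace("smile", "ipsi", 3, cfg))
#' length(tr$samples[[1]])
#' @export
simulate_trace <- function(pose, side, hb, cfg, muscle = "nasalis",
                           repetition = 1L, ipsi_gain = 1, onset_s = NULL) {
  cfg <- validate_synth_config(cfg)
  hb <- check_hb(hb)
  side <- match.arg(side, c("ipsi", "contra"))
  n <- round(cfg$trace_duration_s * cfg$sampling_rate_hz)
  if (is.null(onset_s)) {
    pad <- 0.05 * cfg$trace_duration_s
    onset_s <- runif(1, pad, cfg$trace_duration_s - cfg$tension_duration_s - pad)
  }
  amp <- drive_amplitude(side, hb, cfg, ipsi_gain) * rlnorm_cv(1, cfg$repetition_cv)
  env <- tension_envelope(n, cfg$sampling_rate_hz, onset_s, cfg$tension_duration_s)
  sigma <- cfg$baseline_noise_uv + amp * env
  samples <- sigma * bandlimited_noise(n, cfg$sampling_rate_hz)
  tibble::tibble(
    muscle = muscle, side = side, pose = pose,
    repetition = as.integer(repetition),
    fs = cfg$sampling_rate_hz, samples = list(samples)
  )
}

# which repetitions of a pose survive this session's dropout rule
dropout_reps <- function(pose, measurement_id, cfg, first_measurement_id) {
  d <- cfg$dropout
  if (is.null(d)) return(1:3)
  applies <- if (is.null(d$measurement_ids)) {
    measurement_id == first_measurement_id
  } else {
    measurement_id %in% d$measurement_ids
  }
  if (!applies) return(1:3)
  if (pose %in% d$missing_poses) return(integer(0))
  if (pose %in% d$single_rep_poses) return(1L)
  1:3
}

#' Simulate one measurement session
#'
#' One patient visit: 3 muscles x 2 sides x 7 poses x 3 repetitions = 126
#' traces, minus any configured dropouts. The tension onset is shared across
#' the six channels of one repetition (the patient tenses all muscles at
#' once); the ipsi/contra gain mismatch is drawn once per muscle and session.
#'
#' @param patient_id,measurement_id,timepoint Session metadata.
#' @param hb True HB grade 1--6 used to drive the simulation.
#' @param operated_side `"left"` or `"right"` (metadata; `"ipsi"` always
#'   refers to this side).
#' @param cfg A [synth_config()].
#' @param hb_observed Clinically recorded grade; defaults to `hb`, `NA` for
#'   sessions emitted as unlabeled.
#' @param first_measurement_id Used to resolve a [dropout_spec()] with no
#'   explicit measurement ids; defaults to this session's id.
#' @return Tibble of traces with session metadata, `hb` (observed, possibly
#'   `NA`) and `hb_true`, plus an attribute `"dropouts"` listing applied
#'   dropout rules.
#' @export
simulate_session <- function(patient_id, measurement_id, timepoint, hb,
                             operated_side, cfg, hb_observed = hb,
                             first_measurement_id = measurement_id) {
  cfg <- validate_synth_config(cfg)
  hb <- check_hb(hb)
  muscles <- semg_muscles()
  gains <- setNames(rlnorm_cv(length(muscles), cfg$subject_asymmetry_cv), muscles)

  rows <- list()
  dropped <- list()
  for (pose in cfg$poses) {
    reps <- dropout_reps(pose, measurement_id, cfg, first_measurement_id)
    if (length(reps) < 3) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        measurement_id = measurement_id, pose = pose,
        rule = if (length(reps) == 0) "missing_pose" else "single_repetition",
        repetitions_kept = length(reps)
      )
    }
    for (rep in reps) {
      pad <- 0.05 * cfg$trace_duration_s
      onset <- runif(1, pad, cfg$trace_duration_s - cfg$tension_duration_s - pad)
      for (m in muscles) {
        for (s in c("ipsi", "contra")) {
          rows[[length(rows) + 1]] <- simulate_trace(
            pose, s, hb, cfg, muscle = m, repetition = rep,
            ipsi_gain = gains[[m]], onset_s = onset
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  hb_obs <- if (is.na(hb_observed)) NA_integer_ else as.integer(hb_observed)
  hb_truth <- hb
  out <- tibble::add_column(
    out,
    measurement_id = measurement_id, patient_id = patient_id,
    timepoint = timepoint, operated_side = operated_side,
    hb = hb_obs, hb_true = hb_truth,
    .before = 1
  )
  attr(out, "dropouts") <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(measurement_id = character(), pose = character(),
                   rule = character(), repetitions_kept = integer())
  out
}

# spread n sessions as evenly as possible over patients (some get one extra)
allocate_sessions <- function(n_sessions, n_patients) {
  n_patients <- min(n_patients, n_sessions)
  counts <- rep(n_sessions %/% n_patients, n_patients)
  extra <- n_sessions %% n_patients
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}

session_timepoints <- function(k) {
  base <- c("preop", "postop", "followup")
  if (k <= 3) head(base, k) else c(base, paste0("followup_", seq_len(k - 3) + 1))
}

#' Simulate a full synthetic cohort
#'
#' Generates the configured number of measurements per HB grade (default: the
#' emulated 59-measurement perioperative cohort, 30/17/5/3/2 for grades 1--5
#' plus two unlabeled), spread over patients so that most contribute two
#' sessions (preop/postop) and some a third (follow-up). The operated side is
#' fixed per patient; assigned grades are shuffled over session slots.
#' Fully deterministic given the configuration seed.
#'
#' @param cfg A [synth_config()].
#' @return Tibble of traces (one row per channel x pose x repetition) with
#'   metadata columns; attributes `"config"` and `"dropouts"`. The column
#'   `hb_true` records the assigned grade for every session including the
#'   unlabeled ones; `hb` is the observed clinical label (`NA` if missing).
#' @seealso [cohort_labels()], [process_traces()]
#' @examples
#' cfg <- synth_config(cohort_distribution = c("1" = 2, "3" = 2),
#'                     n_unlabeled = 0, n_patients = 2,
#'                     sampling_rate_hz = 200, trace_duration_s = 2,
#'                     tension_duration_s = 0.8, relaxation_duration_s = 1.2)
#' traces <- simulate_cohort(cfg)
#' dplyr::n_distinct(traces$measurement_id)
#' @export
simulate_cohort <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  withr::with_seed(cfg$seed, {
    cd <- cfg$cohort_distribution
    slots <- tibble::tibble(
      hb_true = c(rep(as.integer(names(cd)), cd),
                  as.integer(head(cfg$unlabeled_truth_grades, cfg$n_unlabeled))),
      labeled = rep(c(TRUE, FALSE), c(sum(cd), cfg$n_unlabeled))
    )
    n <- nrow(slots)
    if (n == 0) stop("cohort_distribution yields an empty cohort", call. = FALSE)
    slots <- slots[sample.int(n), ]

    counts <- allocate_sessions(n, cfg$n_patients)
    patients <- tibble::tibble(
      patient_id = sprintf("P%02d", seq_along(counts)),
      operated_side = sample(c("left", "right"), length(counts), replace = TRUE),
      n_sessions = counts
    )
    meta <- tidyr::unnest(
      dplyr::mutate(patients,
                    timepoint = purrr::map(.data$n_sessions, session_timepoints)),
      "timepoint"
    )
    meta$measurement_id <- sprintf("M%03d", seq_len(nrow(meta)))
    meta$hb_true <- slots$hb_true
    meta$hb <- ifelse(slots$labeled, slots$hb_true, NA_integer_)

    first_id <- meta$measurement_id[[1]]
    sessions <- purrr::pmap(
      meta[, c("patient_id", "measurement_id", "timepoint", "operated_side",
               "hb_true", "hb")],
      function(patient_id, measurement_id, timepoint, operated_side, hb_true, hb) {
        simulate_session(patient_id, measurement_id, timepoint, hb_true,
                         operated_side, cfg, hb_observed = hb,
                         first_measurement_id = first_id)
      }
    )
    out <- dplyr::bind_rows(sessions)
    attr(out, "config") <- cfg
    attr(out, "dropouts") <- dplyr::bind_rows(purrr::map(sessions, attr, "dropouts"))
    out
  })
}

#' Session-level metadata of a trace table
#'
#' @param traces Trace tibble from [simulate_cohort()] or [read_cohort_csv()].
#' @return One row per measurement: `patient_id`, `measurement_id`,
#'   `timepoint`, `operated_side`, `hb` (and `hb_true` when present).
#' @export
cohort_labels <- function(traces) {
  cols <- intersect(
    c("patient_id", "measurement_id", "timepoint", "operated_side", "hb", "hb_true"),
    names(traces)
  )
  dplyr::distinct(traces[, cols])
}

#' Write / read a cohort as long-format CSV
#'
#' `write_cohort_csv()` writes `labels.csv` (one row per measurement) and
#' `signals.csv` (long format: `measurement_id, channel, side, pose,
#' repetition, sample_index, value_uv`). The signal file grows large for full
#' cohorts at 1000 Hz; prefer in-memory pipelines for simulation studies.
#' `read_cohort_csv()` restores the nested trace tibble.
#'
#' @param traces Trace tibble.
#' @param dir Output (input) directory.
#' @param fs Sampling rate to attach on read, Hz (stored per trace on write).
#' @return `write_cohort_csv()` the directory invisibly; `read_cohort_csv()`
#'   a trace tibble.
#' @export
write_cohort_csv <- function(traces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort_labels(traces), file.path(dir, "labels.csv"), na = "")
  long <- tidyr::unnest(
    dplyr::mutate(
      traces[, c("measurement_id", "muscle", "side", "pose", "repetition",
                 "fs", "samples")],
      sample_index = purrr::map(.data$samples, seq_along)
    ),
    c("samples", "sample_index")
  )
  long <- dplyr::rename(long, channel = "muscle", value_uv = "samples")
  readr::write_csv(
    long[, c("measurement_id", "channel", "side", "pose", "repetition",
             "fs", "sample_index", "value_uv")],
    file.path(dir, "signals.csv")
  )
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir, fs = NULL) {
  labels_path <- file.path(dir, "labels.csv")
  signals_path <- file.path(dir, "signals.csv")
  if (!file.exists(labels_path) || !file.exists(signals_path)) {
    stop("`", dir, "` does not contain labels.csv and signals.csv", call. = FALSE)
  }
  labels <- readr::read_csv(labels_path, show_col_types = FALSE)
  long <- readr::read_csv(signals_path, show_col_types = FALSE)
  if (is.null(long$fs)) {
    if (is.null(fs)) stop("signals.csv lacks an `fs` column; supply `fs`", call. = FALSE)
    long$fs <- fs
  }
  long <- dplyr::arrange(long, .data$measurement_id, .data$channel, .data$side,
                         .data$pose, .data$repetition, .data$sample_index)
  nested <- dplyr::summarise(
    dplyr::group_by(long, .data$measurement_id, .data$channel, .data$side,
                    .data$pose, .data$repetition, .data$fs),
    samples = list(.data$value_uv), .groups = "drop"
  )
  nested <- dplyr::rename(nested, muscle = "channel")
  out <- dplyr::left_join(nested, labels, by = "measurement_id")
  front <- intersect(
    c("measurement_id", "patient_id", "timepoint", "operated_side", "hb",
      "hb_true"), names(out)
  )
  dplyr::relocate(out, dplyr::all_of(front))
}
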