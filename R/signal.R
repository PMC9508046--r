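# Envelope extraction: rectification, running-average smoothing, selection of
# the 500 ms maximum-activity epoch, 95th-percentile amplitude.

window_samples <- function(window_ms, fs) {
  max(1L, as.integer(round(window_ms * fs / 1000)))
}

#' Full-wave rectification
#'
#' Replaces every sample by its absolute value. Idempotent.
#'
#' @param x Numeric vector of samples (uV).
#' @return Numeric vector, same length.
#' @export
rectify <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  abs(x)
}

#' Centered running-average smoothing
#'
#' Centered moving average with truncated windows at the edges (the average
#' runs over the samples actually available, so constants map to constants and
#' no zero-padding bias is introduced). For an even window length the extra
#' sample lies to the right of the center.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate, Hz.
#' @param window_ms Smoothing window, milliseconds (default 100). Converted to
#'   `round(window_ms * fs / 1000)` samples, minimum 1.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_running_average <- function(x, fs, window_ms = 100) {
  if (!is.numeric(x) || length(x) == 0) stop("`x` must be a nonempty numeric vector", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  w <- window_samples(window_ms, fs)
  n <- length(x)
  if (w > n) stop("smoothing window (", w, " samples) exceeds trace length (", n, ")", call. = FALSE)
  if (w == 1L) return(x)
  hl <- (w - 1L) %/% 2L          # samples to the left of center
  hr <- w - 1L - hl              # samples to the right
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Select the maximum-activity epoch
#'
#' Finds the contiguous epoch (default 500 ms) maximizing the mean of the
#' smoothed rectified signal — the automated counterpart of manually picking
#' the epoch containing the maximum amplitudes of a movement. Ties are broken
#' by the earliest start.
#'
#' @param x Numeric vector: the rectified, smoothed trace.
#' @param fs Sampling rate, Hz.
#' @param epoch_ms Epoch length, milliseconds (default 500).
#' @return Epoch start offset in seconds (0 = first sample).
#' @export
select_epoch <- function(x, fs, epoch_ms = 500) {
  if (!is.numeric(x) || length(x) == 0) stop("`x` must be a nonempty numeric vector", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  w <- window_samples(epoch_ms, fs)
  n <- length(x)
  if (w > n) stop("epoch (", w, " samples) exceeds trace length (", n, ")", call. = FALSE)
  cs <- c(0, cumsum(x))
  sums <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  (which.max(sums) - 1L) / fs
}

#' 95th-percentile envelope amplitude
#'
#' The single amplitude summarizing one epoch: the 95th percentile of the
#' smoothed rectified samples, with linear interpolation between order
#' statistics (type 7 quantile).
#'
#' @param x Nonempty numeric vector of nonnegative (rectified) samples.
#' @return Amplitude in the units of `x`.
#' @export
amplitude_95 <- function(x) {
  if (length(x) == 0) stop("`x` must be nonempty", call. = FALSE)
  if (any(is.na(x))) stop("`x` contains NA", call. = FALSE)
  if (any(x < 0)) stop("`x` must be nonnegative (rectify first)", call. = FALSE)
  unname(quantile(x, 0.95, type = 7))
}

# full chain for one trace; manual_start_s overrides the automatic epoch
envelope_amplitude <- function(samples, fs, window_ms, epoch_ms,
                               manual_start_s = NA_real_) {
  sm <- smooth_running_average(rectify(samples), fs, window_ms)
  w <- window_samples(epoch_ms, fs)
  if (is.na(manual_start_s)) {
    start_s <- select_epoch(sm, fs, epoch_ms)
  } else {
    start_s <- manual_start_s
    first <- as.integer(round(start_s * fs)) + 1L
    if (first < 1L || first + w - 1L > length(sm)) {
      stop("manual epoch start ", start_s, " s out of range", call. = FALSE)
    }
  }
  first <- as.integer(round(start_s * fs)) + 1L
  list(amplitude_uv = amplitude_95(sm[first:(first + w - 1L)]),
       epoch_start_s = start_s)
}

#' Extract envelope amplitudes from a trace table
#'
#' Applies the full processing chain — rectification, running-average
#' smoothing, maximum-activity epoch selection, 95th percentile — to every
#' trace, yielding one amplitude per channel x pose x repetition. Manually
#' selected epochs (the original manual workflow) can be supplied per trace
#' and take precedence over automatic selection; traces absent from the input
#' simply produce no record and are handled by downstream imputation.
#'
#' @param traces Trace tibble with columns `measurement_id`, `muscle`, `side`,
#'   `pose`, `repetition`, `fs`, `samples` (list-column of numeric vectors).
#' @param window_ms Smoothing window, ms.
#' @param epoch_ms Epoch length, ms.
#' @param manual_epochs Optional tibble with columns `measurement_id`,
#'   `muscle`, `side`, `pose`, `repetition`, `epoch_start_s` overriding the
#'   automatic epoch for the listed traces. An out-of-range start is an error
#'   naming the trace.
#' @return Tibble: `measurement_id`, `muscle`, `side`, `pose`, `repetition`,
#'   `amplitude_uv`, `epoch_start_s`.
#' @examples
#' cfg <- synth_config(cohort_distribution = c("1" = 1), n_unlabeled = 0,
#'                     n_patients = 1, sampling_rate_hz = 200,
#'                     trace_duration_s = 2, tension_duration_s = 0.8,
#'                     relaxation_duration_s = 1.2)
#' amps <- process_traces(simulate_cohort(cfg))
#' nrow(amps)  # 3 muscles x 2 sides x 7 poses x 3 repetitions
#' @export
process_traces <- function(traces, window_ms = 100, epoch_ms = 500,
                           manual_epochs = NULL) {
  needed <- c("measurement_id", "muscle", "side", "pose", "repetition", "fs", "samples")
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols)) {
    stop("`traces` lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- traces[, setdiff(needed, "samples")]
  out$.manual <- NA_real_
  if (!is.null(manual_epochs)) {
    key <- c("measurement_id", "muscle", "side", "pose", "repetition")
    me <- dplyr::rename(manual_epochs[, c(key, "epoch_start_s")],
                        .manual_in = "epoch_start_s")
    out <- dplyr::left_join(out, me, by = key)
    out$.manual <- out$.manual_in
    out$.manual_in <- NULL
  }
  res <- purrr::pmap(
    list(traces$samples, traces$fs, out$.manual,
         traces$measurement_id, traces$muscle, traces$side, traces$pose,
         traces$repetition),
    function(samples, fs, manual, mid, muscle, side, pose, rep) {
      tryCatch(
        envelope_amplitude(samples, fs, window_ms, epoch_ms, manual),
        error = function(e) {
          stop("trace ", mid, "/", muscle, "/", side, "/", pose, "/rep", rep,
               ": ", conditionMessage(e), call. = FALSE)
        }
      )
    }
  )
  out$amplitude_uv <- purrr::map_dbl(res, "amplitude_uv")
  out$epoch_start_s <- purrr::map_dbl(res, "epoch_start_s")
  out$.manual <- NULL
  out$fs <- NULL
  tibble::as_tibble(out)
}

#' Write / read amplitude records
#'
#' @param amplitudes Amplitude tibble from [process_traces()].
#' @param path CSV path.
#' @return The path (write) or the amplitude tibble (read).
#' @export
write_amplitudes_csv <- function(amplitudes, path) {
  readr::write_csv(amplitudes, path)
  invisible(path)
}

#' @rdname write_amplitudes_csv
#' @export
read_amplitudes_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(repetition = readr::col_integer()))
}
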