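# Shared fixtures (cached: simulation is the slow part of the suite).

fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1L) {
  key <- paste(name, seed, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- make_fixture(name, seed = seed)
  }
  fixture_cache[[key]]
}

# quiet synth_config for small, fast cohorts
small_synth_config <- function(...) {
  synth_config(sampling_rate_hz = 200, trace_duration_s = 2,
               tension_duration_s = 0.8, relaxation_duration_s = 1.2, ...)
}

# amplitude record constructor for hand-built feature inputs
amp_tbl <- function(measurement_id, muscle, pose, repetition, side, amplitude_uv) {
  tibble::tibble(
    measurement_id = measurement_id, muscle = muscle, pose = pose,
    repetition = as.integer(repetition), side = side,
    amplitude_uv = amplitude_uv, epoch_start_s = 0
  )
}

# one-measurement labels table
lbl_tbl <- function(measurement_id, patient_id = "P01", hb = 1L) {
  tibble::tibble(measurement_id = measurement_id, patient_id = patient_id,
                 hb = as.integer(hb))
}

# prediction tibble with class attribute, for metric tests
pred_tbl <- function(true, prob, lev = colnames(prob)) {
  stopifnot(!is.null(lev))
  out <- tibble::tibble(
    measurement_id = sprintf("M%03d", seq_along(true)),
    patient_id = sprintf("P%03d", seq_along(true)),
    true = factor(true, levels = lev),
    predicted = factor(lev[apply(prob, 1, which.max)], levels = lev)
  )
  colnames(prob) <- paste0("p_", lev)
  out <- dplyr::bind_cols(out, tibble::as_tibble(prob))
  attr(out, "classes") <- lev
  out
}
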