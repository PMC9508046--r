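test_that("lateralization index matches its defining ratio and boundary values", {
  expect_equal(lateralization_index(5, 5), 0)
  expect_equal(lateralization_index(3, 0), 1)     # activity only ipsilateral
  expect_equal(lateralization_index(0, 7), -1)    # activity only contralateral
  expect_equal(lateralization_index(3, 1), 0.5)
  expect_equal(lateralization_index(0, 0), 0)     # degenerate case defined as 0
  expect_error(lateralization_index(-1, 2), "nonnegative")
  expect_error(lateralization_index(1, NA), "NA")
  withr::with_seed(61, {
    i <- runif(100, 0, 50); c <- runif(100, 0, 50)
    li <- lateralization_index(i, c)
    expect_true(all(li >= -1 & li <= 1))
    expect_equal(lateralization_index(c, i), -li)  # antisymmetry
  })
})

test_that("features average the per-repetition indices and flag partial poses", {
  # repetition LIs 0.2, 0.4, 0.6 -> feature 0.4
  poses <- semg_default_poses()
  base <- tidyr::expand_grid(muscle = semg_muscles(), pose = poses,
                             repetition = 1:3, side = c("ipsi", "contra"))
  base$amplitude_uv <- ifelse(base$side == "ipsi", 1, 1)
  base$amplitude_uv[base$muscle == "nasalis" & base$pose == "smile" & base$side == "ipsi"] <-
    c(1.5, 7, 4)[base$repetition[base$muscle == "nasalis" & base$pose == "smile" & base$side == "ipsi"]]
  base$amplitude_uv[base$muscle == "nasalis" & base$pose == "smile" & base$side == "contra"] <-
    c(1, 3, 1)[base$repetition[base$muscle == "nasalis" & base$pose == "smile" & base$side == "contra"]]
  amps <- amp_tbl("M1", base$muscle, base$pose, base$repetition, base$side,
                  base$amplitude_uv)
  f <- build_features(amps, lbl_tbl("M1"), poses = poses)
  expect_equal(f$li_nasalis_smile, 0.4)
  expect_equal(f$imp_nasalis_smile, "none")
  expect_equal(ncol(f[grep("^li_", names(f))]), 21)

  # a pose with a single usable repetition keeps that LI, flagged
  amps1 <- dplyr::filter(amps, !(muscle == "nasalis" & pose == "smile" &
                                   repetition > 1))
  f1 <- build_features(amps1, lbl_tbl("M1"), poses = poses)
  expect_equal(f1$li_nasalis_smile, 0.2)
  expect_equal(f1$imp_nasalis_smile, "partial_repetitions")

  # an unpaired repetition (one side missing) is dropped from the average
  amps2 <- dplyr::filter(amps, !(muscle == "nasalis" & pose == "smile" &
                                   repetition == 3 & side == "contra"))
  f2 <- build_features(amps2, lbl_tbl("M1"), poses = poses)
  expect_equal(f2$li_nasalis_smile, 0.3)
  expect_equal(f2$imp_nasalis_smile, "partial_repetitions")
})

test_that("whole-movement gaps are imputed from the muscle's other poses", {
  poses <- paste0("pose", 1:7)
  lis <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)           # pose7 missing -> 0.35
  grid <- tidyr::expand_grid(muscle = semg_muscles(), pose = poses[1:6],
                             repetition = 1:3)
  # per-muscle LI values; only the first muscle carries the 0.1..0.6 pattern
  li_of <- function(muscle, pose) {
    v <- lis[match(pose, poses[1:6])]
    ifelse(muscle == "orbicularis_oculi", v, 0)
  }
  target <- li_of(grid$muscle, grid$pose)
  ipsi <- 1 + target; contra <- 1 - target          # LI(1+v, 1-v) = v
  amps <- dplyr::bind_rows(
    amp_tbl("M1", grid$muscle, grid$pose, grid$repetition, "ipsi", ipsi),
    amp_tbl("M1", grid$muscle, grid$pose, grid$repetition, "contra", contra)
  )
  f <- build_features(amps, lbl_tbl("M1"), poses = poses)
  expect_equal(f$li_orbicularis_oculi_pose7, 0.35)
  expect_equal(f$imp_orbicularis_oculi_pose7, "whole_movement")
  # imputation stays inside the muscle's observed range
  expect_gte(f$li_orbicularis_oculi_pose7, 0.1)
  expect_lte(f$li_orbicularis_oculi_pose7, 0.6)

  # without gaps impute_missing is the identity
  long <- tibble::tibble(measurement_id = "M1",
                         muscle = rep(semg_muscles(), each = 2),
                         pose = rep(c("a", "b"), 3),
                         li = runif(6, -1, 1), imputed = "none")
  expect_equal(impute_missing(long), long)

  # a muscle with no observed pose at all cannot be imputed
  long$li[long$muscle == "nasalis"] <- NA
  expect_error(impute_missing(long), "cannot impute.*nasalis")
})

test_that("feature building is antisymmetric under side swap and scale invariant", {
  traces <- cached_fixture("dropouts")
  labels <- cohort_labels(traces)
  amps <- process_traces(traces)
  f <- build_features(amps, labels)

  swapped <- amps
  swapped$side <- ifelse(amps$side == "ipsi", "contra", "ipsi")
  f_swap <- build_features(swapped, labels)
  li <- as.matrix(f[, feature_cols(f)])
  li_swap <- as.matrix(f_swap[, feature_cols(f_swap)])
  expect_equal(li_swap, -li)

  scaled <- amps
  scaled$amplitude_uv <- amps$amplitude_uv * 17.3
  f_scaled <- build_features(scaled, labels)
  expect_equal(as.matrix(f_scaled[, feature_cols(f_scaled)]), li)

  expect_true(all(li >= -1 & li <= 1))
  expect_equal(length(feature_cols(f)), 21)
})

test_that("a measurement with no usable pair is rejected", {
  amps <- amp_tbl("M1", "nasalis", "smile", 1:3, "ipsi", c(1, 2, 3))
  expect_error(build_features(amps, lbl_tbl("M1")), "no usable ipsi/contra pair")
})

test_that("feature tables survive the CSV round trip", {
  traces <- cached_fixture("dropouts")
  f <- build_features(process_traces(traces), cohort_labels(traces))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(f, path)
  f2 <- read_features_csv(path)
  expect_equal(as.data.frame(f2[, names(f)]), as.data.frame(f))
  expect_equal(feature_cols(f2), feature_cols(f))
})
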