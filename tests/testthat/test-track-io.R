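cfg_list <- list(fps = 10000, scale_mm_per_px = 0.005,
                 cheliceral_length_mm = 0.46, sex = "F")

write_track_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

base_rows <- function(side = "L", frames = seq(0, 40, by = 4)) {
  data.frame(
    specimen_id = "P1", strike_id = "A", side = side,
    frame_index = frames, time_s = frames / 10000,
    x_px = seq_along(frames), y_px = rev(seq_along(frames))
  )
}

test_that("a well-formed two-chelicera file yields two validated tracks", {
  path <- write_track_csv(rbind(base_rows("L"), base_rows("R")))
  tracks <- read_tracks(path, cfg_list)
  expect_length(tracks, 2L)
  expect_named(tracks, c("P1/A/L", "P1/A/R"))
  expect_s3_class(tracks[[1]], "tracked_strike")
  # stride-4 digitization: times are 0, 4/fps, 8/fps, ...
  expect_equal(tracks[[1]]$times, seq(0, 40, by = 4) / 10000)
})

test_that("malformed track files raise classified errors", {
  rows <- base_rows()
  rows$frame_index[3] <- rows$frame_index[2] # duplicate
  rows$time_s <- rows$frame_index / 10000
  expect_error(read_tracks(write_track_csv(rows), cfg_list),
               "duplicated frame_index 4")

  expect_error(read_tracks(write_track_csv(base_rows()[, -6]), cfg_list),
               "missing column.*x_px")

  rows <- base_rows()
  rows$side[2] <- "X"
  expect_error(read_tracks(write_track_csv(rows), cfg_list),
               "unknown side code 'X' at row 2")

  expect_error(
    read_tracks(write_track_csv(base_rows(frames = c(0, 4, 8, 12, 16))),
                cfg_list),
    "at least 6"
  )

  rows <- base_rows()
  rows$time_s[4] <- rows$time_s[4] + 1e-6 # inconsistent with frame/fps
  expect_error(read_tracks(write_track_csv(rows), cfg_list),
               "inconsistent with frame_index/fps")

  expect_error(read_tracks(write_track_csv(base_rows()),
                           list(fps = 10000)),
               "config is missing")
})

test_that("calibration scales pixels to mm and refuses to run twice", {
  mk <- function(scale) {
    tracked_strike("P1", "A", "L", frame_index = 0:5,
                   x_px = c(100, 1, 2, 3, 4, 5), y_px = rep(0, 6),
                   fps = 1000, scale_mm_per_px = scale,
                   cheliceral_length_mm = 0.46)
  }
  ident <- calibrate(mk(1))
  expect_equal(ident$x_mm, c(100, 1, 2, 3, 4, 5))
  scaled <- calibrate(mk(0.01))
  expect_equal(scaled$x_mm[1], 1.0)
  expect_equal(scaled$y_mm[1], 0.0)
  expect_error(calibrate(scaled), "already calibrated")
  broken <- mk(1)
  broken$scale_mm_per_px <- -1 # corrupted after construction
  expect_error(calibrate(broken), "scale")
})

test_that("drift removal subtracts the reference frame-wise", {
  sim <- simulate_strike(strike_sim_config(noise_px = 0, digitize_every = 1))
  tr <- sim$tracks$L
  const_ref <- tracked_strike("P1", tr$strike_id, "body", tr$frame_index,
                              x_px = rep(7, length(tr$times)),
                              y_px = rep(-3, length(tr$times)),
                              fps = tr$fps, scale_mm_per_px = tr$scale_mm_per_px,
                              cheliceral_length_mm = tr$cheliceral_length_mm)
  shifted <- remove_drift(tr, const_ref)
  expect_equal(shifted$x_px, tr$x_px - 7)
  expect_equal(shifted$y_px, tr$y_px + 3)

  zeroed <- remove_drift(tr, tr)
  expect_true(all(zeroed$x_px == 0) && all(zeroed$y_px == 0))

  bad_ref <- tracked_strike("P1", tr$strike_id, "body",
                            tr$frame_index[-1], x_px = tr$x_px[-1],
                            y_px = tr$y_px[-1], fps = tr$fps,
                            scale_mm_per_px = tr$scale_mm_per_px,
                            cheliceral_length_mm = tr$cheliceral_length_mm)
  expect_error(remove_drift(tr, bad_ref), "times do not match")
})

test_that("removing a simulated lunge recovers the drift-free arc length", {
  cfg_drift <- strike_sim_config(noise_px = 0, digitize_every = 1,
                                 drift_mm_per_s = c(5, 0), seed = 2)
  cfg_still <- strike_sim_config(noise_px = 0, digitize_every = 1,
                                 drift_mm_per_s = c(0, 0), seed = 2)
  drifted <- simulate_strike(cfg_drift)
  still <- simulate_strike(cfg_still)
  corrected <- remove_drift(drifted$tracks$L, drifted$reference)
  s_corr <- max(cumulative_arc_length(calibrate(corrected))$s_mm)
  s_still <- max(cumulative_arc_length(calibrate(still$tracks$L))$s_mm)
  expect_equal(s_corr, s_still, tolerance = 1e-10)
  # and uncorrected drift really does distort the arc
  s_drift <- max(cumulative_arc_length(calibrate(drifted$tracks$L))$s_mm)
  expect_gt(abs(s_drift - s_still) / s_still, 0.001)
})

test_that("scale inference from the arc radius recovers the calibration", {
  cfg <- strike_sim_config(noise_px = 0, digitize_every = 1,
                           scale_mm_per_px = 0.0042)
  sim <- simulate_strike(cfg)
  expect_equal(infer_scale(sim$tracks$L), 0.0042, tolerance = 1e-6)
})

test_that("results CSV carries unit comments and reads back", {
  df <- data.frame(P_W = 1.5, O_W_per_kg = 2.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(df, path, units = c(P_W = "watts", O_W_per_kg = "W/kg"))
  lines <- readLines(path)
  expect_match(lines[1], "^# P_W: watts")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$O_W_per_kg, 2.5)
})
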