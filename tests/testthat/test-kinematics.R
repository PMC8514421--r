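test_that("chord-sum displacement handles degenerate and exact cases", {
  same <- traj_mm(rep(2, 6), rep(3, 6))
  expect_equal(cumulative_arc_length(same)$s_mm, rep(0, 6))

  d <- cumulative_arc_length(traj_mm(c(0, 3), c(0, 4), times = 0:1))
  expect_equal(d$s_mm, c(0, 5)) # 3-4-5 triangle
  expect_equal(d$theta_rad, d$s_mm / 1) # theta = s / L exactly

  bad <- traj_mm(c(0, 3), c(0, 4), times = 0:1, L = -1)
  expect_error(cumulative_arc_length(bad), "positive")
})

test_that("chord sums over a 1-degree-sampled quarter circle reach pi/2 within 0.005%", {
  ang <- seq(0, 90, by = 1) * pi / 180 # 91 points, radius 1 mm
  d <- cumulative_arc_length(traj_mm(cos(ang), sin(ang), times = seq_along(ang)))
  expect_equal(max(d$s_mm), pi / 2, tolerance = 5e-5)
  # chord sums always undershoot the true arc
  expect_lt(max(d$s_mm), pi / 2)
})

test_that("linear displacement yields zero angular acceleration and v = omega * L", {
  t <- seq(0, 0.01, length.out = 50)
  fit <- fit_quintic_spline(disp_series(t, 300 * t, L = 0.46))
  prof <- differentiate(fit, cheliceral_length_mm = 0.46)
  expect_lt(max(abs(prof$alpha)) / 300, 1e-3)
  expect_equal(prof$v, prof$omega * 0.46e-3)
  expect_equal(prof$peak_v, prof$peak_omega * 0.46e-3)
  expect_equal(prof$peak_a, prof$peak_alpha * 0.46e-3)
})

test_that("noise-free strikes recover peak omega, peak alpha and sweep", {
  sim <- sim_noise_free()
  prof <- strike_kinematics(sim$tracks$L)
  expect_equal(prof$peak_omega, sim$truth$peak_omega, tolerance = 0.01)
  expect_equal(prof$peak_alpha, sim$truth$peak_alpha, tolerance = 0.03)
  expect_equal(prof$sweep_rad, sim$truth$gape_rad, tolerance = 0.005)
  expect_equal(prof$t_peak_omega, 0.006, tolerance = 0.02) # tau = 1/2
})

test_that("strike window follows the digitized span, with a thresholded option", {
  sim <- sim_noise_free()
  series <- cumulative_arc_length(calibrate(sim$tracks$L))
  w <- strike_window(series)
  expect_equal(w$duration_s, 0.012)

  prof <- strike_kinematics(sim$tracks$L)
  wt <- strike_window(prof, threshold_frac = 0.02)
  expect_gte(wt$t_start, 0)
  expect_lte(wt$t_end, 0.012)
  # smoothstep velocity is symmetric about T/2
  expect_equal((wt$t_start + wt$t_end) / 2, 0.006, tolerance = 0.02)
  expect_error(strike_window(prof, threshold_frac = 1.5), "0, 1")

  single <- disp_series(0, 0)
  expect_error(strike_window(single), "at least 2")
})

test_that("chelicerae averaging is the arithmetic mean and idempotent on equals", {
  sim <- sim_noise_free(seed = 9)
  left <- strike_kinematics(sim$tracks$L)
  right <- strike_kinematics(sim$tracks$R)
  avg <- average_chelicerae(left, right)
  expect_equal(avg$peak_omega, (left$peak_omega + right$peak_omega) / 2)
  expect_equal(avg$sweep_rad, (left$sweep_rad + right$sweep_rad) / 2)
  expect_equal(avg$duration_s, (left$duration_s + right$duration_s) / 2)
  expect_equal(avg$averaged_n, 2L)
  # mirrored noise-free chelicerae are kinematically identical
  expect_equal(avg$peak_omega, left$peak_omega, tolerance = 1e-6)

  expect_message(solo <- average_chelicerae(left, NULL), "one chelicera")
  expect_equal(solo$peak_omega, left$peak_omega)
  expect_equal(solo$averaged_n, 1L)

  other <- strike_kinematics(
    simulate_strike(strike_sim_config(noise_px = 0, digitize_every = 1,
                                      strike_id = "other"))$tracks$R)
  expect_error(average_chelicerae(left, other), "different strikes")
})

test_that("recovery error grows with digitization noise and sweep stays accurate", {
  med_err <- function(noise_px, n = 15) {
    errs <- vapply(seq_len(n), function(s) {
      sim <- simulate_strike(strike_sim_config(noise_px = noise_px, seed = s))
      prof <- average_chelicerae(strike_kinematics(sim$tracks$L),
                                 strike_kinematics(sim$tracks$R))
      abs(prof$peak_omega / sim$truth$peak_omega - 1)
    }, numeric(1))
    median(errs)
  }
  e <- vapply(c(0.25, 0.5, 1.5), med_err, numeric(1))
  expect_true(all(diff(e) > 0)) # monotone in noise
  expect_lt(e[2], 0.05)

  sweeps <- vapply(1:15, function(s) {
    sim <- simulate_strike(strike_sim_config(seed = s))
    prof <- strike_kinematics(sim$tracks$L)
    abs(prof$sweep_rad / sim$truth$gape_rad - 1)
  }, numeric(1))
  expect_lt(median(sweeps), 0.02)
})

test_that("profile export writes the dense kinematic series", {
  prof <- strike_kinematics(sim_noise_free()$tracks$L)
  path <- withr::local_tempfile(fileext = ".csv")
  export_profile(prof, path)
  back <- utils::read.csv(path)
  expect_named(back, c("time_s", "theta_rad", "omega_rad_s",
                       "alpha_rad_s2", "v_m_s", "a_m_s2"))
  expect_equal(nrow(back), length(prof$times))
  expect_equal(max(back$omega_rad_s), prof$peak_omega)
})
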