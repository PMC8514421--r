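# shared builders for small in-code fixtures

# a calibrated trajectory straight from coordinates (mm)
traj_mm <- function(x, y, times = seq_along(x) - 1, L = 1,
                    side = "L", strike = "s1") {
  structure(
    list(specimen_id = "spec", strike_id = strike, side = side,
         times = times, x_mm = x, y_mm = y, cheliceral_length_mm = L,
         drift_corrected = FALSE, sex = NA_character_),
    class = "calibrated_trajectory"
  )
}

# a displacement series straight from theta(t)
disp_series <- function(times, theta, L = 1) {
  structure(
    list(specimen_id = "spec", strike_id = "s1", side = "L",
         times = times, s_mm = theta * L, theta_rad = theta,
         cheliceral_length_mm = L),
    class = "displacement_series"
  )
}

# default noise-free simulation at the study parameterization
sim_noise_free <- function(...) {
  simulate_strike(strike_sim_config(noise_px = 0, digitize_every = 1, ...))
}

# illustrative allometric coefficients (kg / mm^3): chelicera modelled as a
# cylinder of diameter 0.2 L and density ~1080 kg/m^3; adductor ~60% of it
C_CHELICERA <- 3.4e-8
C_MUSCLE <- 2.0e-8
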