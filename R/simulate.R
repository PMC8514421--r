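#' Configuration for a simulated cheliceral strike
#'
#' Bundles the physical and camera parameters that define one simulated
#' strike: the angular sweep and closure time of the chelicera, the length
#' of the rotating paturon, and the imaging/digitization model (frame rate,
#' spatial calibration, digitization noise, digitization stride, optional
#' whole-body lunge drift).
#'
#' Defaults are the species means reported for the trap-jaw malkarid
#' *Pararchaea alba*: a 172.4 degree sweep closed in 12 ms by a 0.46 mm
#' chelicera, filmed at 10,000 frames per second and digitized on every
#' fourth frame with 0.5 px point-tool noise.
#'
#' @param gape_deg Total angular sweep of one chelicera during closure,
#'   degrees; must lie in (0, 180].
#' @param duration_s Closure time, seconds (> 0).
#' @param cheliceral_length_mm Length of the chelicera (pivot to tracked
#'   distal edge), mm (> 0).
#' @param fps Camera frame rate, frames per second (> 0).
#' @param scale_mm_per_px Spatial calibration, mm per pixel (> 0).
#' @param noise_px Standard deviation of isotropic Gaussian digitization
#'   noise added to each pixel coordinate (>= 0).
#' @param drift_mm_per_s Length-2 numeric: constant-velocity planar
#'   translation of the whole body (the lunge), mm/s.
#' @param digitize_every Integer frame stride >= 1; points are digitized on
#'   every `digitize_every`-th frame.
#' @param seed Integer seed controlling all stochastic draws (R's default
#'   Mersenne-Twister generator via [set.seed()]).
#' @param profile Angular profile family; only `"smoothstep"` (the quintic
#'   smoothstep) is implemented.
#' @param specimen_id,strike_id,sex Identifiers carried into the tracks.
#' @return An object of class `strike_sim_config` (a validated list).
#' @seealso [make_angle_profile()], [simulate_strike()]
#' @export
#' @examples
#' cfg <- strike_sim_config(gape_deg = 172.4, duration_s = 0.012)
#' cfg$fps
strike_sim_config <- function(gape_deg = 172.4,
                              duration_s = 0.012,
                              cheliceral_length_mm = 0.46,
                              fps = 10000,
                              scale_mm_per_px = 0.005,
                              noise_px = 0.5,
                              drift_mm_per_s = c(0, 0),
                              digitize_every = 4L,
                              seed = 1L,
                              profile = "smoothstep",
                              specimen_id = "sim",
                              strike_id = "sim-1",
                              sex = "F") {
  stopifnot(is.numeric(gape_deg), length(gape_deg) == 1L)
  if (!(gape_deg > 0 && gape_deg <= 180)) {
    stop("`gape_deg` must lie in (0, 180], got ", gape_deg)
  }
  if (!(is.numeric(duration_s) && length(duration_s) == 1L && duration_s > 0)) {
    stop("`duration_s` must be a positive number")
  }
  if (!(is.numeric(cheliceral_length_mm) && cheliceral_length_mm > 0)) {
    stop("`cheliceral_length_mm` must be positive")
  }
  if (!(is.numeric(fps) && fps > 0)) stop("`fps` must be positive")
  if (!(is.numeric(scale_mm_per_px) && scale_mm_per_px > 0)) {
    stop("`scale_mm_per_px` must be positive")
  }
  if (!(is.numeric(noise_px) && noise_px >= 0)) {
    stop("`noise_px` must be non-negative")
  }
  if (length(drift_mm_per_s) != 2L || !is.numeric(drift_mm_per_s)) {
    stop("`drift_mm_per_s` must be a length-2 numeric vector")
  }
  digitize_every <- as.integer(digitize_every)
  if (is.na(digitize_every) || digitize_every < 1L) {
    stop("`digitize_every` must be an integer >= 1")
  }
  profile <- match.arg(profile, "smoothstep")
  structure(
    list(
      gape_deg = gape_deg, duration_s = duration_s,
      cheliceral_length_mm = cheliceral_length_mm, fps = fps,
      scale_mm_per_px = scale_mm_per_px, noise_px = noise_px,
      drift_mm_per_s = as.numeric(drift_mm_per_s),
      digitize_every = digitize_every, seed = as.integer(seed),
      profile = profile, specimen_id = specimen_id,
      strike_id = strike_id, sex = sex
    ),
    class = "strike_sim_config"
  )
}

#' Analytic angular closure profile with known extrema
#'
#' Builds the ground-truth angular displacement of one chelicera during a
#' simulated strike. The default (and only) family is the quintic
#' smoothstep
#' \deqn{\theta(t) = \Theta\,(10\tau^3 - 15\tau^4 + 6\tau^5), \quad \tau = t/T,}
#' which is C^2, starts and ends at rest, and has closed-form extrema:
#' peak angular velocity \eqn{1.875\,\Theta/T} at \eqn{\tau = 1/2} and peak
#' angular acceleration \eqn{(10/\sqrt{3})\,\Theta/T^2} at
#' \eqn{\tau = (1 - 1/\sqrt 3)/2}. These analytic peaks are the recovery
#' targets for validating the spline-based kinematics.
#'
#' @param config A [strike_sim_config()].
#' @return An object of class `sim_truth`: list with `theta_fun`,
#'   `omega_fun`, `alpha_fun` (vectorized functions of time in seconds,
#'   radians-based), `peak_omega` (rad/s), `peak_alpha` (rad/s^2),
#'   `gape_rad`, and `duration_s`.
#' @export
#' @examples
#' truth <- make_angle_profile(strike_sim_config(gape_deg = 180, duration_s = 1))
#' truth$peak_omega # 1.875 * pi
make_angle_profile <- function(config) {
  stopifnot(inherits(config, "strike_sim_config"))
  Theta <- config$gape_deg * pi / 180
  T <- config$duration_s
  if (Theta <= 0 || T <= 0) stop("gape and duration must be positive")
  theta_fun <- function(t) {
    tau <- pmin(pmax(t / T, 0), 1)
    Theta * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  omega_fun <- function(t) {
    tau <- t / T
    out <- (Theta / T) * 30 * tau^2 * (1 - tau)^2
    out[tau < 0 | tau > 1] <- 0
    out
  }
  alpha_fun <- function(t) {
    tau <- t / T
    out <- (Theta / T^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)
    out[tau < 0 | tau > 1] <- 0
    out
  }
  structure(
    list(
      theta_fun = theta_fun, omega_fun = omega_fun, alpha_fun = alpha_fun,
      peak_omega = 1.875 * Theta / T,
      peak_alpha = (10 / sqrt(3)) * Theta / T^2,
      gape_rad = Theta, duration_s = T, profile = config$profile
    ),
    class = "sim_truth"
  )
}

#' Simulate digitized point tracks for one strike
#'
#' Places the tracked distal cheliceral edge on a circular arc of radius
#' equal to the cheliceral length around a fixed pivot, sweeping through
#' the ground-truth angle profile; the left and right chelicerae are
#' mirrored about the midline and move synchronously. Coordinates are
#' converted to pixels, degraded with i.i.d. Gaussian digitization noise,
#' optionally translated by a constant-velocity body lunge, and subsampled
#' to every `digitize_every`-th frame — emulating manual point-tool
#' digitization of stabilized high-speed video. A body reference series
#' (the pivot, digitized with the same noise model) is returned for
#' drift-removal workflows.
#'
#' The draw order is fixed (left x, left y, right x, right y, reference x,
#' reference y) so a given seed always yields identical tracks.
#'
#' @param truth A [make_angle_profile()] result.
#' @param config The matching [strike_sim_config()].
#' @return Object of class `simulated_strike`: list with `truth`, `config`,
#'   `tracks` (named list `L`, `R` of [tracked_strike()] objects) and
#'   `reference` (body-point `tracked_strike` with side `"body"`).
#' @export
simulate_track <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "strike_sim_config"))
  frames <- seq(0L, floor(config$duration_s * config$fps), by = config$digitize_every)
  if (length(frames) < 6L) {
    stop("fewer than 6 digitized frames fall inside the strike (got ",
         length(frames), "); decrease `digitize_every` or increase fps")
  }
  times <- frames / config$fps
  theta <- truth$theta_fun(times)
  Theta <- truth$gape_rad
  L <- config$cheliceral_length_mm

  # midline along +y; each chelicera starts open and sweeps toward midline
  phi_R <- pi / 2 - (Theta - theta)
  phi_L <- pi / 2 + (Theta - theta)
  drift <- outer(times, config$drift_mm_per_s) # n x 2, mm
  pivot_mm <- drift
  pt_mm <- function(phi) cbind(pivot_mm[, 1] + L * cos(phi),
                               pivot_mm[, 2] + L * sin(phi))

  set.seed(config$seed)
  n <- length(times)
  digitize <- function(p_mm) {
    px <- p_mm / config$scale_mm_per_px
    px[, 1] <- px[, 1] + stats::rnorm(n, 0, config$noise_px)
    px[, 2] <- px[, 2] + stats::rnorm(n, 0, config$noise_px)
    px
  }
  left_px <- digitize(pt_mm(phi_L))
  right_px <- digitize(pt_mm(phi_R))
  ref_px <- digitize(pivot_mm)

  mk <- function(side, px) {
    tracked_strike(
      specimen_id = config$specimen_id, strike_id = config$strike_id,
      side = side, frame_index = frames, times = times,
      x_px = px[, 1], y_px = px[, 2], fps = config$fps,
      scale_mm_per_px = config$scale_mm_per_px,
      cheliceral_length_mm = config$cheliceral_length_mm, sex = config$sex
    )
  }
  structure(
    list(
      truth = truth, config = config,
      tracks = list(L = mk("L", left_px), R = mk("R", right_px)),
      reference = mk("body", ref_px)
    ),
    class = "simulated_strike"
  )
}

#' Simulate a full strike in one call
#'
#' Convenience wrapper: [make_angle_profile()] followed by
#' [simulate_track()].
#'
#' @inheritParams simulate_track
#' @return A `simulated_strike`; see [simulate_track()].
#' @export
#' @examples
#' sim <- simulate_strike(strike_sim_config(noise_px = 0, seed = 7))
#' names(sim$tracks)
simulate_strike <- function(config) {
  simulate_track(make_angle_profile(config), config)
}

#' Write a simulated strike as an on-disk fixture
#'
#' Emits the files the track reader consumes: `tracks.csv` (schema
#' `specimen_id, strike_id, side, frame_index, time_s, x_px, y_px`),
#' `config.yaml` (fps, scale, cheliceral length, stride, sex), and
#' `reference.csv` (the body reference series, side `"body"`). Numeric
#' columns are written at 15 significant digits so the fixture round-trips
#' losslessly at print precision.
#'
#' @param sim A `simulated_strike`.
#' @param path Directory to write into (created if absent).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_strike_fixture <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_strike"))
  if (missing(path) || is.null(path) || !nzchar(path)) {
    stop("`path` must be a non-empty directory path")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  track_df <- function(tr) {
    data.frame(
      specimen_id = tr$specimen_id, strike_id = tr$strike_id,
      side = tr$side, frame_index = tr$frame_index,
      time_s = tr$times, x_px = tr$x_px, y_px = tr$y_px,
      stringsAsFactors = FALSE
    )
  }
  tracks <- rbind(track_df(sim$tracks$L), track_df(sim$tracks$R))
  f_tracks <- file.path(path, "tracks.csv")
  f_ref <- file.path(path, "reference.csv")
  f_cfg <- file.path(path, "config.yaml")
  utils::write.csv(format(tracks, digits = 15, trim = TRUE, scientific = FALSE),
                   f_tracks, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(track_df(sim$reference), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   f_ref, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(
      fps = sim$config$fps,
      scale_mm_per_px = sim$config$scale_mm_per_px,
      cheliceral_length_mm = sim$config$cheliceral_length_mm,
      digitize_every = sim$config$digitize_every,
      sex = sim$config$sex
    ),
    f_cfg
  )
  invisible(c(tracks = f_tracks, reference = f_ref, config = f_cfg))
}
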