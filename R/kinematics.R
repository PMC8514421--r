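#' Cumulative arc-length displacement of the tracked point
#'
#' Converts a calibrated planar trajectory into cumulative displacement:
#' the running sum of unsigned chord lengths between consecutive digitized
#' points (the chord-sum approximation of arc length), and the equivalent
#' angular displacement obtained by dividing by the cheliceral length.
#' Noise-induced back-steps are permitted and contribute their unsigned
#' length, matching the "cumulative displacement" convention.
#'
#' @param traj A [calibrate()]d trajectory.
#' @return Object of class `displacement_series`: list with `times` (s),
#'   `s_mm` (cumulative displacement, mm, starting at 0), `theta_rad`
#'   (`s_mm / L`), and `cheliceral_length_mm`.
#' @export
#' @examples
#' tr <- calibrate(simulate_strike(strike_sim_config(noise_px = 0))$tracks$L)
#' d <- cumulative_arc_length(tr)
#' max(d$theta_rad) * 180 / pi # ~ the gape in degrees
cumulative_arc_length <- function(traj) {
  stopifnot(inherits(traj, "calibrated_trajectory"))
  L <- traj$cheliceral_length_mm
  if (!(is.numeric(L) && L > 0)) stop("cheliceral length must be positive")
  n <- length(traj$times)
  if (n < 2L) stop("need at least 2 points")
  steps <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  s <- c(0, cumsum(steps))
  structure(
    list(
      specimen_id = traj$specimen_id, strike_id = traj$strike_id,
      side = traj$side, times = traj$times, s_mm = s, theta_rad = s / L,
      cheliceral_length_mm = L
    ),
    class = "displacement_series"
  )
}

#' Full kinematic profile from a fitted spline
#'
#' Evaluates the fitted displacement spline and its analytic first and
#' second derivatives on a dense grid (default 10x the digitized
#' sampling), yielding angular velocity and acceleration; linear velocity
#' and acceleration of the distal tracked point follow as v = omega * L and
#' a = alpha * L with L in metres. Peaks are the maxima of the dense
#' series; at ties the earliest time wins.
#'
#' @param fit A [fit_quintic_spline()] result.
#' @param cheliceral_length_mm Cheliceral length L, mm; taken from `series`
#'   metadata by [strike_kinematics()].
#' @param dense_factor Evaluation-grid refinement relative to the number of
#'   digitized samples (>= 1; default 10).
#' @param meta Optional named list of identifiers to carry along.
#' @return Object of class `kinematic_profile`: dense `times`, `theta_rad`,
#'   `omega` (rad/s), `alpha` (rad/s^2), `v` (m/s), `a` (m/s^2); scalars
#'   `peak_omega`, `peak_alpha`, `peak_v`, `peak_a`, `t_peak_omega` (s),
#'   `sweep_rad`, `duration_s` (first to last digitized frame), `edf`, and
#'   the underlying `fit`.
#' @export
differentiate <- function(fit, cheliceral_length_mm, dense_factor = 10,
                          meta = NULL) {
  stopifnot(inherits(fit, "quintic_pspline"))
  L_mm <- cheliceral_length_mm
  if (!(is.numeric(L_mm) && L_mm > 0)) stop("cheliceral length must be positive")
  if (dense_factor < 1) stop("`dense_factor` must be >= 1")
  L_m <- L_mm / 1000
  grid <- seq(fit$range[1], fit$range[2],
              length.out = max(2L, ceiling(fit$n * dense_factor)))
  theta <- predict(fit, grid, deriv = 0L)
  omega <- predict(fit, grid, deriv = 1L)
  alpha <- predict(fit, grid, deriv = 2L)
  i_w <- which.max(omega) # earliest index at ties
  i_a <- which.max(alpha)
  structure(
    c(
      list(
        times = grid, theta_rad = theta, omega = omega, alpha = alpha,
        v = omega * L_m, a = alpha * L_m,
        peak_omega = omega[i_w], peak_alpha = alpha[i_a],
        peak_v = omega[i_w] * L_m, peak_a = alpha[i_a] * L_m,
        t_peak_omega = grid[i_w],
        sweep_rad = theta[length(theta)] - theta[1],
        duration_s = fit$range[2] - fit$range[1],
        cheliceral_length_mm = L_mm, edf = fit$edf, fit = fit
      ),
      if (!is.null(meta)) meta
    ),
    class = "kinematic_profile"
  )
}

#' @export
print.kinematic_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<kinematic_profile> sweep %.1f deg in %.4g s; ",
           "peak omega %.4g rad/s, peak alpha %.4g rad/s^2, peak v %.4g m/s\n"),
    x$sweep_rad * 180 / pi, x$duration_s, x$peak_omega, x$peak_alpha, x$peak_v
  ))
  invisible(x)
}

#' One-call kinematics for a single chelicera
#'
#' Chains [calibrate()], [cumulative_arc_length()],
#' [fit_quintic_spline()] and [differentiate()].
#'
#' @param track A [tracked_strike()].
#' @param smoothing Passed to [fit_quintic_spline()] (`NULL` = GCV).
#' @param dense_factor Passed to [differentiate()].
#' @return A `kinematic_profile`.
#' @export
strike_kinematics <- function(track, smoothing = NULL, dense_factor = 10) {
  series <- cumulative_arc_length(calibrate(track))
  fit <- fit_quintic_spline(series, smoothing = smoothing)
  differentiate(fit, series$cheliceral_length_mm, dense_factor = dense_factor,
                meta = list(specimen_id = series$specimen_id,
                            strike_id = series$strike_id, side = series$side))
}

#' Strike window and duration
#'
#' Default definition: the strike lasts from the first to the last
#' digitized point (digitization runs from open to closed position), so
#' the duration is the digitized time span. An alternative thresholded
#' definition returns the window where the fitted angular velocity is at
#' least `threshold_frac` of its peak, for sensitivity analyses.
#'
#' @param x A `displacement_series` (default definition only) or a
#'   `kinematic_profile` (either definition).
#' @param threshold_frac `NULL` for the default definition, or a fraction
#'   in (0, 1) of peak angular velocity.
#' @return List with `t_start`, `t_end`, `duration_s`.
#' @export
strike_window <- function(x, threshold_frac = NULL) {
  if (inherits(x, "displacement_series")) {
    if (length(x$times) < 2L) stop("need at least 2 digitized frames")
    if (!is.null(threshold_frac)) {
      stop("thresholded windows need a fitted `kinematic_profile`")
    }
    return(list(t_start = x$times[1], t_end = x$times[length(x$times)],
                duration_s = x$times[length(x$times)] - x$times[1]))
  }
  stopifnot(inherits(x, "kinematic_profile"))
  if (is.null(threshold_frac)) {
    return(list(t_start = x$times[1], t_end = x$times[length(x$times)],
                duration_s = x$duration_s))
  }
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop("`threshold_frac` must lie in (0, 1)")
  }
  above <- which(x$omega >= threshold_frac * x$peak_omega)
  if (!length(above)) stop("no samples above threshold")
  list(t_start = x$times[above[1]], t_end = x$times[above[length(above)]],
       duration_s = x$times[above[length(above)]] - x$times[above[1]])
}

#' Average the two synchronously striking chelicerae
#'
#' Chelicerae strike synchronously, so per-strike kinematics are reported
#' as the arithmetic mean of the left and right profiles: scalar summaries
#' (peaks, sweep, duration) are averaged directly, and the series are
#' averaged pointwise after re-evaluating both fitted splines on the
#' common time support. If one chelicera is missing (`NULL`), the other is
#' passed through with an `averaged_n = 1` flag and a message.
#'
#' @param left,right `kinematic_profile` objects for the same strike (one
#'   may be `NULL`).
#' @return A `kinematic_profile` with an `averaged_n` field (2, or 1 on
#'   pass-through).
#' @export
average_chelicerae <- function(left, right) {
  if (is.null(left) && is.null(right)) stop("both chelicerae missing")
  if (is.null(left) || is.null(right)) {
    out <- if (is.null(left)) right else left
    message("only one chelicera available for strike '",
            out$strike_id, "'; passing it through unaveraged")
    out$averaged_n <- 1L
    return(out)
  }
  stopifnot(inherits(left, "kinematic_profile"),
            inherits(right, "kinematic_profile"))
  if (!is.null(left$strike_id) && !is.null(right$strike_id) &&
      !identical(left$strike_id, right$strike_id)) {
    stop("cannot average chelicerae from different strikes: '",
         left$strike_id, "' vs '", right$strike_id, "'")
  }
  lo <- max(left$times[1], right$times[1])
  hi <- min(left$times[length(left$times)], right$times[length(right$times)])
  if (hi <= lo) stop("profiles have no overlapping time support")
  grid <- seq(lo, hi, length.out = max(length(left$times), length(right$times)))
  L_mm <- mean(c(left$cheliceral_length_mm, right$cheliceral_length_mm))
  L_m <- L_mm / 1000
  avg <- function(deriv) {
    (predict(left$fit, grid, deriv = deriv) +
       predict(right$fit, grid, deriv = deriv)) / 2
  }
  theta <- avg(0L)
  omega <- avg(1L)
  alpha <- avg(2L)
  structure(
    list(
      times = grid, theta_rad = theta, omega = omega, alpha = alpha,
      v = omega * L_m, a = alpha * L_m,
      peak_omega = mean(c(left$peak_omega, right$peak_omega)),
      peak_alpha = mean(c(left$peak_alpha, right$peak_alpha)),
      peak_v = mean(c(left$peak_v, right$peak_v)),
      peak_a = mean(c(left$peak_a, right$peak_a)),
      t_peak_omega = mean(c(left$t_peak_omega, right$t_peak_omega)),
      sweep_rad = mean(c(left$sweep_rad, right$sweep_rad)),
      duration_s = mean(c(left$duration_s, right$duration_s)),
      cheliceral_length_mm = L_mm,
      edf = mean(c(left$edf, right$edf)),
      fit = NULL, averaged_n = 2L,
      specimen_id = left$specimen_id, strike_id = left$strike_id,
      side = "averaged"
    ),
    class = "kinematic_profile"
  )
}

#' Export a kinematic profile as CSV
#'
#' Writes the dense time series (`time_s, theta_rad, omega_rad_s,
#' alpha_rad_s2, v_m_s, a_m_s2`) — the displacement, velocity and
#' acceleration curves of one strike.
#'
#' @param profile A `kinematic_profile`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_profile <- function(profile, path) {
  stopifnot(inherits(profile, "kinematic_profile"))
  df <- data.frame(
    time_s = profile$times, theta_rad = profile$theta_rad,
    omega_rad_s = profile$omega, alpha_rad_s2 = profile$alpha,
    v_m_s = profile$v, a_m_s2 = profile$a
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
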