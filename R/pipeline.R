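#' Analyze one strike (both chelicerae) end to end
#'
#' Runs the full per-strike pipeline: per-chelicera calibration,
#' cumulative arc length, penalized quintic spline fit, analytic
#' differentiation; averages the two synchronously striking chelicerae;
#' and, when a [chelicera_body()] is supplied, appends rigid-rod
#' energetics (kinetic energy, strike power, mass-specific power output,
#' muscle-ceiling verdict).
#'
#' @param tracks A list of [tracked_strike()] objects for one strike
#'   (sides `"L"`/`"R"`; one may be absent).
#' @param body Optional [chelicera_body()] / [estimate_masses()] result.
#' @param smoothing,dense_factor Passed to [strike_kinematics()].
#' @param drift_reference Optional body reference `tracked_strike`; when
#'   given, [remove_drift()] is applied to every chelicera first.
#' @return One-row data frame (`strike_summary`): identifiers,
#'   `n_chelicerae`, `peak_omega_rad_s`, `peak_alpha_rad_s2`, `peak_v_m_s`,
#'   `peak_a_m_s2`, `duration_s`, `sweep_deg`, `edf`, and — with a body —
#'   `E_max_J`, `t_E_max_s`, `P_W`, `O_W_per_kg`, `exceeds_muscle_limit`.
#'   The averaged `kinematic_profile` is attached as attribute `"profile"`.
#' @export
#' @examples
#' sim <- simulate_strike(strike_sim_config(noise_px = 0, digitize_every = 1))
#' analyze_strike(sim$tracks)
analyze_strike <- function(tracks, body = NULL, smoothing = NULL,
                           dense_factor = 10, drift_reference = NULL) {
  sides <- vapply(tracks, function(t) t$side, character(1))
  if (!is.null(drift_reference)) {
    tracks <- lapply(tracks, remove_drift, reference = drift_reference)
  }
  prof_of <- function(side) {
    i <- which(sides == side)
    if (!length(i)) return(NULL)
    strike_kinematics(tracks[[i[1]]], smoothing = smoothing,
                      dense_factor = dense_factor)
  }
  avg <- average_chelicerae(prof_of("L"), prof_of("R"))
  out <- data.frame(
    specimen_id = avg$specimen_id %||% NA_character_,
    strike_id = avg$strike_id %||% NA_character_,
    n_chelicerae = avg$averaged_n %||% 1L,
    peak_omega_rad_s = avg$peak_omega,
    peak_alpha_rad_s2 = avg$peak_alpha,
    peak_v_m_s = avg$peak_v,
    peak_a_m_s2 = avg$peak_a,
    duration_s = avg$duration_s,
    sweep_deg = avg$sweep_rad * 180 / pi,
    edf = avg$edf,
    stringsAsFactors = FALSE
  )
  if (!is.null(body)) {
    en <- strike_energetics(avg, body)
    out$E_max_J <- en$E_max_J
    out$t_E_max_s <- en$t_E_max_s
    out$P_W <- en$P_W
    out$O_W_per_kg <- en$O_W_per_kg
    out$exceeds_muscle_limit <- en$exceeds_muscle_limit
  }
  attr(out, "profile") <- avg
  out
}

#' Analyze a collection of tracks strike by strike
#'
#' Groups tracks by (specimen, strike), analyzes each strike with
#' [analyze_strike()], and binds the per-strike rows.
#'
#' @param tracks Named list of [tracked_strike()] objects, e.g. from
#'   [read_tracks()].
#' @param body Optional [chelicera_body()], or a function
#'   `function(cheliceral_length_mm)` returning one per strike (for
#'   length-dependent allometric estimates).
#' @param ... Passed to [analyze_strike()].
#' @return Data frame with one row per strike.
#' @export
analyze_tracks <- function(tracks, body = NULL, ...) {
  keys <- vapply(tracks, function(t) paste(t$specimen_id, t$strike_id,
                                           sep = "/"), character(1))
  rows <- lapply(split(tracks, keys), function(grp) {
    b <- if (is.function(body)) body(grp[[1]]$cheliceral_length_mm) else body
    analyze_strike(grp, body = b, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
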