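#' Maximum mass-specific power output of conventional muscle
#'
#' The customary ~400 W/kg ceiling: a strike whose mass-specific power
#' output exceeds it is taken as indirect evidence of elastic energy
#' storage ("power amplification").
#' @export
MUSCLE_POWER_LIMIT_W_KG <- 400

#' Physical properties of one chelicera
#'
#' Masses and length used by the rigid-rod energetics, each tagged with
#' its provenance (`"measured"` or `"allometric estimate"`).
#'
#' @param M_kg Chelicera mass, kg (> 0).
#' @param L_m Chelicera length, m (> 0).
#' @param m_muscle_kg Adductor (closer) muscle mass, kg (> 0).
#' @param provenance Single string or named character vector giving the
#'   provenance of the values.
#' @return Object of class `chelicera_body`.
#' @export
chelicera_body <- function(M_kg, L_m, m_muscle_kg, provenance = "measured") {
  if (!(is.numeric(M_kg) && M_kg > 0)) stop("`M_kg` must be positive")
  if (!(is.numeric(L_m) && L_m > 0)) stop("`L_m` must be positive")
  if (!(is.numeric(m_muscle_kg) && m_muscle_kg > 0)) {
    stop("`m_muscle_kg` must be positive")
  }
  structure(
    list(M_kg = M_kg, L_m = L_m, m_muscle_kg = m_muscle_kg,
         provenance = provenance),
    class = "chelicera_body"
  )
}

#' Moment of inertia of the chelicera as a uniform thin rod
#'
#' The chelicera is modelled as a thin rod of uniform density rotating
#' about a fixed pivot at one end, giving \eqn{I = \frac{1}{3} M L^2}.
#'
#' @param M_kg Chelicera mass, kg (> 0).
#' @param L_m Chelicera length, m (> 0).
#' @return Moment of inertia, kg m^2.
#' @export
#' @examples
#' moment_of_inertia(3, 1) # 1 kg m^2
moment_of_inertia <- function(M_kg, L_m) {
  if (!(is.numeric(M_kg) && all(M_kg > 0))) stop("`M_kg` must be positive")
  if (!(is.numeric(L_m) && all(L_m > 0))) stop("`L_m` must be positive")
  M_kg * L_m^2 / 3
}

#' Rotational kinetic energy series
#'
#' \eqn{E(t) = \frac{1}{2} I \omega(t)^2}, elementwise over the smoothed
#' angular-velocity series.
#'
#' @param I_kg_m2 Moment of inertia, kg m^2 (>= 0).
#' @param omega_rad_s Angular velocity series, rad/s.
#' @return Kinetic energy series, J.
#' @export
kinetic_energy <- function(I_kg_m2, omega_rad_s) {
  if (!(is.numeric(I_kg_m2) && length(I_kg_m2) == 1L && I_kg_m2 >= 0)) {
    stop("`I_kg_m2` must be a single non-negative number")
  }
  0.5 * I_kg_m2 * omega_rad_s^2
}

#' Strike power from the kinetic-energy peak
#'
#' Strike power is the peak kinetic energy divided by the time taken to
#' reach it, \eqn{P = E_{max} / t_{E,max}}, with time measured from strike
#' onset (the first digitized frame). If several samples tie for the
#' maximum, the earliest wins. A peak at onset itself is a degenerate
#' division and raises an error.
#'
#' @param E_series Kinetic energy series, J.
#' @param times Times of the series, s.
#' @param t_onset Strike onset time, s; defaults to the first time.
#' @return List with `E_max_J`, `t_E_max_s` (relative to onset), `P_W`.
#' @export
strike_power <- function(E_series, times, t_onset = times[1]) {
  if (!length(E_series)) stop("empty energy series")
  if (length(E_series) != length(times)) stop("series/time length mismatch")
  if (any(t_onset > times)) stop("`t_onset` must not exceed any series time")
  i <- which.max(E_series) # earliest at ties
  t_rel <- times[i] - t_onset
  if (t_rel <= 0) {
    stop("kinetic energy peaks at strike onset; strike power is undefined")
  }
  list(E_max_J = E_series[i], t_E_max_s = t_rel, P_W = E_series[i] / t_rel)
}

#' Mass-specific power output
#'
#' \eqn{O = P / m}, the strike power per unit adductor muscle mass, in
#' W/kg. Values above [MUSCLE_POWER_LIMIT_W_KG] (400 W/kg) would indicate
#' power amplification by stored elastic energy.
#'
#' @param P_W Strike power, W (>= 0).
#' @param m_muscle_kg Adductor muscle mass, kg (> 0).
#' @return Mass-specific power output, W/kg.
#' @seealso [exceeds_muscle_limit()]
#' @export
mass_specific_power <- function(P_W, m_muscle_kg) {
  if (!(is.numeric(m_muscle_kg) && all(m_muscle_kg > 0))) {
    stop("`m_muscle_kg` must be positive")
  }
  if (any(P_W < 0)) stop("`P_W` must be non-negative")
  P_W / m_muscle_kg
}

#' Does the power output exceed the conventional-muscle ceiling?
#'
#' @param O_W_per_kg Mass-specific power output, W/kg.
#' @param limit Ceiling, W/kg; default [MUSCLE_POWER_LIMIT_W_KG].
#' @return Logical.
#' @export
exceeds_muscle_limit <- function(O_W_per_kg, limit = MUSCLE_POWER_LIMIT_W_KG) {
  O_W_per_kg > limit
}

#' Allometric estimation of chelicera and muscle mass from length
#'
#' Geometric-similarity model \eqn{m = c L^{k}} (default exponent 3): mass
#' scales with the cube of cheliceral length. The coefficients must be
#' supplied by the user — typically a regression on previously measured
#' related species — and are never defaulted; the returned masses are
#' flagged `"allometric estimate"`.
#'
#' @param L_mm Cheliceral length, mm (> 0).
#' @param c_muscle Coefficient for adductor muscle mass, kg per mm^exponent.
#' @param c_chelicera Coefficient for whole-chelicera mass, kg per
#'   mm^exponent.
#' @param exponent Scaling exponent; default 3 (geometric similarity).
#' @return A [chelicera_body()] with provenance `"allometric estimate"`.
#' @export
#' @examples
#' estimate_masses(1, c_muscle = 1, c_chelicera = 2) # 1 kg muscle, 2 kg chelicera
estimate_masses <- function(L_mm, c_muscle, c_chelicera, exponent = 3) {
  if (missing(c_muscle) || missing(c_chelicera) ||
      is.null(c_muscle) || is.null(c_chelicera)) {
    stop("allometric coefficients `c_muscle` and `c_chelicera` are required; ",
         "supply values from a regression on measured related species ",
         "(no defaults are assumed)")
  }
  if (!(is.numeric(L_mm) && L_mm > 0)) stop("`L_mm` must be positive")
  chelicera_body(
    M_kg = c_chelicera * L_mm^exponent,
    L_m = L_mm / 1000,
    m_muscle_kg = c_muscle * L_mm^exponent,
    provenance = c(M_kg = "allometric estimate",
                   m_muscle_kg = "allometric estimate",
                   L_m = "measured")
  )
}

#' Full strike energetics from a kinematic profile
#'
#' Computes the moment of inertia, the kinetic-energy series from the
#' smoothed angular velocity, the strike power, the mass-specific power
#' output, and the muscle-ceiling verdict.
#'
#' @param profile A `kinematic_profile` (typically chelicerae-averaged).
#' @param body A [chelicera_body()] or [estimate_masses()] result.
#' @return Object of class `energetics_result`: list with `I_kg_m2`,
#'   `E_series_J`, `times`, `E_max_J`, `t_E_max_s`, `P_W`, `O_W_per_kg`,
#'   `exceeds_muscle_limit`.
#' @export
strike_energetics <- function(profile, body) {
  stopifnot(inherits(profile, "kinematic_profile"),
            inherits(body, "chelicera_body"))
  I <- moment_of_inertia(body$M_kg, body$L_m)
  E <- kinetic_energy(I, profile$omega)
  pw <- strike_power(E, profile$times, t_onset = profile$times[1])
  O <- mass_specific_power(pw$P_W, body$m_muscle_kg)
  structure(
    list(
      I_kg_m2 = I, E_series_J = E, times = profile$times,
      E_max_J = pw$E_max_J, t_E_max_s = pw$t_E_max_s, P_W = pw$P_W,
      O_W_per_kg = O, exceeds_muscle_limit = exceeds_muscle_limit(O),
      body = body
    ),
    class = "energetics_result"
  )
}
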