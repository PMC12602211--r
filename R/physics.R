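# Force balance, relative wind, and the power--speed relation.

#' Rolling-resistance coefficients for rubber on asphalt
#'
#' Published range and midpoint of the rolling friction coefficient between
#' a bicycle tire and asphalt under dry and wet conditions. The midpoints
#' (0.014 dry, 0.0036 wet) are the defaults used by [race_env()].
#'
#' @return A `data.frame` with columns `surface`, `mu_min`, `mu_max`,
#'   `mu_mean` (the midpoint, computed).
#' @export
rolling_resistance_table <- function() {
  df <- data.frame(
    surface = c("dry", "wet"),
    mu_min = c(0.010, 0.0022),
    mu_max = c(0.018, 0.005)
  )
  df$mu_mean <- (df$mu_min + df$mu_max) / 2
  df
}

# Sliding (grip) coefficients used for the cornering limit.
SLIDING_COEFF <- c(dry = 0.9, wet = 0.4)

#' Race environment
#'
#' Physical constants and weather for a simulation run. Wind direction uses
#' the same convention as segment headings — degrees clockwise from north,
#' and it is the direction the wind blows *toward* — so the along-segment
#' wind component is `V_wind * cos(D_wind - D_seg)`.
#'
#' @param air_density air density rho (kg/m^3); 1.225 is sea level at 15 C.
#' @param gravity gravitational acceleration g (m/s^2).
#' @param wind_speed wind speed (m/s, >= 0).
#' @param wind_direction direction the wind blows toward (degrees clockwise
#'   from north).
#' @param surface `"dry"` or `"wet"`; selects the default rolling and
#'   sliding friction coefficients.
#' @param rolling_coeff rolling resistance coefficient mu; defaults to the
#'   surface midpoint from [rolling_resistance_table()].
#' @param sliding_coeff sliding friction coefficient mu_sli used by the
#'   cornering limit; defaults to 0.9 dry / 0.4 wet.
#' @return A `velo_env` list.
#' @examples
#' race_env(surface = "wet")$rolling_coeff  # 0.0036
#' @export
race_env <- function(air_density = 1.225, gravity = 9.81, wind_speed = 0,
                     wind_direction = 0, surface = c("dry", "wet"),
                     rolling_coeff = NULL, sliding_coeff = NULL) {
  surface <- match.arg(surface)
  stopifnot_scalar(air_density, "air_density", 0, strict_lower = TRUE)
  stopifnot_scalar(gravity, "gravity", 0, strict_lower = TRUE)
  stopifnot_scalar(wind_speed, "wind_speed", 0)
  stopifnot_scalar(wind_direction, "wind_direction")
  tab <- rolling_resistance_table()
  if (is.null(rolling_coeff))
    rolling_coeff <- tab$mu_mean[tab$surface == surface]
  if (is.null(sliding_coeff))
    sliding_coeff <- unname(SLIDING_COEFF[surface])
  stopifnot_scalar(rolling_coeff, "rolling_coeff", 0)
  stopifnot_scalar(sliding_coeff, "sliding_coeff", 0)
  structure(list(air_density = air_density, gravity = gravity,
                 wind_speed = wind_speed,
                 wind_direction = wind_direction %% 360,
                 surface = surface, rolling_coeff = rolling_coeff,
                 sliding_coeff = sliding_coeff),
            class = "velo_env")
}

#' Rider parameters
#'
#' The defaults are documented placeholders for a generic elite male rider
#' (75 kg incl. equipment, drag area `C * S = 0.25` m^2, recovery power
#' 300 W, 20 kJ above-recovery budget); they are not measured values and
#' every report echoes them. Speed caps follow elite time-trial speeds:
#' 20.83 m/s flat/uphill for men (18.06 m/s for women); the descent cap is
#' a separate, higher bound.
#'
#' @param mass rider plus equipment mass (kg).
#' @param drag_coeff air drag coefficient C (dimensionless).
#' @param frontal_area frontal windward area S (m^2).
#' @param recovery_power power sustainable indefinitely through aerobic
#'   metabolism (W); riding at or below it does not draw on the budget.
#' @param energy_budget total work capacity above recovery power for the
#'   whole race, W_all (J); analogous to W' of critical-power theory.
#' @param v_max_flat speed cap on flat and uphill segments (m/s).
#' @param v_max_descent speed cap on descents (m/s, `>= v_max_flat`).
#' @return A `velo_rider` list.
#' @examples
#' rider(mass = 68, recovery_power = 260)
#' @export
rider <- function(mass = 75, drag_coeff = 1.0, frontal_area = 0.25,
                  recovery_power = 300, energy_budget = 20000,
                  v_max_flat = 20.83, v_max_descent = 25) {
  stopifnot_scalar(mass, "mass", 0, strict_lower = TRUE)
  stopifnot_scalar(drag_coeff, "drag_coeff", 0, strict_lower = TRUE)
  stopifnot_scalar(frontal_area, "frontal_area", 0, strict_lower = TRUE)
  stopifnot_scalar(recovery_power, "recovery_power", 0, strict_lower = TRUE)
  stopifnot_scalar(energy_budget, "energy_budget", 0)
  stopifnot_scalar(v_max_flat, "v_max_flat", 0, strict_lower = TRUE)
  stopifnot_scalar(v_max_descent, "v_max_descent", 0, strict_lower = TRUE)
  if (v_max_flat > v_max_descent)
    vp_validation_error("'v_max_flat' must not exceed 'v_max_descent'")
  structure(list(mass = mass, drag_coeff = drag_coeff,
                 frontal_area = frontal_area,
                 recovery_power = recovery_power,
                 energy_budget = energy_budget,
                 v_max_flat = v_max_flat, v_max_descent = v_max_descent),
            class = "velo_rider")
}

#' Relative wind speed
#'
#' `V_rel = V_people - V_wind * cos(alpha)`, where `alpha` is the angle
#' between the rider's heading and the direction the wind blows toward.
#' `alpha = 0` is a pure tailwind (wind moving with the rider reduces the
#' relative wind); `alpha = 180` is a pure headwind. The result may be
#' negative when a tailwind exceeds the rider's speed.
#'
#' @param v_people rider ground speed (m/s, >= 0).
#' @param v_wind wind speed (m/s, >= 0).
#' @param alpha_deg angle between rider heading and wind-toward direction
#'   (degrees).
#' @return Signed relative wind speed (m/s).
#' @examples
#' relative_wind_speed(15, 5, 180)  # 20: headwind
#' @export
relative_wind_speed <- function(v_people, v_wind, alpha_deg) {
  if (any(v_people < 0) || any(v_wind < 0))
    vp_validation_error("speeds must be >= 0")
  v_people - v_wind * cos(deg2rad(alpha_deg))
}

as_segment <- function(segment) {
  if (inherits(segment, "velo_course") || is.data.frame(segment)) {
    if (nrow(segment) != 1L)
      vp_validation_error("expected a single segment (one-row course)")
    segment <- as.list(segment)
  }
  segment
}

#' Force breakdown on a segment at a given speed
#'
#' The total resistive force the rider must overcome:
#' `F_c = F_air + F_g + F_r + F_acc` with
#' `F_air = 1/2 C rho S V_rel |V_rel|` (signed so a strong tailwind pushes
#' forward rather than, as naive squaring would have it, backward),
#' `F_r = mu m g cos(gamma)`, `F_g = m g sin(gamma)` (negative downhill),
#' `F_acc = m a`. The wind angle is taken from the wind direction and the
#' segment heading.
#'
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param segment a one-row [velo_course()] (or list with `grade_angle`,
#'   `heading_deg`).
#' @param v rider speed (m/s, >= 0).
#' @param a acceleration (m/s^2), default 0 (steady-state riding).
#' @return A list of class `velo_forces` with components `F_air`, `F_g`,
#'   `F_r`, `F_acc`, `F_c` (N) and `V_rel` (m/s).
#' @examples
#' seg <- velo_course(100, grade_pct = 0)
#' force_breakdown(rider(), race_env(), seg, v = 10)
#' @export
force_breakdown <- function(rider, env, segment, v, a = 0) {
  if (any(v < 0)) vp_validation_error("'v' must be >= 0")
  seg <- as_segment(segment)
  alpha <- env$wind_direction - seg$heading_deg
  v_rel <- relative_wind_speed(v, env$wind_speed, alpha)
  f_air <- 0.5 * rider$drag_coeff * env$air_density * rider$frontal_area *
    v_rel * abs(v_rel)
  f_r <- env$rolling_coeff * rider$mass * env$gravity * cos(seg$grade_angle)
  f_g <- rider$mass * env$gravity * sin(seg$grade_angle)
  f_acc <- rider$mass * a
  structure(list(F_air = f_air, F_g = f_g, F_r = f_r, F_acc = f_acc,
                 F_c = f_air + f_g + f_r + f_acc, V_rel = v_rel),
            class = "velo_forces")
}

#' Pedal power required to sustain a total force at a speed
#'
#' `P = max(F_c * v, 0)`. In force equilibrium the rider's output power
#' equals the power of the total resistance; negative products (a
#' gravity-assisted descent) clamp to zero because the rider cannot absorb
#' energy through the pedals.
#'
#' @param f_c total resistive force (N), may be negative.
#' @param v rider speed (m/s, >= 0).
#' @return Power (W, >= 0). Vectorized.
#' @examples
#' required_power(30, 10)   # 300
#' required_power(-50, 12)  # 0
#' @export
required_power <- function(f_c, v) {
  if (any(v < 0)) vp_validation_error("'v' must be >= 0")
  pmax(f_c * v, 0)
}

#' Steady-state speed at a given pedal power
#'
#' Inverts the power--speed relation: finds the unique `v >= 0` solving
#' `P = F_c(v) * v` at zero acceleration by bracketed root-finding
#' ([stats::uniroot()], relative tolerance 1e-9). On descents (or with a
#' strong tailwind) where the resistive force is negative at low speed, the
#' solution lies at or above the coasting terminal speed, the root of
#' `F_c(v) = 0`; `P = 0` then returns the terminal speed itself.
#'
#' @param P pedal power (W, >= 0).
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param segment a one-row [velo_course()].
#' @param v_ceiling hard bracket ceiling (m/s); exceeding it raises a
#'   numerical error.
#' @return Speed (m/s).
#' @examples
#' seg <- velo_course(100, grade_pct = 0)
#' speed_at_power(300, rider(), race_env(), seg)
#' @export
speed_at_power <- function(P, rider, env, segment, v_ceiling = 40) {
  stopifnot_scalar(P, "P", 0)
  seg <- as_segment(segment)
  fc <- function(v) force_breakdown(rider, env, seg, v)$F_c
  pw <- function(v) fc(v) * v

  fc0 <- fc(0)
  v_lo <- 0
  if (fc0 < 0) {
    if (fc(v_ceiling) < 0)
      vp_numerical_error(sprintf(
        "no terminal speed below the %g m/s ceiling (runaway descent)",
        v_ceiling))
    v_lo <- uniroot(fc, c(0, v_ceiling), tol = 1e-12)$root
    if (P == 0) return(v_lo)
  }
  if (P == 0) return(0)
  if (pw(v_ceiling) < P)
    vp_numerical_error(sprintf(
      "power %g W not reachable below the %g m/s ceiling", P, v_ceiling))
  uniroot(function(v) pw(v) - P, c(v_lo, v_ceiling), tol = 1e-12)$root
}

#' Recovery speed on a segment
#'
#' The speed sustainable at exactly the rider's recovery power on the given
#' segment: `speed_at_power(P_recover, ...)`. It is the lower speed bound on
#' flat and uphill segments during optimization; on descents where coasting
#' already exceeds the powered flat speed it equals the terminal speed.
#'
#' @inheritParams speed_at_power
#' @return Speed (m/s).
#' @export
recovery_speed <- function(rider, env, segment, v_ceiling = 40) {
  speed_at_power(rider$recovery_power, rider, env, segment,
                 v_ceiling = v_ceiling)
}
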