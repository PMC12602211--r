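# Racing-line corner geometry and friction-limited safe speeds.

#' Corner specification
#'
#' Geometry of a road corner: the inner-bend radius `r`, the road width
#' `d`, and the interior intersection angle `theta` of the two roads
#' (180 degrees means the roads continue straight through).
#'
#' @param r inner-bend radius (m, > 0).
#' @param d road width (m, >= 0).
#' @param theta_deg interior intersection angle (degrees, in (0, 180]).
#' @return A `velo_corner` list.
#' @examples
#' corner_spec(36.5, 0, 180)
#' @export
corner_spec <- function(r, d = 0, theta_deg = 90) {
  stopifnot_scalar(r, "r", 0, strict_lower = TRUE)
  stopifnot_scalar(d, "d", 0)
  stopifnot_scalar(theta_deg, "theta_deg", 0, 180, strict_lower = TRUE)
  structure(list(r = r, d = d, theta_deg = theta_deg),
            class = "velo_corner")
}

#' Largest turning radius through a corner
#'
#' The racing line through a corner is the arc of the largest circle that
#' fits in the junction: tangent to the outer road edges on entry and exit
#' and to the apex of the inner bend mid-corner. Its radius is
#' `R = r + d * (1 - sin(theta / 2))`, which reduces to the inner radius
#' when the road has no width (`d = 0`) or continues straight through
#' (`theta = 180`).
#'
#' @param corner a [corner_spec()].
#' @return Effective turn radius R (m), always `>= r`.
#' @examples
#' max_turn_radius(corner_spec(10, 6, 90))  # 10 + 6 * (1 - sin(45 deg))
#' @export
max_turn_radius <- function(corner) {
  corner$r + corner$d * (1 - sin(deg2rad(corner$theta_deg) / 2))
}

#' Friction-limited safe corner speed
#'
#' The fastest speed through a corner at which the required centripetal
#' force does not exceed the tire grip limit: setting
#' `mu_sli * m * g = m * V^2 / R` gives `V_mb = sqrt(mu_sli * g * R)` with
#' `R` from [max_turn_radius()]. Mass cancels; grip (0.9 dry, 0.4 wet) and
#' geometry alone set the cap.
#'
#' @param corner a [corner_spec()].
#' @param env a [race_env()]; supplies `sliding_coeff` and `gravity`.
#' @return Safe speed V_mb (m/s).
#' @examples
#' safe_corner_speed(corner_spec(36.5, 0, 180), race_env())  # ~17.95
#' @export
safe_corner_speed <- function(corner, env) {
  sqrt(env$sliding_coeff * env$gravity * max_turn_radius(corner))
}

#' Per-segment speed caps for a course
#'
#' Combines the rider's class speed limits with the corner grip limits:
#' flat and uphill segments are capped at `v_max_flat` (the elite maximum
#' for the discipline), descents at `v_max_descent`, and segments carrying
#' a corner additionally at the corner's safe speed [safe_corner_speed()].
#'
#' @param course a [velo_course()].
#' @param env a [race_env()].
#' @param rider a [rider()].
#' @return A numeric vector of caps (m/s), one per segment, with attribute
#'   `corner_speed` (the V_mb per segment, `NA` where no corner).
#' @export
apply_corner_limits <- function(course, env, rider) {
  validate_course(course)
  class_cap <- ifelse(course$grade_angle < 0, rider$v_max_descent,
                      rider$v_max_flat)
  v_mb <- rep(NA_real_, nrow(course))
  idx <- which(!is.na(course$corner_r_m))
  for (i in idx) {
    v_mb[i] <- safe_corner_speed(
      corner_spec(course$corner_r_m[i], course$corner_d_m[i],
                  course$corner_theta_deg[i]), env)
  }
  caps <- pmin(class_cap, v_mb, na.rm = TRUE)
  attr(caps, "corner_speed") <- v_mb
  caps
}

#' Per-segment speed bounds for optimization
#'
#' The search interval for each segment's speed gene: the lower bound is
#' the recovery speed (the speed sustainable at `P_recover`), the upper
#' bound the cap from [apply_corner_limits()]. The lower bound is clipped
#' to the cap so the interval is never empty (on steep descents the
#' coasting terminal speed can exceed the cap; the interval then collapses
#' to the cap).
#'
#' @inheritParams apply_corner_limits
#' @return A list with numeric vectors `lower` and `upper` (m/s) and
#'   `cap`/`corner_speed` diagnostics.
#' @export
speed_bounds <- function(course, env, rider) {
  caps <- apply_corner_limits(course, env, rider)
  v_rec <- vapply(seq_len(nrow(course)), function(i)
    recovery_speed(rider, env, course[i, , drop = FALSE]), numeric(1))
  lower <- pmin(v_rec, caps)
  bad <- which(lower > caps)
  if (length(bad))
    vp_validation_error(sprintf(
      "segment %d has infeasible speed bounds (lower %g > upper %g)",
      bad[1], lower[bad[1]], caps[bad[1]]))
  list(lower = lower, upper = as.numeric(caps),
       recovery_speed = v_rec, corner_speed = attr(caps, "corner_speed"))
}
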