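# Shared toy world for exact-arithmetic checks: constants chosen so that
# 1/2 * C * rho * S = 0.2 and mu * m * g = 3, giving the flat-road cubic
# P(v) = 0.2 v^3 + 3 v (so P(10) = 230 W exactly).

toy_env <- function(...) {
  race_env(air_density = 1, gravity = 9.81,
           rolling_coeff = 3 / (75 * 9.81), ...)
}

toy_rider <- function(recovery_power = 200, energy_budget = 15000, ...) {
  rider(mass = 75, drag_coeff = 0.4, frontal_area = 1,
        recovery_power = recovery_power, energy_budget = energy_budget, ...)
}

# flat / uphill / flat, 500 m each
toy_course_3seg <- function(up_grade_pct = 4) {
  velo_course(length_m = c(500, 500, 500),
              grade_pct = c(0, up_grade_pct, 0),
              name = "toy 3-segment")
}

flat_segment <- function(length_m = 1000, heading_deg = 0) {
  velo_course(length_m, grade_pct = 0, heading_deg = heading_deg)
}

# closed-form flat-road power for the toy world (independent oracle)
toy_flat_power <- function(v) 0.2 * v^3 + 3 * v
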