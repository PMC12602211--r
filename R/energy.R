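# Strategy simulation: per-segment times, powers, and the energy budget.

# Precompute everything about (course, rider, env) that does not depend on
# the speed vector, so that GA fitness evaluation is a handful of
# vectorized operations.
course_context <- function(course, rider, env) {
  validate_course(course)
  gamma <- course$grade_angle
  alpha <- env$wind_direction - course$heading_deg
  list(
    n = nrow(course),
    s = course$length_m,
    gamma = gamma,
    k_air = 0.5 * rider$drag_coeff * env$air_density * rider$frontal_area,
    f_r = env$rolling_coeff * rider$mass * env$gravity * cos(gamma),
    f_g = rider$mass * env$gravity * sin(gamma),
    wind_along = env$wind_speed * cos(deg2rad(alpha)),
    is_corner = !is.na(course$corner_r_m),
    mass = rider$mass,
    p_recover = rider$recovery_power,
    w_all = rider$energy_budget
  )
}

# Core simulation of a speed vector against a precomputed context.
# Corner segments are ridden at min(entry speed, V_mb) with zero pedal
# power (the rider cannot produce power mid-corner); v_mb comes from the
# bounds. recharge_rate > 0 credits a fraction of the power deficit below
# recovery back to the budget (cumulative balance floored at 0).
sim_fast <- function(v, ctx, v_mb = NULL, recharge_rate = 0) {
  v_eff <- v
  if (any(ctx$is_corner) && !is.null(v_mb)) {
    for (i in which(ctx$is_corner)) {
      entry <- if (i == 1L) v[i] else v_eff[i - 1L]
      v_eff[i] <- min(entry, v_mb[i])
    }
  }
  v_rel <- v_eff - ctx$wind_along
  f_air <- ctx$k_air * v_rel * abs(v_rel)
  f_c <- f_air + ctx$f_r + ctx$f_g
  p <- pmax(f_c * v_eff, 0)
  p[ctx$is_corner] <- 0
  t <- ctx$s / v_eff
  w_i <- pmax(p - ctx$p_recover, 0) * t
  if (recharge_rate > 0) {
    credit <- recharge_rate * pmax(ctx$p_recover - p, 0) * t
    bal <- 0
    for (i in seq_along(w_i)) {
      bal <- max(bal + w_i[i] - credit[i], 0)
    }
    w_total <- bal
  } else {
    w_total <- sum(w_i)
  }
  list(v_eff = v_eff, v_rel = v_rel, f_air = f_air, f_c = f_c,
       p = p, t = t, w_i = w_i, T = sum(t), W = w_total)
}

#' Simulate a pacing strategy over a course
#'
#' Rides the course at the given per-segment target speeds, assuming
#' constant speed (zero acceleration) within each segment. For each segment
#' the force balance, required power, traversal time, and net work above
#' recovery power `W_i = max(P_i - P_recover, 0) * t_i` are computed; the
#' total above-recovery work `W` is compared against the rider's budget
#' `W_all`. Segments carrying a corner are traversed at
#' `min(entry speed, V_mb)` with zero pedal power: the corner costs no
#' budget and its speed gene is advisory only.
#'
#' Net work below recovery is clamped at zero by default (coasting does not
#' refill the budget); set `recharge_rate > 0` to credit that fraction of
#' the sub-recovery power deficit back (cumulative balance floored at 0).
#'
#' The kinetic-energy difference between consecutive segments is reported
#' as the `accel_energy_J` diagnostic (sum of positive
#' `m/2 * (v_{i+1}^2 - v_i^2)`), but is *not* charged to the budget:
#' within-segment acceleration is outside the model.
#'
#' @param strategy numeric vector of target speeds (m/s), one per segment.
#' @param course a [velo_course()].
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param recharge_rate fraction of sub-recovery power deficit credited
#'   back to the budget (default 0 = off).
#' @return A `velo_sim` list: `segments` (a per-segment `data.frame` with
#'   speeds, forces, power, time and work), `total_time_s`, `total_work_J`,
#'   `budget_J`, `remaining_budget_J`, `accel_energy_J`, `bounds`, and
#'   `feasible` (all speeds within bounds and `W <= W_all`).
#' @examples
#' crs <- make_bridge_course()
#' simulate_strategy(10, crs, rider(), race_env())$total_time_s  # 150
#' @export
simulate_strategy <- function(strategy, course, rider, env,
                              recharge_rate = 0) {
  validate_course(course)
  if (length(strategy) != nrow(course))
    vp_validation_error(sprintf(
      "strategy has %d speeds but the course has %d segments",
      length(strategy), nrow(course)))
  if (any(!is.finite(strategy) | strategy <= 0))
    vp_validation_error("strategy speeds must be finite and > 0")
  ctx <- course_context(course, rider, env)
  bounds <- speed_bounds(course, env, rider)
  sim <- sim_fast(strategy, ctx, v_mb = bounds$corner_speed,
                  recharge_rate = recharge_rate)
  in_bounds <- all(strategy >= bounds$lower - 1e-9 &
                   strategy <= bounds$upper + 1e-9)
  ke <- 0.5 * rider$mass * diff(sim$v_eff^2)
  seg_df <- data.frame(
    length_m = ctx$s,
    grade_pct = 100 * tan(ctx$gamma),
    heading_deg = course$heading_deg,
    is_corner = ctx$is_corner,
    speed_target = strategy,
    speed_eff = sim$v_eff,
    V_rel = sim$v_rel,
    F_air = sim$f_air,
    F_g = ctx$f_g,
    F_r = ctx$f_r,
    F_acc = 0,
    F_c = sim$f_c,
    power_W = sim$p,
    time_s = sim$t,
    work_J = sim$w_i
  )
  structure(list(
    segments = seg_df,
    total_time_s = sim$T,
    total_work_J = sim$W,
    budget_J = rider$energy_budget,
    remaining_budget_J = rider$energy_budget - sim$W,
    accel_energy_J = sum(pmax(ke, 0)),
    bounds = bounds,
    feasible = in_bounds && sim$W <= rider$energy_budget + 1e-9
  ), class = "velo_sim")
}

#' @export
print.velo_sim <- function(x, ...) {
  cat(sprintf(
    "<velo_sim> T = %.2f s, W = %.1f J of %.1f J (%s)\n",
    x$total_time_s, x$total_work_J, x$budget_J,
    if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Net work above recovery power for one segment
#'
#' `W_i = max(P - P_recover, 0) * t`: riding above recovery power draws on
#' the finite budget in proportion to the excess power and the time spent;
#' riding at or below it costs nothing (and, by the default clamp, refunds
#' nothing).
#'
#' @param P segment power (W).
#' @param P_recover recovery power (W).
#' @param t segment time (s, >= 0).
#' @return Work above recovery (J, >= 0). Vectorized.
#' @examples
#' segment_net_work(300, 200, 10)  # 1000
#' @export
segment_net_work <- function(P, P_recover, t) {
  if (any(t < 0)) vp_validation_error("'t' must be >= 0")
  pmax(P - P_recover, 0) * t
}

#' Constant-power reference strategy
#'
#' The natural comparison strategy: ride every segment at one target power.
#' Given `P_target`, each segment's speed is
#' `min(speed_at_power(P_target), cap)`. When `P_target` is omitted, the
#' power that exactly exhausts the energy budget is found by bisection on
#' the simulated total work (tolerance 1 J). If even riding at the caps
#' cannot spend the budget, the capped strategy is returned with
#' `attr(, "budget_unattainable") = TRUE`.
#'
#' @param course a [velo_course()].
#' @param rider a [rider()].
#' @param env a [race_env()].
#' @param P_target target power (W, `>= recovery_power`); `NULL` (default)
#'   solves for the budget-exhausting power.
#' @param tol_J bisection tolerance on the spent budget (J).
#' @return Numeric speed vector with attributes `P_target`, `W` (spent
#'   budget), and `budget_unattainable`.
#' @export
constant_power_baseline <- function(course, rider, env, P_target = NULL,
                                    tol_J = 1) {
  validate_course(course)
  ctx <- course_context(course, rider, env)
  bounds <- speed_bounds(course, env, rider)

  speeds_at <- function(P) {
    v <- vapply(seq_len(ctx$n), function(i)
      speed_at_power(P, rider, env, course[i, , drop = FALSE]), numeric(1))
    pmin(pmax(v, bounds$lower), bounds$upper)
  }
  work_at <- function(v) sim_fast(v, ctx, v_mb = bounds$corner_speed)$W

  finish <- function(v, P, unattainable) {
    structure(v, P_target = P, W = work_at(v),
              budget_unattainable = unattainable)
  }

  if (!is.null(P_target)) {
    if (P_target < rider$recovery_power)
      vp_validation_error("'P_target' must be >= the recovery power")
    return(finish(speeds_at(P_target), P_target, FALSE))
  }

  v_cap <- bounds$upper
  w_cap <- work_at(v_cap)
  if (w_cap <= rider$energy_budget + tol_J) {
    # even full-gas at the caps fits in the budget
    p_cap <- max(sim_fast(v_cap, ctx, v_mb = bounds$corner_speed)$p)
    return(finish(v_cap, p_cap, w_cap < rider$energy_budget - tol_J))
  }
  lo <- rider$recovery_power             # W(lo) = 0 <= W_all always
  hi <- lo + 50
  while (work_at(speeds_at(hi)) < rider$energy_budget && hi < 1e5) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    w <- work_at(speeds_at(mid))
    if (abs(w - rider$energy_budget) <= tol_J) break
    if (w < rider$energy_budget) lo <- mid else hi <- mid
  }
  finish(speeds_at(mid), mid, FALSE)
}
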