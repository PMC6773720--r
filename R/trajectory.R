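#' Parabolic target trajectory with linear air drag
#'
#' Constructs the physical parameters of one target trajectory. The target is
#' launched rightwards and upwards (downwards for inverted gravity) and
#' decelerated by a drag force proportional to velocity, giving the equations
#' of motion x'' = -(c/m) x', y'' = -g - (c/m) y'. Their closed-form solution
#' is evaluated by [target_state()].
#'
#' Gravity is specified as a signed multiple of earth gravity. Positive
#' multiples start the target 0.5 m above the ground; the inverted condition
#' (`gravity_mult = -1`) is the mirror image: the target starts at 3.5 m,
#' moves downward, and "gravity" pulls it back up toward the ceiling. The
#' start x is placed so the trajectory is horizontally centred on the scene
#' (apex, or valley, at x = 0 in the drag-free limit).
#'
#' @param gravity_mult signed gravity multiple; the study uses
#'   -1, 0.7, 0.85, 1, 1.15, 1.3.
#' @param v_xi initial horizontal velocity, m/s (> 0; rightward).
#' @param v_yi initial vertical speed, m/s (> 0; direction follows the sign
#'   of `gravity_mult`).
#' @param m target mass, kg.
#' @param c linear drag coefficient, kg/s (0 gives the ballistic limit).
#' @param z_plane depth of the motion plane, m (constant).
#' @return an object of class `trajectory_params`.
#' @examples
#' p <- trajectory_params(1, v_xi = 3, v_yi = 6)
#' return_time(p)
#' @export
trajectory_params <- function(gravity_mult, v_xi, v_yi,
                              m = 0.057, c = 0.005, z_plane = -6.15) {
  stopifnot(length(gravity_mult) == 1, gravity_mult != 0,
            v_xi > 0, v_yi > 0, m > 0, c >= 0)
  g <- 9.81 * abs(gravity_mult)
  start_y <- if (gravity_mult > 0) 0.5 else 3.5
  p <- structure(
    list(gravity_mult = gravity_mult, g = g, v_xi = v_xi, v_yi = v_yi,
         m = m, c = c, start_x = 0, start_y = start_y, z_plane = z_plane),
    class = "trajectory_params")
  # centre the trajectory: start half the full horizontal extent to the left
  tr <- return_time(p)
  p$start_x <- -(p$v_xi * tr * phi1((p$c / p$m) * tr)) / 2
  p
}

#' @export
print.trajectory_params <- function(x, ...) {
  cat(sprintf(
    "Target trajectory: %g g (g = %.4f m/s^2), v_xi = %g m/s, v_yi = %g m/s\n",
    x$gravity_mult, x$g, x$v_xi, x$v_yi))
  cat(sprintf("  m = %g kg, c = %g kg/s, start = (%.4f, %.2f) m, z = %.2f m\n",
              x$m, x$c, x$start_x, x$start_y, x$z_plane))
  cat(sprintf("  flight time to return height: %.5f s\n", return_time(x)))
  invisible(x)
}

#' Target kinematic state at given times
#'
#' Evaluates position and velocity of the target under linear drag. With
#' k = c/m the closed forms are
#' \deqn{x(t) = x_0 + v_{xi}\, t\, \phi_1(kt), \quad
#'       y(t) = y_0 \pm (v_{yi}\, t\, \phi_1(kt) - g\, t^2 \phi_2(kt))}
#' where \eqn{\phi_1(u) = (1-e^{-u})/u}, \eqn{\phi_2(u) = (e^{-u}-1+u)/u^2},
#' and the sign mirrors the inverted-gravity condition. These are evaluated
#' with series branches near u = 0 so the ballistic limit c -> 0 is exact to
#' machine precision. Velocities are the analytic time derivatives.
#'
#' @param params a [trajectory_params()] object.
#' @param t numeric vector of times, s (all >= 0).
#' @return data.frame with columns `t, x, y, vx, vy` (y up-positive, signed).
#' @export
target_state <- function(params, t) {
  if (any(t < 0)) stop("t must be non-negative")
  k <- params$c / params$m
  g <- params$g
  u <- k * t
  sgn <- if (params$gravity_mult > 0) 1 else -1
  ekt <- exp(-u)
  dx <- params$v_xi * t * phi1(u)
  dy <- params$v_yi * t * phi1(u) - g * t^2 * phi2(u)
  data.frame(
    t = t,
    x = params$start_x + dx,
    y = params$start_y + sgn * dy,
    vx = params$v_xi * ekt,
    vy = sgn * (params$v_yi * ekt - g * t * phi1(u)))
}

#' Flight time back to the starting height
#'
#' Smallest t > 0 at which the target returns to its launch height
#' (y = 0.5 m, or 3.5 m for inverted gravity), found by bracketed root
#' search on the closed-form vertical displacement.
#'
#' @param params a [trajectory_params()] object.
#' @param t_max upper bracket for the search, s.
#' @return flight time, s.
#' @export
return_time <- function(params, t_max = 10) {
  k <- params$c / params$m
  g <- params$g
  # vertical displacement / t: v_yi * phi1(kt) - g t phi2(kt); positive at
  # 0+, negative once past the return point.
  f <- function(t) params$v_yi * phi1(k * t) - g * t * phi2(k * t)
  if (f(t_max) >= 0) stop("no return to start height within bracket")
  stats::uniroot(f, c(1e-9, t_max), tol = 1e-12)$root
}

#' Horizontal coincidence position
#'
#' The x position at which the target crosses its starting height again —
#' where the ball meets the table (or, inverted, the ceiling lamp).
#'
#' @param params a [trajectory_params()] object.
#' @return x position at the return time, m.
#' @export
coincidence_x <- function(params) {
  target_state(params, return_time(params))$x
}

#' Occlusion onset time
#'
#' The target disappears at a fraction of its flight time, drawn within the
#' short (20--25%) or long (45--50%) occlusion band.
#'
#' @param params a [trajectory_params()] object.
#' @param fraction occluded-onset fraction of the flight time; must lie in
#'   \[0.20, 0.25\] or \[0.45, 0.50\].
#' @return occlusion onset time, s.
#' @export
occlusion_onset <- function(params, fraction) {
  if (!((fraction >= 0.20 && fraction <= 0.25) ||
        (fraction >= 0.45 && fraction <= 0.50))) {
    stop("fraction must lie in [0.20, 0.25] (short) or [0.45, 0.50] (long)")
  }
  fraction * return_time(params)
}

#' Time-to-contact under an earth-gravity assumption
#'
#' Predicted remaining time for a target to cover a vertical distance `d_y`
#' toward the coincidence height, assuming drag-free fall at earth gravity.
#' Solving \eqn{d_y = (g/2) t^2 - v_{up} t} for the positive root gives
#' \deqn{t = \frac{v_{up} + \sqrt{v_{up}^2 + 2 g\, d_y}}{g}}
#' with \eqn{v_{up}} the upward-positive vertical velocity at occlusion onset
#' (negative solutions are discarded). Returns 0 when `d_y = 0` and the
#' target is not moving away from the coincidence height.
#'
#' @param v_y_last signed vertical velocity at occlusion onset, m/s,
#'   up-positive (i.e. away from the coincidence height).
#' @param d_y remaining vertical distance toward coincidence, m (>= 0).
#' @param g_earth assumed gravity, m/s^2.
#' @return predicted time to contact, s.
#' @examples
#' predict_ttc_1g(0, 4.905)  # free fall through 4.905 m: 1 s
#' @export
predict_ttc_1g <- function(v_y_last, d_y, g_earth = 9.81) {
  if (any(d_y < 0)) stop("d_y must be non-negative")
  (v_y_last + sqrt(v_y_last^2 + 2 * g_earth * d_y)) / g_earth
}

#' Export a sampled trajectory as a trial table
#'
#' Samples the target state on a regular clock (display 85 Hz or tracker
#' 200 Hz) and marks visibility against the occlusion onset.
#'
#' @param params a [trajectory_params()] object.
#' @param trial_id identifier copied into every row.
#' @param occ_fraction occlusion-onset fraction (see [occlusion_onset()]);
#'   `NULL` for a fully visible trajectory.
#' @param rate sampling rate, Hz.
#' @return data.frame with columns
#'   `trial_id, t, x, y, vx, vy, visible` (visible coded 0/1).
#' @export
sample_trajectory <- function(params, trial_id = 1L, occ_fraction = NULL,
                              rate = 200) {
  tr <- return_time(params)
  tt <- seq(0, tr, by = 1 / rate)
  st <- target_state(params, tt)
  t_occ <- if (is.null(occ_fraction)) Inf else occlusion_onset(params, occ_fraction)
  cbind(trial_id = trial_id, st, visible = as.integer(st$t < t_occ))
}
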