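# Target kinematics: closed-form drag solution against an independent ODE
# integration, ballistic limits, mirror symmetry, and the 1g TTC formula
# against a root-finding oracle.

design_combos <- expand.grid(g = c(0.7, 0.85, 1, 1.15, 1.3, -1),
                             v_yi = c(4.5, 6), v_xi = c(3, 4))

# independent oracle: numeric integration of x''=-(c/m)x', y''=-g_s-(c/m)y'
ode_state <- function(params, times) {
  g_signed <- 9.81 * params$gravity_mult
  deriv <- function(t, y, parms) {
    list(c(y[3], y[4], -(params$c / params$m) * y[3],
           -g_signed - (params$c / params$m) * y[4]))
  }
  sgn <- if (params$gravity_mult > 0) 1 else -1
  y0 <- c(params$start_x, params$start_y, params$v_xi, sgn * params$v_yi)
  deSolve::ode(y0, times, deriv, NULL, method = "rk4", hini = 1e-3)
}

test_that("state at t = 0 equals the launch conditions", {
  for (i in c(1, 6, 19)) {
    p <- trajectory_params(design_combos$g[i], design_combos$v_xi[i],
                           design_combos$v_yi[i])
    st <- target_state(p, 0)
    sgn <- if (design_combos$g[i] > 0) 1 else -1
    expect_equal(st$x, p$start_x)
    expect_equal(st$y, p$start_y)
    expect_equal(st$vx, p$v_xi)
    expect_equal(st$vy, sgn * p$v_yi)
  }
  expect_error(target_state(trajectory_params(1, 3, 6), -0.1), "non-negative")
})

test_that("vanishing drag reproduces the ballistic closed form", {
  p <- trajectory_params(1, 3, 6, c = 1e-12)
  st <- target_state(p, 0.5)
  expect_equal(st$y - p$start_y, 6 * 0.5 - 4.905 * 0.25, tolerance = 1e-9)
  expect_equal(return_time(p), 2 * 6 / 9.81, tolerance = 1e-8)
  # exact zero drag takes the same code path
  p0 <- trajectory_params(1, 3, 6, c = 0)
  tt <- seq(0, return_time(p0), length.out = 50)
  st0 <- target_state(p0, tt)
  expect_equal(st0$y, p0$start_y + 6 * tt - 4.905 * tt^2, tolerance = 1e-12)
  expect_equal(st0$x, p0$start_x + 3 * tt, tolerance = 1e-12)
})

test_that("drag trajectories converge to ballistic ones as c -> 0", {
  for (i in seq_len(nrow(design_combos))) {
    p_eps <- trajectory_params(design_combos$g[i], design_combos$v_xi[i],
                               design_combos$v_yi[i], c = 1e-10)
    p_0 <- trajectory_params(design_combos$g[i], design_combos$v_xi[i],
                             design_combos$v_yi[i], c = 0)
    tt <- seq(0, return_time(p_0), length.out = 40)
    a <- target_state(p_eps, tt); b <- target_state(p_0, tt)
    expect_lt(max(abs(a$x - b$x), abs(a$y - b$y)), 1e-6)
  }
})

test_that("drag solution matches RK4 integration on every design condition", {
  skip_if_not_installed("deSolve")
  for (i in seq_len(nrow(design_combos))) {
    p <- trajectory_params(design_combos$g[i], design_combos$v_xi[i],
                           design_combos$v_yi[i])
    tt <- seq(0, return_time(p), length.out = 25)
    ode <- ode_state(p, tt)
    st <- target_state(p, tt)
    expect_lt(max(abs(st$x - ode[, 2]), abs(st$y - ode[, 3])), 1e-6)
  }
})

test_that("return time agrees with the ODE-oracle flight time", {
  skip_if_not_installed("deSolve")
  p <- trajectory_params(1, 3, 6)
  tr <- return_time(p)
  # refine the oracle's crossing of the start height by interpolation
  tt <- seq(tr - 0.01, tr + 0.01, by = 1e-5)
  ode <- ode_state(p, c(0, tt))[-1, ]
  cross <- stats::approx(ode[, 3], tt, xout = p$start_y)$y
  expect_lt(abs(tr - cross), 1e-6)
  expect_lt(abs(coincidence_x(p) -
                stats::approx(tt, ode[, 2], xout = cross)$y), 1e-6)
})

test_that("inverted gravity mirrors the upright trajectory about y = 2 m", {
  p_up <- trajectory_params(1, 3, 6)
  p_dn <- trajectory_params(-1, 3, 6)
  tt <- seq(0, return_time(p_up), length.out = 60)
  a <- target_state(p_up, tt); b <- target_state(p_dn, tt)
  expect_equal(b$y, 4 - a$y, tolerance = 1e-12)
  expect_equal(b$x, a$x, tolerance = 1e-12)
  expect_equal(b$vy, -a$vy, tolerance = 1e-12)
  expect_equal(return_time(p_dn), return_time(p_up), tolerance = 1e-9)
})

test_that("the vertical extremum sits at x = 0 (ballistic) or nearby (drag)", {
  for (i in seq_len(nrow(design_combos))) {
    p0 <- trajectory_params(design_combos$g[i], design_combos$v_xi[i],
                            design_combos$v_yi[i], c = 0)
    t_peak <- stats::uniroot(function(t) target_state(p0, t)$vy,
                             c(1e-9, return_time(p0)), tol = 1e-12)$root
    expect_lt(abs(target_state(p0, t_peak)$x), 1e-8)
    pd <- trajectory_params(design_combos$g[i], design_combos$v_xi[i],
                            design_combos$v_yi[i])
    t_peak_d <- stats::uniroot(function(t) target_state(pd, t)$vy,
                               c(1e-9, return_time(pd)), tol = 1e-12)$root
    # the drag asymmetry grows with flight time; across the design it
    # stays below 2.5% of the horizontal half-extent (8 cm at worst)
    expect_lt(abs(target_state(pd, t_peak_d)$x), 0.025 * abs(pd$start_x))
  }
})

test_that("coincidence position is symmetric and obeys the ballistic scaling law", {
  p <- trajectory_params(1, 3, 4.5, c = 0)
  expect_equal(coincidence_x(p), -p$start_x, tolerance = 1e-9)
  expect_equal(coincidence_x(p), 3 * (2 * 4.5 / 9.81) / 2, tolerance = 1e-9)
  # ballistic range v_xi * 2 v_yi / g is invariant under g x 4 with both
  # launch velocities doubled
  p4 <- trajectory_params(4, 6, 9, c = 0)
  expect_equal(coincidence_x(p4) - p4$start_x, coincidence_x(p) - p$start_x,
               tolerance = 1e-9)
})

test_that("1g TTC equals the quadratic/bisection oracle", {
  expect_equal(predict_ttc_1g(0, 4.905), 1, tolerance = 1e-12)
  expect_equal(predict_ttc_1g(-9.81, 14.715), 1, tolerance = 1e-12)
  # bisection oracle on the displacement equation over a 100-point grid
  grid <- expand.grid(v = seq(-6, 6, length.out = 10),
                      d = seq(0.05, 4, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    v <- grid$v[i]; d <- grid$d[i]
    oracle <- stats::uniroot(function(t) (9.81 / 2) * t^2 - v * t - d,
                             c(0, 100), tol = 1e-12)$root
    expect_lt(abs(predict_ttc_1g(v, d) - oracle), 1e-9)
  }
  expect_equal(predict_ttc_1g(-1, 0), 0)
  expect_error(predict_ttc_1g(0, -0.1), "non-negative")
})

test_that("occlusion onset validates its fraction bands", {
  p <- trajectory_params(1, 3, 6, c = 1e-12)
  expect_equal(occlusion_onset(p, 0.5), 0.61162, tolerance = 1e-4)
  expect_equal(occlusion_onset(p, 0.25), 0.30581, tolerance = 1e-4)
  expect_error(occlusion_onset(p, 0.3), "fraction")
  expect_error(occlusion_onset(p, 0.55), "fraction")
  pd <- trajectory_params(1, 3, 6)
  expect_equal(occlusion_onset(pd, 0.45), 0.45 * return_time(pd))
})
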