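# Gaze preprocessing: stage-ordered filtering, scene mapping, Gaussian
# smoothing against a direct-convolution oracle, lagged kinematics against
# analytic derivatives, saccade classification and the pursuit gain.

make_trace <- function(n = 100, conf = 1, x = 0.5, y = 0.5) {
  data.frame(trial_id = 1L, t = (seq_len(n) - 1) / 200,
             x_surf = rep(x, n), y_surf = rep(y, n),
             confidence = rep(conf, n))
}

test_that("filter stages count against the remaining frames, in order", {
  tr <- make_trace(100)
  clean <- filter_trace(tr)
  expect_equal(clean$report$n_kept, 100)

  tr$confidence[1:10] <- 0.5
  tr$x_surf[11:15] <- 1.2
  tr$x_surf[16:17] <- NA
  f <- filter_trace(tr)
  expect_equal(f$report$n_low_confidence, 10)
  expect_equal(f$report$n_out_of_bounds, 5)
  expect_equal(f$report$n_missing, 2)
  expect_equal(f$report$n_kept, 83)
  expect_equal(f$report$n_kept,
               f$report$n_total - f$report$n_low_confidence -
                 f$report$n_out_of_bounds - f$report$n_missing)

  # a low-confidence out-of-bounds frame counts at the confidence stage
  tr2 <- make_trace(10)
  tr2$confidence[1] <- 0.1; tr2$x_surf[1] <- 2
  f2 <- filter_trace(tr2)
  expect_equal(f2$report$n_low_confidence, 1)
  expect_equal(f2$report$n_out_of_bounds, 0)

  # y_surf = -0.2 is inside the stated -0.3 lower bound
  tr3 <- make_trace(10, y = -0.2)
  expect_equal(filter_trace(tr3)$report$n_kept, 10)
  tr4 <- make_trace(10, y = -0.35)
  expect_equal(filter_trace(tr4)$report$n_out_of_bounds, 10)

  empty <- filter_trace(make_trace(5, conf = 0.1))
  expect_false(empty$report$valid)
})

test_that("surface-to-scene mapping is the depth ray-scaling and inverts exactly", {
  geom <- scene_geometry()
  ctr <- map_to_scene(0.5, 0.5, geom)
  expect_equal(ctr$x, 0)
  expect_equal(ctr$y, geom$eye_height)
  # 0.1 m right of centre on screen -> 0.3075 m right at stimulus depth
  p <- map_to_scene(0.5 + 0.1 / geom$screen_w, 0.5, geom)
  expect_equal(p$x, 0.1 * 6.15 / 2, tolerance = 1e-12)
  xs <- runif(50); ys <- runif(50, -0.3, 1)
  sc <- map_to_scene(xs, ys, geom)
  back <- scene_to_surface(sc$x, sc$y, geom)
  expect_equal(back$x, xs, tolerance = 1e-12)
  expect_equal(back$y, ys, tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves DC and interior ramps, matches direct convolution", {
  expect_equal(smooth_gaussian(rep(3.2, 50), 3), rep(3.2, 50))
  ramp <- seq(0, 1, length.out = 100)
  sm <- smooth_gaussian(ramp, 3)
  expect_equal(sm[20:80], ramp[20:80], tolerance = 1e-9)
  # direct-convolution oracle with the same reflected padding
  set.seed(1)
  x <- rnorm(80)
  sigma <- 2.5
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad <- c(x[(r + 1):2], x, x[(80 - 1):(80 - r)])
  oracle <- vapply(seq_along(x), function(i) {
    sum(k * pad[i:(i + 2 * r)])
  }, numeric(1))
  expect_equal(smooth_gaussian(x, sigma), oracle, tolerance = 1e-12)
})

test_that("lagged tangential velocity matches uniform and analytic motion", {
  t <- (0:199) / 200
  v <- tangential_velocity(t, 2 * t * 0.6, 2 * t * 0.8)  # 2 m/s straight line
  expect_equal(v[!is.na(v)], rep(2, sum(!is.na(v))), tolerance = 1e-9)
  v0 <- tangential_velocity(t, rep(0.3, 200), rep(0.1, 200))
  expect_equal(v0[!is.na(v0)], rep(0, sum(!is.na(v0))), tolerance = 1e-12)
  # simulated target trace: within 1% of the analytic tangential speed
  p <- trajectory_params(1, 3, 6)
  tt <- seq(0, return_time(p), by = 1 / 200)
  st <- target_state(p, tt)
  v_hat <- tangential_velocity(tt, st$x, st$y)
  v_true <- sqrt(st$vx^2 + st$vy^2)
  interior <- which(!is.na(v_hat))
  rel <- abs(v_hat[interior] - v_true[interior]) / v_true[interior]
  expect_lt(max(rel), 0.01)
})

test_that("velocity and acceleration are masked across large gaps", {
  t <- c((0:49) / 200, (50:99) / 200 + 1)   # 1 s gap in the middle
  x <- 2 * t; y <- rep(0, 100)
  v <- tangential_velocity(t, x, y)
  # windows i = 51..59 span the gap and are assigned to samples 46..54
  expect_true(all(is.na(v[46:54])))
  expect_false(anyNA(v[10:45]))
  expect_false(anyNA(v[56:90]))
  a <- acceleration(t, v)
  expect_true(all(is.na(a[46:54])))
  expect_false(all(is.na(a)))
})

test_that("lagged acceleration recovers a constant ramp within 1%", {
  t <- (0:299) / 200
  v <- 1 + 3 * t   # constant tangential acceleration of 3 m/s^2
  a <- acceleration(t, v)
  expect_equal(a[!is.na(a)], rep(3, sum(!is.na(a))), tolerance = 0.01)
  a0 <- acceleration(t, rep(2, 300))
  expect_equal(a0[!is.na(a0)], rep(0, sum(!is.na(a0))), tolerance = 1e-12)
})

test_that("saccade classification applies both thresholds and the merge rules", {
  n <- 200
  t <- (seq_len(n) - 1) / 200
  tsp <- rep(6, n)
  # eye speed at a constant 1.6x target speed: everything saccadic
  cl <- classify_saccades(t, rep(9.6, n), rep(0, n), tsp)
  expect_equal(nrow(cl$segments), 1)
  expect_true(all(cl$mask))
  # sub-threshold pursuit: nothing
  cl0 <- classify_saccades(t, rep(6, n), rep(0, n), tsp)
  expect_equal(nrow(cl0$segments), 0)
  # two bursts 1 sample apart merge under merge_gap = 2
  v <- rep(6, n); v[50:54] <- 20; v[56:60] <- 20
  cl2 <- classify_saccades(t, v, rep(0, n), tsp)
  expect_equal(nrow(cl2$segments), 1)
  expect_equal(cl2$segments$onset, 50)
  expect_equal(cl2$segments$offset, 60)
  # sub-minimum-duration bursts are dropped
  v3 <- rep(6, n); v3[100] <- 30
  expect_equal(nrow(classify_saccades(t, v3, rep(0, n), tsp)$segments), 0)
  # acceleration criterion alone suffices, in either sign
  a4 <- rep(0, n); a4[120:124] <- 400; a4[150:154] <- -400
  cl4 <- classify_saccades(t, rep(6, n), a4, tsp)
  expect_equal(nrow(cl4$segments), 2)
})

test_that("injected minimum-jerk saccades are localized within 2 samples", {
  p <- trajectory_params(1, 3, 6)
  tt <- seq(0, return_time(p), by = 1 / 200)
  st <- target_state(p, tt)
  n <- length(tt)
  mj <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  amp <- 2 * pi / 180 * 6.15      # 2 degrees at the stimulus plane
  dur <- 6                        # ~30 ms, main-sequence duration for 2 deg
  gain <- 0.9
  ex <- st$x[1] + gain * (st$x - st$x[1])
  ey <- st$y[1] + gain * (st$y - st$y[1])
  onsets <- c(60, 150)
  for (o in onsets) {
    tau <- pmin(pmax((seq_len(n) - o) / dur, 0), 1)
    # catch-up saccades point along the target's path at their onset
    dir <- c(st$vx[o], st$vy[o]) / sqrt(st$vx[o]^2 + st$vy[o]^2)
    ex <- ex + amp * dir[1] * mj(tau)
    ey <- ey + amp * dir[2] * mj(tau)
  }
  xs <- smooth_gaussian(ex, 3); ys <- smooth_gaussian(ey, 3)
  v <- tangential_velocity(tt, xs, ys)
  a <- acceleration(tt, v)
  cl <- classify_saccades(tt, v, a, sqrt(st$vx^2 + st$vy^2))
  expect_equal(nrow(cl$segments), 2)
  expect_true(all(abs(cl$segments$onset - onsets) <= 2))
  # and no false positives on the saccade-free version, up to gain 1.2
  for (g2 in c(0.8, 1.0, 1.2)) {
    e2x <- smooth_gaussian(st$x[1] + g2 * (st$x - st$x[1]), 3)
    e2y <- smooth_gaussian(st$y[1] + g2 * (st$y - st$y[1]), 3)
    v2 <- tangential_velocity(tt, e2x, e2y)
    a2 <- acceleration(tt, v2)
    expect_equal(nrow(classify_saccades(tt, v2, a2,
                                        sqrt(st$vx^2 + st$vy^2))$segments), 0)
  }
})

test_that("pursuit gain averages eligible samples and flags empty windows", {
  n <- 200
  t <- (seq_len(n) - 1) / 200
  tsp <- rep(6, n)
  v <- rep(6, n); v[40:45] <- 30    # one catch-up saccade
  cl <- classify_saccades(t, v, rep(0, n), tsp)
  s <- compute_gain(t, v, tsp, cl, t_occ = 0.9, mask_pad = 0)
  expect_true(s$valid)
  expect_equal(s$gain, 1, tolerance = 1e-6)
  expect_equal(s$first_catchup_offset_t, cl$segments$offset_t[1])
  # everything saccadic after the catch-up: invalid
  v2 <- rep(30, n)
  cl2 <- classify_saccades(t, v2, rep(0, n), tsp)
  s2 <- compute_gain(t, v2, tsp, cl2, t_occ = 0.9, mask_pad = 0)
  expect_false(s2$valid)
  # no saccade at all and no fallback: invalid; with fallback: valid
  cl3 <- classify_saccades(t, rep(5.4, n), rep(0, n), tsp)
  s3 <- compute_gain(t, rep(5.4, n), tsp, cl3, t_occ = 0.9)
  expect_false(s3$valid)
  s4 <- compute_gain(t, rep(5.4, n), tsp, cl3, t_occ = 0.9,
                     fallback_start = 0.2)
  expect_true(s4$valid)
  expect_equal(s4$gain, 0.9, tolerance = 1e-9)
})

test_that("the preprocessing pipeline is deterministic", {
  cond <- list(gravity_mult = 1, v_xi = 3, v_yi = 6, occ_fraction = 0.22)
  tr <- simulate_trial_gaze(cond, oculomotor_profile(), seed = 11)
  p <- trajectory_params(1, 3, 6)
  t_occ <- 0.22 * return_time(p)
  a <- preprocess_trial(tr, p, t_occ)
  b <- preprocess_trial(tr, p, t_occ)
  expect_identical(a, b)
})
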