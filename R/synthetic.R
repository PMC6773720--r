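# Synthetic oculomotor and response generators. These produce gaze traces
# and button presses with the statistical structure the analysis assumes
# (per-subject random intercepts in gain, catch-up saccades, confidence
# dropouts, 1g-extrapolation-plus-noise timing), so the whole downstream
# pipeline is testable without recorded data.

#' Oculomotor generative profile
#'
#' Parameters of the synthetic eye. `gain_true` is the pursuit gain
#' (eye speed / target speed); it may be a single number or a vector named
#' by gravity multiple. The default per-gravity gains place 1 g pursuit at
#' 0.80 and offset the other gravities by the graded differences the
#' paradigm is designed to detect (higher gain below 1 g, lower above,
#' and a 0.13 deficit for inverted gravity).
#'
#' Variability defaults follow the design assumption that trial-to-trial
#' variability is 6 times the between-subject variability: subject
#' intercept SD 0.037 and trial SD 0.222 gain units (the trial SD is what a
#' reported contrast standard error of 0.005 over ~1900 trials per level
#' implies). The dropout rate defaults to 6.4% of frames.
#'
#' @param gain_true pursuit gain, scalar or named by gravity multiple.
#' @param pursuit_latency pursuit onset latency, s; the first catch-up
#'   saccade is launched here.
#' @param catchup_threshold positional eye-target error (m) that triggers a
#'   catch-up saccade during visible pursuit.
#' @param saccade_duration duration of an inserted saccade, s.
#' @param dropout_rate probability a sample's confidence falls below 0.9.
#' @param pos_noise_sd isotropic gaze position noise, m (scene units).
#' @param subject_intercept_sd SD of per-subject gain intercepts.
#' @param trial_noise_sd SD of per-trial gain noise.
#' @param occlusion_saccade insert a predictive saccade after occlusion
#'   onset toward the 1g-extrapolated coincidence point?
#' @param occlusion_saccade_latency latency of that saccade after occlusion
#'   onset, s.
#' @param gain_decay_tau exponential time constant of pursuit gain decay
#'   after occlusion, s.
#' @return list of class `oculomotor_profile`.
#' @export
oculomotor_profile <- function(gain_true = c("0.7" = 0.853, "0.85" = 0.829,
                                             "1" = 0.8, "1.15" = 0.757,
                                             "1.3" = 0.735, "-1" = 0.67),
                               pursuit_latency = 0.15,
                               catchup_threshold = 0.3,
                               saccade_duration = 0.05,
                               dropout_rate = 0.064,
                               pos_noise_sd = 0.005,
                               subject_intercept_sd = 0.037,
                               trial_noise_sd = 6 * subject_intercept_sd,
                               occlusion_saccade = TRUE,
                               occlusion_saccade_latency = 0.21,
                               gain_decay_tau = 0.3) {
  stopifnot(all(gain_true > 0), dropout_rate >= 0, dropout_rate < 1,
            pursuit_latency >= 0, saccade_duration > 0)
  structure(list(gain_true = gain_true, pursuit_latency = pursuit_latency,
                 catchup_threshold = catchup_threshold,
                 saccade_duration = saccade_duration,
                 dropout_rate = dropout_rate, pos_noise_sd = pos_noise_sd,
                 subject_intercept_sd = subject_intercept_sd,
                 trial_noise_sd = trial_noise_sd,
                 occlusion_saccade = occlusion_saccade,
                 occlusion_saccade_latency = occlusion_saccade_latency,
                 gain_decay_tau = gain_decay_tau),
            class = "oculomotor_profile")
}

#' Response-timing generative behaviour
#'
#' The synthetic button press mixes a 1g-extrapolation estimate of the
#' occluded duration with the cohort-mean occluded duration (a central
#' tendency), adds Gaussian motor noise, and is delayed by the projection
#' system.
#'
#' @param lambda_central mixture weight on the central-tendency predictor
#'   (0 = pure 1g extrapolation, 1 = pure central tendency).
#' @param motor_noise_sd SD of motor/decision noise, s.
#' @param response_offset constant response bias, s.
#' @param system_delay apparatus delay added to every response, s.
#' @return list of class `timing_behavior`.
#' @export
timing_behavior <- function(lambda_central = 0, motor_noise_sd = 0.08,
                            response_offset = 0, system_delay = 0.049259) {
  stopifnot(lambda_central >= 0, lambda_central <= 1,
            motor_noise_sd >= 0, system_delay >= 0)
  structure(list(lambda_central = lambda_central,
                 motor_noise_sd = motor_noise_sd,
                 response_offset = response_offset,
                 system_delay = system_delay),
            class = "timing_behavior")
}

# per-gravity gain lookup
resolve_gain <- function(gain_true, gravity_mult) {
  if (length(gain_true) == 1 && is.null(names(gain_true))) {
    return(unname(gain_true))
  }
  key <- as.character(gravity_mult)
  if (!key %in% names(gain_true)) {
    stop("no gain_true entry for gravity ", key)
  }
  unname(gain_true[[key]])
}

# state of the (drag) stimulus at occlusion onset, expressed in the frame in
# which gravity points toward the coincidence height: v_up is the velocity
# away from coincidence, d_y the remaining distance toward it
occlusion_state <- function(params, fraction) {
  tr <- return_time(params)
  t_occ <- occlusion_onset(params, fraction)
  st <- target_state(params, t_occ)
  sgn <- if (params$gravity_mult > 0) 1 else -1
  list(t_occ = t_occ, return_time = tr, remaining = tr - t_occ,
       x = st$x, vx = st$vx,
       v_up = sgn * st$vy, d_y = sgn * (st$y - params$start_y))
}

# minimum-jerk position fraction on tau in [0, 1]
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate one trial's gaze trace
#'
#' The synthetic eye fixates the launch point, launches a catch-up saccade
#' at the pursuit latency, and thereafter moves with displacement equal to
#' `gain` times the target displacement. Whenever the accumulated position
#' error exceeds the catch-up threshold during visible motion, a
#' minimum-jerk saccade realigns the eye with the (extrapolated) target
#' position at the saccade's end. After occlusion onset the pursuit gain
#' decays exponentially and, optionally, one predictive saccade is made
#' toward the 1g-extrapolated coincidence point. Gaussian position noise is
#' added, confidence values are drawn below 0.9 for dropout samples, and
#' the scene path is mapped to surface coordinates with the inverse of
#' [map_to_scene()].
#'
#' @param cond list or one-row data.frame with `gravity_mult, v_xi, v_yi,
#'   occ_fraction` (and optionally `trial_id`).
#' @param profile an [oculomotor_profile()].
#' @param seed integer seed.
#' @param gain_offset additive gain deviation for this trial (subject
#'   intercept plus trial noise), applied to the profile's per-gravity gain.
#' @param geometry a [scene_geometry()].
#' @param rate sampling rate, Hz.
#' @return data.frame `trial_id, t, x_surf, y_surf, confidence`.
#' @export
simulate_trial_gaze <- function(cond, profile, seed = 1L, gain_offset = 0,
                                geometry = scene_geometry(), rate = 200) {
  params <- trajectory_params(cond$gravity_mult, cond$v_xi, cond$v_yi)
  occ <- occlusion_state(params, cond$occ_fraction)
  t_end <- occ$return_time
  tt <- seq(0, t_end, by = 1 / rate)
  n <- length(tt)
  st <- target_state(params, tt)
  gain0 <- resolve_gain(profile$gain_true, cond$gravity_mult) + gain_offset
  dur_i <- max(2L, round(profile$saccade_duration * rate))

  ex <- numeric(n); ey <- numeric(n)
  ex[1] <- st$x[1]; ey[1] <- st$y[1]
  sac_end <- 0L           # last sample index of the saccade in progress
  sac_from <- c(NA, NA); sac_to <- c(NA, NA); sac_start <- 0L
  first_done <- FALSE; occ_sac_done <- !isTRUE(profile$occlusion_saccade)

  launch <- function(i, land) {
    sac_start <<- i; sac_end <<- min(n, i + dur_i - 1L)
    sac_from <<- c(ex[i - 1], ey[i - 1]); sac_to <<- land
  }
  for (i in 2:n) {
    visible <- tt[i] < occ$t_occ
    if (i <= sac_end) {
      tau <- (i - sac_start + 1) / (sac_end - sac_start + 1)
      s <- min_jerk(tau)
      ex[i] <- sac_from[1] + s * (sac_to[1] - sac_from[1])
      ey[i] <- sac_from[2] + s * (sac_to[2] - sac_from[2])
      next
    }
    gain_i <- if (!first_done) {
      0  # fixation at the launch point until the first catch-up saccade
    } else if (visible) {
      gain0
    } else {
      gain0 * exp(-(tt[i] - occ$t_occ) / profile$gain_decay_tau)
    }
    ex[i] <- ex[i - 1] + gain_i * (st$x[i] - st$x[i - 1])
    ey[i] <- ey[i - 1] + gain_i * (st$y[i] - st$y[i - 1])
    if (visible) {
      err <- sqrt((ex[i] - st$x[i])^2 + (ey[i] - st$y[i])^2)
      trigger <- (!first_done && tt[i] >= profile$pursuit_latency) ||
        (first_done && err > profile$catchup_threshold)
      if (trigger) {
        first_done <- TRUE
        j <- min(n, i + dur_i - 1L)
        launch(i, c(st$x[j], st$y[j]))  # land on the target's future position
        tau <- 1 / (sac_end - sac_start + 1)
        s <- min_jerk(tau)
        ex[i] <- sac_from[1] + s * (sac_to[1] - sac_from[1])
        ey[i] <- sac_from[2] + s * (sac_to[2] - sac_from[2])
      }
    } else if (!occ_sac_done &&
               tt[i] >= occ$t_occ + profile$occlusion_saccade_latency) {
      # predictive saccade to the 1g-extrapolated coincidence point
      ttc <- predict_ttc_1g(occ$v_up, occ$d_y)
      land_x <- occ$x + occ$vx * ttc
      occ_sac_done <- TRUE
      launch(i, c(land_x, params$start_y))
      tau <- 1 / (sac_end - sac_start + 1)
      s <- min_jerk(tau)
      ex[i] <- sac_from[1] + s * (sac_to[1] - sac_from[1])
      ey[i] <- sac_from[2] + s * (sac_to[2] - sac_from[2])
    }
  }

  with_seed(seed, {
    if (profile$pos_noise_sd > 0) {
      ex <- ex + stats::rnorm(n, 0, profile$pos_noise_sd)
      ey <- ey + stats::rnorm(n, 0, profile$pos_noise_sd)
    }
    drop <- stats::runif(n) < profile$dropout_rate
    conf <- ifelse(drop, stats::runif(n, 0, 0.9), stats::runif(n, 0.9, 1))
    surf <- scene_to_surface(ex, ey, geometry)
    data.frame(trial_id = if (!is.null(cond$trial_id)) cond$trial_id else 1L,
               t = tt, x_surf = surf$x, y_surf = surf$y, confidence = conf)
  })
}

#' Simulate one button-press response time
#'
#' Response = occlusion onset + mixture of the 1g-extrapolated time to
#' contact and the cohort-mean occluded duration, plus Gaussian motor noise
#' and the system delay.
#'
#' @param cond list with `gravity_mult, v_xi, v_yi, occ_fraction`.
#' @param behavior a [timing_behavior()].
#' @param mean_occluded cohort-mean occluded duration, s (required when
#'   `lambda_central > 0`).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param params optional [trajectory_params()] overriding the default
#'   (drag) stimulus built from `cond`, e.g. a ballistic variant.
#' @return response time from motion onset, s.
#' @export
simulate_response <- function(cond, behavior, mean_occluded = NULL,
                              seed = NULL, params = NULL) {
  if (is.null(params)) {
    params <- trajectory_params(cond$gravity_mult, cond$v_xi, cond$v_yi)
  }
  occ <- occlusion_state(params, cond$occ_fraction)
  lam <- behavior$lambda_central
  if (lam > 0 && is.null(mean_occluded)) {
    stop("mean_occluded is required when lambda_central > 0")
  }
  ttc <- predict_ttc_1g(occ$v_up, occ$d_y)
  central <- if (lam > 0) mean_occluded else 0
  noise_fun <- function() stats::rnorm(1, behavior$response_offset,
                                       behavior$motor_noise_sd)
  noise <- if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
  occ$t_occ + (1 - lam) * ttc + lam * central + noise + behavior$system_delay
}

#' Simulate a cohort's tidy trial dataset
#'
#' Generates per-subject experiment plans ([build_experiment()], inversion
#' block first for odd-numbered subjects), draws per-subject gain
#' intercepts and per-trial gain noise, and produces per-trial response
#' times from the timing behaviour. Gains are generated at the statistical
#' level (the same generative model the trace simulator realizes sample by
#' sample); full gaze traces for each trial are returned on request.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param profile an [oculomotor_profile()].
#' @param behavior a [timing_behavior()].
#' @param seed integer seed.
#' @param include_training keep training-block trials in the output?
#' @param raw_traces also simulate and return the gaze trace of every trial
#'   (slow; intended for small plans)?
#' @return data.frame with one row per trial: subject, block and condition
#'   columns, `t_occ`, `occluded_duration`, `t_coincidence`, `gain`,
#'   `t_response`. With `raw_traces = TRUE` the traces are attached as a
#'   list attribute `"traces"`.
#' @export
simulate_cohort <- function(n_subjects = 10, profile = oculomotor_profile(),
                            behavior = timing_behavior(), seed = 1L,
                            include_training = FALSE, raw_traces = FALSE) {
  stopifnot(n_subjects >= 2)
  seeds <- with_seed(seed, sample.int(2^31 - 1, n_subjects + 1))
  intercepts <- with_seed(seeds[n_subjects + 1],
                          stats::rnorm(n_subjects, 0, profile$subject_intercept_sd))
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    plan <- build_experiment(sprintf("s%02d", s),
                             inversion_first = (s %% 2 == 1), seed = seeds[s])
    trials <- plan$trials
    if (!include_training) {
      trials <- trials[trials$block_type != "training", , drop = FALSE]
    }
    n <- nrow(trials)
    # cache flight kinematics per unique condition cell
    key <- paste(trials$gravity_mult, trials$v_xi, trials$v_yi)
    ucells <- !duplicated(key)
    cache <- list()
    for (i in which(ucells)) {
      cache[[key[i]]] <- trajectory_params(trials$gravity_mult[i],
                                           trials$v_xi[i], trials$v_yi[i])
    }
    tr_time <- vapply(cache, return_time, numeric(1))[key]
    t_occ <- trials$occ_fraction * tr_time
    v_up <- numeric(n); d_y <- numeric(n)
    for (k in names(cache)) {
      idx <- which(key == k)
      p <- cache[[k]]
      stk <- target_state(p, t_occ[idx])
      sgn <- if (p$gravity_mult > 0) 1 else -1
      v_up[idx] <- sgn * stk$vy
      d_y[idx] <- sgn * (stk$y - p$start_y)
    }
    ttc <- predict_ttc_1g(v_up, d_y)
    occluded <- tr_time - t_occ
    # cohort-mean occluded duration per block type (the central tendency)
    mean_occ <- stats::ave(occluded, trials$block_type)
    lam <- behavior$lambda_central
    trial_stats <- with_seed(seeds[s] + 1L, {
      gain <- vapply(trials$gravity_mult,
                     function(gm) resolve_gain(profile$gain_true, gm),
                     numeric(1)) +
        intercepts[s] + stats::rnorm(n, 0, profile$trial_noise_sd)
      noise <- stats::rnorm(n, behavior$response_offset,
                            behavior$motor_noise_sd)
      list(gain = gain, noise = noise)
    })
    trials$t_occ <- t_occ
    trials$occluded_duration <- occluded
    trials$t_coincidence <- tr_time
    trials$gain <- trial_stats$gain
    trials$t_response <- t_occ + (1 - lam) * ttc + lam * mean_occ +
      trial_stats$noise + behavior$system_delay
    out[[s]] <- trials
  }
  dat <- do.call(rbind, out)
  rownames(dat) <- NULL
  if (raw_traces) {
    traces <- vector("list", nrow(dat))
    for (i in seq_len(nrow(dat))) {
      traces[[i]] <- simulate_trial_gaze(
        as.list(dat[i, ]), profile, seed = seeds[1] + i,
        gain_offset = dat$gain[i] -
          resolve_gain(profile$gain_true, dat$gravity_mult[i]))
    }
    attr(dat, "traces") <- traces
  }
  dat
}
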