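# Gaze preprocessing: surface -> scene mapping, confidence/bounds filtering,
# Gaussian position smoothing, lagged kinematics, threshold saccade
# classification and the per-trial pursuit gain.

#' Viewing geometry of the display and stimulus plane
#'
#' Physical geometry linking surface-normalized gaze coordinates (0--1 on the
#' back-projection screen) to scene coordinates at the stimulus depth. Gaze
#' points on the screen plane are ray-scaled about the viewpoint by the
#' depth ratio `stim_depth / screen_dist` (3.075 for the defaults), so gaze
#' positions and velocities are expressed where the line of sight crosses
#' the stimulus plane.
#'
#' @param screen_w,screen_h screen width and height, m.
#' @param screen_dist viewing distance to the screen, m.
#' @param stim_depth unsigned depth of the stimulus plane, m.
#' @param eye_height height of the viewpoint above the ground, m.
#' @param screen_center_y height of the screen centre above the ground, m.
#' @return a list of class `scene_geometry`.
#' @export
scene_geometry <- function(screen_w = 1.84, screen_h = 2.44, screen_dist = 2,
                           stim_depth = 6.15, eye_height = 1.22,
                           screen_center_y = 1.22) {
  structure(list(screen_w = screen_w, screen_h = screen_h,
                 screen_dist = screen_dist, stim_depth = stim_depth,
                 eye_height = eye_height, screen_center_y = screen_center_y),
            class = "scene_geometry")
}

#' Map surface-normalized gaze to scene coordinates
#'
#' Surface coordinates (x right, y up, (0,0) bottom-left of the screen) are
#' converted to screen-plane metres and scaled to the stimulus depth by
#' similar triangles about the viewpoint.
#'
#' @param x_surf,y_surf surface-normalized gaze coordinates.
#' @param geometry a [scene_geometry()] object.
#' @return list with scene-coordinate vectors `x` and `y` (m).
#' @export
map_to_scene <- function(x_surf, y_surf, geometry = scene_geometry()) {
  s <- geometry$stim_depth / geometry$screen_dist
  x_scr <- (x_surf - 0.5) * geometry$screen_w
  y_scr <- (y_surf - 0.5) * geometry$screen_h +
    geometry$screen_center_y - geometry$eye_height
  list(x = x_scr * s, y = geometry$eye_height + y_scr * s)
}

#' Inverse of [map_to_scene()]
#'
#' @param x_scene,y_scene scene coordinates at the stimulus depth, m.
#' @param geometry a [scene_geometry()] object.
#' @return list with surface-normalized vectors `x` and `y`.
#' @export
scene_to_surface <- function(x_scene, y_scene, geometry = scene_geometry()) {
  s <- geometry$stim_depth / geometry$screen_dist
  x_scr <- x_scene / s
  y_scr <- (y_scene - geometry$eye_height) / s -
    (geometry$screen_center_y - geometry$eye_height)
  list(x = x_scr / geometry$screen_w + 0.5,
       y = y_scr / geometry$screen_h + 0.5)
}

#' Filter a raw gaze trace
#'
#' Applies the three exclusion stages in order: (1) samples with tracker
#' confidence below `conf_min`; (2) samples with gaze outside the display
#' (`x_surf` outside \[0, 1\] or `y_surf` outside \[-0.3, 1\]); (3) samples
#' with missing data. Each stage counts against the frames remaining after
#' the previous one.
#'
#' @param trace data.frame with columns `t, x_surf, y_surf, confidence`
#'   (extra columns are carried through).
#' @param conf_min confidence threshold.
#' @param x_bounds,y_bounds allowed surface-coordinate ranges.
#' @return list with elements `trace` (the kept rows) and `report`, a
#'   `filter_report` with counts `n_total, n_low_confidence, n_out_of_bounds,
#'   n_missing, n_kept` and a `valid` flag (FALSE when nothing survives).
#' @export
filter_trace <- function(trace, conf_min = 0.9,
                         x_bounds = c(0, 1), y_bounds = c(-0.3, 1)) {
  n_total <- nrow(trace)
  low_conf <- !is.na(trace$confidence) & trace$confidence < conf_min
  trace <- trace[!low_conf, , drop = FALSE]
  oob <- with(trace,
              (!is.na(x_surf) & (x_surf < x_bounds[1] | x_surf > x_bounds[2])) |
              (!is.na(y_surf) & (y_surf < y_bounds[1] | y_surf > y_bounds[2])))
  trace <- trace[!oob, , drop = FALSE]
  missing <- is.na(trace$t) | is.na(trace$x_surf) | is.na(trace$y_surf) |
    is.na(trace$confidence)
  trace <- trace[!missing, , drop = FALSE]
  report <- structure(
    list(n_total = n_total, n_low_confidence = sum(low_conf),
         n_out_of_bounds = sum(oob), n_missing = sum(missing),
         n_kept = nrow(trace), valid = nrow(trace) > 0),
    class = "filter_report")
  rownames(trace) <- NULL
  list(trace = trace, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Gaze filter: %d frames; removed %d low-confidence, %d out-of-bounds, %d missing; kept %d (%s)\n",
    x$n_total, x$n_low_confidence, x$n_out_of_bounds, x$n_missing, x$n_kept,
    if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Gaussian smoothing of a sampled signal
#'
#' Convolution with a normalized Gaussian kernel in the sample domain,
#' truncated at 4 standard deviations, with mirror-reflected boundaries.
#'
#' @param x numeric vector.
#' @param sigma_samples kernel standard deviation in samples (> 0).
#' @return smoothed vector of the same length.
#' @export
smooth_gaussian <- function(x, sigma_samples = 3) {
  stopifnot(sigma_samples > 0)
  n <- length(x)
  r <- ceiling(4 * sigma_samples)
  kernel <- stats::dnorm(-r:r, sd = sigma_samples)
  kernel <- kernel / sum(kernel)
  if (n == 1) return(x)
  ridx <- pmin(pmax(seq(r + 1, 2), 1), n)      # mirror about the first sample
  lidx <- pmin(pmax(seq(n - 1, n - r), 1), n)  # mirror about the last sample
  padded <- c(x[ridx], x, x[lidx])
  out <- stats::filter(padded, kernel, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

# lagged-difference derivative with window-centre assignment; gaps larger
# than gap_factor * lag nominal intervals leave the estimate undefined
.lagged_rate <- function(t, value, lag, rate, gap_factor, norm2 = NULL) {
  n <- length(t)
  out <- rep(NA_real_, n)
  if (n <= lag) return(out)
  i <- (lag + 1):n
  dt <- t[i] - t[i - lag]
  if (is.null(norm2)) {
    num <- value[i] - value[i - lag]
  } else {
    num <- sqrt((value[i] - value[i - lag])^2 + (norm2[i] - norm2[i - lag])^2)
  }
  v <- num / dt
  v[dt > gap_factor * lag / rate] <- NA_real_
  # window-centre assignment; for odd lags the centre falls between two
  # samples and the tie goes to the earlier one
  out[i - as.integer(ceiling(lag / 2))] <- v
  out
}

#' Tangential gaze velocity
#'
#' Lagged-difference speed: the Euclidean displacement over `lag` samples
#' divided by the elapsed time, assigned to the window-centre sample
#' (index i - floor(lag/2)). Actual timestamps are used, so dropped frames
#' do not bias the estimate; windows spanning a gap longer than
#' `gap_factor * lag / rate` seconds are left undefined.
#'
#' @param t sample timestamps, s.
#' @param x,y smoothed scene positions, m.
#' @param lag difference lag in samples.
#' @param rate nominal sampling rate, Hz.
#' @param gap_factor maximum tolerated window stretch.
#' @return numeric vector of speeds (m/s), NA where undefined.
#' @export
tangential_velocity <- function(t, x, y, lag = 9, rate = 200, gap_factor = 3) {
  stopifnot(lag >= 1)
  .lagged_rate(t, x, lag, rate, gap_factor, norm2 = y)
}

#' Tangential acceleration
#'
#' Lagged-difference derivative of the tangential velocity, same contract
#' as [tangential_velocity()]. Undefined wherever the velocity is.
#'
#' @param t sample timestamps, s.
#' @param v_tan tangential velocity, m/s.
#' @inheritParams tangential_velocity
#' @return numeric vector of accelerations (m/s^2, signed), NA where
#'   undefined.
#' @export
acceleration <- function(t, v_tan, lag = 5, rate = 200, gap_factor = 3) {
  stopifnot(lag >= 1)
  .lagged_rate(t, v_tan, lag, rate, gap_factor)
}

#' Threshold-based saccade classification
#'
#' A sample is saccadic when the magnitude of the tangential acceleration
#' exceeds `acc_threshold` or the eye speed exceeds `vel_ratio` times the
#' instantaneous target speed. Contiguous saccadic samples form segments;
#' segments separated by at most `merge_gap` samples are merged, and
#' segments shorter than `min_dur` samples are dropped.
#'
#' @param t sample timestamps, s.
#' @param v_tan eye tangential speed, m/s.
#' @param acc eye tangential acceleration, m/s^2.
#' @param target_speed target tangential speed at the same samples, m/s.
#' @param acc_threshold acceleration threshold, m/s^2.
#' @param vel_ratio velocity threshold as a multiple of target speed.
#' @param merge_gap maximum inter-segment gap to merge, samples.
#' @param min_dur minimum segment length, samples.
#' @return list with `segments` (data.frame `onset, offset, onset_t,
#'   offset_t`; indices into the series) and the logical `mask`.
#' @export
classify_saccades <- function(t, v_tan, acc, target_speed,
                              acc_threshold = 300, vel_ratio = 1.5,
                              merge_gap = 2, min_dur = 2) {
  raw <- (abs(acc) > acc_threshold) | (v_tan > vel_ratio * target_speed)
  raw[is.na(raw)] <- FALSE
  n <- length(raw)
  segs <- .runs_true(raw)
  # merge across short gaps
  if (nrow(segs) > 1) {
    keep <- rep(TRUE, nrow(segs))
    for (i in 2:nrow(segs)) {
      j <- max(which(keep[1:(i - 1)]))
      if (segs$onset[i] - segs$offset[j] - 1 <= merge_gap) {
        segs$offset[j] <- segs$offset[i]
        keep[i] <- FALSE
      }
    }
    segs <- segs[keep, , drop = FALSE]
  }
  segs <- segs[segs$offset - segs$onset + 1 >= min_dur, , drop = FALSE]
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(segs))) mask[segs$onset[i]:segs$offset[i]] <- TRUE
  segs$onset_t <- t[segs$onset]
  segs$offset_t <- t[segs$offset]
  rownames(segs) <- NULL
  list(segments = segs, mask = mask)
}

.runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(onset = starts[r$values], offset = ends[r$values])
}

#' Per-trial pursuit gain
#'
#' The pursuit gain is the mean, over eligible samples, of eye tangential
#' speed divided by target tangential speed. Eligible samples lie after the
#' offset of the first catch-up saccade following motion onset, before
#' occlusion onset, and outside saccade segments.
#'
#' @param t sample timestamps, s.
#' @param v_tan eye tangential speed, m/s.
#' @param target_speed target tangential speed, m/s.
#' @param saccades result of [classify_saccades()].
#' @param t_occ occlusion onset time, s.
#' @param t_motion_onset motion onset time, s.
#' @param fallback_start window start to use when no saccade segment exists
#'   (`NULL` flags the trial invalid in that case).
#' @param mask_pad samples of padding added around each saccade segment when
#'   selecting eligible samples. A lagged velocity estimate near a saccade
#'   boundary uses positions inside the saccade (half the velocity lag on
#'   either side, widened further by the smoothing kernel's support), so
#'   unpadded estimates there are contaminated by saccadic displacement;
#'   the default covers the velocity half-window plus 3 smoothing SDs at
#'   the default settings.
#' @return object of class `pursuit_summary`: list with `gain`,
#'   `n_eligible`, `first_catchup_offset_t`, `n_saccades` and `valid`.
#' @export
compute_gain <- function(t, v_tan, target_speed, saccades, t_occ,
                         t_motion_onset = 0, fallback_start = NULL,
                         mask_pad = 12) {
  segs <- saccades$segments
  # only saccades launched during visible motion qualify as the catch-up
  segs <- segs[segs$onset_t >= t_motion_onset & segs$onset_t < t_occ, ,
               drop = FALSE]
  start <- if (nrow(segs) > 0) {
    segs$offset_t[1]
  } else if (!is.null(fallback_start)) {
    fallback_start
  } else {
    NA_real_
  }
  if (is.na(start)) {
    return(structure(list(gain = NA_real_, n_eligible = 0L,
                          first_catchup_offset_t = NA_real_,
                          n_saccades = nrow(saccades$segments), valid = FALSE),
                     class = "pursuit_summary"))
  }
  mask <- saccades$mask
  if (mask_pad > 0 && any(mask)) {
    idx <- which(mask)
    n <- length(mask)
    for (d in seq_len(mask_pad)) {
      mask[pmax(idx - d, 1)] <- TRUE
      mask[pmin(idx + d, n)] <- TRUE
    }
  }
  ok <- t > start & t < t_occ & !mask &
    is.finite(v_tan) & is.finite(target_speed) & target_speed > 0
  gain <- if (any(ok)) mean(v_tan[ok] / target_speed[ok]) else NA_real_
  structure(list(gain = gain, n_eligible = sum(ok),
                 first_catchup_offset_t = if (nrow(segs) > 0) segs$offset_t[1] else NA_real_,
                 n_saccades = nrow(saccades$segments), valid = any(ok)),
            class = "pursuit_summary")
}

#' @export
print.pursuit_summary <- function(x, ...) {
  cat(sprintf("Pursuit gain %.4f over %d samples (%d saccades%s)\n",
              x$gain, x$n_eligible, x$n_saccades,
              if (x$valid) "" else "; trial INVALID"))
  invisible(x)
}

#' Full gaze preprocessing for one trial
#'
#' Runs the stages in order: confidence/bounds/missing filtering, surface to
#' scene mapping, Gaussian position smoothing, lagged tangential velocity
#' and acceleration, saccade classification against the analytic target
#' speed, and the pursuit-gain summary.
#'
#' @param trace raw gaze data.frame (`t, x_surf, y_surf, confidence`).
#' @param params the trial's [trajectory_params()].
#' @param t_occ occlusion onset time, s.
#' @param config a [run_config()] list of pipeline constants.
#' @param geometry a [scene_geometry()].
#' @return list with `series` (data.frame `t, x, y, x_smooth, y_smooth,
#'   v_tan, acc, target_speed, saccade_mask`), `segments`, `summary`
#'   (a `pursuit_summary`), `report` (a `filter_report`) and `valid`.
#' @export
preprocess_trial <- function(trace, params, t_occ, config = run_config(),
                             geometry = scene_geometry()) {
  f <- filter_trace(trace, conf_min = config$conf_min,
                    x_bounds = config$x_bounds, y_bounds = config$y_bounds)
  if (!f$report$valid) {
    return(list(series = NULL, segments = NULL, summary = NULL,
                report = f$report, valid = FALSE))
  }
  tr <- f$trace
  sc <- map_to_scene(tr$x_surf, tr$y_surf, geometry)
  xs <- smooth_gaussian(sc$x, config$smooth_sigma)
  ys <- smooth_gaussian(sc$y, config$smooth_sigma)
  v <- tangential_velocity(tr$t, xs, ys, lag = config$vel_lag,
                           rate = config$rate, gap_factor = config$gap_factor)
  a <- acceleration(tr$t, v, lag = config$acc_lag,
                    rate = config$rate, gap_factor = config$gap_factor)
  st <- target_state(params, tr$t)
  tspeed <- sqrt(st$vx^2 + st$vy^2)
  sac <- classify_saccades(tr$t, v, a, tspeed,
                           acc_threshold = config$acc_threshold,
                           vel_ratio = config$vel_ratio,
                           merge_gap = config$merge_gap,
                           min_dur = config$min_dur)
  summ <- compute_gain(tr$t, v, tspeed, sac, t_occ,
                       fallback_start = config$fallback_start,
                       mask_pad = config$gain_mask_pad)
  series <- data.frame(t = tr$t, x = sc$x, y = sc$y,
                       x_smooth = xs, y_smooth = ys,
                       v_tan = v, acc = a, target_speed = tspeed,
                       target_x = st$x, target_y = st$y,
                       saccade_mask = sac$mask)
  list(series = series, segments = sac$segments, summary = summ,
       report = f$report, valid = summ$valid)
}
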