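# Saccade- and lag-based exploratory metrics. All metrics are missing-safe:
# an absent event yields NA, never a fabricated zero.

#' Landing error of the first post-occlusion saccade
#'
#' Horizontal landing position (smoothed gaze at segment offset) of the
#' first saccade whose onset falls after occlusion onset, minus the
#' coincidence position where the target meets the table. Negative values
#' are leftward undershoots.
#'
#' @param series preprocessed kinematic series (from [preprocess_trial()]).
#' @param segments saccade segment table.
#' @param t_occ occlusion onset time, s.
#' @param x_coincidence target coincidence x position, m.
#' @return signed error, m; `NA` when no post-occlusion saccade exists.
#' @export
occlusion_saccade_error_x <- function(series, segments, t_occ, x_coincidence) {
  post <- segments[segments$onset_t > t_occ, , drop = FALSE]
  if (nrow(post) == 0) return(NA_real_)
  series$x_smooth[post$offset[1]] - x_coincidence
}

#' Gaze-target lag at a reference time
#'
#' Spatial error (gaze minus target) at a reference sample: either 40% of
#' the flight time (`rule = "fraction_40pct"`, used for the inversion
#' block) or 0.4 s after motion onset (`rule = "after_0.4s"`, used for the
#' graded-gravity blocks, where 40% of fast trajectories can collide with
#' the first catch-up saccade). If the reference sample is saccade-masked,
#' the nearest unmasked sample within 5 samples is used; otherwise the
#' metric is missing.
#'
#' @param series preprocessed kinematic series.
#' @param return_time flight time of the trial, s.
#' @param rule `"fraction_40pct"` or `"after_0.4s"`.
#' @param max_shift how far (samples) to look for an unmasked neighbour.
#' @return list `dx, dy, reference_t, reference_rule` (dx, dy in m;
#'   gaze below the target gives dy < 0).
#' @export
gaze_lag_at <- function(series, return_time, rule = c("fraction_40pct",
                                                      "after_0.4s"),
                        max_shift = 5) {
  rule <- match.arg(rule)
  ref_t <- if (rule == "fraction_40pct") 0.4 * return_time else 0.4
  miss <- list(dx = NA_real_, dy = NA_real_, reference_t = ref_t,
               reference_rule = rule)
  if (ref_t > max(series$t)) return(miss)
  i <- which.min(abs(series$t - ref_t))
  if (series$saccade_mask[i]) {
    cand <- which(!series$saccade_mask)
    cand <- cand[abs(cand - i) <= max_shift]
    if (length(cand) == 0) return(miss)
    i <- cand[which.min(abs(cand - i))]
  }
  list(dx = series$x_smooth[i] - series$target_x[i],
       dy = series$y_smooth[i] - series$target_y[i],
       reference_t = series$t[i], reference_rule = rule)
}

#' Count saccades overlapping a time window
#'
#' @param segments saccade segment table.
#' @param window numeric length-2 window `(t0, t1)`, s.
#' @return integer count of segments with any overlap.
#' @export
count_saccades <- function(segments, window) {
  if (is.null(segments) || nrow(segments) == 0) return(0L)
  sum(segments$offset_t >= window[1] & segments$onset_t <= window[2])
}

#' Error after the first catch-up saccade
#'
#' Gaze minus target position at the offset sample of the first saccade
#' after motion onset.
#'
#' @param series preprocessed kinematic series.
#' @param segments saccade segment table.
#' @param t_motion_onset motion onset time, s.
#' @return list `dx, dy` (m); both `NA` when no catch-up saccade exists.
#' @export
catchup_saccade_error <- function(series, segments, t_motion_onset = 0) {
  segs <- segments[segments$onset_t >= t_motion_onset, , drop = FALSE]
  if (nrow(segs) == 0) return(list(dx = NA_real_, dy = NA_real_))
  i <- segs$offset[1]
  list(dx = series$x_smooth[i] - series$target_x[i],
       dy = series$y_smooth[i] - series$target_y[i])
}

#' Per-trial event metrics table
#'
#' Convenience wrapper collecting the exploratory metrics of one
#' preprocessed trial into a single row.
#'
#' @param prep result of [preprocess_trial()].
#' @param params the trial's [trajectory_params()].
#' @param t_occ occlusion onset time, s.
#' @param trial_id identifier for the output row.
#' @param lag_rule reference rule for [gaze_lag_at()].
#' @return one-row data.frame `trial_id, saccade_error_x, lag_dx, lag_dy,
#'   n_saccades, catchup_dx, catchup_dy`.
#' @export
event_metrics <- function(prep, params, t_occ, trial_id = 1L,
                          lag_rule = "fraction_40pct") {
  tr <- return_time(params)
  lag <- gaze_lag_at(prep$series, tr, lag_rule)
  cu <- catchup_saccade_error(prep$series, prep$segments)
  data.frame(
    trial_id = trial_id,
    saccade_error_x = occlusion_saccade_error_x(prep$series, prep$segments,
                                                t_occ, coincidence_x(params)),
    lag_dx = lag$dx, lag_dy = lag$dy,
    n_saccades = count_saccades(prep$segments, c(0, t_occ)),
    catchup_dx = cu$dx, catchup_dy = cu$dy)
}
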