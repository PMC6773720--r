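# Temporal interception errors, the 1g-extrapolation and central-tendency
# predictors, and observed-vs-predicted model comparison.

#' Corrected temporal error of a button press
#'
#' Raw error is the response time minus the true coincidence time (negative
#' = pressed too early); the corrected error additionally subtracts the
#' measured system delay. Trials with an absolute raw error at or above the
#' exclusion threshold are flagged as outliers.
#'
#' @param t_response response time from motion onset, s (`NA` for a missing
#'   response, which is excluded).
#' @param params the trial's [trajectory_params()].
#' @param system_delay apparatus delay, s.
#' @param exclusion absolute raw-error exclusion threshold, s.
#' @return list of class `timing_result`: `t_response, t_coincidence,
#'   raw_error, corrected_error, excluded`.
#' @export
temporal_error <- function(t_response, params, system_delay = 0.049259,
                           exclusion = 0.5) {
  tc <- return_time(params)
  if (is.na(t_response)) {
    return(structure(list(t_response = NA_real_, t_coincidence = tc,
                          raw_error = NA_real_, corrected_error = NA_real_,
                          excluded = TRUE),
                     class = "timing_result"))
  }
  raw <- t_response - tc
  structure(list(t_response = t_response, t_coincidence = tc,
                 raw_error = raw, corrected_error = raw - system_delay,
                 excluded = abs(raw) >= exclusion),
            class = "timing_result")
}

#' Predicted temporal error under the earth-gravity model
#'
#' Applies the drag-free 1g time-to-contact formula ([predict_ttc_1g()]) to
#' the true stimulus state at occlusion onset (vertical velocity and
#' remaining vertical distance toward the coincidence height) and subtracts
#' the true remaining flight time. Negative predictions mean the model
#' expects the target earlier than it arrives — the case for gravities
#' below 1 g. Inverted-gravity trials are evaluated in the mirrored frame
#' (a gravity prior of earth magnitude along the stimulus' own vertical
#' direction).
#'
#' @param params the trial's [trajectory_params()].
#' @param fraction occlusion-onset fraction of the flight time.
#' @param g_earth assumed gravity magnitude, m/s^2.
#' @return predicted signed temporal error, s.
#' @export
predict_error_1g <- function(params, fraction, g_earth = 9.81) {
  occ <- occlusion_state(params, fraction)
  predict_ttc_1g(occ$v_up, occ$d_y, g_earth) - occ$remaining
}

#' Predicted temporal error under a central tendency
#'
#' If responses were timed from the mean of all experienced occluded
#' durations, the expected error of a trial is that mean minus the trial's
#' own occluded duration. The mean is taken within the trial's block type.
#'
#' @param occluded_duration the trial's occluded duration(s), s.
#' @param block_type block label(s) aligned with `occluded_duration`.
#' @return predicted signed temporal error(s), s.
#' @export
predict_error_central <- function(occluded_duration, block_type = NULL) {
  if (is.null(block_type)) {
    return(mean(occluded_duration) - occluded_duration)
  }
  stats::ave(occluded_duration, block_type) - occluded_duration
}

#' Build the per-trial timing table for a cohort
#'
#' Computes raw and corrected temporal errors with outlier flags, plus the
#' 1g-model and central-tendency predictions, for every trial of a tidy
#' cohort dataset (see [simulate_cohort()]).
#'
#' @param cohort tidy per-trial data.frame with columns `gravity_mult,
#'   v_xi, v_yi, occ_fraction, occluded_duration, t_coincidence,
#'   t_response, block_type`.
#' @param config a [run_config()] (supplies the delay and exclusion rule).
#' @return the cohort with columns `raw_error, corrected_error, excluded,
#'   predicted_1g, predicted_central` appended.
#' @export
timing_table <- function(cohort, config = run_config()) {
  raw <- cohort$t_response - cohort$t_coincidence
  cohort$raw_error <- raw
  cohort$corrected_error <- raw - config$system_delay
  cohort$excluded <- is.na(raw) | abs(raw) >= config$error_exclusion
  # vectorized over trials within each kinematic combination
  key <- paste(cohort$gravity_mult, cohort$v_xi, cohort$v_yi)
  pred <- rep(NA_real_, nrow(cohort))
  for (k in unique(key)) {
    idx <- which(key == k)
    i <- idx[1]
    p <- trajectory_params(cohort$gravity_mult[i], cohort$v_xi[i],
                           cohort$v_yi[i])
    tr <- return_time(p)
    t_occ <- cohort$occ_fraction[idx] * tr
    st <- target_state(p, t_occ)
    sgn <- if (p$gravity_mult > 0) 1 else -1
    ttc <- predict_ttc_1g(sgn * st$vy, sgn * (st$y - p$start_y))
    pred[idx] <- ttc - (tr - t_occ)
  }
  cohort$predicted_1g <- pred
  cohort$predicted_central <- predict_error_central(cohort$occluded_duration,
                                                    cohort$block_type)
  cohort
}

#' Compare observed errors against model predictions
#'
#' Pearson correlations between observed corrected errors and each
#' predictor, overall and per occlusion category, plus per
#' gravity-by-occlusion cell medians of observed and predicted errors.
#' Excluded trials are dropped; a zero-variance predictor yields a missing
#' correlation.
#'
#' @param timing a [timing_table()] data.frame.
#' @return list of class `model_comparison`: `r_1g`, `r_central`
#'   (each with elements `overall, short, long`), `cell_medians`
#'   (data.frame per gravity x occlusion cell) and `preferred`
#'   (`"1g"`, `"central"`, or `NA` if neither correlation is defined).
#' @export
compare_models <- function(timing) {
  d <- timing[!timing$excluded & !is.na(timing$corrected_error), , drop = FALSE]
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  by_occ <- function(pred) {
    c(overall = safe_cor(d$corrected_error, pred),
      short = safe_cor(d$corrected_error[d$occ_category == "short"],
                       pred[d$occ_category == "short"]),
      long = safe_cor(d$corrected_error[d$occ_category == "long"],
                      pred[d$occ_category == "long"]))
  }
  r1 <- by_occ(d$predicted_1g)
  rc <- by_occ(d$predicted_central)
  cells <- unique(d[, c("gravity_mult", "occ_category")])
  cells <- cells[order(cells$gravity_mult, cells$occ_category), , drop = FALSE]
  med <- function(idx, col) stats::median(d[[col]][idx])
  cell_medians <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    idx <- d$gravity_mult == cells$gravity_mult[i] &
      d$occ_category == cells$occ_category[i]
    data.frame(gravity_mult = cells$gravity_mult[i],
               occ_category = cells$occ_category[i],
               median_observed = med(idx, "corrected_error"),
               median_predicted_1g = med(idx, "predicted_1g"),
               median_predicted_central = med(idx, "predicted_central"),
               n = sum(idx))
  }))
  preferred <- if (is.na(r1["overall"]) && is.na(rc["overall"])) {
    NA_character_
  } else if (is.na(rc["overall"]) ||
             (!is.na(r1["overall"]) && r1["overall"] >= rc["overall"])) {
    "1g"
  } else {
    "central"
  }
  structure(list(r_1g = r1, r_central = rc, cell_medians = cell_medians,
                 preferred = preferred, n = nrow(d)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Observed vs predicted temporal error (n = %d trials)\n", x$n))
  cat(sprintf("  1g extrapolation: r = %.3f (short %.3f, long %.3f)\n",
              x$r_1g["overall"], x$r_1g["short"], x$r_1g["long"]))
  cat(sprintf("  central tendency: r = %.3f (short %.3f, long %.3f)\n",
              x$r_central["overall"], x$r_central["short"],
              x$r_central["long"]))
  cat(sprintf("  preferred predictor: %s\n", x$preferred))
  invisible(x)
}
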