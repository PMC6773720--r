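# Mixed-model inference: ML fits with per-subject random intercepts,
# likelihood-ratio model comparison, the two confirmatory analyses, and the
# simulation-based power analysis for the repeated-measures design.

#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood fit (not REML, so that likelihood-ratio tests between
#' nested fixed-effect structures are valid) of
#' `response ~ fixed_terms + (1 | group)`. Categorical gravity predictors
#' should be supplied as factors with 1 g as the reference level (see
#' [gravity_factor()]).
#'
#' @param data data.frame of per-trial records.
#' @param response name of the response column.
#' @param fixed_terms character vector of fixed-effect terms (may include
#'   interactions, e.g. `"gravity * occ_category"`); empty for a null
#'   (intercept-only) model.
#' @param group name of the grouping column (>= 2 levels).
#' @return object of class `lmm_fit`: list with `fixed_effects` (data.frame
#'   `term, estimate, se`), `random_intercept_var`, `residual_var`,
#'   `loglik`, `df`, `n_obs`, `n_groups`, `singular`, `formula` and the
#'   underlying `model`.
#' @export
fit_lmm <- function(data, response, fixed_terms, group = "subject") {
  if (length(unique(data[[group]])) < 2) {
    stop("need at least 2 grouping levels")
  }
  for (term in fixed_terms) {
    vars <- all.vars(stats::as.formula(paste("~", term)))
    for (v in vars) {
      if (is.factor(data[[v]]) || is.character(data[[v]])) {
        if (length(unique(data[[v]])) < 2) {
          stop("fixed factor '", v, "' has a single level")
        }
      }
    }
  }
  rhs <- paste(c(if (length(fixed_terms)) fixed_terms else "1",
                 sprintf("(1 | %s)", group)), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressMessages(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")))
  sm <- summary(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- stats::logLik(fit)
  structure(list(
    fixed_effects = data.frame(term = rownames(sm$coefficients),
                               estimate = sm$coefficients[, "Estimate"],
                               se = sm$coefficients[, "Std. Error"],
                               row.names = NULL),
    random_intercept_var = vc$vcov[vc$grp == group],
    residual_var = vc$vcov[vc$grp == "Residual"],
    loglik = as.numeric(ll),
    df = attr(ll, "df"),
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit)[[group]],
    singular = lme4::isSingular(fit),
    formula = fml,
    model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML):", deparse(x$formula), "\n")
  cat(sprintf("  %d obs, %d groups; logLik = %.2f (df = %d)%s\n",
              x$n_obs, x$n_groups, x$loglik, x$df,
              if (x$singular) " [singular fit]" else ""))
  print(x$fixed_effects, digits = 4)
  cat(sprintf("  random intercept var = %.5g, residual var = %.5g\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' Chi-square test of `2 * (logLik_full - logLik_null)` on the difference
#' in parameter counts.
#'
#' @param full,null [fit_lmm()] objects on the same data, null nested in
#'   full.
#' @return object of class `lrt_result`: list `chi2, df, p`.
#' @export
lrt <- function(full, null) {
  if (full$n_obs != null$n_obs) stop("models were fit to different data")
  df <- full$df - null$df
  if (df < 0) stop("models are not nested (null has more parameters)")
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi^2 = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Gravity as an unordered factor with 1 g reference
#'
#' @param gravity_mult numeric gravity multiples.
#' @return factor with `"1"` as first (reference) level.
#' @export
gravity_factor <- function(gravity_mult) {
  lev <- unique(as.character(gravity_mult))
  stats::relevel(factor(as.character(gravity_mult), levels = lev), ref = "1")
}

#' Confirmatory analysis of pursuit gains
#'
#' Within one block type, fits `gain ~ gravity + (1 | subject)` by ML
#' against the intercept-only null and reports the per-level contrasts
#' against 1 g with the likelihood-ratio test. The inversion block
#' (1 g vs -1 g) is analysed separately from the graded-gravity blocks.
#'
#' @param cohort tidy per-trial dataset with `gain`, `gravity_mult`,
#'   `block_type`, `subject`.
#' @param block_type `"inversion"` or `"main"`.
#' @return object of class `gain_report`: list with `full`, `null`
#'   (`lmm_fit`s), `lrt`, `coefficients` and `block_type`.
#' @export
analyze_gain <- function(cohort, block_type = c("inversion", "main")) {
  block_type <- match.arg(block_type)
  d <- cohort[cohort$block_type == block_type & !is.na(cohort$gain), ,
              drop = FALSE]
  d$gravity <- gravity_factor(d$gravity_mult)
  full <- fit_lmm(d, "gain", "gravity")
  null <- fit_lmm(d, "gain", character(0))
  structure(list(full = full, null = null, lrt = lrt(full, null),
                 coefficients = full$fixed_effects,
                 block_type = block_type, n_obs = full$n_obs),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("Pursuit-gain analysis, %s block (%d trials)\n",
              x$block_type, x$n_obs))
  print(x$coefficients, digits = 4)
  print(x$lrt)
  invisible(x)
}

#' Confirmatory analysis of corrected temporal errors
#'
#' Within one block type, fits the pre-specifiable interaction model
#' `error ~ gravity * occ_category + (1 | subject)` and the simpler
#' gravity-only model, keeps the interaction model only when the
#' likelihood-ratio test says dropping it loses fit (p < alpha), and
#' compares the selected model against the intercept-only null. Outlier
#' trials (`excluded`) are dropped first.
#'
#' @param timing a [timing_table()] data.frame.
#' @param block_type `"inversion"` or `"main"`.
#' @param alpha selection level for the interaction term.
#' @return object of class `timing_report`: list with `selected`
#'   (`"interaction"` or `"gravity_only"`), `fit`, `null`, `lrt_selection`,
#'   `lrt_null`, `coefficients`.
#' @export
analyze_timing <- function(timing, block_type = c("inversion", "main"),
                           alpha = 0.05) {
  block_type <- match.arg(block_type)
  d <- timing[timing$block_type == block_type & !timing$excluded, ,
              drop = FALSE]
  d$gravity <- gravity_factor(d$gravity_mult)
  full <- fit_lmm(d, "corrected_error", "gravity * occ_category")
  simple <- fit_lmm(d, "corrected_error", "gravity")
  sel <- lrt(full, simple)
  use_full <- sel$p < alpha
  fit <- if (use_full) full else simple
  null <- fit_lmm(d, "corrected_error", character(0))
  structure(list(selected = if (use_full) "interaction" else "gravity_only",
                 fit = fit, null = null, lrt_selection = sel,
                 lrt_null = lrt(fit, null),
                 coefficients = fit$fixed_effects,
                 block_type = block_type, n_obs = fit$n_obs),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("Temporal-error analysis, %s block (%d trials): %s model\n",
              x$block_type, x$n_obs, x$selected))
  print(x$coefficients, digits = 4)
  cat("vs null: "); print(x$lrt_null)
  invisible(x)
}

#' Simulation-based power for the two-condition gain contrast
#'
#' Monte-Carlo power of the random-intercept LMM with a likelihood-ratio
#' test at level `alpha`, for a two-condition within-subject design with a
#' given true gain difference. Trial-to-trial noise is `sd_ratio` times the
#' between-subject intercept SD, the variability structure the design
#' assumes.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per condition per subject.
#' @param effect true gain difference between the two conditions.
#' @param sd_ratio intra- over inter-subject variability ratio.
#' @param subject_sd between-subject intercept SD (gain units).
#' @param alpha test level.
#' @param n_sims number of simulated cohorts.
#' @param seed integer seed.
#' @return object of class `power_result`: list `power, rejections, n_sims`
#'   and the design parameters.
#' @export
power_simulation <- function(n_subjects = 10, n_trials = 60, effect = 0.1,
                             sd_ratio = 6, subject_sd = 0.037, alpha = 0.05,
                             n_sims = 200, seed = 1L) {
  stopifnot(n_sims >= 1)
  trial_sd <- sd_ratio * subject_sd
  n <- n_subjects * n_trials * 2
  template <- data.frame(
    subject = rep(seq_len(n_subjects), each = 2 * n_trials),
    condition = factor(rep(rep(c("a", "b"), each = n_trials), n_subjects)))
  shift <- ifelse(template$condition == "b", effect, 0)
  rejections <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_sims)) {
      intercept <- stats::rnorm(n_subjects, 0, subject_sd)
      template$gain <- 0.8 + shift + intercept[template$subject] +
        stats::rnorm(n, 0, trial_sd)
      full <- fit_lmm(template, "gain", "condition")
      null <- fit_lmm(template, "gain", character(0))
      if (lrt(full, null)$p < alpha) hits <- hits + 1L
    }
    hits
  })
  structure(list(power = rejections / n_sims, rejections = rejections,
                 n_sims = n_sims, n_subjects = n_subjects,
                 n_trials = n_trials, effect = effect, alpha = alpha),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Power %.3f (%d/%d rejections at alpha = %g): effect %g, %d subjects x %d trials/condition\n",
    x$power, x$rejections, x$n_sims, x$alpha, x$effect, x$n_subjects,
    x$n_trials))
  invisible(x)
}
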