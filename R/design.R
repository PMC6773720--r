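# Experimental design enumeration: fully crossed blocks, shuffled per seed,
# with per-trial occlusion fractions drawn uniformly inside their band.

.occ_bounds <- list(short = c(0.20, 0.25), long = c(0.45, 0.50))

# enumerate a fully crossed block and shuffle it; occ_fraction is drawn
# per trial, uniform within its category band
.build_block <- function(gravities, n_reps, block_type, block_id, seed) {
  grid <- expand.grid(
    gravity_mult = gravities,
    v_yi = c(4.5, 6),
    v_xi = c(3, 4),
    occ_category = c("short", "long"),
    rep_index = seq_len(n_reps),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  with_seed(seed, {
    grid <- grid[sample.int(n), , drop = FALSE]
    lo <- vapply(.occ_bounds[grid$occ_category], `[`, numeric(1), 1)
    hi <- vapply(.occ_bounds[grid$occ_category], `[`, numeric(1), 2)
    grid$occ_fraction <- stats::runif(n, lo, hi)
  })
  rownames(grid) <- NULL
  data.frame(
    block_id = block_id,
    block_type = block_type,
    grid[, c("gravity_mult", "v_xi", "v_yi", "occ_category",
             "occ_fraction", "rep_index")],
    trial_index = seq_len(n),
    stringsAsFactors = FALSE)
}

#' Build one main experimental block
#'
#' One block of the main design: 5 gravity multiples (0.7--1.3 g) crossed
#' with 2 initial vertical velocities, 2 initial horizontal velocities and
#' 2 occlusion categories, 8 repetitions per combination — 320 trials,
#' each combination equally often, order shuffled.
#'
#' @param seed integer seed controlling the shuffle and the per-trial
#'   occlusion-fraction draws.
#' @param block_id index stored in the `block_id` column.
#' @return data.frame of trial conditions, one row per trial.
#' @export
build_main_block <- function(seed, block_id = 1L) {
  .build_block(c(0.7, 0.85, 1, 1.15, 1.3), 8L, "main", block_id, seed)
}

#' Build the gravity-inversion block
#'
#' 2 gravities (1 g and -1 g) crossed with 2 vertical velocities,
#' 2 horizontal velocities and 2 occlusion categories, 24 repetitions per
#' combination — 384 trials.
#'
#' @inheritParams build_main_block
#' @return data.frame of trial conditions.
#' @export
build_inversion_block <- function(seed, block_id = 1L) {
  .build_block(c(1, -1), 24L, "inversion", block_id, seed)
}

#' Build the training block
#'
#' Each combination of the 6 gravity levels, 2 vertical velocities,
#' 2 horizontal velocities and 2 occlusion categories exactly once —
#' 48 trials.
#'
#' @inheritParams build_main_block
#' @return data.frame of trial conditions.
#' @export
build_training_block <- function(seed, block_id = 0L) {
  .build_block(c(0.7, 0.85, 1, 1.15, 1.3, -1), 1L, "training", block_id, seed)
}

#' Build a full single-subject experiment plan
#'
#' Training block first, then three main blocks and one inversion block
#' (1344 experimental trials in total). Half the cohort receives the
#' inversion block first, the other half last.
#'
#' @param subject_id subject label.
#' @param inversion_first logical; place the inversion block before the
#'   main blocks?
#' @param seed integer seed; per-block seeds are derived from it.
#' @return an object of class `experiment_plan`: a list with elements
#'   `subject_id`, `inversion_first`, `seed` and `trials` (a data.frame
#'   with a `subject` column prepended).
#' @export
build_experiment <- function(subject_id, inversion_first = FALSE, seed = 1L) {
  seeds <- with_seed(seed, sample.int(2^31 - 1, 5))
  training <- build_training_block(seeds[1], block_id = 0L)
  mains <- lapply(1:3, function(i) build_main_block(seeds[i + 1], block_id = i))
  inv <- build_inversion_block(seeds[5], block_id = 4L)
  experimental <- if (inversion_first) c(list(inv), mains) else c(mains, list(inv))
  blocks <- c(list(training), experimental)
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- i - 1L
  trials <- do.call(rbind, blocks)
  trials <- cbind(subject = subject_id, trials)
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  structure(list(subject_id = subject_id, inversion_first = inversion_first,
                 seed = seed, trials = trials),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  n_exp <- sum(x$trials$block_type != "training")
  cat(sprintf("Experiment plan for subject %s (seed %d)\n", x$subject_id, x$seed))
  cat(sprintf("  %d trials (%d experimental + %d training), inversion block %s\n",
              nrow(x$trials), n_exp, sum(x$trials$block_type == "training"),
              if (x$inversion_first) "first" else "last"))
  invisible(x)
}
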