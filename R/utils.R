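# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# phi1(u) = (1 - exp(-u))/u, phi1(0) = 1. Series branch avoids cancellation
# for small u (relative truncation error < 1e-15 at the switch point).
phi1 <- function(u) {
  out <- u
  small <- abs(u) < 1e-3
  us <- u[small]
  out[small] <- 1 - us / 2 + us^2 / 6 - us^3 / 24 + us^4 / 120
  ub <- u[!small]
  out[!small] <- -expm1(-ub) / ub
  out
}

# phi2(u) = (exp(-u) - 1 + u)/u^2, phi2(0) = 1/2.
phi2 <- function(u) {
  out <- u
  small <- abs(u) < 1e-3
  us <- u[small]
  out[small] <- 1 / 2 - us / 6 + us^2 / 24 - us^3 / 120 + us^4 / 720
  ub <- u[!small]
  out[!small] <- (expm1(-ub) + ub) / ub^2
  out
}
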