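# Internal numerical helpers shared across modules.

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler. With `sd = 0` the mean is returned unchanged
#' (degenerate distribution), which keeps deterministic test configurations
#' valid.
#'
#' @param n Number of draws.
#' @param mean,sd Mean and standard deviation of the parent normal.
#' @param lower,upper Truncation bounds (open at `lower`, closed at `upper`
#'   for continuous distributions the distinction is immaterial).
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stopifnot-style check with a readable message
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
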