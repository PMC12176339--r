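#' Round half away from zero
#'
#' Presentation rounding used in all printed percentages and monetary
#' figures: ties go away from zero (so 75.55 -> 75.6), unlike [round()]'s
#' round-half-even. Internal arithmetic is never rounded; this is applied
#' only when a number is reported.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return `x` rounded to `digits` places, half away from zero.
#' @export
#' @examples
#' round_half_up(75.55, 1)  # 75.6
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
# All exported stochastic entry points take an explicit seed and route
# through this, so no call mutates global RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ji <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "judimpact_error")))
}
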