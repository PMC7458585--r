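#' Round half away from zero
#'
#' Base \code{round()} uses banker's rounding (round-half-to-even), which is
#' inappropriate for display percentages and integer search-volume indices
#' where the convention is round-half-up. A small epsilon absorbs binary
#' representation artifacts (e.g. \code{963000/100000 * 100} falling a hair
#' below 963).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half-up to \code{digits} places.
#' @examples
#' round_half_up(0.5)      # 1, where round(0.5) is 0
#' round_half_up(35.65, 1) # 35.7
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# Keeps every stochastic routine a pure function of its seed argument.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Shared stop() wrapper that prefixes the failing pipeline stage so
# end-to-end runs fail with a stage-named message.
stage_error <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
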