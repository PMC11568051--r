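#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; similarity weights use the
#' conventional half-up rule after scaling to \[0, 100\].
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Display percentage for degree-gain quantities
#'
#' Rounds to whole percent (half away from zero), the convention used when
#' reporting proportional degree gains (e.g. 68.75 prints as 69).
#'
#' @param pct numeric percentage
#' @return integer percentage
#' @export
pct_display_gain <- function(pct) as.integer(round_half_up(pct))

#' Display percentage for saturation quantities
#'
#' Saturation percentages are reported truncated toward zero (4/15 of the L1
#' neighbourhood prints as 26%, not 27%), a conservative "reached at least"
#' convention.
#'
#' @param pct numeric percentage
#' @return integer percentage
#' @export
pct_display_saturation <- function(pct) as.integer(trunc(pct))

# 1-decimal display, round-half-to-even (58.65 -> 58.6)
fmt1 <- function(x) round(x, 1)

# deterministic seed scoping: run expr under `seed`, restore the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
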