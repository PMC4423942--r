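#' Evaluate a tail StepFunction at a statistic value
#'
#' For a lower-tail function returns \eqn{\Pr(V \le v)}; for an upper-tail
#' function \eqn{\Pr(V \ge v)}.  Comparisons of statistic values use an
#' absolute tolerance of 1e-12 in the direction that keeps the result
#' conservative (mass sitting within tolerance of \code{v} is included in
#' the tail).
#'
#' @param sf a \linkS4class{StepFunction}.
#' @param v statistic value.
#' @return the tail probability (0 when \code{v} lies beyond all breakpoints).
#' @export
evaluateStepFunction <- function(sf, v) {
  stopifnot(is(sf, "StepFunction"))
  bp <- sf@breakpoints
  if (!length(bp)) return(0)
  if (sf@side == "lower") {
    i <- findInterval(v + .v_tol, bp)
    if (i == 0L) 0 else exp(sf@logProb[i])
  } else {
    i <- findInterval(v - .v_tol, bp, left.open = TRUE) + 1L
    if (i > length(bp)) 0 else exp(sf@logProb[i])
  }
}

# build a lower-tail StepFunction from a grid-DP result
gridStepFunction <- function(v, k, L, side) {
  new("StepFunction", breakpoints = as.numeric(v), logProb = as.numeric(k) * L,
      levels = as.integer(k), gridStep = L, side = side)
}

# upper-tail function of V from the mirrored (lower-tail of -V) grid result
mirroredUpper <- function(v, k, L) {
  gridStepFunction(rev(-v), rev(k), L, "upper")
}
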