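#' Asymptotic log-rank p-value
#'
#' Normal / chi-squared approximation under either variance convention: the
#' normalized statistic \eqn{z = v / \sqrt{\mathrm{Var}(V)}} is referred to
#' N(0,1) (two-sided) or, equivalently, \eqn{z^2} to \eqn{\chi^2_1}; both
#' forms give identical p-values and are exposed for parity with common
#' implementations.  With the conditional (hypergeometric) variance this
#' reproduces the behaviour of standard log-rank software (e.g.
#' \code{survival::survdiff}, given distinct event times); with the
#' permutational variance it is the asymptotic form of the permutation test.
#' No continuity correction is applied.
#'
#' @param seq an \linkS4class{EventSequence}.
#' @param null which variance to normalize by: \code{"conditional"} or
#'   \code{"permutational"}.
#' @param form \code{"chisq"} or \code{"normal"} (identical values).
#' @return a \linkS4class{LogrankResult} (method \code{"asym_cond"} or
#'   \code{"asym_perm"}).  Zero variance gives p = 1 with a
#'   \code{"zero_variance"} flag.
#' @export
asymptoticPValue <- function(seq,
                             null = c("conditional", "permutational"),
                             form = c("chisq", "normal")) {
  stopifnot(is(seq, "EventSequence"))
  null <- match.arg(null)
  form <- match.arg(form)
  v <- logrankStatistic(seq)
  vr <- if (null == "conditional") condVariance(seq) else permVariance(seq)
  method <- if (null == "conditional") "asym_cond" else "asym_perm"
  if (vr <= 0) {
    return(new("LogrankResult", statistic = v, pValue = 1, method = method,
               variance = vr, n = seq@n, n1 = seq@n1,
               flags = "zero_variance"))
  }
  z <- v / sqrt(vr)
  p <- if (form == "normal") 2 * pnorm(abs(z), lower.tail = FALSE)
       else pchisq(z^2, df = 1, lower.tail = FALSE)
  p <- min(1, max(p, .Machine$double.xmin))
  new("LogrankResult", statistic = v, pValue = p, method = method,
      variance = vr, n = seq@n, n1 = seq@n1)
}
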