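#' EventSequence: ordered event representation of a two-group survival cohort
#'
#' A cohort of right-censored survival records reduces, for the purposes of
#' the log-rank statistic and both exact null distributions, to two binary
#' vectors read off the time-ordered records: \code{x} (group membership of
#' each ordered event; 1 = group 1, e.g. mutated) and \code{c} (1 = death
#' observed, 0 = censored).  Only the order of events matters; actual times
#' are discarded.
#'
#' @slot x integer vector of 0/1 group labels in event order.
#' @slot c integer vector of 0/1 censoring indicators in event order
#'   (1 = uncensored).
#' @slot n total number of records.
#' @slot n1 number of group-1 records (\code{sum(x)}).
#' @slot ordering integer permutation mapping positions in the ordered
#'   sequence back to rows of the input records (may be empty when the
#'   sequence was built directly from \code{x} and \code{c}).
#' @exportClass EventSequence
setClass("EventSequence",
  representation(x = "integer", c = "integer", n = "integer", n1 = "integer",
                 ordering = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@x) != object@n || length(object@c) != object@n)
      msg <- c(msg, "x and c must both have length n")
    if (!all(object@x %in% c(0L, 1L))) msg <- c(msg, "x must be binary")
    if (!all(object@c %in% c(0L, 1L))) msg <- c(msg, "c must be binary")
    if (sum(object@x) != object@n1) msg <- c(msg, "n1 must equal sum(x)")
    if (length(object@ordering) &&
        !setequal(object@ordering, seq_len(object@n)))
      msg <- c(msg, "ordering must be a permutation of 1..n")
    if (is.null(msg)) TRUE else msg
  })

#' StepFunction: monotone step representation of a tail probability
#'
#' Represents one tail of a null distribution of the log-rank statistic as a
#' monotone step function of the statistic value v.  For side
#' \code{"lower"} the represented function is \eqn{\Pr(V \le v)}
#' (non-decreasing); for side \code{"upper"} it is \eqn{\Pr(V \ge v)}
#' (non-increasing).  Probabilities are stored in log space.  For
#' FPTAS-discretized functions, \code{levels} holds the integer grid
#' exponents k with represented probability \eqn{(1-\epsilon_1)^k} and
#' \code{gridStep} holds \eqn{\log(1-\epsilon_1)}; for exact functions
#' \code{levels} is empty and \code{gridStep} is \code{NA}.
#'
#' @slot breakpoints numeric, strictly increasing statistic values.
#' @slot logProb numeric, log probabilities at the breakpoints (monotone
#'   consistently with \code{side}).
#' @slot levels integer grid level indices (FPTAS functions only).
#' @slot gridStep numeric, log of the grid ratio \eqn{1-\epsilon_1}
#'   (\code{NA} for exact functions).
#' @slot side \code{"lower"} or \code{"upper"}.
#' @exportClass StepFunction
setClass("StepFunction",
  representation(breakpoints = "numeric", logProb = "numeric",
                 levels = "integer", gridStep = "numeric", side = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@side %in% c("lower", "upper"))
      msg <- c(msg, "side must be 'lower' or 'upper'")
    if (length(object@breakpoints) != length(object@logProb))
      msg <- c(msg, "breakpoints and logProb lengths differ")
    if (is.unsorted(object@breakpoints, strictly = FALSE))
      msg <- c(msg, "breakpoints must be increasing")
    d <- diff(object@logProb)
    if (length(d)) {
      if (object@side == "lower" && any(d < 0))
        msg <- c(msg, "lower-tail probabilities must be non-decreasing in v")
      if (object@side == "upper" && any(d > 0))
        msg <- c(msg, "upper-tail probabilities must be non-increasing in v")
    }
    if (any(object@logProb > 1e-9)) msg <- c(msg, "probabilities must be <= 1")
    if (is.null(msg)) TRUE else msg
  })

#' PermNullDistribution: the permutational null of the log-rank statistic
#'
#' The full null distribution of the log-rank statistic under uniform random
#' labeling, for a fixed censoring vector, group-1 size and (for FPTAS
#' output) approximation parameter.  It is reusable across any group-label
#' vector with the same censoring vector and the same number of ones, which
#' is what makes distribution caching effective in screens.
#'
#' @slot cens integer censoring vector (1 = uncensored), in event order.
#' @slot n1 group-1 size the distribution conditions on.
#' @slot epsilon approximation parameter of the FPTAS run (0 for the exact,
#'   undiscretized dynamic program).
#' @slot P lower-tail \linkS4class{StepFunction}.
#' @slot Q upper-tail \linkS4class{StepFunction}.
#' @slot support numeric support values of the exact distribution (exact DP
#'   only; empty for FPTAS output).
#' @slot counts numeric labeling counts per support value (exact DP only;
#'   they sum to \code{choose(n, n1)}).
#' @slot cacheKey character digest of (cens, n1, epsilon).
#' @exportClass PermNullDistribution
setClass("PermNullDistribution",
  representation(cens = "integer", n1 = "integer", epsilon = "numeric",
                 P = "StepFunction", Q = "StepFunction",
                 support = "numeric", counts = "numeric", cacheKey = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (object@n1 < 0 || object@n1 > length(object@cens))
      msg <- c(msg, "n1 out of range")
    if (length(object@support) != length(object@counts))
      msg <- c(msg, "support and counts lengths differ")
    if (is.null(msg)) TRUE else msg
  })

#' LogrankResult: the outcome of a single log-rank test
#'
#' @slot statistic observed log-rank statistic v.
#' @slot pValue p-value in (0, 1].
#' @slot method one of \code{"perm_exact_enum"}, \code{"perm_exact_fptas"},
#'   \code{"perm_mc"}, \code{"cond_exact"}, \code{"asym_cond"},
#'   \code{"asym_perm"}.
#' @slot epsilon FPTAS approximation parameter (\code{NA} otherwise); when
#'   present the reported p-value p-hat satisfies
#'   \eqn{p \le \hat p \le (1+\epsilon) p}.
#' @slot ciLow,ciHigh Clopper-Pearson interval bounds (Monte-Carlo method
#'   only, \code{NA} otherwise).
#' @slot variance normalizing variance used (asymptotic methods, \code{NA}
#'   otherwise).
#' @slot n,n1 cohort and group-1 sizes.
#' @slot flags character vector of annotations (e.g.
#'   \code{"zero_variance"}, \code{"conservative_bound"}).
#' @exportClass LogrankResult
setClass("LogrankResult",
  representation(statistic = "numeric", pValue = "numeric", method = "character",
                 epsilon = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 variance = "numeric", n = "integer", n1 = "integer",
                 flags = "character"),
  prototype(epsilon = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
            variance = NA_real_, flags = character(0)),
  validity = function(object) {
    msg <- NULL
    methods <- c("perm_exact_enum", "perm_exact_fptas", "perm_mc",
                 "cond_exact", "asym_cond", "asym_perm")
    if (!object@method %in% methods)
      msg <- c(msg, paste("method must be one of:", paste(methods, collapse = ", ")))
    if (!(object@pValue > 0 && object@pValue <= 1))
      msg <- c(msg, "pValue must be in (0, 1]")
    if (object@method == "perm_exact_fptas" && is.na(object@epsilon))
      msg <- c(msg, "FPTAS results must record epsilon")
    if (is.null(msg)) TRUE else msg
  })

#' ConditionalNull: exact conditional null of the log-rank statistic
#'
#' With ties broken, each uncensored event time j contributes an independent
#' Bernoulli term with success probability \eqn{p_j = R_{j,1}/R_j} (group-1
#' at-risk over total at-risk), and the statistic is the sum of the centered
#' terms.  The support/mass slots hold the convolved exact distribution.
#'
#' @slot probs Bernoulli probabilities \eqn{p_j}, one per uncensored event.
#' @slot support achievable statistic values, sorted.
#' @slot mass probabilities per support value (sum to 1).
#' @exportClass ConditionalNull
setClass("ConditionalNull",
  representation(probs = "numeric", support = "numeric", mass = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@probs < 0 | object@probs > 1))
      msg <- c(msg, "probs must lie in [0, 1]")
    if (length(object@support) != length(object@mass))
      msg <- c(msg, "support and mass lengths differ")
    if (length(object@mass) && abs(sum(object@mass) - 1) > 1e-9)
      msg <- c(msg, "mass must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' MutationMatrix: binary gene-by-patient mutation incidence
#'
#' @slot incidence integer matrix of 0/1 entries; rownames are gene
#'   identifiers, colnames patient identifiers, both unique.
#' @exportClass MutationMatrix
setClass("MutationMatrix",
  representation(incidence = "matrix"),
  validity = function(object) {
    msg <- NULL
    inc <- object@incidence
    if (is.null(rownames(inc)) || is.null(colnames(inc)))
      msg <- c(msg, "incidence must have gene rownames and patient colnames")
    else {
      if (anyDuplicated(rownames(inc))) msg <- c(msg, "duplicate gene identifiers")
      if (anyDuplicated(colnames(inc))) msg <- c(msg, "duplicate patient identifiers")
    }
    if (!all(inc %in% c(0L, 1L))) msg <- c(msg, "incidence entries must be 0/1")
    if (is.null(msg)) TRUE else msg
  })

#' MetageneSet: groups of genes with identical mutation patterns
#'
#' Genes mutated in exactly the same set of patients are statistically
#' indistinguishable for survival association, so they are collapsed into
#' metagenes before testing.
#'
#' @slot pattern integer metagene-by-patient 0/1 matrix (one row per
#'   metagene, rownames are metagene labels).
#' @slot members named list mapping each metagene label to the character
#'   vector of member gene identifiers.
#' @exportClass MetageneSet
setClass("MetageneSet",
  representation(pattern = "matrix", members = "list"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@pattern) != length(object@members))
      msg <- c(msg, "one members entry per metagene required")
    if (!all(lengths(object@members) >= 1L))
      msg <- c(msg, "every metagene must have at least one member gene")
    if (!all(object@pattern %in% c(0L, 1L)))
      msg <- c(msg, "pattern entries must be 0/1")
    if (is.null(msg)) TRUE else msg
  })
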