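#' @name accessors
#' @title Accessors for exactLogrank classes
#' @param object an object of one of the package's S4 classes.
#' @description Accessor generics: \code{pValue} and \code{statValue} extract
#'   the p-value and observed statistic from a \linkS4class{LogrankResult};
#'   \code{testMethod} its method tag; \code{groupLabels} and
#'   \code{censorIndicators} the binary vectors of an
#'   \linkS4class{EventSequence}; \code{nGroup1} the group-1 count;
#'   \code{mutationFrequency} the per-gene mutation frequencies of a
#'   \linkS4class{MutationMatrix}.
NULL

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("statValue", function(object) standardGeneric("statValue"))

#' @rdname accessors
#' @export
setGeneric("testMethod", function(object) standardGeneric("testMethod"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("censorIndicators", function(object) standardGeneric("censorIndicators"))

#' @rdname accessors
#' @export
setGeneric("nGroup1", function(object) standardGeneric("nGroup1"))

#' @rdname accessors
#' @export
setGeneric("mutationFrequency", function(object) standardGeneric("mutationFrequency"))

#' @rdname accessors
#' @export
setMethod("pValue", "LogrankResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setMethod("statValue", "LogrankResult", function(object) object@statistic)

#' @rdname accessors
#' @export
setMethod("testMethod", "LogrankResult", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("groupLabels", "EventSequence", function(object) object@x)

#' @rdname accessors
#' @export
setMethod("censorIndicators", "EventSequence", function(object) object@c)

#' @rdname accessors
#' @export
setMethod("nGroup1", "EventSequence", function(object) object@n1)

#' @rdname accessors
#' @export
setMethod("mutationFrequency", "MutationMatrix",
          function(object) rowMeans(object@incidence))

#' @describeIn accessors number of records in an EventSequence.
#' @export
setMethod("length", "EventSequence", function(x) x@n)

setMethod("show", "EventSequence", function(object) {
  cat(sprintf("EventSequence: n = %d, n1 = %d, uncensored = %d\n",
              object@n, object@n1, sum(object@c)))
  k <- min(object@n, 20L)
  cat("  x:", paste(object@x[seq_len(k)], collapse = ""),
      if (object@n > k) "...\n" else "\n")
  cat("  c:", paste(object@c[seq_len(k)], collapse = ""),
      if (object@n > k) "...\n" else "\n")
})

setMethod("show", "LogrankResult", function(object) {
  cat(sprintf("Log-rank test (%s): n = %d, n1 = %d\n",
              object@method, object@n, object@n1))
  cat(sprintf("  statistic v = %.6g, p = %.6g\n", object@statistic, object@pValue))
  if (!is.na(object@epsilon))
    cat(sprintf("  conservative FPTAS bound: p <= p-hat <= (1+%.3g) p\n",
                object@epsilon))
  if (!is.na(object@ciLow))
    cat(sprintf("  Clopper-Pearson interval: [%.6g, %.6g]\n",
                object@ciLow, object@ciHigh))
  if (!is.na(object@variance))
    cat(sprintf("  variance = %.6g\n", object@variance))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "PermNullDistribution", function(object) {
  kind <- if (object@epsilon > 0) sprintf("FPTAS, epsilon = %g", object@epsilon)
          else "exact dynamic program"
  cat(sprintf("PermNullDistribution (%s): n = %d, n1 = %d\n",
              kind, length(object@cens), object@n1))
  cat(sprintf("  lower-tail breakpoints: %d, upper-tail: %d\n",
              length(object@P@breakpoints), length(object@Q@breakpoints)))
})

setMethod("show", "StepFunction", function(object) {
  cat(sprintf("StepFunction (%s tail): %d breakpoints", object@side,
              length(object@breakpoints)))
  if (!is.na(object@gridStep))
    cat(sprintf(", grid ratio %.8g", exp(object@gridStep)))
  cat("\n")
})

setMethod("show", "MutationMatrix", function(object) {
  cat(sprintf("MutationMatrix: %d genes x %d patients, %d calls\n",
              nrow(object@incidence), ncol(object@incidence),
              sum(object@incidence)))
})

setMethod("show", "MetageneSet", function(object) {
  cat(sprintf("MetageneSet: %d metagenes over %d patients (%d member genes)\n",
              nrow(object@pattern), ncol(object@pattern),
              sum(lengths(object@members))))
})
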