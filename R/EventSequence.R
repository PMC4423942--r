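#' Construct an EventSequence from binary vectors
#'
#' Low-level constructor taking the ordered group-label and censoring vectors
#' directly.  Most users will instead call \code{\link{buildEventSequence}} on
#' patient-level records.
#'
#' @param x binary vector (1 = group 1) in event order.
#' @param c binary vector (1 = uncensored) in event order.
#' @param ordering optional integer permutation mapping event positions to
#'   input record rows.
#' @return an \linkS4class{EventSequence}.
#' @export
#' @examples
#' EventSequence(c(1, 0, 0), c(1, 1, 0))
EventSequence <- function(x, c, ordering = integer(0)) {
  x <- as.integer(x); c <- as.integer(c)
  obj <- new("EventSequence", x = x, c = c, n = length(x),
             n1 = sum(x), ordering = as.integer(ordering))
  validObject(obj)
  obj
}

#' Reduce patient-level survival records to an ordered event sequence
#'
#' Records are sorted by ascending follow-up time; ties are broken by a
#' uniformly random permutation drawn from a generator seeded with
#' \code{tieSeed}, so the reduction is reproducible.  Only the order of
#' events matters for the log-rank statistic and its exact nulls, so times
#' are discarded after sorting.
#'
#' @param records a data.frame with columns \code{time} (non-negative),
#'   \code{event} (1 = death observed, 0 = censored) and \code{group}
#'   (1 = group 1, e.g. mutated); a \code{sample_id} column is carried
#'   through via the \code{ordering} slot but not otherwise used.
#' @param tieSeed integer seed for tie-breaking.
#' @return an \linkS4class{EventSequence}.
#' @export
#' @examples
#' rec <- data.frame(time = c(3, 5, 7), event = c(1, 1, 0), group = c(0, 1, 0))
#' buildEventSequence(rec)
buildEventSequence <- function(records, tieSeed = 1L) {
  if (is.null(records) || nrow(records) == 0L) dataStop("empty cohort")
  need <- c("time", "event", "group")
  miss <- setdiff(need, names(records))
  if (length(miss))
    dataStop(paste("missing columns:", paste(miss, collapse = ", ")))
  time <- as.numeric(records$time)
  if (any(is.na(time)) || any(time < 0)) dataStop("times must be non-negative")
  event <- as.integer(records$event)
  group <- as.integer(records$group)
  if (!all(event %in% c(0L, 1L))) dataStop("event must be 0/1")
  if (!all(group %in% c(0L, 1L))) dataStop("group must be 0/1")
  jitter <- withSeed(tieSeed, runif(length(time)))
  ord <- order(time, jitter)
  EventSequence(group[ord], event[ord], ordering = ord)
}

#' The two-sample log-rank statistic
#'
#' Evaluates, left to right over the ordered events,
#' \deqn{V = \sum_{j=1}^{n} c_j \left(x_j - \frac{n_1 - \sum_{i<j} x_i}{n-j+1}\right),}
#' the sum over uncensored events of the observed minus expected group-1
#' deaths given the at-risk sets.  Degenerate sequences (no group-1 members,
#' all censored) are legal and give 0.
#'
#' @param seq an \linkS4class{EventSequence}.
#' @return the statistic value \code{v}.
#' @export
#' @examples
#' logrankStatistic(EventSequence(c(1, 0), c(1, 1)))  # 0.5
logrankStatistic <- function(seq) {
  stopifnot(is(seq, "EventSequence"))
  n <- seq@n
  x <- seq@x; cc <- seq@c
  atRisk1 <- seq@n1 - c(0, cumsum(x))[seq_len(n)]  # group-1 at risk before event j
  sum(cc * (x - atRisk1 / (n - seq_len(n) + 1)))
}

#' Log-rank scores (linear rank form)
#'
#' The log-rank statistic is a linear rank statistic: \eqn{V = \sum_i x_i a_i}
#' with scores \eqn{a_i = c_i - \sum_{j \le i} c_j / (n - j + 1)}.  The scores
#' sum to zero, which makes the permutational moments of V those of a simple
#' random sample from a finite population.
#'
#' @param seq an \linkS4class{EventSequence}.
#' @return numeric vector of scores, one per ordered event.
#' @export
logrankScores <- function(seq) {
  stopifnot(is(seq, "EventSequence"))
  n <- seq@n
  seq@c - cumsum(seq@c / (n - seq_len(n) + 1))
}

#' Permutational variance of the log-rank statistic
#'
#' The variance of V under uniform random assignment of the \eqn{n_1} group-1
#' labels: the finite-population variance of a linear rank statistic,
#' \deqn{\mathrm{Var}(V) = \frac{n_1 (n - n_1)}{n (n-1)} \sum_i a_i^2,}
#' with the scores of \code{\link{logrankScores}}.
#'
#' @param seq an \linkS4class{EventSequence} with at least two records.
#' @return the variance (0 when \eqn{n_1 \in \{0, n\}}).
#' @export
permVariance <- function(seq) {
  stopifnot(is(seq, "EventSequence"))
  if (seq@n < 2L) usageStop("permutational variance requires n >= 2")
  a <- logrankScores(seq)
  seq@n1 * (seq@n - seq@n1) / (seq@n * (seq@n - 1)) * sum(a^2)
}

#' Conditional (hypergeometric) variance of the log-rank statistic
#'
#' Under the conditional null each uncensored event time contributes an
#' independent hypergeometric term; with ties broken these are Bernoulli with
#' success probability \eqn{p_j = R_{j,1}/R_j}, and the variance is
#' \eqn{\sum_j p_j (1 - p_j)} over uncensored times.
#'
#' @param seq an \linkS4class{EventSequence}.
#' @return the variance.
#' @export
condVariance <- function(seq) {
  p <- conditionalBernoulliProbs(seq)
  sum(p * (1 - p))
}

# p_j = R_{j,1} / R_j at each uncensored event, given the observed trajectory
conditionalBernoulliProbs <- function(seq) {
  stopifnot(is(seq, "EventSequence"))
  n <- seq@n
  atRisk1 <- seq@n1 - c(0, cumsum(seq@x))[seq_len(n)]
  p <- atRisk1 / (n - seq_len(n) + 1)
  p[seq@c == 1L]
}

#' Read a clinical survival table
#'
#' Reads a delimited text file (tab-separated by default) with a mandatory
#' header and required columns \code{sample_id}, \code{time} and \code{event}
#' (0/1); an optional \code{group} column supplies group labels directly.
#' Lines starting with \code{#} are skipped.
#'
#' @param path file path.
#' @param sep field separator (tab by default; pass \code{","} for CSV).
#' @return a data.frame with one row per patient.
#' @export
readClinicalTable <- function(path, sep = "\t") {
  if (!file.exists(path)) usageStop(paste("cannot read clinical file:", path))
  d <- read.delim(path, sep = sep, comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    dataStop(paste("clinical table lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$sample_id)) dataStop("duplicate sample_id in clinical table")
  d$time <- as.numeric(d$time)
  d$event <- as.integer(d$event)
  if (any(is.na(d$time)) || any(d$time < 0)) dataStop("times must be non-negative")
  if (!all(d$event %in% c(0L, 1L))) dataStop("event must be 0/1")
  d
}
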