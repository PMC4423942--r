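# Genome-wide screening pipeline: frequency filters, metagene collapsing,
# Monte-Carlo prescreen, FPTAS on survivors with distribution caching, and
# multiple-testing correction.

#' Construct a MutationMatrix
#'
#' @param incidence 0/1 matrix with gene rownames and patient colnames.
#' @return a \linkS4class{MutationMatrix}.
#' @export
MutationMatrix <- function(incidence) {
  mode(incidence) <- "integer"
  obj <- new("MutationMatrix", incidence = incidence)
  validObject(obj)
  obj
}

#' Filter genes by mutation frequency
#'
#' Keeps genes whose mutation frequency f (row mean of the incidence matrix)
#' satisfies \code{fmin < f <= fmax}.  The defaults drop genes mutated in at
#' most 1 percent of patients (too few group-1 members to test) and genes
#' mutated in more than 10 percent (where the asymptotic approximation is
#' adequate and the screening protocol excludes them); the boundary closure
#' (strict below, inclusive above) is this package's stated convention.
#'
#' @param m a \linkS4class{MutationMatrix}.
#' @param fmin,fmax frequency bounds, \code{0 <= fmin < fmax <= 1}.
#' @return the filtered \linkS4class{MutationMatrix}.
#' @export
filterGenes <- function(m, fmin = 0.01, fmax = 0.10) {
  stopifnot(is(m, "MutationMatrix"))
  if (!(fmin >= 0 && fmin < fmax && fmax <= 1))
    usageStop("need 0 <= fmin < fmax <= 1")
  f <- rowMeans(m@incidence)
  MutationMatrix(m@incidence[f > fmin & f <= fmax, , drop = FALSE])
}

#' Collapse genes with identical mutation patterns into metagenes
#'
#' Genes mutated in exactly the same patients have identical survival
#' association, so they are grouped into one metagene each; member gene
#' names are recorded.  Output order is deterministic: metagenes are sorted
#' lexicographically by their first member gene.
#'
#' @param m a \linkS4class{MutationMatrix}.
#' @return a \linkS4class{MetageneSet}.
#' @export
collapseMetagenes <- function(m) {
  stopifnot(is(m, "MutationMatrix"))
  inc <- m@incidence
  key <- apply(inc, 1, paste, collapse = "")
  members <- split(rownames(inc), key)
  members <- lapply(members, sort)
  first <- unname(vapply(members, `[`, character(1), 1L))
  members <- unname(members)[order(first)]
  labels <- sort(first)
  pattern <- inc[labels, , drop = FALSE]
  rownames(pattern) <- labels
  names(members) <- labels
  new("MetageneSet", pattern = pattern, members = members)
}

#' Multiple-testing correction
#'
#' Bonferroni (\code{min(1, m * p)}) or Benjamini-Hochberg step-up adjusted
#' q-values with monotonicity enforcement, via \code{stats::p.adjust}.
#'
#' @param p p-values in (0, 1].
#' @param method \code{"bonferroni"} or \code{"bh_fdr"}.
#' @param m correction denominator (defaults to \code{length(p)}).
#' @return adjusted p-values.
#' @export
adjustPValues <- function(p, method = c("bonferroni", "bh_fdr"), m = length(p)) {
  method <- match.arg(method)
  if (any(!(p > 0 & p <= 1))) dataStop("p-values must be in (0, 1]")
  p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH", n = m)
}

#' Screen configuration
#'
#' @param prescreenReps Monte-Carlo labelings per metagene in the prescreen.
#' @param prescreenThreshold MC p-value below which the FPTAS is run.
#' @param epsilon FPTAS approximation parameter for survivors.
#' @param fmin,fmax mutation-frequency filter bounds.
#' @param alpha significance level used for the reported discovery flags.
#' @param tieSeed seed for survival-time tie-breaking.
#' @param mcSeed base seed for the per-metagene Monte-Carlo prescreen.
#' @param conf confidence level of the prescreen Clopper-Pearson intervals.
#' @param correctionM correction denominator; \code{NULL} means the number
#'   of tested metagenes.
#' @return a list of settings for \code{\link{runScreen}}.
#' @export
screenConfig <- function(prescreenReps = 1e4, prescreenThreshold = 0.01,
                         epsilon = 1.5, fmin = 0.01, fmax = 0.10,
                         alpha = 0.05, tieSeed = 1L, mcSeed = 1L,
                         conf = 0.95, correctionM = NULL) {
  list(prescreenReps = as.integer(prescreenReps),
       prescreenThreshold = prescreenThreshold, epsilon = epsilon,
       fmin = fmin, fmax = fmax, alpha = alpha, tieSeed = as.integer(tieSeed),
       mcSeed = as.integer(mcSeed), conf = conf, correctionM = correctionM)
}

#' Run a survival screen over a mutation matrix
#'
#' For each metagene (after frequency filtering and collapsing): builds the
#' event sequence against the shared clinical ordering, estimates the
#' permutational p-value by Monte-Carlo, and, when the estimate is at or
#' below the prescreen threshold, computes the conservative FPTAS p-value,
#' reusing cached null distributions across metagenes with equal group-1
#' counts.  Rows are ranked by the final p-value (FPTAS where present, else
#' the conservative MC estimate, flagged per row); Bonferroni and BH-FDR
#' corrections use the number of tested metagenes as denominator unless
#' overridden in the configuration.
#'
#' @param m a \linkS4class{MutationMatrix}.
#' @param clinical data.frame with columns \code{sample_id}, \code{time},
#'   \code{event} covering exactly the matrix's patients.
#' @param config settings from \code{\link{screenConfig}}.
#' @param cache optional distribution cache to reuse across screens of the
#'   same cohort.
#' @return a data.frame with one row per metagene: \code{metagene},
#'   \code{members}, \code{n1}, \code{f}, \code{mc_p}, \code{mc_ci_low},
#'   \code{mc_ci_high}, \code{exact_p}, \code{epsilon}, \code{p},
#'   \code{p_source}, \code{bonferroni_p}, \code{fdr_q}, \code{rank};
#'   attributes \code{cacheHits}/\code{cacheMisses} report distribution
#'   reuse.
#' @export
runScreen <- function(m, clinical, config = screenConfig(), cache = NULL) {
  stopifnot(is(m, "MutationMatrix"))
  patients <- colnames(m@incidence)
  missingClin <- setdiff(patients, clinical$sample_id)
  missingMat <- setdiff(clinical$sample_id, patients)
  if (length(missingClin) || length(missingMat))
    dataStop(paste0(
      "patient sets differ; absent from clinical: {",
      paste(missingClin, collapse = ", "), "}; absent from matrix: {",
      paste(missingMat, collapse = ", "), "}"))
  clinical <- clinical[match(patients, clinical$sample_id), ]

  filtered <- filterGenes(m, config$fmin, config$fmax)
  mg <- collapseMetagenes(filtered)
  nMeta <- nrow(mg@pattern)
  if (nMeta == 0L) return(emptyScreenResult())

  # shared ordering of the cohort: tie-broken once per screen
  jitter <- withSeed(config$tieSeed, runif(nrow(clinical)))
  ord <- order(clinical$time, jitter)
  cens <- as.integer(clinical$event[ord])
  n <- length(cens)
  if (is.null(cache)) cache <- newDistributionCache()
  hits0 <- cache$hits; misses0 <- cache$misses

  rows <- lapply(seq_len(nMeta), function(i) {
    x <- mg@pattern[i, ord]
    sq <- EventSequence(x, cens)
    mc <- mcPValue(sq, reps = config$prescreenReps,
                   seed = config$mcSeed + i, conf = config$conf)
    exactP <- NA_real_
    if (mc@pValue <= config$prescreenThreshold)
      exactP <- pValue(cachedFptasPValue(cache, sq, config$epsilon))
    data.frame(metagene = rownames(mg@pattern)[i],
               members = paste(mg@members[[i]], collapse = ","),
               n1 = sq@n1, f = sq@n1 / n,
               mc_p = mc@pValue, mc_ci_low = mc@ciLow, mc_ci_high = mc@ciHigh,
               exact_p = exactP,
               epsilon = if (is.na(exactP)) NA_real_ else config$epsilon,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p <- ifelse(is.na(out$exact_p), out$mc_p, out$exact_p)
  out$p_source <- ifelse(is.na(out$exact_p), "mc", "fptas")
  mCorr <- if (is.null(config$correctionM)) nMeta else config$correctionM
  out$bonferroni_p <- adjustPValues(out$p, "bonferroni", m = mCorr)
  out$fdr_q <- adjustPValues(out$p, "bh_fdr", m = mCorr)
  out <- out[order(out$p, out$metagene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "cacheHits") <- cache$hits - hits0
  attr(out, "cacheMisses") <- cache$misses - misses0
  out
}

emptyScreenResult <- function() {
  data.frame(metagene = character(0), members = character(0),
             n1 = integer(0), f = numeric(0), mc_p = numeric(0),
             mc_ci_low = numeric(0), mc_ci_high = numeric(0),
             exact_p = numeric(0), epsilon = numeric(0), p = numeric(0),
             p_source = character(0), bonferroni_p = numeric(0),
             fdr_q = numeric(0), rank = integer(0),
             stringsAsFactors = FALSE)
}

#' Write screen results to a TSV file
#'
#' @param results data.frame from \code{\link{runScreen}}.
#' @param path output file path.
#' @export
writeScreenResults <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
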