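# Synthetic cohorts with exponential survival and censoring, two mutation
# assignment schemes, and the null calibration experiment.

#' Simulate a survival cohort
#'
#' Survival times are exponential with mean \code{meanSurvival} (default 30,
#' arbitrary time units).  Censoring is an independent competing exponential
#' whose rate is chosen so that a record is censored before its event with
#' probability \code{censorFrac}: for competing exponentials the censored
#' fraction is \eqn{\lambda_c / (\lambda_c + \lambda_s)}, giving
#' \eqn{\lambda_c = \frac{censorFrac}{1 - censorFrac} \lambda_s}.  The
#' recorded time is the minimum of the two draws and \code{event} indicates
#' the survival time came first.
#'
#' @param n cohort size (>= 1).
#' @param censorFrac expected fraction of censored records, in [0, 1).
#' @param meanSurvival mean of the survival-time distribution (> 0).
#' @param seed RNG seed.
#' @return a data.frame with columns \code{sample_id}, \code{time},
#'   \code{event}.
#' @export
simulateCohort <- function(n, censorFrac = 0, meanSurvival = 30, seed = NULL) {
  if (n < 1) usageStop("n must be >= 1")
  if (censorFrac < 0 || censorFrac >= 1) usageStop("censorFrac must be in [0, 1)")
  if (meanSurvival <= 0) usageStop("meanSurvival must be > 0")
  withSeed(seed, {
    surv <- rexp(n, rate = 1 / meanSurvival)
    if (censorFrac == 0) {
      time <- surv
      event <- rep(1L, n)
    } else {
      lambdaC <- censorFrac / (1 - censorFrac) / meanSurvival
      cens <- rexp(n, rate = lambdaC)
      time <- pmin(surv, cens)
      event <- as.integer(surv <= cens)
    }
    data.frame(sample_id = sprintf("P%05d", seq_len(n)), time = time,
               event = event, stringsAsFactors = FALSE)
  })
}

#' Assign mutations to exactly a fixed fraction of patients
#'
#' Exactly \code{round(f * n)} patients (round half up) receive the
#' mutation, at positions drawn uniformly without replacement, independent
#' of survival.
#'
#' @param n number of patients.
#' @param f target mutation frequency.
#' @param seed RNG seed.
#' @return binary integer vector of length \code{n}.
#' @export
assignMutationsFixed <- function(n, f, seed = NULL) {
  k <- floor(f * n + 0.5)  # round half up
  if (k < 0 || k > n) usageStop("f * n must round into 0..n")
  x <- integer(n)
  if (k > 0) x[withSeed(seed, sample.int(n, k))] <- 1L
  x
}

#' Assign mutations independently with probability f
#'
#' Each patient is mutated independently with probability \code{f},
#' modelling per-patient mutation occurrence; the realized count varies.
#'
#' @inheritParams assignMutationsFixed
#' @return binary integer vector of length \code{n}.
#' @export
assignMutationsBernoulli <- function(n, f, seed = NULL) {
  if (f < 0 || f > 1) usageStop("f must be in [0, 1]")
  withSeed(seed, as.integer(rbinom(n, 1L, f)))
}

#' Generate a fully-null mutation matrix
#'
#' Independent null genes on a common patient set: each gene's frequency is
#' drawn uniformly from \code{fRange} and its pattern assigned by the chosen
#' scheme, independent of any survival data.  Used by the null-screen
#' experiments.
#'
#' @param nGenes,nPatients matrix dimensions.
#' @param fRange range from which per-gene mutation frequencies are drawn.
#' @param scheme \code{"bernoulli"} (independent per patient) or
#'   \code{"fixed"} (exact rounded count).
#' @param seed RNG seed.
#' @return a \linkS4class{MutationMatrix}.
#' @export
nullMutationMatrix <- function(nGenes, nPatients, fRange = c(0.01, 0.10),
                               scheme = c("bernoulli", "fixed"), seed = NULL) {
  scheme <- match.arg(scheme)
  withSeed(seed, {
    f <- runif(nGenes, fRange[1], fRange[2])
    inc <- vapply(seq_len(nGenes), function(g) {
      if (scheme == "bernoulli") as.integer(rbinom(nPatients, 1L, f[g]))
      else {
        x <- integer(nPatients)
        k <- floor(f[g] * nPatients + 0.5)
        if (k > 0) x[sample.int(nPatients, k)] <- 1L
        x
      }
    }, integer(nPatients))
    inc <- t(inc)
    dimnames(inc) <- list(sprintf("G%05d", seq_len(nGenes)),
                          sprintf("P%05d", seq_len(nPatients)))
    new("MutationMatrix", incidence = inc)
  })
}

#' Null calibration experiment
#'
#' Generates \code{reps} null instances (no association between labels and
#' survival), applies each requested test, and summarizes how uniform the
#' resulting p-values are.  With \code{reuseCohort = TRUE} a single cohort
#' is drawn and only the labels are re-randomized each rep, so all reps
#' share one censoring vector and (with \code{n1} fixed) a single cached
#' FPTAS distribution; otherwise a fresh cohort is drawn per rep.
#'
#' @param n cohort size.
#' @param n1 group-1 size per rep (fixed-count labeling), or \code{NULL} to
#'   use Bernoulli labeling with probability \code{f}.
#' @param f per-patient labeling probability when \code{n1} is \code{NULL}.
#' @param censorFrac expected censored fraction.
#' @param reps number of null instances (>= 100).
#' @param methods subset of \code{c("perm_exact_fptas", "perm_mc",
#'   "cond_exact", "asym_cond", "asym_perm")}.
#' @param seed RNG seed governing all randomness.
#' @param reuseCohort reuse one cohort across reps (see above).
#' @param epsilon FPTAS approximation parameter; the calibration default is
#'   0.01 so the conservative bound distorts the p-value distribution by at
#'   most 1 percent.
#' @param mcReps Monte-Carlo reps per instance for the \code{"perm_mc"}
#'   method.
#' @param meanSurvival mean survival time.
#' @return list with \code{results} (data.frame: rep, method, statistic, p)
#'   and \code{summary} (per method: one-sample Kolmogorov-Smirnov distance
#'   and p-value against Uniform(0,1), and the fraction of p-values below
#'   0.05 / 0.01 / 0.001).
#' @export
calibrationExperiment <- function(n, n1 = NULL, f = NULL, censorFrac = 0,
                                  reps = 2000,
                                  methods = c("perm_exact_fptas", "asym_cond"),
                                  seed = 1L, reuseCohort = TRUE,
                                  epsilon = 0.01, mcReps = 1000,
                                  meanSurvival = 30) {
  if (reps < 100) usageStop("reps must be >= 100")
  known <- c("perm_exact_fptas", "perm_mc", "cond_exact", "asym_cond", "asym_perm")
  if (!all(methods %in% known))
    usageStop(paste("unknown method(s):", paste(setdiff(methods, known), collapse = ", ")))
  if (is.null(n1) && is.null(f)) usageStop("one of n1 or f is required")
  cache <- newDistributionCache()
  rows <- vector("list", reps * length(methods))
  ri <- 0L
  if (reuseCohort) {
    cohort <- simulateCohort(n, censorFrac, meanSurvival, seed = seed)
    ord <- order(cohort$time)
    censBase <- as.integer(cohort$event[ord])
  }
  withSeed(seed + 1L, {
    for (rep in seq_len(reps)) {
      if (!reuseCohort) {
        cohort <- simulateCohort(n, censorFrac, meanSurvival, seed = NULL)
        ord <- order(cohort$time)
        censBase <- as.integer(cohort$event[ord])
      }
      x <- integer(n)
      if (!is.null(n1)) x[sample.int(n, n1)] <- 1L
      else x <- as.integer(rbinom(n, 1L, f))
      sq <- EventSequence(x, censBase)
      for (m in methods) {
        res <- switch(m,
          perm_exact_fptas = cachedFptasPValue(cache, sq, epsilon),
          perm_mc = mcPValue(sq, reps = mcReps,
                             seed = sample.int(.Machine$integer.max, 1L)),
          cond_exact = conditionalExactPValue(sq),
          asym_cond = asymptoticPValue(sq, "conditional"),
          asym_perm = asymptoticPValue(sq, "permutational"))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(rep = rep, method = m,
                                 statistic = res@statistic,
                                 p = res@pValue, stringsAsFactors = FALSE)
      }
    }
  })
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$method), function(d) {
    ks <- suppressWarnings(ks.test(d$p, "punif"))
    data.frame(method = d$method[1], reps = nrow(d),
               ks_distance = unname(ks$statistic), ks_p = ks$p.value,
               frac_below_0.05 = mean(d$p <= 0.05),
               frac_below_0.01 = mean(d$p <= 0.01),
               frac_below_0.001 = mean(d$p <= 0.001),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary,
       cacheHits = cache$hits, cacheMisses = cache$misses)
}
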