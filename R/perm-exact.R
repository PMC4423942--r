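# The exact permutational null: complete enumeration, Monte-Carlo with
# Clopper-Pearson interval, the undiscretized step-function dynamic program,
# and the FPTAS with its conservative (1+epsilon) guarantee.

#' Exact permutational p-value by complete enumeration
#'
#' Enumerates all \code{choose(n, n1)} equally likely assignments of the
#' group-1 labels to the observed (time, censoring) sequence and counts those
#' whose statistic satisfies \eqn{|V| \ge |v_{obs}|} (with absolute tolerance
#' 1e-12 on the comparison).  The count and total are integers, so the
#' returned p-value is an exact rational \code{count / choose(n, n1)}.
#'
#' @param seq an \linkS4class{EventSequence}.
#' @param guard refuse instances with more than this many labelings
#'   (use the FPTAS instead).
#' @return a \linkS4class{LogrankResult} (method \code{"perm_exact_enum"})
#'   with attributes \code{count} and \code{total}.
#' @export
enumeratePValue <- function(seq, guard = 1e7) {
  stopifnot(is(seq, "EventSequence"))
  n <- seq@n; n1 <- seq@n1
  total <- choose(n, n1)
  if (total > guard)
    guardStop(sprintf(
      "choose(%d, %d) = %g labelings exceeds the enumeration guard (%g); use fptasDistribution",
      n, n1, total, guard))
  a <- logrankScores(seq)
  vObs <- abs(logrankStatistic(seq))
  if (n1 == 0L || n1 == n) {
    count <- 1
  } else if (total <= 2e6) {
    vAll <- colSums(matrix(a[combn(n, n1)], nrow = n1))
    count <- sum(abs(vAll) >= vObs - .v_tol)
  } else {
    count <- sum(combn(n, n1, FUN = function(i) abs(sum(a[i])) >= vObs - .v_tol))
  }
  res <- new("LogrankResult", statistic = logrankStatistic(seq),
             pValue = count / total, method = "perm_exact_enum",
             n = n, n1 = n1)
  attr(res, "count") <- as.numeric(count)
  attr(res, "total") <- total
  res
}

#' Monte-Carlo permutational p-value with Clopper-Pearson interval
#'
#' Draws \code{reps} uniformly random labelings with \code{n1} ones (seeded),
#' counts \code{b} draws with \eqn{|V| \ge |v_{obs}|}, and reports the
#' conservative estimator \eqn{\tilde p = (b+1)/(reps+1)} together with the
#' exact Clopper-Pearson interval for the tail probability at confidence
#' \code{conf}.
#'
#' @param seq an \linkS4class{EventSequence}.
#' @param reps number of random labelings (>= 1).
#' @param seed RNG seed.
#' @param conf confidence level of the interval.
#' @return a \linkS4class{LogrankResult} (method \code{"perm_mc"}) with the
#'   interval in \code{ciLow}/\code{ciHigh} and attribute \code{b}.
#' @export
mcPValue <- function(seq, reps = 1e4, seed = 1L, conf = 0.95) {
  stopifnot(is(seq, "EventSequence"))
  if (reps < 1) usageStop("reps must be >= 1")
  reps <- as.integer(reps)
  a <- logrankScores(seq)
  vObs <- abs(logrankStatistic(seq))
  draws <- withSeed(seed, mc_null_stats_cpp(a, seq@n1, reps))
  b <- sum(abs(draws) >= vObs - .v_tol)
  ci <- clopperPearson(b, reps, conf)
  res <- new("LogrankResult", statistic = logrankStatistic(seq),
             pValue = (b + 1) / (reps + 1), method = "perm_mc",
             ciLow = ci[["low"]], ciHigh = ci[["high"]],
             n = seq@n, n1 = seq@n1)
  attr(res, "b") <- b
  res
}

# per-step statistic increments of the at-risk process, shared by the exact
# dynamic program; entering state (t+1, r) from (t, r) [next event group 0]
# adds -c * (n1 - r)/(n - t); from (t, r-1) [group 1] adds
# c * (1 - (n1 - r + 1)/(n - t)).
#' Exact permutational null distribution by dynamic programming
#'
#' Runs the step-function recursion over states (t, r) = (events seen,
#' group-1 events seen) with no discretization, tracking the integer number
#' of label prefixes at each achievable statistic value.  The result is the
#' full exact null distribution of V; support values closer than 1e-12 are
#' merged.  The number of support values can grow exponentially with n, hence
#' the guard.
#'
#' @param cens binary censoring vector in event order (1 = uncensored).
#' @param n1 group-1 size.
#' @param guard maximum n accepted (breakpoint growth is exponential).
#' @param keepLayers if TRUE, attach all intermediate layers (for
#'   diagnostics); each layer t is a list over r of \code{list(v, count)}.
#' @return a \linkS4class{PermNullDistribution} with \code{epsilon = 0},
#'   exact tail step functions, and the support/counts of the distribution.
#' @export
exactPermDistribution <- function(cens, n1, guard = 30L, keepLayers = FALSE) {
  cens <- as.integer(cens)
  n <- length(cens)
  n1 <- as.integer(n1)
  if (n1 < 0L || n1 > n) usageStop("n1 must be in 0..n")
  if (n > guard)
    guardStop(sprintf("n = %d exceeds the exact-DP guard (%d); use fptasDistribution",
                      n, guard))
  cur <- vector("list", n1 + 1L)
  cur[[1L]] <- list(v = 0, count = 1)
  layers <- if (keepLayers) list(cur)
  for (t in 0:(n - 1L)) {
    atRisk <- n - t
    nxt <- vector("list", n1 + 1L)
    for (r in 0:min(t + 1L, n1)) {
      vs <- numeric(0); cs <- numeric(0)
      if (r <= t && !is.null(cur[[r + 1L]]) && (atRisk - (n1 - r)) > 0L) {
        vs <- cur[[r + 1L]]$v - cens[t + 1L] * (n1 - r) / atRisk
        cs <- cur[[r + 1L]]$count
      }
      if (r >= 1L && !is.null(cur[[r]])) {
        vs <- c(vs, cur[[r]]$v + cens[t + 1L] * (1 - (n1 - r + 1) / atRisk))
        cs <- c(cs, cur[[r]]$count)
      }
      if (length(vs)) {
        o <- order(vs); vs <- vs[o]; cs <- cs[o]
        grp <- cumsum(c(1L, as.integer(diff(vs) > .v_tol)))
        nxt[[r + 1L]] <- list(v = vs[!duplicated(grp)],
                              count = as.numeric(rowsum(cs, grp)))
      }
    }
    cur <- nxt
    if (keepLayers) layers[[t + 2L]] <- cur
  }
  fin <- cur[[n1 + 1L]]
  total <- choose(n, n1)
  stopifnot(abs(sum(fin$count) - total) < 1e-6)
  lower <- new("StepFunction", breakpoints = fin$v,
               logProb = log(cumsum(fin$count)) - log(total),
               levels = integer(0), gridStep = NA_real_, side = "lower")
  upper <- new("StepFunction", breakpoints = fin$v,
               logProb = log(rev(cumsum(rev(fin$count)))) - log(total),
               levels = integer(0), gridStep = NA_real_, side = "upper")
  dist <- new("PermNullDistribution", cens = cens, n1 = n1, epsilon = 0,
              P = lower, Q = upper, support = fin$v, counts = fin$count,
              cacheKey = distributionKey(cens, n1, 0))
  if (keepLayers) attr(dist, "layers") <- layers
  dist
}

#' Grid parameters of the FPTAS
#'
#' For approximation parameter \eqn{\epsilon > 0} the probability grid uses
#' ratio \eqn{1-\epsilon_1} with \eqn{(1-\epsilon_1)^{-n} = 1+\epsilon}, i.e.
#' \eqn{\epsilon_1 = 1 - (1+\epsilon)^{-1/n}}, and
#' \eqn{\ell = \lceil -n_1 \log n / \log(1-\epsilon_1) \rceil} levels, enough
#' to reach the smallest possible non-zero probability \eqn{n^{-n_1}}.
#' Evaluated in log space (\code{log1p}/\code{expm1}) for numerical
#' stability at small \eqn{\epsilon} and large n.
#'
#' @param n cohort size.
#' @param n1 group-1 size.
#' @param epsilon approximation parameter (> 0).
#' @return list with \code{eps1}, \code{L} (= \eqn{\log(1-\epsilon_1)}) and
#'   \code{l} (number of grid levels).
#' @export
fptasGrid <- function(n, n1, epsilon) {
  if (epsilon <= 0) usageStop("epsilon must be > 0")
  L <- -log1p(epsilon) / n
  list(eps1 = -expm1(L), L = L,
       l = if (n1 == 0) 0 else ceiling(-n1 * log(n) / L))
}

#' Approximate permutational null distribution (FPTAS)
#'
#' Computes the lower- and upper-tail step functions of the permutational
#' null by the discretized dynamic program: probabilities are restricted to
#' the grid \eqn{(1-\epsilon_1)^k}, every step snaps probabilities up to the
#' grid and keeps at most one breakpoint per level, and after n steps the
#' returned functions \eqn{\tilde P, \tilde Q} sandwich the exact tails:
#' \eqn{\tilde P (1-\epsilon_1)^n \le P \le \tilde P} with
#' \eqn{(1-\epsilon_1)^{-n} = 1+\epsilon}.  P-values evaluated from the
#' result are therefore conservative and at most \eqn{(1+\epsilon)} times
#' the exact p-value.
#'
#' The distribution depends only on (\code{cens}, \code{n1},
#' \code{epsilon}), so it can be reused across any label vector with the
#' same censoring pattern and group-1 count (see
#' \code{\link{cachedFptasPValue}}).
#'
#' @inheritParams exactPermDistribution
#' @param epsilon approximation parameter (> 0); 1.5 is the screening
#'   default, 0.01 the calibration default.
#' @return a \linkS4class{PermNullDistribution}.
#' @export
fptasDistribution <- function(cens, n1, epsilon) {
  cens <- as.integer(cens)
  n <- length(cens)
  n1 <- as.integer(n1)
  if (n1 < 0L || n1 > n) usageStop("n1 must be in 0..n")
  if (epsilon <= 0) usageStop("epsilon must be > 0")
  key <- distributionKey(cens, n1, epsilon)
  if (n1 == 0L || n1 == n) {
    # single labeling: point mass at V = 0
    lower <- new("StepFunction", breakpoints = 0, logProb = 0,
                 levels = 0L, gridStep = NA_real_, side = "lower")
    upper <- new("StepFunction", breakpoints = 0, logProb = 0,
                 levels = 0L, gridStep = NA_real_, side = "upper")
    return(new("PermNullDistribution", cens = cens, n1 = n1,
               epsilon = epsilon, P = lower, Q = upper,
               support = 0, counts = 1, cacheKey = key))
  }
  g <- fptasGrid(n, n1, epsilon)
  if (g$l > 2^31 - 1)
    guardStop(sprintf(
      "grid would need %g levels; this (n, n1, epsilon) combination is not tractable",
      g$l))
  resP <- stepdp_grid_cpp(cens, n1, g$L, as.integer(g$l), 1L)
  resM <- stepdp_grid_cpp(cens, n1, g$L, as.integer(g$l), -1L)
  new("PermNullDistribution", cens = cens, n1 = n1, epsilon = epsilon,
      P = gridStepFunction(resP$v, resP$k, g$L, "lower"),
      Q = mirroredUpper(resM$v, resM$k, g$L),
      cacheKey = key)
}

#' Two-sided p-value from a permutational null distribution
#'
#' Evaluates \eqn{\hat p = P(n, n_1, -|v|) + Q(n, n_1, |v|)}: the lower tail
#' at \eqn{-|v|} plus the upper tail at \eqn{|v|}.  Mass exactly at
#' \eqn{V = 0} may be counted in both tails when \eqn{v = 0}; the result is
#' clamped to 1, which keeps the estimate conservative.  For an exact
#' distribution (\code{epsilon = 0}) the integer labeling counts are summed
#' instead, so the p-value is an exact rational.
#'
#' @param dist a \linkS4class{PermNullDistribution}.
#' @param seq an \linkS4class{EventSequence} whose censoring vector and
#'   group-1 size must match \code{dist}.
#' @return a \linkS4class{LogrankResult} (method \code{"perm_exact_fptas"}
#'   when \code{epsilon > 0}, else \code{"perm_exact_enum"}); exact results
#'   carry attributes \code{count}/\code{total}.
#' @export
fptasPValue <- function(dist, seq) {
  stopifnot(is(dist, "PermNullDistribution"), is(seq, "EventSequence"))
  if (seq@n1 != dist@n1 || !identical(seq@c, dist@cens))
    usageStop("event sequence does not match the distribution's censoring vector and n1")
  v <- logrankStatistic(seq)
  av <- abs(v)
  if (dist@epsilon == 0) {
    count <- sum(dist@counts[dist@support <= -av + .v_tol |
                             dist@support >= av - .v_tol])
    total <- choose(seq@n, seq@n1)
    res <- new("LogrankResult", statistic = v,
               pValue = min(1, count / total), method = "perm_exact_enum",
               n = seq@n, n1 = seq@n1)
    attr(res, "count") <- count
    attr(res, "total") <- total
    return(res)
  }
  p <- evaluateStepFunction(dist@P, -av) + evaluateStepFunction(dist@Q, av)
  p <- min(1, max(p, .Machine$double.xmin))
  new("LogrankResult", statistic = v, pValue = p,
      method = "perm_exact_fptas", epsilon = dist@epsilon,
      n = seq@n, n1 = seq@n1, flags = "conservative_bound")
}

#' Distribution cache for screens
#'
#' A mutable store of \linkS4class{PermNullDistribution} objects keyed by
#' (censoring vector, n1, epsilon).  Two genes measured on the same patients
#' with the same mutation count share the identical null, so screens build
#' each distribution once.  With \code{dir} set, distributions are also
#' persisted to disk (\code{<key>.rds}) and reloaded across sessions.
#'
#' @param dir optional directory for on-disk persistence.
#' @return an environment with fields \code{store}, \code{hits},
#'   \code{misses}, \code{dir}.
#' @export
newDistributionCache <- function(dir = NULL) {
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  env$store <- new.env(parent = emptyenv())
  env$hits <- 0L
  env$misses <- 0L
  env$dir <- dir
  env
}

#' Cached FPTAS p-value
#'
#' Computes the cache key from the sequence's censoring vector, group-1 size
#' and \code{epsilon}; on a miss builds and stores the FPTAS distribution,
#' on a hit reuses it.  The result is bit-for-bit identical to the uncached
#' path.
#'
#' @param cache a cache from \code{\link{newDistributionCache}}.
#' @param seq an \linkS4class{EventSequence}.
#' @param epsilon FPTAS approximation parameter.
#' @return a \linkS4class{LogrankResult} (method \code{"perm_exact_fptas"}).
#' @export
cachedFptasPValue <- function(cache, seq, epsilon) {
  stopifnot(is.environment(cache), is(seq, "EventSequence"))
  key <- distributionKey(seq@c, seq@n1, epsilon)
  dist <- cache$store[[key]]
  if (is.null(dist) && !is.null(cache$dir)) {
    f <- file.path(cache$dir, paste0(key, ".rds"))
    if (file.exists(f)) dist <- readRDS(f)
  }
  if (is.null(dist)) {
    cache$misses <- cache$misses + 1L
    dist <- fptasDistribution(seq@c, seq@n1, epsilon)
    cache$store[[key]] <- dist
    if (!is.null(cache$dir))
      saveRDS(dist, file.path(cache$dir, paste0(key, ".rds")))
  } else {
    cache$hits <- cache$hits + 1L
  }
  fptasPValue(dist, seq)
}
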