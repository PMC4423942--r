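# Independent oracles and fixture generators for the test suite.
#
# The oracles deliberately avoid the package's internal code paths: the
# statistic is evaluated term by term from its defining sum (not via the
# linear-rank scores the package uses), and null distributions are obtained
# by explicit enumeration of labelings.

# log-rank statistic evaluated directly from its definition, one ordered
# event at a time
oracleStatistic <- function(x, cc) {
  n <- length(x)
  n1 <- sum(x)
  seen1 <- 0
  v <- 0
  for (j in seq_len(n)) {
    atRisk1 <- n1 - seen1
    v <- v + cc[j] * (x[j] - atRisk1 / (n - j + 1))
    seen1 <- seen1 + x[j]
  }
  v
}

# all statistic values over the C(n, n1) labelings of a censoring pattern
oracleNullValues <- function(cc, n1) {
  n <- length(cc)
  if (n1 == 0 || n1 == n) {
    x <- integer(n); x[seq_len(n1)] <- 1L
    return(oracleStatistic(x, cc))
  }
  apply(combn(n, n1), 2, function(idx) {
    x <- integer(n); x[idx] <- 1L
    oracleStatistic(x, cc)
  })
}

# exact two-sided permutational p-value by enumeration
oraclePValue <- function(x, cc) {
  vals <- oracleNullValues(cc, sum(x))
  vObs <- abs(oracleStatistic(x, cc))
  mean(abs(vals) >= vObs - 1e-12)
}

# enumeration tail count (numerator of the exact rational p-value)
oracleTailCount <- function(cc, n1, vObs) {
  vals <- oracleNullValues(cc, n1)
  as.numeric(sum(abs(vals) >= abs(vObs) - 1e-12))
}

# random event sequence; censoring patterns include the all-censored and
# uncensored extremes with some probability
randomSequence <- function(n = NULL, nRange = 4:10) {
  if (is.null(n)) n <- sample(nRange, 1)
  n1 <- sample(0:n, 1)
  cc <- rbinom(n, 1, runif(1, 0.2, 1))
  x <- integer(n)
  if (n1 > 0) x[sample(n, n1)] <- 1L
  EventSequence(x, cc)
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "exactLogrank", mustWork = TRUE)
}

cliPath <- function() {
  system.file("cli", "exactlogrank.R", package = "exactLogrank",
              mustWork = TRUE)
}

# run the CLI in a child R process that sees the same library paths
runCli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(cliPath(), args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
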