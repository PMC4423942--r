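# Screening pipeline: frequency filter, metagene collapsing, prescreen,
# caching and multiple-testing correction.

makeMatrix <- function(rows) {
  inc <- do.call(rbind, rows)
  mode(inc) <- "integer"
  dimnames(inc) <- list(names(rows), sprintf("P%03d", seq_len(ncol(inc))))
  MutationMatrix(inc)
}

test_that("the frequency filter applies (fmin, fmax] boundaries", {
  n <- 200
  rows <- list(
    rare = c(rep(1L, 1), rep(0L, n - 1)),         # 0.5%: removed
    low = c(rep(1L, 4), rep(0L, n - 4)),          # 2%: kept
    edge = c(rep(1L, 20), rep(0L, n - 20)),       # exactly 10%: kept
    high = c(rep(1L, 21), rep(0L, n - 21)),       # 10.5%: removed
    zero = rep(0L, n))                            # all-zero: removed
  kept <- rownames(filterGenes(makeMatrix(rows))@incidence)
  expect_identical(sort(kept), c("edge", "low"))
  expect_error(filterGenes(makeMatrix(rows), 0.5, 0.2),
               class = "elr_usage_error")
})

test_that("metagene collapsing groups identical patterns only", {
  rows <- list(
    b1 = c(1L, 0L, 1L, 0L), b2 = c(1L, 0L, 1L, 0L),
    a1 = c(0L, 1L, 0L, 0L),
    near = c(1L, 0L, 1L, 1L))  # differs from b1 in one patient
  mg <- collapseMetagenes(makeMatrix(rows))
  expect_identical(nrow(mg@pattern), 3L)
  expect_identical(mg@members[["b1"]], c("b1", "b2"))
  expect_identical(lengths(mg@members)[["near"]], 1L)
  # deterministic lexicographic order by first member
  expect_identical(rownames(mg@pattern), c("a1", "b1", "near"))
})

test_that("p-value adjustment matches the step-up and cap conventions", {
  expect_equal(adjustPValues(0.2, "bonferroni"), 0.2)
  expect_equal(adjustPValues(0.2, "bh_fdr"), 0.2)
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03), "bh_fdr"), rep(0.03, 3))
  expect_equal(adjustPValues(rep(0.04, 100), "bonferroni"), rep(1, 100))
  expect_error(adjustPValues(c(0.1, 0)), class = "elr_data_error")
})

test_that("a screen prescreens, caches shared nulls, and ranks by final p", {
  set.seed(31)
  n <- 100
  cohort <- simulateCohort(n, censorFrac = 0.3, seed = 5)
  # one strongly associated gene: the ten earliest deaths are all mutated
  hot <- integer(n)
  hot[order(cohort$time)[cohort$event[order(cohort$time)] == 1L][1:10]] <- 1L
  rows <- list(hot = hot,
               dup = hot,                                    # collapses with hot
               nullA = assignMutationsFixed(n, 0.10, seed = 8),
               nullB = assignMutationsFixed(n, 0.10, seed = 9),
               flat = assignMutationsFixed(n, 0.05, seed = 10))
  m <- makeMatrix(rows)
  colnames(m@incidence) <- cohort$sample_id
  cfg <- screenConfig(prescreenReps = 2000, epsilon = 1.5, mcSeed = 2)
  res <- runScreen(m, cohort, cfg)
  expect_identical(nrow(res), 4L)  # hot+dup collapsed
  expect_identical(res$members[res$metagene == "dup"], "dup,hot")
  # the associated metagene survives the prescreen and carries an FPTAS p
  hotRow <- res[res$metagene == "dup", ]
  expect_false(is.na(hotRow$exact_p))
  expect_identical(hotRow$p_source, "fptas")
  expect_identical(hotRow$rank, 1L)
  # null metagenes with moderate MC p short-circuit the exact stage
  expect_true(all(is.na(res$exact_p[res$mc_p > 0.01])))
  # nullA and nullB share (c, n1): at most one FPTAS build for the pair
  expect_identical(order(res$p), seq_len(nrow(res)))
})

test_that("metagene collapsing never changes a p-value", {
  set.seed(32)
  n <- 40
  cohort <- simulateCohort(n, censorFrac = 0.2, seed = 6)
  x <- assignMutationsFixed(n, 0.15, seed = 7)
  m <- makeMatrix(list(g1 = x, g2 = x))
  colnames(m@incidence) <- cohort$sample_id
  cfg <- screenConfig(prescreenReps = 1000, prescreenThreshold = 1, fmin = 0,
                      fmax = 1, mcSeed = 3)
  res <- runScreen(m, cohort, cfg)
  expect_identical(nrow(res), 1L)
  # the metagene's p equals the single-gene p computed directly
  ord <- withr::with_seed(cfg$tieSeed, order(cohort$time, runif(n)))
  sq <- EventSequence(x[ord], as.integer(cohort$event[ord]))
  direct <- pValue(fptasPValue(fptasDistribution(sq@c, sq@n1, cfg$epsilon), sq))
  expect_identical(res$exact_p, direct)
})

test_that("patient mismatches are rejected with the set difference named", {
  m <- makeMatrix(list(g = c(1L, 0L, 1L)))
  clin <- data.frame(sample_id = c("P001", "P002", "P999"),
                     time = 1:3, event = c(1L, 1L, 0L))
  expect_error(runScreen(m, clin), "P003.*P999", class = "elr_data_error")
})

test_that("exact and asymptotic rankings differ on an unbalanced null screen", {
  set.seed(33)
  n <- 100
  cohort <- simulateCohort(n, censorFrac = 0.4, seed = 44)
  ord <- order(cohort$time)
  cens <- as.integer(cohort$event[ord])
  genes <- replicate(30, assignMutationsFixed(n, sample(2:8, 1) / n,
                                              seed = NULL))
  cache <- newDistributionCache()
  pExact <- numeric(30); pAsym <- numeric(30)
  for (g in 1:30) {
    sq <- EventSequence(genes[ord, g], cens)
    pExact[g] <- pValue(cachedFptasPValue(cache, sq, 0.1))
    pAsym[g] <- pValue(asymptoticPValue(sq, "conditional"))
  }
  expect_false(identical(order(pExact)[1:10], order(pAsym)[1:10]))
})
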