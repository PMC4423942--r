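# The exact permutational null: enumeration, Monte-Carlo, the undiscretized
# dynamic program, and the FPTAS with its conservative guarantee.

test_that("enumeration reproduces hand-derived and oracle p-values", {
  sq <- EventSequence(c(1, 0), c(1, 1))
  expect_equal(pValue(enumeratePValue(sq)), 1)  # both labelings give |V| = 0.5
  expect_equal(pValue(enumeratePValue(EventSequence(c(0, 0, 0), c(1, 1, 1)))), 1)
  sq4 <- EventSequence(c(1, 0, 0, 0), rep(1, 4))
  expect_equal(pValue(enumeratePValue(sq4)), 0.5)  # positions 1 and 4 qualify
  set.seed(11)
  for (i in 1:50) {
    sq <- randomSequence(nRange = 3:9)
    expect_equal(pValue(enumeratePValue(sq)), oraclePValue(sq@x, sq@c),
                 tolerance = 1e-14)
  }
  expect_error(enumeratePValue(sq4, guard = 2), class = "elr_guard_error")
})

test_that("Monte-Carlo estimator is seeded, conservative, and CP-calibrated", {
  sq0 <- EventSequence(c(0, 1, 1), c(0, 0, 0))  # v = 0
  expect_equal(pValue(mcPValue(sq0, reps = 50, seed = 3)), 1)
  sq <- EventSequence(c(1, 1, 0, 0, 0, 0, 0, 0), rep(1, 8))
  a <- mcPValue(sq, reps = 1e5, seed = 42)
  b <- mcPValue(sq, reps = 1e5, seed = 42)
  expect_identical(pValue(a), pValue(b))
  expect_identical(c(a@ciLow, a@ciHigh), c(b@ciLow, b@ciHigh))
  p <- pValue(enumeratePValue(sq))
  expect_true(a@ciLow <= p && p <= a@ciHigh)
  expect_equal(pValue(a), (attr(a, "b") + 1) / (1e5 + 1))
})

test_that("the exact DP equals enumeration as rationals on small instances", {
  set.seed(21)
  for (i in 1:40) {
    sq <- randomSequence(nRange = 3:10)
    dist <- exactPermDistribution(sq@c, sq@n1)
    res <- fptasPValue(dist, sq)
    enu <- enumeratePValue(sq)
    expect_identical(attr(res, "count"), attr(enu, "count"))
    expect_identical(attr(res, "total"), attr(enu, "total"))
    # full distribution agreement: support and counts from enumeration
    vals <- sort(oracleNullValues(sq@c, sq@n1))
    grp <- cumsum(c(1L, as.integer(diff(vals) > 1e-12)))
    expect_equal(dist@support, vals[!duplicated(grp)], tolerance = 1e-12)
    expect_identical(dist@counts, as.numeric(table(grp)[unique(grp)]))
  }
  expect_error(exactPermDistribution(rep(1L, 40), 5L), class = "elr_guard_error")
})

test_that("the final lower tail reaches exactly 1 and tails are monotone", {
  set.seed(31)
  for (i in 1:20) {
    sq <- randomSequence(nRange = 3:9)
    dist <- exactPermDistribution(sq@c, sq@n1)
    expect_equal(evaluateStepFunction(dist@P, Inf), 1, tolerance = 1e-12)
    expect_equal(evaluateStepFunction(dist@Q, -Inf), 1, tolerance = 1e-12)
    expect_true(!is.unsorted(dist@P@logProb))
    expect_true(!is.unsorted(rev(dist@Q@logProb)))
  }
})

test_that("DP layer masses follow the hypergeometric marginal", {
  set.seed(41)
  for (i in 1:15) {
    sq <- randomSequence(nRange = 4:10)
    n <- sq@n; n1 <- sq@n1
    layers <- attr(exactPermDistribution(sq@c, n1, keepLayers = TRUE), "layers")
    for (t in 0:n) {
      for (r in 0:n1) {
        cell <- layers[[t + 1]][[r + 1]]
        count <- if (is.null(cell)) 0 else sum(cell$count)
        feasible <- r <= t && (t - r) <= (n - n1)
        expect_identical(count, if (feasible) choose(t, r) else 0)
      }
    }
  }
})

test_that("grid parameters are numerically stable and as defined", {
  for (eps in c(1e-6, 1e-3, 0.1, 1.5, 10)) {
    for (n in c(10, 1000, 1e5)) {
      g <- fptasGrid(n, max(1, n %/% 20), eps)
      # (1 - eps1)^(-n) = 1 + eps, checked in log space
      expect_equal(-n * log1p(-g$eps1), log1p(eps), tolerance = 1e-12)
    }
  }
  g <- fptasGrid(100, 5, 1.5)
  expect_identical(g$l, ceiling(-5 * log(100) / g$L))
  # level counts beyond integer range are reported, not silently truncated
  expect_gt(fptasGrid(1e5, 5000, 1e-6)$l, 2^31)
  expect_error(fptasGrid(10, 2, 0), class = "elr_usage_error")
})

test_that("FPTAS p-values sandwich the exact p-value for all tested epsilon", {
  set.seed(51)
  for (i in 1:60) {
    sq <- randomSequence(nRange = 5:12)
    p <- pValue(enumeratePValue(sq))
    for (eps in c(0.1, 0.5, 1.5)) {
      dist <- fptasDistribution(sq@c, sq@n1, eps)
      ph <- pValue(fptasPValue(dist, sq))
      expect_gte(ph, p * (1 - 1e-9))
      expect_lte(ph, min(1, (1 + eps) * p) * (1 + 1e-9))
      # grid discipline: breakpoint count never exceeds l + 1
      g <- fptasGrid(sq@n, sq@n1, eps)
      expect_lte(length(dist@P@breakpoints), g$l + 1L)
      expect_lte(length(dist@Q@breakpoints), g$l + 1L)
    }
  }
})

test_that("FPTAS handles degenerate group sizes and validates inputs", {
  dist <- fptasDistribution(c(1L, 1L, 0L), 0L, 1.5)
  sq <- EventSequence(c(0, 0, 0), c(1, 1, 0))
  expect_equal(pValue(fptasPValue(dist, sq)), 1)
  expect_error(fptasDistribution(c(1L, 1L), 1L, -1), class = "elr_usage_error")
  expect_error(
    fptasPValue(fptasDistribution(c(1L, 1L, 1L), 1L, 0.5),
                EventSequence(c(1, 1, 0), c(1, 1, 1))),
    class = "elr_usage_error")
})

test_that("a v = 0 observation gets p-hat = 1 via the clamp", {
  sq <- EventSequence(c(1, 0), c(0, 0))
  dist <- fptasDistribution(sq@c, 1L, 0.5)
  expect_equal(pValue(fptasPValue(dist, sq)), 1)
})

test_that("FPTAS p-hat tightens as epsilon decreases, within the guarantee band", {
  set.seed(61)
  for (i in 1:15) {
    sq <- randomSequence(nRange = 6:10)
    p <- pValue(enumeratePValue(sq))
    phats <- vapply(c(1.5, 0.5, 0.1, 0.02), function(eps)
      pValue(fptasPValue(fptasDistribution(sq@c, sq@n1, eps), sq)), numeric(1))
    # each estimate stays within its own band; the band shrinks onto p
    expect_lte(phats[4], p * 1.02 * (1 + 1e-9))
    expect_true(all(phats >= p * (1 - 1e-9)))
  }
})

test_that("the distribution cache reuses builds and is bit-for-bit faithful", {
  cache <- newDistributionCache()
  sqA <- EventSequence(c(1, 0, 1, 0, 0, 0), c(1, 1, 0, 1, 1, 1))
  sqB <- EventSequence(c(0, 1, 0, 0, 1, 0), c(1, 1, 0, 1, 1, 1))  # same c, n1
  sqC <- EventSequence(c(0, 1, 0, 0, 0, 0), c(1, 1, 0, 1, 1, 1))  # different n1
  r1 <- cachedFptasPValue(cache, sqA, 0.5)
  expect_identical(cache$misses, 1L)
  r2 <- cachedFptasPValue(cache, sqB, 0.5)
  expect_identical(cache$hits, 1L)   # no second DP for the shared null
  cachedFptasPValue(cache, sqC, 0.5)
  expect_identical(cache$misses, 2L)  # distinct n1, distinct entry
  set.seed(71)
  for (i in 1:100) {
    sq <- randomSequence(nRange = 4:9)
    if (sq@n1 == 0 || sq@n1 == sq@n) next
    eps <- sample(c(0.2, 1.5), 1)
    cached <- cachedFptasPValue(cache, sq, eps)
    plain <- fptasPValue(fptasDistribution(sq@c, sq@n1, eps), sq)
    expect_identical(pValue(cached), pValue(plain))
  }
})

test_that("the on-disk cache persists distributions across cache objects", {
  dir <- withr::local_tempdir()
  sq <- EventSequence(c(1, 0, 0, 1, 0), c(1, 1, 1, 0, 1))
  c1 <- newDistributionCache(dir)
  p1 <- pValue(cachedFptasPValue(c1, sq, 0.5))
  c2 <- newDistributionCache(dir)
  p2 <- pValue(cachedFptasPValue(c2, sq, 0.5))
  expect_identical(c2$misses, 0L)
  expect_identical(p1, p2)
})

test_that("probabilities survive in log space deep into the tail", {
  # n = 150, n1 = 15: smallest labeling probability is ~1e-33; far tails of
  # the step functions must remain finite and positive in log space
  set.seed(81)
  cc <- rbinom(150, 1, 0.6)
  dist <- fptasDistribution(cc, 15L, 1.5)
  expect_true(all(is.finite(dist@P@logProb)))
  expect_true(all(is.finite(dist@Q@logProb)))
  expect_gt(evaluateStepFunction(dist@P, dist@P@breakpoints[1]), 0)
})
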