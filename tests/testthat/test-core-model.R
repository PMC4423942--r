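# Event-sequence reduction, the log-rank statistic, scores, and the two
# variance conventions.

test_that("records are sorted by time with reproducible seeded tie-breaking", {
  rec <- data.frame(time = c(3, 5, 7), event = c(1, 1, 0), group = c(0, 1, 0))
  sq <- buildEventSequence(rec)
  expect_identical(groupLabels(sq), c(0L, 1L, 0L))
  expect_identical(censorIndicators(sq), c(1L, 1L, 0L))
  expect_identical(nGroup1(sq), 1L)

  one <- buildEventSequence(data.frame(time = 1, event = 1, group = 1))
  expect_identical(groupLabels(one), 1L)
  expect_identical(censorIndicators(one), 1L)

  tied <- data.frame(time = c(3, 3, 1), event = c(1, 0, 1), group = c(1, 0, 0))
  a <- buildEventSequence(tied, tieSeed = 5L)
  b <- buildEventSequence(tied, tieSeed = 5L)
  expect_identical(a@x, b@x)
  expect_identical(a@ordering, b@ordering)
  # the tied pair appears after the untied record, in one of the two orders
  expect_identical(a@x[1], 0L)
  expect_true(identical(a@x[2:3], c(1L, 0L)) || identical(a@x[2:3], c(0L, 1L)))
  # both orders occur across seeds
  orders <- vapply(1:40, function(s)
    paste(buildEventSequence(tied, tieSeed = s)@x, collapse = ""),
    character(1))
  expect_gt(length(unique(orders)), 1L)
})

test_that("degenerate and invalid cohorts are handled as specified", {
  expect_error(buildEventSequence(data.frame()), "empty cohort")
  expect_error(
    buildEventSequence(data.frame(time = -1, event = 1, group = 0)),
    "non-negative")
  # no group-1 members: statistic is identically zero
  sq0 <- EventSequence(c(0, 0, 0), c(1, 1, 0))
  expect_identical(logrankStatistic(sq0), 0)
  # all censored: every term vanishes
  sqc <- EventSequence(c(1, 0, 1), c(0, 0, 0))
  expect_identical(logrankStatistic(sqc), 0)
  expect_error(EventSequence(c(1, 2), c(1, 1)), "binary")
})

test_that("the statistic matches hand-evaluated values and the term-by-term oracle", {
  expect_equal(logrankStatistic(EventSequence(c(1, 0), c(1, 1))), 0.5)
  expect_equal(logrankStatistic(EventSequence(c(1, 0, 0, 0), rep(1, 4))), 3 / 4)
  expect_equal(logrankStatistic(EventSequence(c(0, 0, 0, 1), rep(1, 4))), -13 / 12)
  set.seed(101)
  for (i in 1:200) {
    sq <- randomSequence(nRange = 2:12)
    expect_equal(logrankStatistic(sq), oracleStatistic(sq@x, sq@c),
                 tolerance = 1e-12)
  }
})

test_that("log-rank scores sum to zero and reproduce the statistic", {
  a <- logrankScores(EventSequence(c(1, 0, 0, 0), rep(1, 4)))
  expect_equal(a, c(3 / 4, 5 / 12, -1 / 12, -13 / 12))
  expect_equal(logrankScores(EventSequence(c(1, 0, 1), c(0, 0, 0))),
               c(0, 0, 0))
  set.seed(202)
  for (i in 1:1000) {
    sq <- randomSequence(nRange = 2:10)
    a <- logrankScores(sq)
    expect_lt(abs(sum(a)), 1e-12)
    expect_equal(sum(a[sq@x == 1L]), logrankStatistic(sq), tolerance = 1e-12)
  }
})

test_that("permutational variance matches the closed form and enumeration", {
  sq <- EventSequence(c(1, 0, 0, 0), rep(1, 4))
  expect_equal(permVariance(sq), 23 / 48)  # (1/4) * (276/144)
  expect_identical(permVariance(EventSequence(c(0, 0), c(1, 1))), 0)
  expect_error(permVariance(EventSequence(1, 1)), "n >= 2")
  set.seed(303)
  for (i in 1:60) {
    sq <- randomSequence(nRange = 3:8)
    vals <- oracleNullValues(sq@c, sq@n1)
    # population variance over the equally likely labelings
    empirical <- mean(vals^2) - mean(vals)^2
    expect_equal(permVariance(sq), empirical, tolerance = 1e-10)
    expect_lt(abs(mean(vals)), 1e-10)  # E[V] = 0 under the null
  }
})

test_that("conditional variance matches hand values and the convolution DP", {
  sq <- EventSequence(c(1, 0, 0, 0), rep(1, 4))
  expect_equal(condVariance(sq), 3 / 16)
  expect_identical(condVariance(EventSequence(c(0, 0, 0), c(1, 1, 1))), 0)
  set.seed(404)
  for (i in 1:100) {
    sq <- randomSequence(nRange = 2:10)
    nul <- conditionalNull(sq)
    dpVar <- sum(nul@mass * nul@support^2) - sum(nul@mass * nul@support)^2
    expect_equal(condVariance(sq), dpVar, tolerance = 1e-12)
  }
})

test_that("the clinical reader validates structure and skips comments", {
  clin <- readClinicalTable(fixturePath("clinical_synthetic.tsv"))
  expect_named(clin, c("sample_id", "time", "event", "group"))
  expect_identical(nrow(clin), 12L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "sample_id\ttime\tevent", "s1\t3\t1", "s2\t5\t0"), tmp)
  expect_identical(nrow(readClinicalTable(tmp)), 2L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttime", "s1\t3"), bad)
  expect_error(readClinicalTable(bad), "lacks columns")
})
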