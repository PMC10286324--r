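test_that("per-sample dedup keeps highest confidence, then most support, then first", {
  calls <- makeCalls(
    callRow("S1", "A", "B", "medium"),
    callRow("S1", "A", "B", "high")
  )
  kept <- dedupSampleFusions(calls)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, "high")

  calls <- makeCalls(
    callRow("S1", "A", "B", "high", sr1 = 5, sr2 = 3, dm = 2),  # 10 reads
    callRow("S1", "A", "B", "high", sr1 = 10, sr2 = 10, dm = 5) # 25 reads
  )
  expect_equal(dedupSampleFusions(calls)$split_reads1, 10L)

  # equal confidence and support: first occurrence wins
  calls <- makeCalls(
    callRow("S1", "A", "B", "low", bp1 = "1:111"),
    callRow("S1", "A", "B", "low", bp1 = "1:222")
  )
  expect_equal(dedupSampleFusions(calls)$breakpoint1, "1:111")

  # single call unchanged; different samples never compete
  one <- callRow("S1", "A", "B", "low")
  expect_equal(dedupSampleFusions(one)$key, one$key)
  two <- makeCalls(callRow("S1", "A", "B"), callRow("S2", "A", "B"))
  expect_equal(nrow(dedupSampleFusions(two)), 2L)
})

test_that("dedup is idempotent and never increases the call count", {
  set.seed(7)
  genes <- LETTERS[1:5]
  for (rep in 1:10) {
    n <- sample(1:30, 1)
    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      callRow(
        sample(c("S1", "S2", "S3"), 1),
        sample(genes, 1), sample(genes, 1),
        sample(c("low", "medium", "high"), 1),
        sr1 = sample(0:20, 1)
      )
    }))
    once <- dedupSampleFusions(calls)
    expect_lte(nrow(once), nrow(calls))
    expect_identical(dedupSampleFusions(once)$key, once$key)
    expect_false(anyDuplicated(paste(once$sample_id, once$key)) > 0)
  }
})

test_that("cohort summary counts distinct (sample, key) pairs per level", {
  # S1 = {A high, B low}, S2 = {A high}
  cs <- fusionCallSet(
    cohortConfig("toy", "discovery", "fresh_frozen", nSamples = 2),
    makeCalls(
      callRow("S1", "A", "X", "high"),
      callRow("S1", "B", "X", "low"),
      callRow("S2", "A", "X", "high")
    )
  )
  sm <- summarizeCohort(cs)
  expect_equal(sm["all", "n_fusions"], 3)
  expect_equal(sm["high", "n_fusions"], 2)
  expect_equal(sm["high", "n_unique"], 1)
  expect_equal(sm["high", "mean_per_sample"], 1.0)
  expect_equal(sm["low", "n_fusions"], 1)

  # one sample with key A at both high and low: once per level, once in all
  cs2 <- fusionCallSet(
    cohortConfig("toy2", "discovery", "fresh_frozen", nSamples = 1),
    makeCalls(
      callRow("S1", "A", "X", "high"),
      callRow("S1", "A", "X", "low")
    )
  )
  sm2 <- summarizeCohort(cs2)
  expect_equal(sm2["all", "n_fusions"], 1)
  expect_equal(sm2["high", "n_fusions"], 1)
  expect_equal(sm2["low", "n_fusions"], 1)
  # level sums can exceed the all-confidence total
  expect_gte(sum(sm2[c("high", "medium", "low"), "n_fusions"]),
    sm2["all", "n_fusions"])
})

test_that("summary invariants hold on randomized call sets", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    calls <- do.call(rbind, lapply(1:40, function(i) {
      callRow(
        sprintf("S%d", sample(n, 1)),
        sample(LETTERS[1:6], 1), sample(LETTERS[7:10], 1),
        sample(c("low", "medium", "high"), 1)
      )
    }))
    sm <- summarizeCohort(fusionCallSet(
      cohortConfig("rand", "discovery", "fresh_frozen", nSamples = n), calls
    ))
    levels <- c("high", "medium", "low")
    expect_true(all(sm[levels, "n_fusions"] <= sm["all", "n_fusions"]))
    expect_gte(sum(sm[levels, "n_fusions"]), sm["all", "n_fusions"])
    expect_true(all(sm[levels, "n_unique"] <= sm[levels, "n_fusions"]))
  }
})

test_that("per-sample burden respects scope and zero-call samples", {
  cs <- fusionCallSet(
    cohortConfig("b", "discovery", "fresh_frozen", nSamples = 5),
    makeCalls(
      callRow("S1", "A", "X", "high"),
      callRow("S2", "A", "X", "high"), callRow("S2", "B", "X", "high"),
      callRow("S3", "A", "X", "high"), callRow("S3", "B", "X", "high"),
      callRow("S3", "C", "X", "low"),
      callRow("S4", "A", "X", "high"), callRow("S4", "B", "X", "high"),
      callRow("S4", "C", "X", "high"), callRow("S4", "D", "X", "high")
    )
  )
  clin <- data.frame(sample_id = c("S1", "S2", "S3", "S4", "S5"))
  b <- perSampleBurden(cs, "high_only", clinical = clin)
  expect_equal(b$burden$burden[match("S5", b$burden$sample_id)], 0L)
  expect_equal(sort(b$burden$burden), c(0L, 1L, 2L, 2L, 4L))
  expect_equal(b$median_burden, 2)

  # the even-n median is the midpoint of the central order statistics
  b4 <- perSampleBurden(cs, "all",
    clinical = data.frame(sample_id = c("S1", "S2", "S3", "S4")))
  expect_equal(sort(b4$burden$burden), c(1L, 2L, 3L, 4L))
  expect_equal(b4$median_burden, 2.5)

  # high_only excludes the low-confidence call in S3
  expect_lt(
    b$burden$burden[b$burden$sample_id == "S3"],
    perSampleBurden(cs, "all", clinical = clin)$burden$burden[3]
  )

  # combined scope restricts to the given key set
  bc <- perSampleBurden(cs, "combined", clinical = clin,
    combinedKeys = c("A::X"))
  expect_equal(max(bc$burden$burden), 1L)
  expect_error(perSampleBurden(cs, "combined"), "combined key set")
})

test_that("rank-sum test matches enumeration examples and handles symmetry", {
  r <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact enumeration")
  expect_equal(rankSumTest(c(5, 9, 2), c(5, 9, 2))$p.value, 1)
})

test_that("rank-sum agrees with the permutation oracle for group sizes <= 8", {
  set.seed(23)
  for (rep in 1:20) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    # integer burdens: ties are common
    x <- sample(0:6, nx, replace = TRUE)
    y <- sample(0:6, ny, replace = TRUE)
    expect_equal(rankSumTest(x, y)$p.value, oracleRankSumP(x, y),
      tolerance = 1e-3)
    expect_equal(
      rankSumTest(x, y, alternative = "greater")$p.value,
      oracleRankSumPGreater(x, y),
      tolerance = 1e-3
    )
  }
})

test_that("large-sample approximation tracks stats::wilcox.test", {
  set.seed(5)
  x <- rpois(25, 6); y <- rpois(30, 8)
  mine <- rankSumTest(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(mine$method, "normal approximation with tie and continuity correction")
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("a monotone shift cannot increase the one-sided p", {
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(0:8, 6, replace = TRUE)
    y <- sample(0:8, 6, replace = TRUE)
    p0 <- rankSumTest(x, y, alternative = "greater")$p.value
    p1 <- rankSumTest(x + 3, y, alternative = "greater")$p.value
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("specimen-age tertiles assign ties to the lower group and compare burdens", {
  burden <- data.frame(
    sample_id = sprintf("S%d", 1:9),
    burden = c(9, 8, 7, 7, 4, 3, 1, 1, 0)
  )
  clin <- data.frame(
    sample_id = sprintf("S%d", 1:9),
    specimen_age = c(1, 2, 3, 3, 5, 6, 7, 8, 9)
  )
  res <- ageGroupComparison(burden, clin)
  # the lower empirical tertile falls on the tied age 3; both tied samples
  # stay in the youngest group
  expect_equal(res$cutpoints[1], 3)
  expect_equal(as.vector(table(res$groups$group)), c(4L, 2L, 3L))
  expect_true(all(res$groups$group[res$groups$specimen_age == 3] == 1L))
  expect_lt(res$test$p.value, 0.05)

  clin$specimen_age[4] <- NA
  expect_error(ageGroupComparison(burden, clin), "S4")
  expect_error(ageGroupComparison(burden, clin[1:5, ]), "missing from clinical")
})
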