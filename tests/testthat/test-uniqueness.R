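test_that("equivalence spectra count class sizes exactly", {
  d5 <- data.frame(area = "Z", a = rep(1, 5), b = rep(2, 5))
  sp <- equivalenceSpectrum(d5, c("a", "b"))
  expect_equal(classSpectrum(sp), c("5" = 1L))

  d <- data.frame(a = 1:5)
  expect_equal(unname(classSpectrum(equivalenceSpectrum(d, "a"))["1"]), 5L)

  # hand count: tuples (a,a,a,b,b,c) -> one class of 3, one of 2, one of 1
  d6 <- data.frame(v = c("a", "a", "a", "b", "b", "c"))
  sp6 <- equivalenceSpectrum(d6, "v")
  expect_equal(classSpectrum(sp6), c("1" = 1L, "2" = 1L, "3" = 1L))
  expect_equal(sp6@nRecords, 6L)
  expect_equal(sp6@nClasses, 3L)
})

test_that("spectrum handles areas, missing columns and missing values", {
  d <- tinyRecords()
  sp <- equivalenceSpectrum(d, c("a", "b"), area = "X1A")
  expect_equal(classSpectrum(sp), c("1" = 1L, "2" = 1L, "3" = 1L))
  expect_error(equivalenceSpectrum(d, c("a", "zz")), "not present")
  expect_error(equivalenceSpectrum(d, "a", area = "NOPE"), "no records")
  # NA forms its own category, distinguishable from every observed value
  dna <- data.frame(v = c(1, 1, NA, NA, 2))
  spna <- equivalenceSpectrum(dna, "v")
  expect_equal(classSpectrum(spna), c("1" = 1L, "2" = 2L))
})

test_that("sample uniqueness is the unique fraction", {
  d <- data.frame(v = c("a", "a", "a", "b", "b", "c"))
  expect_equal(sampleUniqueness(equivalenceSpectrum(d, "v")), 1 / 6)
  expect_equal(sampleUniqueness(equivalenceSpectrum(data.frame(v = 1:5), "v")), 1)
  expect_equal(sampleUniqueness(equivalenceSpectrum(data.frame(v = rep(1, 5)), "v")), 0)
})

test_that("Zayatz estimator has the right limits and zero cases", {
  d <- data.frame(v = c("a", "a", "a", "b", "b", "c", "d", "e"))
  sp <- equivalenceSpectrum(d, "v")
  # census case: p = 1 recovers sample uniqueness exactly
  expect_equal(zayatzUniqueness(sp, 1, 8), sampleUniqueness(sp))
  # no sample uniques -> 0
  sp0 <- equivalenceSpectrum(data.frame(v = c(1, 1, 2, 2)), "v")
  expect_equal(zayatzUniqueness(sp0, 0.2, 20), 0)
  # p -> 1 limit (spectrum and population held fixed) approaches sample
  # uniqueness
  ests <- vapply(c(0.5, 0.9, 0.999), function(p)
    zayatzUniqueness(sp, p, 8), numeric(1))
  expect_lt(abs(ests[3] - sampleUniqueness(sp)), 0.01)
  expect_error(zayatzUniqueness(sp, 0, 100), "samplingFraction")
  expect_error(zayatzUniqueness(sp, 0.5, 4), "smaller")
})

test_that("all-singleton and no-singleton spectra behave at the extremes", {
  # every sample class size 1 -> estimate clips at 1 for the area scale
  spAll1 <- equivalenceSpectrum(data.frame(v = 1:20), "v")
  expect_equal(zayatzUniqueness(spAll1, 0.2, 100), 1)
  # no singleton classes at all -> exactly 0 regardless of N
  spNone <- equivalenceSpectrum(data.frame(v = rep(1:10, each = 4)), "v")
  expect_equal(zayatzUniqueness(spNone, 0.2, 10000), 0)
})

test_that("hypergeometric subsampling option agrees closely with binomial", {
  d <- data.frame(v = c(rep(1, 4), rep(2, 3), 3, 4, 5))
  sp <- equivalenceSpectrum(d, "v")
  b <- zayatzUniqueness(sp, 0.2, 45)
  h <- zayatzUniqueness(sp, 0.2, 45, method = "hypergeometric")
  expect_gt(h, 0)
  expect_lt(abs(b - h), 0.1)
})

test_that("pigeonhole flag follows the drawer principle", {
  expect_true(pigeonholeFlag(15, 48)$flag)
  r <- pigeonholeFlag(100, 10)
  expect_false(r$flag)
  expect_equal(r$minMaxClassSize, 10)
  expect_true(pigeonholeFlag(48, 48)$flag)
})

test_that("uniform-allocation expectation matches the closed form", {
  expect_equal(round(expectedNonuniqueUniform(15, 48), 2), 0.26)
  expect_equal(expectedNonuniqueUniform(1, 48), 0)
  expect_equal(expectedNonuniqueUniform(2, 1), 1)
})

test_that("threshold indicators are strict at both thresholds", {
  expect_equal(thresholdIndicators(0.143), c(I05 = 1L, I20 = 0L))
  expect_equal(thresholdIndicators(0.56), c(I05 = 1L, I20 = 1L))
  expect_equal(thresholdIndicators(0.05), c(I05 = 0L, I20 = 0L))
  expect_equal(thresholdIndicators(0.20), c(I05 = 1L, I20 = 0L))
  # implication I20 -> I05 over a grid
  for (u in seq(0, 1, by = 0.01)) {
    ind <- thresholdIndicators(u)
    expect_true(ind[["I05"]] >= ind[["I20"]])
  }
})

test_that("per-area pipeline assembles estimates with indicators", {
  synth <- smallSynth()
  est <- uniquenessEstimates(sampleRecords(synth), c("age", "gender"),
                             popTable(synth), 0.2)
  expect_equal(nrow(est), nrow(popTable(synth)))
  expect_true(all(est$est_population_uniqueness >= 0 &
                  est$est_population_uniqueness <= 1))
  expect_equal(est$I05, as.integer(est$est_population_uniqueness > 0.05))
  expect_equal(est$I20, as.integer(est$est_population_uniqueness > 0.20))
  badPop <- popTable(synth)[-1, ]
  expect_error(uniquenessEstimates(sampleRecords(synth), c("age", "gender"),
                                   badPop, 0.2),
               "no population entry")
})
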