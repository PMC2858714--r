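test_that("suppression percentages follow hand counts", {
  records <- data.frame(
    area = c(rep("A", 10), rep("B", 20), rep("C", 70)),
    age = 1L, gender = 1L, stringsAsFactors = FALSE)
  pt <- data.frame(area = c("A", "B", "C"), pop = c(5000, 900, 60000),
                   stringsAsFactors = FALSE)
  sch <- defaultQidScheme()
  # model that flags only the middle area: logit = 1 iff pop < 1000
  m <- new("LogitRiskModel", thresholdLabel = "5%",
           coef = c(intercept = 0, pop = -1, maxcombs = 0,
                    interaction = 0),
           popCenter = 1000, maxcombsCenter = 48, scale = 1,
           provenance = "fitted", vcov = matrix(NA_real_, 4, 4),
           fitInfo = list())
  rep1 <- suppressionReport(records, pt, m, sch, c("age", "gender"))
  expect_equal(rep1@percentSuppressed, 20)
  expect_equal(rep1@recordsSuppressed, 20L)
  expect_equal(sum(rep1@areas$flagged), 1L)
  expect_equal(rep1@areas$area[rep1@areas$flagged], "B")
})

test_that("all-flagged and none-flagged datasets give 100% and 0%", {
  records <- data.frame(area = rep(c("A", "B"), c(3, 7)), age = 1L,
                        gender = 1L)
  pt <- data.frame(area = c("A", "B"), pop = c(100, 200))
  sch <- defaultQidScheme()
  mkModel <- function(b0) new("LogitRiskModel", thresholdLabel = "5%",
    coef = c(intercept = b0, pop = 0, maxcombs = 0, interaction = 0),
    popCenter = 0, maxcombsCenter = 0, scale = 1, provenance = "fitted",
    vcov = matrix(NA_real_, 4, 4), fitInfo = list())
  expect_equal(suppressionReport(records, pt, mkModel(10), sch,
                                 c("age", "gender"))@percentSuppressed, 100)
  expect_equal(suppressionReport(records, pt, mkModel(-10), sch,
                                 c("age", "gender"))@percentSuppressed, 0)
})

test_that("the zero rule flags any area with estimated uniques", {
  synth <- smallSynth(seed = 23, nAreas = 3, popRange = c(100, 300))
  rep0 <- suppressionReport(sampleRecords(synth), popTable(synth), "zero",
                            synth@scheme, c("age", "schooling", "marital"),
                            samplingFraction = 0.2)
  est <- uniquenessEstimates(sampleRecords(synth),
                             c("age", "schooling", "marital"),
                             popTable(synth), 0.2)
  expect_equal(sum(rep0@areas$flagged),
               sum(est$est_population_uniqueness > 0))
  expect_equal(thresholdLabel(rep0), "0%")
})

test_that("missing population entries are reported with offenders", {
  records <- data.frame(area = c("A", "B"), age = 1L, gender = 1L)
  pt <- data.frame(area = "A", pop = 100)
  expect_error(suppressionReport(records, pt, "zero", defaultQidScheme(),
                                 c("age", "gender"), samplingFraction = 1),
               "B")
})

test_that("record and population tables round-trip through CSV", {
  synth <- smallSynth(seed = 29, nAreas = 3, popRange = c(30, 80))
  smp <- sampleRecords(synth)
  fRec <- withr::local_tempfile(fileext = ".csv")
  writeRecordTable(smp, fRec)
  back <- readRecordTable(fRec)
  expect_equal(back, smp)

  fPop <- withr::local_tempfile(fileext = ".csv")
  writeRecordTable(popTable(synth), fPop)
  expect_equal(readPopulationTable(fPop), popTable(synth))

  dup <- rbind(popTable(synth), popTable(synth)[1, ])
  fDup <- withr::local_tempfile(fileext = ".csv")
  writeRecordTable(dup, fDup)
  expect_error(readPopulationTable(fDup), "duplicate")
})

test_that("suppression reports serialise to valid JSON", {
  records <- data.frame(area = rep(c("A", "B"), c(4, 6)), age = 1:2,
                        gender = 1L)
  pt <- data.frame(area = c("A", "B"), pop = c(50, 80))
  rep0 <- suppressionReport(records, pt, "zero", defaultQidScheme(),
                            c("age", "gender"), samplingFraction = 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeSuppressionReport(rep0, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$records_total, rep0@recordsTotal)
  expect_equal(obj$records_suppressed, rep0@recordsSuppressed)
  expect_equal(length(obj$areas), 2L)
  schema <- jsonlite::read_json(system.file("extdata",
    "suppression-report-schema.json", package = "sdcArea"))
  expect_true(all(unlist(schema$required) %in% names(obj)))
})

test_that("the command-line dispatcher runs end to end", {
  cli <- system.file("cli", "sdc-area.R", package = "sdcArea")
  expect_true(nzchar(cli))
  out <- withr::local_tempfile(fileext = ".csv")
  # the subprocess must see the library this package is installed in
  res <- system2("Rscript", c(cli, "enumerate-models", "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=",
                              paste(.libPaths(), collapse = .Platform$path.sep)))
  expect_true(file.exists(out))
  models <- utils::read.csv(out)
  expect_equal(nrow(models), 358L)
})
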