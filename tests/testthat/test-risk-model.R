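test_that("center/scale transformation is exact arithmetic", {
  cs <- centerScale(10000, 3240, popCenter = 10000, maxcombsCenter = 1000)
  expect_equal(cs$pop_cs, 0)
  expect_equal(cs$maxcombs_cs, 0.224)
  cs2 <- centerScale(20000, 1000, popCenter = 10000, maxcombsCenter = 1000)
  expect_equal(cs2$pop_cs, 1)
  expect_error(centerScale(1, 1), "centering constants")
})

test_that("published models flag high risk at the centering point", {
  m05 <- publishedRiskModel("5%", popCenter = 10000, maxcombsCenter = 5000)
  m20 <- publishedRiskModel("20%", popCenter = 10000, maxcombsCenter = 5000)
  expect_equal(riskCoef(m05),
               c(intercept = 779.1, pop = -37.35, maxcombs = 137.8,
                 interaction = -6.5))
  expect_equal(riskCoef(m20),
               c(intercept = 63.3, pop = -6, maxcombs = 11.8,
                 interaction = -1))
  # inputs at both centres leave only the intercept: logistic(779.1) and
  # logistic(63.3), both numerically 1
  expect_equal(predictRisk(m05, 10000, 5000), 1)
  expect_equal(predictRisk(m20, 10000, 5000), 1)
  expect_true(flagSmallArea(m05, 10000, 5000))
  expect_true(flagSmallArea(m20, 10000, 5000))
  # centering constants are never guessed
  expect_error(publishedRiskModel("5%"), "centering")
})

test_that("published 5% logit decreases in POP at the MaxCombs centre", {
  m05 <- publishedRiskModel("5%", popCenter = 10000, maxcombsCenter = 5000)
  b <- riskCoef(m05)
  expect_lt(b[["pop"]], 0)
  # at the MaxCombs centre the logit is linear in POP with slope b1/scale,
  # hence strictly decreasing
  pops <- seq(200, 78457, length.out = 50)
  lgt <- b[["intercept"]] + b[["pop"]] * (pops - 10000) / 10000
  expect_true(all(diff(lgt) < 0))
  expect_equal(diff(lgt)[1], b[["pop"]] / 10000 * diff(pops)[1])
})

test_that("flagging uses a strict cutoff and matches the sign rule", {
  m <- publishedRiskModel("5%", popCenter = 10000, maxcombsCenter = 5000)
  # pi exactly 0.5 (logit 0) is not flagged
  b <- riskCoef(m)
  # solve for pop_cs giving logit 0 at maxcombs centre: b0 + b1 * x = 0
  popAtHalf <- 10000 + 10000 * (-b[["intercept"]] / b[["pop"]])
  expect_equal(predictRisk(m, popAtHalf, 5000), 0.5)
  expect_false(flagSmallArea(m, popAtHalf, 5000))
  expect_true(flagSmallArea(m, popAtHalf - 1, 5000))
  expect_false(flagSmallArea(m, popAtHalf + 1, 5000))
})

test_that("flagging at cutoff 0.5 is invariant to monotone fixes of 0.5", {
  m <- publishedRiskModel("20%", popCenter = 5000, maxcombsCenter = 2000)
  pops <- c(500, 5000, 50000)
  mc <- c(6, 2000, 90000)
  pr <- predictRisk(m, pops, mc)
  g <- function(x) x^3 / (x^3 + (1 - x)^3)  # strictly monotone, g(0.5)=0.5
  expect_equal(pr > 0.5, g(pr) > 0.5)
})

test_that("down-sampling intercept correction follows the prior formula", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = -1.5, pop = -1, maxcombs = 0.4, interaction = -0.02)
  sim <- simulateRiskObservations(8000, beta, scaler, seed = 3)
  m <- fitRiskModel(sim$data, "y", "downsample", seed = 2, scaler = scaler)
  tau <- mean(sim$data$y)
  ybar <- m@fitInfo$balanced_prevalence
  expect_equal(ybar, 0.5)  # equal-size classes by construction
  expect_equal(m@fitInfo$intercept_correction,
               -log(((1 - tau) / tau) * (ybar / (1 - ybar))))
  # tau = 0.5 would give zero correction; tau = 0.25, ybar = 0.5 -> -ln 3
  expect_equal(-log(((1 - 0.25) / 0.25) * 1), -log(3))
  # balanced subset: all minority kept, equal majority draw
  expect_equal(m@fitInfo$n_balanced,
               2L * min(sum(sim$data$y), sum(1 - sim$data$y)))
})

test_that("down-sampling draw is seeded and reproducible", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = -2, pop = -1, maxcombs = 0.4, interaction = -0.02)
  sim <- simulateRiskObservations(4000, beta, scaler, seed = 8)
  m1 <- fitRiskModel(sim$data, "y", "downsample", seed = 5, scaler = scaler)
  m2 <- fitRiskModel(sim$data, "y", "downsample", seed = 5, scaler = scaler)
  expect_identical(riskCoef(m1), riskCoef(m2))
})

test_that("KZ bias term equals brute-force matrix arithmetic", {
  # small single-predictor design with hand-checkable dimensions
  set.seed(11)
  X <- cbind(intercept = 1, x = rnorm(12))
  eta <- -0.3 + 0.8 * X[, "x"]
  pi <- plogis(eta)
  expect_equal(kzBiasTerm(X, pi), kzBiasBruteForce(X, pi),
               tolerance = 1e-12, ignore_attr = TRUE)
  # and on the 4-column risk design
  X4 <- cbind(intercept = 1, pop = rnorm(30), maxcombs = rnorm(30))
  X4 <- cbind(X4, interaction = X4[, "pop"] * X4[, "maxcombs"])
  pi4 <- plogis(drop(X4 %*% c(-1, -0.5, 0.7, 0.1)))
  expect_equal(kzBiasTerm(X4, pi4), kzBiasBruteForce(X4, pi4),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("KZ converges to plain ML on large balanced data", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = 0.2, pop = -0.8, maxcombs = 0.3,
            interaction = -0.02)
  sim <- simulateRiskObservations(1e5, beta, scaler, seed = 2)
  mk <- fitRiskModel(sim$data, "y", "kz", scaler = scaler)
  mm <- fitRiskModel(sim$data, "y", "ml", scaler = scaler)
  expect_lt(max(abs(riskCoef(mk) - riskCoef(mm))), 0.005)
})

test_that("KZ beats uncorrected ML on rare positives (RMSE over replicates)", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = -6.5, pop = -1.2, maxcombs = 0.5,
            interaction = -0.03)
  errs <- vapply(1:50, function(s) {
    sim <- simulateRiskObservations(5000, beta, scaler, seed = 100 + s)
    if (length(unique(sim$data$y)) < 2) return(c(NA_real_, NA_real_))
    mk <- suppressWarnings(
      fitRiskModel(sim$data, "y", "kz", scaler = scaler))
    mm <- suppressWarnings(
      fitRiskModel(sim$data, "y", "ml", scaler = scaler))
    c(sqrt(mean((riskCoef(mk) - beta)^2)),
      sqrt(mean((riskCoef(mm) - beta)^2)))
  }, numeric(2))
  expect_lt(mean(errs[1, ], na.rm = TRUE), mean(errs[2, ], na.rm = TRUE))
})

test_that("fitting requires both classes and valid columns", {
  d <- data.frame(pop = 1:10 * 100, max_combs = 48, I05 = 1L)
  expect_error(fitRiskModel(d, "I05"), "both classes")
  expect_error(fitRiskModel(data.frame(pop = 1, I05 = 0), "I05"),
               "missing column")
})

test_that("influence removal catches a planted outlier and respects Inf", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = 0, pop = -2, maxcombs = 0.5, interaction = 0)
  sim <- simulateRiskObservations(300, beta, scaler, seed = 6)
  d <- sim$data
  names(d)[names(d) == "y"] <- "I05"
  # plant one gross outlier: enormous leverage point with a contrary label
  d <- rbind(d, data.frame(pop = 78457, max_combs = 718848, I05 = 0L))
  d$I05[nrow(d)] <- ifelse(mean(d$I05) > 0.5, 0L, 1L)
  res <- removeInfluential(d, "I05")
  expect_true(nrow(d) %in% res$removed)
  expect_lt(res$removedFraction, 0.2)
  resInf <- removeInfluential(d, "I05", cutoff = Inf)
  expect_equal(resInf$removedFraction, 0)
  expect_equal(nrow(resInf$kept), nrow(d))
})

test_that("influence removal on clean data removes only a small fraction", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = -0.5, pop = -1, maxcombs = 0.3, interaction = -0.01)
  sim <- simulateRiskObservations(1000, beta, scaler, seed = 9)
  d <- sim$data
  names(d)[names(d) == "y"] <- "I05"
  res <- removeInfluential(d, "I05")
  expect_lt(res$removedFraction, 0.1)
  expect_true(all(c(0, 1) %in% res$kept$I05))
})

test_that("risk-model files round-trip", {
  scaler <- list(popCenter = 10000, maxcombsCenter = 10000)
  beta <- c(intercept = -2, pop = -1, maxcombs = 0.4, interaction = -0.02)
  sim <- simulateRiskObservations(4000, beta, scaler, seed = 4)
  m <- fitRiskModel(sim$data, "y", "downsample", seed = 1, scaler = scaler)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeRiskModel(m, path)
  m2 <- readRiskModel(path)
  expect_equal(riskCoef(m2), riskCoef(m))
  expect_equal(m2@popCenter, m@popCenter)
  expect_equal(m2@scale, m@scale)
  expect_equal(thresholdLabel(m2), thresholdLabel(m))
  expect_equal(predictRisk(m2, 5000, 500), predictRisk(m, 5000, 500))
})
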