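test_that("composite log-likelihood follows the multinomial form", {
  obs <- SFS(c(0, 5, 3, 2, 0))
  expect_equal(compositeLogLik(obs, c(0.5, 0.3, 0.2)),
    5 * log(0.5) + 3 * log(0.3) + 2 * log(0.2))
  # information inequality: truth beats random perturbations
  p0 <- c(0.5, 0.3, 0.2)
  obs2 <- SFS(c(0, 50, 30, 20, 0))
  llTrue <- compositeLogLik(obs2, p0)
  set.seed(1)
  for (r in 1:100) {
    p <- p0 + runif(3, -0.1, 0.1)
    p <- pmax(p, 1e-4); p <- p / sum(p)
    expect_gte(llTrue, compositeLogLik(obs2, p))
  }
  # flooring keeps zero-probability classes finite
  obs3 <- SFS(c(0, 10, 0, 0, 0), folded = TRUE)
  expect_equal(compositeLogLik(obs3, c(1, 0)), 10 * log(1 - 1e-10),
    tolerance = 1e-12)
  expect_error(compositeLogLik(obs, c(0.5, 0.3, 0.2, 0.1)), "length")
  expect_error(compositeLogLik(SFS(c(5, 0, 0, 0, 0)), c(1, 0, 0)),
    "no segregating")
})

test_that("AIC and Akaike weights follow their definitions", {
  expect_equal(aicScore(0, 0), 0)
  expect_equal(aicScore(-100, 3), 206)
  expect_equal(aicScore(-50, 3) - aicScore(-50, 2), 2)
  expect_equal(akaikeWeights(100), 1)
  expect_equal(akaikeWeights(c(100, 102)), c(0.7311, 0.2689),
    tolerance = 1e-4)
  expect_equal(akaikeWeights(rep(7, 5)), rep(0.2, 5))
  set.seed(2)
  a <- runif(6, 100, 120)
  expect_equal(sum(akaikeWeights(a)), 1)
  perm <- sample(6)
  expect_equal(akaikeWeights(a)[perm], akaikeWeights(a[perm]))
})

test_that("scenario fitting is deterministic and self-consistent", {
  sc <- defaultScenarios()$constant
  mut <- MutationModel(muSite = 1e-8, locusLength = 300, numLoci = 20000)
  # observed spectrum built from the model's own expectation at ne = 5000
  lens <- expectedBranchLengthsExact(8, sc@builder(c(ne = 5000)))
  seg <- 1e-8 * lens * 20000 * 300
  obs <- SFS(c(20000 * 300 - sum(seg), seg, 0))
  f1 <- fitScenario(obs, sc, mut, seed = 11)
  f2 <- fitScenario(obs, sc, mut, seed = 11)
  expect_identical(f1@estimate, f2@estimate)
  expect_identical(f1@logLik, f2@logLik)
  expect_equal(unname(f1@estimate["ne"]), 5000, tolerance = 1e-3)
})

test_that("constant-size truth is recovered within a factor of 1.5", {
  sc <- defaultScenarios()$constant
  mut <- MutationModel(muSite = 1e-8, locusLength = 300, numLoci = 20000)
  set.seed(33)
  obs <- simulateSFS(8, EpochSchedule(0, 5000, 0), mut)
  fit <- fitScenario(obs, sc, mut, seed = 34)
  expect_gt(unname(fit@estimate["ne"]), 5000 / 1.5)
  expect_lt(unname(fit@estimate["ne"]), 5000 * 1.5)
})

test_that("scenario comparison fills weights that sum to one", {
  mut <- MutationModel(muSite = 1e-8, locusLength = 300, numLoci = 10000)
  set.seed(44)
  obs <- simulateSFS(8, EpochSchedule(0, 8000, 0), mut)
  sc <- defaultScenarios()[c("constant", "constantLow", "decline")]
  fits <- compareScenarios(obs, sc, mut, seed = 45)
  w <- vapply(fits, slot, numeric(1), "weight")
  expect_equal(sum(w), 1)
  expect_identical(attr(fits, "selected"), "constant")
})

test_that("bootstrap percentiles use linear interpolation", {
  ci <- codemog:::.percentileCI(cbind(a = 1:100))
  expect_equal(unname(ci[1, ]), c(3.475, 97.525))
  # degenerate replicates give a zero-width interval
  ci0 <- codemog:::.percentileCI(cbind(a = rep(2.5, 30)))
  expect_equal(unname(ci0[1, ]), c(2.5, 2.5))
})

test_that("parametric bootstrap brackets the estimate on clean data", {
  sc <- defaultScenarios()$constant
  mut <- MutationModel(muSite = 1e-8, locusLength = 300, numLoci = 5000)
  set.seed(55)
  obs <- simulateSFS(8, EpochSchedule(0, 5000, 0), mut)
  fit <- fitScenario(obs, sc, mut, seed = 56)
  fit <- parametricBootstrap(fit, sc, mut, B = 12, folded = FALSE,
    seed = 57)
  expect_equal(nrow(fit@ci), 1)
  expect_lte(fit@ci["ne", "2.5%"], unname(fit@estimate["ne"]))
  expect_gte(fit@ci["ne", "97.5%"], unname(fit@estimate["ne"]))
  expect_equal(fit@details$bootstrap$dropped, 0)
})

test_that("optimizer respects parameter bounds", {
  sc <- defaultScenarios()$constantLow  # truth far above the upper bound
  mut <- MutationModel(muSite = 1e-8, locusLength = 300, numLoci = 5000)
  set.seed(66)
  obs <- simulateSFS(8, EpochSchedule(0, 20000, 0), mut)
  fit <- fitScenario(obs, sc, mut, seed = 67)
  expect_lte(unname(fit@estimate["ne"]), sc@upper[1] + 1e-6)
  expect_gte(unname(fit@estimate["ne"]), sc@lower[1] - 1e-6)
})
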