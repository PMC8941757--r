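test_that("the xi grid and draws honour the synchrony structure", {
  pr <- HyperPrior(taxaCount = 6)
  expect_equal(xiGrid(pr), (1:6) / 6)
  expect_equal(round(min(xiGrid(pr)), 3), 0.167)
  set.seed(1)
  d1 <- drawCoDemography(pr, fixedXi = 1)
  expect_equal(length(unique(d1@taxa$tPulse)), 1L)
  expect_true(all(d1@taxa$synchronous))
  d2 <- drawCoDemography(pr, fixedXi = 1 / 6)
  expect_equal(sum(d2@taxa$synchronous), 1L)
  expect_equal(d2@taxa$tPulse[d2@syncSet], d2@sharedTime)
  set.seed(9); a <- drawCoDemography(pr)
  set.seed(9); b <- drawCoDemography(pr)
  expect_identical(a@taxa, b@taxa)
  expect_error(drawCoDemography(pr, fixedXi = 0.4), "grid")
})

test_that("reference tables are reproducible and sorted within classes", {
  pr <- HyperPrior(taxaCount = 4)
  t1 <- simulateReferenceTable(pr, 10, seed = 5)
  t2 <- simulateReferenceTable(pr, 10, seed = 5)
  expect_identical(t1@asfs, t2@asfs)
  expect_identical(t1@params, t2@params)
  # every row satisfies the per-class non-increasing invariant
  nCls <- 4  # folded n = 8
  for (r in seq_len(nrow(t1@asfs))) {
    m <- matrix(t1@asfs[r, ], nrow = 4)  # taxa x classes
    for (j in seq_len(nCls)) expect_false(is.unsorted(rev(m[, j])))
  }
})

test_that("the two reference-table methods agree in distribution", {
  # sparse regime: multinomial-on-expectation vs explicit per-locus
  # simulation give the same aSFS law (compare bin means over repeats)
  pr <- HyperPrior(taxaCount = 4, neBounds = c(4000, 4001),
    epsBounds = c(0.049, 0.05), timeBounds = c(2999, 3000),
    growthBounds = c(1.999, 2))
  mut <- MutationModel(numLoci = 800, locusLength = 125)
  tE <- simulateReferenceTable(pr, 300, mutation = mut, seed = 21,
    method = "expected")
  tL <- simulateReferenceTable(pr, 300, mutation = mut, seed = 22,
    method = "locus")
  mE <- colMeans(tE@asfs); mL <- colMeans(tL@asfs)
  seE <- apply(tE@asfs, 2, sd) / sqrt(300)
  seL <- apply(tL@asfs, 2, sd) / sqrt(300)
  expect_true(all(abs(mE - mL) < 4 * sqrt(seE^2 + seL^2)))
})

test_that("a near-point-mass prior concentrates on the expected spectrum", {
  pr <- HyperPrior(taxaCount = 4, neBounds = c(8000, 8001),
    epsBounds = c(0.049, 0.05), timeBounds = c(2999, 3000),
    growthBounds = c(1.999, 2))
  tab <- simulateReferenceTable(pr, 400, seed = 31)
  # expected folded proportions of the single model
  ep <- bottleneckSchedule(8000, 0.05, 3000, 2, 30000)
  lens <- expectedBranchLengthsExact(8, ep)
  pf <- numeric(4)
  for (i in 1:7) pf[min(i, 8 - i)] <- pf[min(i, 8 - i)] + lens[i]
  pf <- pf / sum(pf)
  # mean over the 4 rank bins of one class estimates that class proportion
  for (cl in 1:4) {
    bins <- ((cl - 1) * 4 + 1):(cl * 4)
    est <- mean(tab@asfs[, bins])
    se <- sd(rowMeans(tab@asfs[, bins])) / sqrt(400)
    expect_lt(abs(est - pf[cl]), 4 * se + 1e-3)
  }
})

test_that("rejection matches a brute-force distance computation", {
  pr <- HyperPrior(taxaCount = 4)
  tab <- simulateReferenceTable(pr, 50, seed = 41)
  obs <- tab@asfs[17, ]
  res <- abcReject(obs, tab, 10)
  # naive double loop
  sds <- apply(tab@asfs, 2, sd)
  keep <- sds > 0
  d <- numeric(50)
  for (r in 1:50) {
    d[r] <- sqrt(sum(((tab@asfs[r, keep] - obs[keep]) / sds[keep])^2))
  }
  expect_equal(res@distances, sort(d)[1:10], tolerance = 1e-12)
  expect_equal(res@acceptedIdx[1], 17L)
  expect_equal(res@distances[1], 0)
  all50 <- abcReject(obs, tab, 50)
  expect_equal(sort(all50@acceptedIdx), 1:50)
  expect_error(abcReject(obs, tab, 0), "positive")
  expect_error(abcReject(obs, tab, 51), "table size")
})

test_that("Bayes factors compare accepted counts with antisymmetry", {
  pr <- HyperPrior(taxaCount = 2)
  res <- new("ABCResult", acceptedIdx = 1:4, distances = rep(0, 4),
    posterior = data.frame(xi = c(1, 1, 0.5, 1)),
    xiCounts = setNames(c(1L, 3L), c("0.500", "1.000")),
    xiGrid = c(0.5, 1), k = 4L)
  bf <- bayesFactorMatrix(res, pr)
  expect_equal(bf["0.500", "1.000"], 3)
  expect_equal(bf["1.000", "0.500"], 1 / 3)
  expect_true(all(abs(bf * t(bf) - 1) < 1e-12))
  # equal counts, equal priors: all ones
  res@xiCounts <- setNames(c(2L, 2L), c("0.500", "1.000"))
  expect_true(all(bayesFactorMatrix(res, pr) == 1))
  # 1200 vs 300 gives 4
  res@xiCounts <- setNames(c(300L, 1200L), c("0.500", "1.000"))
  expect_equal(bayesFactorMatrix(res, pr)["0.500", "1.000"], 4)
  # zero counts get the continuity correction on every cell
  res@xiCounts <- setNames(c(0L, 10L), c("0.500", "1.000"))
  expect_equal(bayesFactorMatrix(res, pr)["0.500", "1.000"], 10.5 / 0.5)
})

test_that("hyperposteriors summarize accepted draws", {
  pr <- HyperPrior(taxaCount = 4)
  tab <- simulateReferenceTable(pr, 120, seed = 51)
  obs <- tab@asfs[3, ]
  res <- abcReject(obs, tab, 30)
  post <- estimateHyperposterior(res)
  expect_equal(colMeans(post),
    colMeans(res@posterior[, c("meanEps", "dispEps", "sharedTime",
      "meanNe")]), tolerance = 1e-12)
  # identical eps across taxa contribute zero dispersion
  expect_equal(dispersionIndex(c(0.1, 0.1, 0.1)), 0)
  expect_equal(dispersionIndex(c(0.1, 0.3)), 0.1)
  expect_equal(dispersionIndex(3 * c(0.1, 0.3)),
    3 * dispersionIndex(c(0.1, 0.3)))
  expect_error(dispersionIndex(c(-1, 0.5)), "positive")
})

test_that("local-linear adjustment shrinks error on a linear relationship", {
  # synthetic table where the parameter is a linear function of the bins
  set.seed(61)
  nSims <- 400; nBins <- 6
  X <- matrix(runif(nSims * nBins), nSims, nBins)
  beta <- runif(nBins, -1, 1)
  theta <- 2 + X %*% beta + rnorm(nSims, sd = 0.05)
  pr <- HyperPrior(taxaCount = 6)
  params <- data.frame(xi = rep(1, nSims), sharedTime = theta,
    meanNe = theta, meanEps = theta, dispEps = theta)
  tab <- new("ReferenceTable", params = params, asfs = X, prior = pr,
    nHaploid = 8L, folded = TRUE, mutation = MutationModel(), seed = 61L)
  xObs <- runif(nBins)
  thetaTrue <- as.numeric(2 + xObs %*% beta)
  res <- abcReject(xObs, tab, 100)
  plain <- estimateHyperposterior(res)
  adj <- estimateHyperposterior(res, table = tab, observed = xObs,
    adjust = "local-linear")
  rmse <- function(v) sqrt(mean((v - thetaTrue)^2))
  expect_lt(rmse(adj$meanNe), 0.5 * rmse(plain$meanNe))
  # too few accepted draws falls back with a warning
  resSmall <- abcReject(xObs, tab, 4)
  expect_warning(
    estimateHyperposterior(resSmall, table = tab, observed = xObs,
      adjust = "local-linear"), "falling back")
})

test_that("the confusion matrix is exact on a separable toy table", {
  pr <- HyperPrior(taxaCount = 2)
  # two xi strata with constant, well separated aSFS rows
  params <- data.frame(
    xi = rep(c(0.5, 1), each = 4),
    sharedTime = 1, meanNe = 1, meanEps = 0.5, dispEps = 0)
  asfs <- rbind(matrix(rep(c(1, 0, 0, 0), 4), 4, byrow = TRUE),
    matrix(rep(c(0, 0, 0, 1), 4), 4, byrow = TRUE))
  asfs <- asfs + matrix(seq(0, 0.07, length.out = 32), 8, 4)  # break ties
  tab <- new("ReferenceTable", params = params, asfs = asfs, prior = pr,
    nHaploid = 8L, folded = TRUE, mutation = MutationModel(), seed = 1L)
  cm <- podConfusionMatrix(tab, podsPerModel = 4, k = 3, seed = 7)
  expect_equal(unname(cm), diag(2))
  expect_equal(unname(rowSums(cm)), c(1, 1))
  expect_error(podConfusionMatrix(tab, podsPerModel = 5, k = 3),
    "fewer than")
})

test_that("confusion matrix reproduces a hand-computed 4-row example", {
  pr <- HyperPrior(taxaCount = 2)
  params <- data.frame(xi = c(0.5, 0.5, 1, 1), sharedTime = 1,
    meanNe = 1, meanEps = 0.5, dispEps = 0)
  # rows: A=(0), B=(1), C=(2), D=(9). With k = 1 and leave-one-out:
  # A's nearest is B (xi 0.5) -> correct; B is equidistant from A and C and
  # the tie resolves to the lower row index A (xi 0.5) -> correct;
  # C's nearest is B (xi 0.5) -> wrong; D's nearest is C (xi 1) -> correct.
  asfs <- matrix(c(0, 1, 2, 9), ncol = 1)
  tab <- new("ReferenceTable", params = params, asfs = asfs, prior = pr,
    nHaploid = 8L, folded = TRUE, mutation = MutationModel(), seed = 1L)
  cm <- podConfusionMatrix(tab, podsPerModel = 2, k = 1, seed = 3)
  expect_equal(unname(cm), matrix(c(1, 0.5, 0, 0.5), 2))
})

test_that("posterior overlap behaves like an overlap coefficient", {
  set.seed(71)
  a <- rnorm(20000)
  expect_gte(posteriorOverlap(a, a), 0.99)
  expect_equal(posteriorOverlap(rnorm(5000), rnorm(5000) + 100), 0)
  ov <- posteriorOverlap(rnorm(50000), rnorm(50000) + 3)
  expect_lt(abs(ov - gaussianOverlap(3)), 0.02)
})

test_that("the mean bottleneck strength is recovered from the aSFS", {
  # posterior mean of E(eps) should land within the central 95% spread of
  # the prior-predictive E(eps) around the truth (i.e. beat the prior)
  pr <- HyperPrior(taxaCount = 6)
  tab <- simulateReferenceTable(pr, 4000, seed = 91)
  # prior-predictive spread of the 6-taxon mean of U(epsBounds)
  sdPrior <- diff(pr@epsBounds) / sqrt(12) / sqrt(6)
  halfWidth <- qnorm(0.975) * sdPrior
  set.seed(92)
  pods <- sample(nrow(tab@asfs), 4)
  errs <- vapply(pods, function(r) {
    keep <- setdiff(seq_len(nrow(tab@asfs)), r)
    sub <- new("ReferenceTable", params = tab@params[keep, ],
      asfs = tab@asfs[keep, ], prior = pr, nHaploid = tab@nHaploid,
      folded = tab@folded, mutation = tab@mutation, seed = tab@seed)
    post <- estimateHyperposterior(abcReject(tab@asfs[r, ], sub, 100))
    abs(mean(post$meanEps) - tab@params$meanEps[r])
  }, numeric(1))
  expect_lt(mean(errs), halfWidth)
})
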