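test_that("generated genotypes and SFS are mutually consistent", {
  ep <- EpochSchedule(0, 2000, 0)
  mut <- MutationModel(muSite = 1e-8, locusLength = 200, numLoci = 500)
  gen <- generatePopulation(4, ep, mut, seed = 11)
  expect_equal(ncol(gen$genotypes), 4)
  expect_true(all(gen$genotypes %in% 0:2))  # zero missingness
  recomputed <- sfsFromGenotypes(gen$genotypes, polarized = TRUE,
    invariantSites = gen$manifest$invariantSites)
  expect_identical(sfsCounts(recomputed), sfsCounts(gen$sfs))
  expect_equal(segregatingSites(gen$sfs), gen$manifest$segregatingSites)
})

test_that("mu = 0 produces an all-invariant dataset", {
  gen <- generatePopulation(3, EpochSchedule(0, 1000, 0),
    MutationModel(muSite = 0, locusLength = 100, numLoci = 50), seed = 2)
  expect_equal(nrow(gen$genotypes), 0)
  expect_equal(segregatingSites(gen$sfs), 0)
  expect_equal(sfsCounts(gen$sfs)[1], 5000)
})

test_that("regeneration under the same seed is identical", {
  ep <- growthDeclineSchedule(500, 5000, 500, 6000)
  mut <- MutationModel(muSite = 1e-8, locusLength = 200, numLoci = 300)
  g1 <- generatePopulation(5, ep, mut, seed = 77)
  g2 <- generatePopulation(5, ep, mut, seed = 77)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$manifest, g2$manifest)
  # and the written files are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeVCF(g1$genotypes, f1); writeVCF(g2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-site diversity matches the neutral expectation", {
  N <- 5000
  mut <- MutationModel(muSite = 1e-8, locusLength = 100, numLoci = 20000)
  gen <- generatePopulation(4, EpochSchedule(0, N, 0), mut, seed = 13)
  # pi per site from the unfolded SFS; SE from locus-level resampling
  cts <- sfsCounts(gen$sfs)[2:8]
  n <- 8
  piHat <- sum(cts * (1:7) * (n - (1:7))) * 2 / (n * (n - 1)) /
    gen$manifest$totalSites
  locus <- sub(":.*", "", rownames(gen$genotypes))
  alt <- rowSums(gen$genotypes)
  siteContrib <- 2 * alt * (n - alt) / (n * (n - 1)) / mut@locusLength
  perLocus <- tapply(siteContrib, locus, sum)
  perLocus <- c(perLocus, rep(0, mut@numLoci - length(perLocus)))
  se <- sd(perLocus) / sqrt(mut@numLoci)
  expect_lt(abs(piHat - 4 * N * 1e-8), 3 * se)
})

test_that("co-distributed generation honours the synchrony truth", {
  pr <- HyperPrior(taxaCount = 6)
  mut <- MutationModel(muSite = 1e-8, locusLength = 100, numLoci = 100)
  g1 <- generateCodistributed(pr, xi = 1, nDiploids = 4, mutation = mut,
    seed = 5)
  expect_equal(length(unique(g1$draw@taxa$tPulse)), 1L)
  gHalf <- generateCodistributed(pr, xi = 0.5, nDiploids = 4,
    mutation = mut, seed = 6)
  expect_equal(sum(gHalf$draw@taxa$synchronous), 3L)
  expect_equal(length(unique(gHalf$draw@taxa$tPulse[
    gHalf$draw@taxa$synchronous])), 1L)
  g2 <- generateCodistributed(pr, xi = 1, nDiploids = 4, mutation = mut,
    seed = 5)
  expect_identical(g1$manifest, g2$manifest)
  expect_identical(asfsValues(g1$asfs), asfsValues(g2$asfs))
  expect_s4_class(g1$asfs, "AggregateSFS")
})

test_that("manifests serialize to JSON and document regeneration", {
  gen <- generatePopulation(3, EpochSchedule(0, 500, 0),
    MutationModel(numLoci = 20), seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeManifest(gen$manifest, f)
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(m$seed, 3)
  expect_equal(m$mutation$numLoci, 20)
  expect_equal(m$totalSites, 2000)
})
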