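test_that("coalescence times have the Kingman expectation under constant N", {
  set.seed(101)
  ep <- EpochSchedule(0, 100, 0)
  t2 <- replicate(20000, coalescenceTime(2, 0, ep))
  expect_lt(abs(mean(t2) - 200), 3 * sd(t2) / sqrt(length(t2)))
  t3 <- replicate(20000, coalescenceTime(3, 0, ep))
  expect_lt(abs(mean(t3) - 200 / 3), 3 * sd(t3) / sqrt(length(t3)))
})

test_that("coalescence times under growth match the quadrature oracle", {
  # growth backwards (g > 0) needs a terminal constant epoch; match the
  # oracle by integrating the survival function piecewise
  N0 <- 500; g <- 5e-4; tEnd <- 4000
  ep <- EpochSchedule(c(0, tEnd), c(N0, N0 * exp(g * tEnd)), c(g, 0))
  lam <- function(t) {
    ifelse(t < tEnd,
      (1 - exp(-g * t)) / (2 * N0 * g),
      (1 - exp(-g * tEnd)) / (2 * N0 * g) +
        (t - tEnd) / (2 * N0 * exp(g * tEnd)))
  }
  oracle <- integrate(function(t) exp(-lam(t)), 0, Inf,
    rel.tol = 1e-10)$value
  set.seed(7)
  draws <- replicate(30000, coalescenceTime(2, 0, ep))
  expect_lt(abs(mean(draws) - oracle), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("histories that never coalesce are rejected", {
  expect_error(EpochSchedule(0, 1000, 1e-4), "terminal")
  expect_error(EpochSchedule(c(0, 10), c(5, 10), c(0, 0.1)), "terminal")
})

test_that("genealogy class lengths match neutral expectations", {
  set.seed(202)
  N <- 1000
  ep <- EpochSchedule(0, N, 0)
  reps <- 10000
  lens <- matrix(0, reps, 9)
  for (r in seq_len(reps)) lens[r, ] <- simulateGenealogy(10, ep)
  tot <- rowSums(lens)
  expTot <- 4 * N * sum(1 / (1:9))
  expect_lt(abs(mean(tot) - expTot), 3 * sd(tot) / sqrt(reps))
  for (i in 1:9) {
    expect_lt(abs(mean(lens[, i]) - 4 * N / i),
      3 * sd(lens[, i]) / sqrt(reps))
  }
  # n = 2: the single class is twice the pairwise coalescence time
  one <- simulateGenealogy(2, ep)
  expect_length(one, 1)
})

test_that("expected lengths scale linearly with population size", {
  # constant N: lengths are proportional to N outright
  e1 <- expectedBranchLengthsExact(8, EpochSchedule(0, 500, 0))
  e10 <- expectedBranchLengthsExact(8, EpochSchedule(0, 5000, 0))
  expect_equal(e10 / e1, rep(10, 7), ignore_attr = TRUE, tolerance = 1e-9)
  # varying N: the coalescent is scale-free once sizes, times and rates are
  # scaled together (N -> cN, t -> ct, g -> g/c)
  cf <- 10
  ep1 <- EpochSchedule(c(0, 2000), c(500, 5000), c(log(10) / 2000, 0))
  epC <- EpochSchedule(c(0, 2000 * cf), c(500 * cf, 5000 * cf),
    c(log(10) / (2000 * cf), 0))
  expect_equal(expectedBranchLengthsExact(8, epC) /
    expectedBranchLengthsExact(8, ep1), rep(cf, 7),
    ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("simulated spectra are reproducible and respect theta/i", {
  ep <- EpochSchedule(0, 5000, 0)
  mut <- MutationModel(muSite = 1e-8, locusLength = 100, numLoci = 20000)
  set.seed(5)
  s1 <- simulateSFS(8, ep, mut)
  set.seed(5)
  s2 <- simulateSFS(8, ep, mut)
  expect_identical(sfsCounts(s1), sfsCounts(s2))
  # theta/i expectation per class, SE estimated from locus batches
  set.seed(6)
  batches <- t(replicate(40, {
    sfsCounts(simulateSFS(8, ep, MutationModel(1e-8, 100, 2000)))[2:8]
  }))
  tot <- colSums(batches)
  thetaSite <- 4 * 5000 * 1e-8
  expTot <- thetaSite * 40 * 2000 * 100 / (1:7)
  se <- apply(batches, 2, sd) * sqrt(40)
  expect_true(all(abs(tot - expTot) < 3 * se))
  # mu = 0: nothing segregates
  s0 <- simulateSFS(8, ep, MutationModel(0, 100, 100))
  expect_equal(segregatingSites(s0), 0)
})

test_that("exact expected spectrum agrees with the simulator and msprime", {
  ep <- growthDeclineSchedule(1000, 10000, 1000, 6000, 30000)
  ex <- expectedBranchLengthsExact(8, ep)
  # internal cross-check: Monte Carlo from the simulator
  set.seed(9)
  mc <- expectedBranchLengths(8, ep, 60000)
  expect_true(all(abs(mc - ex) / ex < 0.05))
  # independent oracle: msprime with the identical piecewise-exponential
  # history (initial_size is diploid; msprime's growth_rate is the
  # forward-time rate, the negative of the backward rate used here)
  script <- sprintf(paste0(
    "import msprime, json\n",
    "dem = msprime.Demography()\n",
    "dem.add_population(initial_size=%g, growth_rate=%g)\n",
    "dem.add_population_parameters_change(time=%g, initial_size=%g, growth_rate=%g)\n",
    "dem.add_population_parameters_change(time=%g, initial_size=%g, growth_rate=0)\n",
    "R = 3000; rate = 1e-3\n",
    "s = [0.0]*7; ss = [0.0]*7\n",
    "for i, ts in enumerate(msprime.sim_ancestry(samples={'pop_0': 4},\n",
    "        ploidy=2, demography=dem, num_replicates=R, random_seed=12)):\n",
    "    mts = msprime.sim_mutations(ts, rate=rate, random_seed=i+1,\n",
    "        discrete_genome=False)\n",
    "    afs = mts.allele_frequency_spectrum(polarised=True, span_normalise=False)\n",
    "    for j in range(7):\n",
    "        v = afs[j+1]/rate\n",
    "        s[j] += v; ss[j] += v*v\n",
    "mean = [x/R for x in s]\n",
    "se = [((ss[j]/R - mean[j]**2)/R)**0.5 for j in range(7)]\n",
    "print(json.dumps({'mean': mean, 'se': se}))\n"),
    ep@NStart[1], -ep@growthRate[1],
    ep@tStart[2], ep@NStart[2], -ep@growthRate[2],
    ep@tStart[3], ep@NStart[3])
  out <- tryCatch(system2("python", "-", input = script, stdout = TRUE,
    stderr = FALSE), warning = function(w) NULL, error = function(e) NULL)
  expect_false(is.null(out))
  ms <- jsonlite::fromJSON(out[length(out)])
  expect_true(all(abs(ms$mean - ex) < 3 * ms$se))
})
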