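test_that("folding merges mirror-image classes without doubling the centre", {
  expect_equal(sfsCounts(fold(SFS(c(0, 6, 2, 3, 0)))), c(0, 9, 2, 0, 0))
  expect_equal(sfsCounts(fold(SFS(c(5, 7, 1)))), c(6, 7, 0))
  # symmetric input: outer classes add, the central class is untouched
  expect_equal(sfsCounts(fold(SFS(c(0, 4, 9, 4, 0)))), c(0, 8, 9, 0, 0))
  expect_true(isFolded(fold(SFS(c(0, 1, 1, 1, 0)))))
  expect_error(fold(fold(SFS(c(0, 1, 1, 1, 0)))), "already folded")
})

test_that("projection matches brute-force subsample enumeration", {
  spectra <- list(
    c(0, 6, 0, 0, 0),
    c(0, 0, 6, 0, 0),
    c(3, 1, 4, 1, 5),
    c(0, 2.5, 0, 7, 1))
  for (cts in spectra) {
    p <- projectSFS(SFS(cts), 2)
    expect_equal(sfsCounts(p), bruteProject(cts, 2), tolerance = 1e-9)
  }
  p <- projectSFS(SFS(c(1, 2, 3, 4, 5, 6, 7)), 4)
  expect_equal(sfsCounts(p), bruteProject(c(1, 2, 3, 4, 5, 6, 7), 4),
    tolerance = 1e-9)
})

test_that("projection keeps the singleton example and monomorphic gain", {
  p <- projectSFS(SFS(c(0, 6, 0, 0, 0)), 2)
  expect_equal(sfsCounts(p)[2], 3.0)
  expect_equal(attr(p, "monomorphicGain")[1], 3.0)
  p2 <- projectSFS(SFS(c(0, 0, 6, 0, 0)), 2)
  expect_equal(sfsCounts(p2)[2], 4.0)
})

test_that("projection conserves mass, composes, and commutes with folding", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    cts <- c(rpois(1, 50), rpois(n - 1, 10), rpois(1, 3))
    s <- SFS(cts)
    m <- sample(4:(n - 1), 1)
    p <- projectSFS(s, m)
    expect_equal(sum(sfsCounts(p)), sum(cts), tolerance = 1e-9)
    # n -> m -> k equals n -> k
    k <- sample(2:(m - 1), 1)
    expect_equal(sfsCounts(projectSFS(p, k)),
      sfsCounts(projectSFS(s, k)), tolerance = 1e-9)
    # fold(project) equals folding the projected counts by hand
    f <- fold(p)
    byHand <- numeric(m + 1)
    for (i in 0:m) {
      j <- min(i, m - i)
      byHand[j + 1] <- byHand[j + 1] + sfsCounts(p)[i + 1]
    }
    expect_equal(sfsCounts(f), byHand, tolerance = 1e-12)
  }
  expect_equal(sfsCounts(projectSFS(SFS(c(1, 2, 3, 4, 5)), 4)),
    c(1, 2, 3, 4, 5))  # m == n identity
  expect_error(projectSFS(SFS(c(0, 1, 0)), 1), ">= 2")
  expect_error(projectSFS(SFS(c(0, 1, 0)), 5), "exceed")
})

test_that("normalization covers segregating classes only and sums to one", {
  expect_equal(unname(normalizeSFS(SFS(c(0, 5, 5, 0, 0), folded = TRUE))),
    c(0.5, 0.5))
  expect_equal(unname(normalizeSFS(SFS(c(0, 9, 0, 0, 0)))), c(1, 0, 0))
  expect_equal(unname(normalizeSFS(SFS(c(0, 1, 2, 3, 0)))), c(1, 2, 3) / 6)
  expect_error(normalizeSFS(SFS(c(10, 0, 0, 0, 5))), "zero segregating")
})

test_that("aggregate SFS sorts within class and ignores taxon order", {
  a <- SFS(c(0, 5, 3, 2, 0))
  b <- SFS(c(0, 6, 2, 2, 0))
  ab <- buildASFS(list(a, b))
  expect_equal(asfsValues(ab), c(0.6, 0.5, 0.3, 0.2, 0.2, 0.2))
  expect_equal(asfsValues(buildASFS(list(b, a))), asfsValues(ab))
  # two identical spectra: each class holds its proportion twice
  aa <- buildASFS(list(a, a))
  expect_equal(asfsValues(aa), rep(normalizeSFS(a), each = 2),
    ignore_attr = TRUE)
  # layout bookkeeping
  expect_equal(binLayout(ab)$class, rep(1:3, each = 2))
  expect_equal(binLayout(ab)$rank, rep(1:2, 3))
  expect_error(buildASFS(list(a, SFS(c(0, 1, 0)))), "sample size")
  expect_error(buildASFS(list(a, fold(b))), "folding")
})

test_that("genotype tallying filters incomplete sites and hand-tallies", {
  fx <- handTallyFixture()
  s <- sfsFromGenotypes(fx$genotypes)
  expect_equal(sfsCounts(s), fx$folded)
  expect_true(isFolded(s))
  expect_equal(attr(s, "sitesExcluded"), fx$excluded)
  # all-heterozygous site in 3 diploids: class 3 of n = 6
  s2 <- sfsFromGenotypes(rbind(c(1, 1, 1)), polarized = TRUE)
  expect_equal(sfsCounts(s2)[4], 1)
  expect_false(isFolded(s2))
  # invariant retained sites go to class 0
  s3 <- sfsFromGenotypes(rbind(c(0, 0), c(1, 0)), invariantSites = 7)
  expect_equal(sfsCounts(s3)[1], 8)
  # a non-genotype value is rejected with the site named
  bad <- rbind(c(0, 3))
  rownames(bad) <- "chr1:99"
  expect_error(sfsFromGenotypes(bad), "chr1:99")
})

test_that("SFS validity catches malformed spectra", {
  expect_error(SFS(c(0, -1, 0)), "non-negative")
  expect_error(SFS(c(0, 1, 2, 3, 4), folded = TRUE), "folded")
  expect_error(new("SFS", counts = c(0, 1), nHaploid = 4L,
    folded = FALSE, polarized = FALSE), "length")
})
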