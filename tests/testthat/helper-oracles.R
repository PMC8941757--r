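# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Brute-force down-projection: enumerate every m-subset of n genes and
# average the resulting spectra. Input/output are plain count vectors
# (classes 0..n / 0..m).
bruteProject <- function(counts, m) {
  n <- length(counts) - 1L
  subs <- combn(n, m)
  out <- numeric(m + 1L)
  for (i in 0:n) {
    if (counts[i + 1L] == 0) next
    # genes 1..i carry the derived allele
    tally <- numeric(m + 1L)
    for (s in seq_len(ncol(subs))) {
      j <- sum(subs[, s] <= i)
      tally[j + 1L] <- tally[j + 1L] + 1
    }
    out <- out + counts[i + 1L] * tally / ncol(subs)
  }
  out
}

# Brute-force rarefied allele count: average the number of distinct alleles
# over every g-subset of the genes at one locus.
bruteAllelicRichness <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- combn(length(genes), g)
  mean(apply(subs, 2L, function(ix) length(unique(genes[ix]))))
}

# Mean pairwise difference per site by direct double loop over haplotypes.
brutePi <- function(haps, L) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) tot <- tot + sum(haps[i, ] != haps[j, ])
  }
  tot / choose(n, 2) / L
}

# Numerical inversion oracle for the coalescence-time distribution: mean of
# T for k lineages from t = 0 under N(t) = N0 * exp(g t), via the survival
# function S(t) = exp(-C(k,2) * Lambda(t)).
oracleMeanCoalTime <- function(k, N0, g, upper = Inf) {
  lam <- function(t) {
    if (g == 0) t / (2 * N0) else (1 - exp(-g * t)) / (2 * N0 * g)
  }
  pair <- choose(k, 2)
  integrate(function(t) exp(-pair * vapply(t, lam, numeric(1))),
    0, upper, rel.tol = 1e-10)$value
}

# A tiny deterministic genotype fixture: 10 sites x 2 diploids with a known
# hand tally (class = minor copies out of n = 4).
handTallyFixture <- function() {
  g <- rbind(
    c(0, 0),   # invariant            -> class 0
    c(1, 0),   # 1 alt copy           -> class 1
    c(2, 0),   # 2 alt copies         -> class 2
    c(1, 1),   # 2 alt copies         -> class 2
    c(2, 1),   # 3 alt -> minor 1     -> class 1
    c(2, 2),   # 4 alt -> minor 0     -> class 0
    c(0, 1),   # 1 alt                -> class 1
    c(NA, 1),  # missing              -> excluded
    c(1, 2),   # 3 alt -> minor 1     -> class 1
    c(0, 2))   # 2 alt copies         -> class 2
  rownames(g) <- paste0("locus_", 1:10, ":1")
  # expected folded counts for the 9 complete sites: classes 0..4
  list(genotypes = g, folded = c(2, 4, 3, 0, 0), excluded = 1L)
}

# standard-normal overlap of N(0,1) and N(mu,1): 2 * pnorm(-|mu|/2)
gaussianOverlap <- function(mu) 2 * pnorm(-abs(mu) / 2)
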