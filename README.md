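# codemog

Comparative demographic inference from site frequency spectra, for
population geneticists asking whether co-distributed populations responded
to past climatic change **in concert**. The package was built around the
comparative phylogeography of two co-distributed freshwater fishes (the
southern and Yarra pygmy perches, *Nannoperca australis* and *N. obscura*)
and automates that workflow end to end on ddRAD-type SNP data:

* **SFS construction** — complete-data filtering of diploid genotypes
  (VCF in), hypergeometric down-projection to a common sample size,
  folding, dadi-style text I/O;
* **Single-population coalescent simulation** under piecewise-exponential
  demography (Rcpp kernel), plus an exact expected-SFS computation;
* **Demographic scenario selection** per population: composite likelihood
  `sum_i O_i log p_i` over SFS classes, AIC = 2k − 2ℓ, Akaike weights
  `w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`, parametric-bootstrap percentile
  confidence intervals;
* **Hierarchical ABC co-demography** over the aggregate SFS (per-class,
  cross-taxon sorted normalized spectra): rejection sampling against a
  simulated reference table, Bayes-factor matrices over the synchrony
  hyperparameter ξ ∈ {z/T}, posteriors for the bottleneck strength
  ε (post/pre size ratio), its dispersion index Var(ε)/Mean(ε), timing and
  mean Ne, and leave-one-out pseudo-observed-dataset confusion matrices;
* **Diversity statistics** — rarefied allelic richness, Nei's unbiased gene
  diversity, nucleotide diversity, and species-level pooled/Welch t or
  Wilcoxon comparisons with F-test-based automatic selection;
* **Synthetic ddRAD-like data generation** with a truth manifest, so every
  stage is testable with known demographic truth.

## Worked example

The packaged per-population diversity table for the two pygmy perch species
(8 + 5 populations) reproduces the species-level comparisons:

```r
library(codemog)
res <- diversityComparisons()
res$comparisons$AR
#> pooled-variance t = 2.38 (df = 11.00), p = 0.0364
res$comparisons$snps
#> Welch t = 4.63 (df = 8.27), p = 0.00155
```

Allelic richness and gene diversity differ by a pooled-variance t-test
(the F-test finds no variance difference), SNP counts by Welch's t-test;
all three are significantly higher in *N. australis*, the species with the
wider range.

Demographic scenario selection on a synthetic population with known truth:

```r
mut <- MutationModel(muSite = 1e-8, locusLength = 300, numLoci = 20000)
set.seed(7)
obs <- simulateSFS(8, EpochSchedule(0, 10000, 0), mut)  # constant N = 10,000
fits <- compareScenarios(obs, defaultScenarios(), mut, seed = 8)
attr(fits, "selected")
#> [1] "constant"
round(vapply(fits, slot, numeric(1), "weight"), 3)
#>      constant        growth   constantLow growthDecline       decline
#>         0.999         0.000         0.000         0.000         0.001
fits$constant@estimate
#>       ne
#> 9950.414
```

The constant-size model is selected decisively (Akaike weight 0.999) and
the true size of 10,000 is recovered within half a percent. The hierarchical ABC stage works the same
way at the multi-population level — see `xiRecoveryExperiment()` and the
vignette for the full co-demographic model.

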