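---
title: "Comparative demographic inference with codemog: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative demographic inference with codemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codemog)
```

# The scientific problem

When several co-distributed populations are hit by the same climatic event,
did they contract together? `codemog` implements the inference chain used to
ask this question from reduced-representation (ddRAD-type) SNP data:

1. per-population **site frequency spectra** (SFS) built under a
   complete-data filter, down-projected to a common sample size and
   optionally folded;
2. per-population **demographic scenario selection** by SFS composite
   likelihood with AIC and Akaike weights, with parametric-bootstrap
   confidence intervals;
3. **hierarchical approximate Bayesian computation** (hABC) across
   populations over the *aggregate* SFS, estimating the proportion of taxa
   whose contraction is synchronous (`xi`), the bottleneck strength
   (`eps`, the post/pre decline size ratio), its cross-taxon dispersion
   `Var(eps)/Mean(eps)`, and the pulse timing;
4. per-population **diversity statistics** (rarefied allelic richness, Nei's
   unbiased gene diversity, nucleotide diversity) with species-level
   t / Wilcoxon comparisons.

A synthetic-data generator with a fully recorded truth manifest makes every
stage testable without any external download.

# The coalescent engine

## Model

Each population follows a single-population Kingman coalescent under a
piecewise-exponential size history (`EpochSchedule`): time runs backwards in
generations, and within an epoch the diploid size is
$N(t) = N_0 e^{g (t - t_0)}$. The coalescent rate for $k$ lineages is
$\binom{k}{2} / (2N(t))$; waiting times are drawn by closed-form inversion of
the integrated intensity within each epoch, with carry-over at boundaries.
Histories whose terminal epoch grows without bound into the past
($g > 0$) have a finite total intensity — with positive probability the
sample never coalesces — and are rejected at validity checking.

Mutations follow the infinite-sites model at rate $\mu$ per site per
generation (default $10^{-8}$, with a one-year generation time assumed for
any year conversion): per locus, the mutation count is Poisson in the total
tree length, and each mutation lands on frequency class $i$ with probability
proportional to the class-$i$ branch length. Only the SFS is consumed
downstream, so no sequences are simulated. Loci are unlinked (one genealogy
each); there is no recombination, migration or selection.

## Exact expected spectra

The scenario-fitting objective needs the expected SFS at arbitrary
parameter values, many thousands of times. Monte-Carlo averaging of
simulated genealogies leaves a bias/noise floor that is shared across an
optimisation via common random numbers but *not* across competing models of
different flexibility: at realistic SNP counts (thousands), a
four-parameter scenario can exploit the Monte-Carlo wiggle of its own
expected-spectrum surface and overtake the generating model's AIC. We
observed exactly this in development, so the default objective uses an
exact computation instead (`expectedBranchLengthsExact()`):

* under any deterministic $N(t)$ the coalescent is a deterministic time
  change of the standard-rate Kingman process, so the ancestral
  lineage-count distribution $P(A(t) = k)$ is Tavaré's classical formula
  evaluated at the rescaled time $\Omega(t) = \int_0^t ds / (2N(s))$
  (closed form per epoch);
* $E[T_k]$, the expected time spent with $k$ lineages, is the time integral
  of that probability, evaluated by composite Gauss–Legendre quadrature on
  a geometric grid of rescaled times (truncated where survival drops below
  $e^{-40}$);
* the expected branch length subtending $i$ of $n$ tips follows from the
  uniform-partition probability $\binom{n-i-1}{k-2} / \binom{n-1}{k-1}$.

The result is exact to quadrature accuracy (machine precision on constant
histories, verified independently against a survival-function integral and
against msprime), costs well under a millisecond, and makes the fitting
objective a deterministic function of the parameters. The Monte-Carlo path
remains available (`expectedMethod = "mc"`; `expectedSFS()`), with common
random numbers as the second-best route to a deterministic objective.

# Scenario fitting

## Composite likelihood and the monomorphic class

The objective is the multinomial composite log-likelihood
$\sum_i O_i \log p_i$ over frequency classes, with expected class
probabilities floored at $10^{-10}$ and renormalized. By default the
invariant class is included: $p_i = \mu\, E[L_i]$ per site with the
monomorphic remainder $1 - \sum_i p_i$. This matters. Over segregating
classes alone, the normalized spectrum of a constant-size population is
independent of $N$ — two constant-size scenarios that differ only in their
size bounds would be *indistinguishable in principle*. Including the
monomorphic mass ties the spectrum to the absolute mutational input and
identifies the size scale, exactly as fixing the mutation rate does in
standard SFS likelihood tools. `compositeLogLik()` retains the
segregating-only form as its default surface (`monomorphic = FALSE`) for
shape-only comparisons.

## The default scenario set

Five candidate syndromes over a 30,000-generation window (configurable;
`defaultScenarios()`):

| scenario | free parameters | sketch |
|---|---|---|
| constant | `ne` in [1e3, 1e5] | flat |
| growth | `ne`, anc/cur ratio in [0.02, 0.5] | expansion to present |
| constantLow | `ne` in [50, 1e3] | flat but small |
| growthDecline | `ne`, peak ratio, anc ratio, `tPeak` | hump: growth to a peak, then decline |
| decline | `ne`, anc/cur ratio in [2, 50], `tOnset` | contraction starting `tOnset` ago |

Two design points were settled empirically. First, the decline syndrome
carries a free onset time with a constant ancestral size before it: a
gradual decline spread over the whole window is nearly unidentifiable from
a small constant size at $n = 8$. Second, `scenarioTruths()` pins one
representative parameter vector per syndrome for validation experiments,
chosen so the syndrome is actually expressed at the sample size used — a
growth phase that predates the sample's entire coalescent history is
invisible to any method, and a "recovery" experiment built on it would
measure nothing.

Optimisation is Nelder–Mead (Brent in one dimension) on log/logit-
transformed coordinates — bounds are enforced by the transform — with
restarts from jittered incumbents (`cycles`). Model ranking uses
AIC $= 2k - 2\ell$ and Akaike weights; bootstrap intervals are percentile
(2.5/97.5, linear interpolation between order statistics) over refits of
spectra re-simulated at the MLE.

# The co-demographic hierarchical model

Each of $T$ taxa follows a bottleneck-atop-growth history: constant current
size `ne` back to its pulse time, an instantaneous size jump by
$1/\varepsilon$ at the pulse (the forward-time contraction of strength
$\varepsilon$ = post/pre size ratio), then an exponential relaxation back to
an ancestral size `preDecline / growth` at the 30,000-generation horizon.
The hyperparameter `xi` lives on the grid $\{z/T\}$: $\mathrm{round}(\xi T)$
taxa share a single pulse time, the rest draw independent times;
$\xi = 1/T$ is the fully asynchronous model (0.167 for six taxa).

The cross-taxon summary is the **aggregate SFS**: each taxon's spectrum is
normalized over its segregating classes, and within every frequency class
the $T$ values are sorted in non-increasing order. Taxon identity is
deliberately discarded; what remains is the cross-taxon dispersion of
spectrum shapes per class, which is exactly where synchrony leaves its
mark — a shared pulse time co-moves all taxa's shapes, independent times
mix them.

## Reference-table simulation in the sparse-SNP regime

ddRAD data are *sparse*: far fewer than one SNP per locus, loci unlinked.
In that regime the per-taxon class counts, conditional on the total SNP
number, are exactly multinomial on the normalized expected branch lengths,
and the total is Poisson with mean $\mu \times \text{total sites} \times
E[\text{tree length}]$ (a mixed-Poisson aggregation over independent
genealogies). The default reference-table method samples from this law
directly using the exact expectations — a faithful simulation of the
observable, at a cost independent of the locus count — which is what makes
$5 \times 10^4$-row tables a few minutes' work. Explicit per-locus
simulation is retained (`method = "locus"`) and the two are tested to agree
in distribution.

## Rejection, Bayes factors, posteriors

Distances are Euclidean over bins standardized by the reference-table
standard deviation (zero-variance bins dropped); the smallest $k$ draws are
accepted with ties broken by row index. Synchrony model choice uses the top
1,500 of 1.5 million draws at full scale — top 3% at the package's
50,000-draw validation scale — and Bayes factors
$(n_a/n_b)(\pi_b/\pi_a)$ with a +0.5 continuity correction on all counts
when any is zero. Hyperparameter posteriors (top 100 draws by default) are
the accepted draws' cross-taxon summaries — $E(\varepsilon)$,
$\mathrm{Var}(\varepsilon)/\mathrm{Mean}(\varepsilon)$, shared time, mean
`ne` — optionally corrected by distance-weighted (Epanechnikov) local-linear
regression on the standardized bins, which falls back to plain rejection
with a warning when fewer than `bins + 2` draws are accepted. Pseudo-
observed-dataset (POD) classification removes the POD's own row from the
candidate set; bin standard deviations are taken from the full table, whose
perturbation by one row is negligible at any realistic size. Posterior
agreement between populations is summarized by the histogram overlap
coefficient (64 bins over the pooled range) — the cross-population
comparison metric.

## Where synchrony is detectable — and where it is not

The default hyperprior (`HyperPrior()`) is deliberately an *informed* one:
current `ne` uniform on [4,000, 12,000], $\varepsilon$ on [0.02, 0.08]
(12–50-fold contractions), pulse time on [500, 10,000] generations, growth
magnitude on [1, 3]. Sensitivity mapping with a supervised-classifier
diagnostic during development showed that with only six taxa, eight haploid
samples and folded four-class spectra, the aggregate SFS carries almost no
synchrony information once the nuisance priors are broad or the
$\varepsilon$ prior admits near-flat histories: a pulse that leaves no
imprint on a taxon's spectrum cannot correlate taxa. In the informed regime
the machinery recovers full synchrony decisively (the package's acceptance
experiment: Bayes factors favour $\xi = 1$ over $\xi = 1/6$ in $\ge 80\%$
of synchronous-truth PODs, and the POD confusion matrix shows the
characteristic pattern of extreme models — fully synchronous, fully
asynchronous — classifying far better than intermediate ones). Mirroring
the workflow this package automates, hyperprior bounds should be set from
the preceding per-population fits; treat the shipped defaults as a starting
point, and expect timing posteriors to be much less resolved than
$\xi$ — at this scale the aggregate SFS localizes *whether* taxa pulsed
together far better than *when*.

# Diversity statistics

Rarefied allelic richness is the exact expectation
$\sum_a [1 - \binom{N - N_a}{g} / \binom{N}{g}]$ of the allele count in a
subsample of $g$ genes; the conventional rarefaction to four diploids is
$g = 8$ genes, but the operation is parameterized in genes so either
reading is expressible. Gene diversity is Nei's unbiased
$\frac{n}{n-1}(1 - \sum p^2)$; nucleotide diversity is the mean pairwise
difference per site. Species-level comparisons follow the conventional
decision rule: an F-test of variance equality at $\alpha = 0.05$ selects
the pooled-variance t-test when non-significant and Welch otherwise, with
Wilcoxon rank-sum available; |t| is reported to two decimals. On the
packaged pygmy-perch per-population table this reproduces pooled t = 2.38
(allelic richness), pooled t = 2.93 (gene diversity) and Welch t = 4.63
(SNP counts), and species mean nucleotide diversities of
$2.83 \times 10^{-4}$ and $5.78 \times 10^{-5}$.

```{r diversity}
res <- diversityComparisons()
res$comparisons$AR
res$comparisons$snps
```

# The synthetic-data generator

`generatePopulation()` emulates the post-filtering product of a ddRAD
pipeline: thousands of short unlinked loci, 3–20 diploids per population,
biallelic SNPs, zero missingness (the complete-data filter is emulated by
construction rather than by discarding sites). Loci are 300 bp by default —
within the 300–800 bp size-selection window of the protocol the data type
comes from — and 20,000 loci at that length put per-population SNP counts
in the low thousands, the scale such datasets actually show.
Haploid genes $2j-1, 2j$ form diploid $j$; each mutation's carrier set
comes from an explicit tip-set genealogy, so the emitted genotype table,
its SFS and the truth manifest are mutually consistent and byte-identical
under a repeated seed. `generateCodistributed()` layers the hierarchical
truth (a fixed $\xi$, shared pulse times) on top.

What the generator does **not** emulate: missing data (filtered upstream in
the real workflow), linkage within loci beyond the shared genealogy,
sequencing error, allele dropout, and reference bias. Passing tests
therefore demonstrate the correctness of the inference machinery on clean
complete-data input, not robustness to those artefacts.

# Numerical choices and degenerate inputs

* Expected-spectrum quadrature: 12-point Gauss–Legendre on a geometric
  grid of 48 rescaled-time points up to $\tau = 40$; relative accuracy far
  beyond the $10^{-8}$ the objective uses.
* Probability floors: expected class probabilities floored at $10^{-10}$
  before renormalization; zero accepted counts in Bayes factors corrected
  by +0.5 on every count.
* Ties: rejection and POD classification break distance ties by row index;
  the POD confusion matrix assigns count ties to the smaller $\xi$.
* Degenerate spectra: normalization of a zero-segregating spectrum is an
  error by default; reference-table construction treats such a taxon as an
  all-zero proportion row (`allowZero`), since weak-mutation draws do occur
  under the prior.
* A folded spectrum cannot be polarized, cannot be folded again, and
  projection must precede folding.

# Scale of the shipped validation experiments

The package's acceptance experiments run at desk scale: scenario selection
uses 20 replicate datasets per syndrome of 20,000 loci at $n = 8$; the hABC
experiment uses a 50,000-row reference table (top 3% acceptance, matching
the full-scale 1,500 of 1.5 million), 20 synchronous-truth PODs and a
50-POD-per-model confusion matrix. Full-scale settings (1.5 million draws,
top 1,500 / top 100, 50 PODs) are the package defaults in `runConfig()`.

# Known limitations

* One-dimensional spectra only; no joint (multi-population) SFS, so no
  migration or split-time inference.
* The composite likelihood treats sites as independent; within-locus
  linkage makes it a composite, not a true, likelihood — AIC comparisons
  inherit that approximation.
* Synchrony detection at $T = 6$, $n = 8$ requires an informed hyperprior
  (above); with broad priors the honest answer is that the aggregate SFS
  cannot tell synchronous from asynchronous pulses.
* The timing hyperparameter is weakly identified at this scale.
* LD-based effective-size estimation and nonparametric multi-epoch
  reconstructions are out of scope.
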