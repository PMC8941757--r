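# Validation experiments: self-contained synthetic studies exercising the
# full pipeline at known truth. They back the package's acceptance checks
# and give users a one-call way to audit the machinery on their own machine.

#' Representative truth parameters for the five default scenarios
#'
#' One parameter vector per default scenario, chosen so each demographic
#' syndrome is actually expressed at n = 8 haploids (a growth-then-decline
#' history whose growth phase predates the sample's coalescence would be
#' indistinguishable from a simpler model by any method).
#'
#' @return named list of named parameter vectors.
#' @export
scenarioTruths <- function() {
  list(
    constant = c(ne = 10000),
    growth = c(ne = 20000, ratio = 0.05),
    constantLow = c(ne = 300),
    growthDecline = c(ne = 5000, peakRatio = 5, ancRatio = 0.1,
      tPeak = 8000),
    decline = c(ne = 500, ratio = 20, tOnset = 5000))
}

#' Scenario-selection recovery experiment
#'
#' Generates datasets under each default scenario at its representative
#' truth (unfolded spectra of unlinked loci; the synthetic data are
#' polarized by construction), fits all five scenarios to every dataset by
#' composite likelihood, and reports how often AIC selects the generating
#' scenario.
#'
#' @param repsPerScenario replicate datasets per generating scenario.
#' @param mutation the \linkS4class{MutationModel} of each dataset.
#' @param nHaploid haploid sample size.
#' @param seed integer seed.
#' @return data.frame with one row per dataset (\code{truth},
#'   \code{selected}); the \code{"accuracy"} attribute maps scenario name
#'   to the fraction recovered.
#' @export
scenarioSelectionExperiment <- function(repsPerScenario = 20,
                                        mutation = MutationModel(
                                          muSite = 1e-8, locusLength = 300,
                                          numLoci = 20000),
                                        nHaploid = 8, seed = 1) {
  scenarios <- defaultScenarios()
  truths <- scenarioTruths()
  set.seed(seed)
  rows <- list()
  for (nm in names(truths)) {
    ep <- scenarios[[nm]]@builder(truths[[nm]])
    for (r in seq_len(repsPerScenario)) {
      obs <- simulateSFS(nHaploid, ep, mutation)
      fits <- compareScenarios(obs, scenarios, mutation,
        seed = sample.int(.Machine$integer.max, 1L))
      rows[[length(rows) + 1L]] <- data.frame(truth = nm,
        selected = attr(fits, "selected"))
    }
  }
  out <- do.call(rbind, rows)
  acc <- vapply(names(truths), function(nm)
    mean(out$selected[out$truth == nm] == nm), numeric(1))
  attr(out, "accuracy") <- acc
  out
}

#' Synchrony (xi) recovery experiment
#'
#' Builds a reference table from the co-demographic hyperprior, treats
#' fully synchronous (xi = 1) rows as pseudo-observed datasets, and checks
#' whether Bayes factors favour the fully synchronous over the fully
#' asynchronous (xi = 1/T) model under leave-one-out rejection ABC;
#' optionally also computes the POD confusion matrix over the whole grid.
#'
#' @param prior the \linkS4class{HyperPrior}.
#' @param nSims reference-table size.
#' @param nPods synchronous-truth pseudo-observed datasets.
#' @param topFrac accepted fraction for model choice (0.03 = top 3%).
#' @param podsPerModel PODs per xi value for the confusion matrix (NULL
#'   skips it).
#' @param mutation per-taxon \linkS4class{MutationModel}.
#' @param seed integer seed.
#' @return list: \code{winRate} (fraction of xi = 1 PODs with
#'   BF(1 vs 1/T) > 1), \code{bayesFactors} (per-POD BF values),
#'   \code{confusion} (matrix or NULL), \code{table}.
#' @export
xiRecoveryExperiment <- function(prior = HyperPrior(taxaCount = 6),
                                 nSims = 50000, nPods = 20,
                                 topFrac = 0.03, podsPerModel = 50,
                                 mutation = MutationModel(numLoci = 5000,
                                   locusLength = 300),
                                 seed = 1) {
  set.seed(seed)
  tableSeed <- sample.int(.Machine$integer.max, 1L)
  tab <- simulateReferenceTable(prior, nSims, mutation = mutation,
    seed = tableSeed)
  xi <- tab@params$xi
  grid <- xiGrid(prior)
  k <- max(1L, round(topFrac * nSims))
  set.seed(seed + 1L)
  pods <- sample(which(abs(xi - 1) < 1e-9), nPods)
  sds <- apply(tab@asfs, 2L, stats::sd)
  keep <- sds > 0
  st <- sweep(tab@asfs[, keep, drop = FALSE], 2L, sds[keep], "/")
  bfs <- vapply(pods, function(r) {
    d <- sqrt(colSums((t(st) - st[r, ])^2))
    d[r] <- Inf  # leave the POD's own row out
    ord <- order(d)[seq_len(k)]
    n1 <- sum(abs(xi[ord] - 1) < 1e-9)
    nA <- sum(abs(xi[ord] - grid[1L]) < 1e-9)
    if (n1 == 0 || nA == 0) { n1 <- n1 + 0.5; nA <- nA + 0.5 }
    n1 / nA
  }, numeric(1))
  cm <- NULL
  if (!is.null(podsPerModel)) {
    cm <- podConfusionMatrix(tab, podsPerModel = podsPerModel, k = k,
      seed = seed + 2L)
  }
  list(winRate = mean(bfs > 1), bayesFactors = bfs, confusion = cm,
    table = tab)
}
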