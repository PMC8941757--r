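#' Site frequency spectrum
#'
#' Container for a one-dimensional site frequency spectrum: per-class site
#' counts for a sample of \code{nHaploid} gene copies. Class index equals the
#' number of copies of the derived (unfolded) or minor (folded) allele, so
#' \code{counts} has length \code{nHaploid + 1} with classes \code{0..n}.
#' Class 0 holds invariant-but-retained sites; class \code{n} (unfolded) holds
#' sites fixed for the derived allele in the sample.
#'
#' @slot counts numeric vector of non-negative per-class site counts,
#'   length \code{nHaploid + 1}.
#' @slot nHaploid integer, haploid sample size n.
#' @slot folded logical; if \code{TRUE}, classes above \code{floor(n/2)} are 0.
#' @slot polarized logical; \code{TRUE} iff the ancestral state is assumed
#'   known (unfolded spectra only).
#'
#' @seealso [SFS()], [fold()], [projectSFS()], [normalizeSFS()]
#' @export
setClass("SFS",
  representation(
    counts = "numeric",
    nHaploid = "integer",
    folded = "logical",
    polarized = "logical"
  )
)

setValidity("SFS", function(object) {
  n <- object@nHaploid
  msg <- character()
  if (length(n) != 1L || is.na(n) || n < 2L)
    msg <- c(msg, "nHaploid must be a single integer >= 2")
  if (length(object@counts) != n + 1L)
    msg <- c(msg, sprintf("counts must have length nHaploid + 1 (%d)", n + 1L))
  if (anyNA(object@counts) || any(!is.finite(object@counts)))
    msg <- c(msg, "counts must be finite and non-missing")
  else if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (isTRUE(object@folded)) {
    hi <- seq.int(floor(n / 2) + 2L, n + 1L)
    if (length(hi) && any(object@counts[hi] != 0))
      msg <- c(msg, "folded SFS must have zero counts above floor(n/2)")
    if (isTRUE(object@polarized))
      msg <- c(msg, "a folded SFS cannot be polarized")
  }
  if (length(msg)) msg else TRUE
})

#' Aggregate site frequency spectrum
#'
#' Cross-taxon summary statistic for hierarchical ABC: each taxon's SFS is
#' normalized over its segregating classes, then within every frequency class
#' the T taxon values are sorted in non-increasing order and the classes
#' concatenated in ascending frequency order. The taxon identity of each
#' value is deliberately discarded; only the cross-taxon dispersion per
#' frequency class is retained.
#'
#' @slot values numeric vector, length \code{taxaCount * nClasses}.
#' @slot taxaCount integer, number of taxa T.
#' @slot nHaploid integer, shared haploid sample size.
#' @slot folded logical, shared folding state.
#' @slot binLayout data.frame mapping vector position to
#'   \code{(class, rank)}: allele-frequency class and within-class rank.
#'
#' @seealso [buildASFS()]
#' @export
setClass("AggregateSFS",
  representation(
    values = "numeric",
    taxaCount = "integer",
    nHaploid = "integer",
    folded = "logical",
    binLayout = "data.frame"
  )
)

setValidity("AggregateSFS", function(object) {
  msg <- character()
  if (object@taxaCount < 2L) msg <- c(msg, "taxaCount must be >= 2")
  if (nrow(object@binLayout) != length(object@values))
    msg <- c(msg, "binLayout must have one row per value")
  cls <- object@binLayout$class
  for (cl in unique(cls)) {
    v <- object@values[cls == cl]
    if (is.unsorted(rev(v), strictly = FALSE))
      msg <- c(msg, sprintf("values within class %d must be non-increasing", cl))
  }
  if (length(msg)) msg else TRUE
})

#' Piecewise-exponential demographic history
#'
#' A single-population size history, time measured backwards from the present
#' in generations. Within epoch e the diploid effective size is
#' \code{N(t) = NStart[e] * exp(growthRate[e] * (t - tStart[e]))}.
#' The first epoch starts at time 0; the last extends to infinity and must
#' have \code{growthRate <= 0} so that the coalescent intensity integral
#' diverges and coalescence is certain.
#'
#' @slot tStart numeric, epoch start times (generations ago), increasing,
#'   first 0.
#' @slot NStart numeric, diploid effective size at each epoch start.
#' @slot growthRate numeric, backward exponential rate per epoch.
#'
#' @seealso [EpochSchedule()], [growthDeclineSchedule()],
#'   [bottleneckSchedule()]
#' @export
setClass("EpochSchedule",
  representation(
    tStart = "numeric",
    NStart = "numeric",
    growthRate = "numeric"
  )
)

setValidity("EpochSchedule", function(object) {
  msg <- character()
  k <- length(object@tStart)
  if (k < 1L) msg <- c(msg, "at least one epoch required")
  if (length(object@NStart) != k || length(object@growthRate) != k)
    msg <- c(msg, "tStart, NStart and growthRate must have equal length")
  else {
    if (object@tStart[1L] != 0) msg <- c(msg, "first epoch must start at t = 0")
    if (k > 1L && any(diff(object@tStart) <= 0))
      msg <- c(msg, "epoch start times must be strictly increasing")
    if (any(!is.finite(object@tStart)) || any(!is.finite(object@NStart)) ||
        any(!is.finite(object@growthRate)))
      msg <- c(msg, "epoch fields must be finite")
    else {
      if (any(object@NStart <= 0)) msg <- c(msg, "NStart must be positive")
      if (object@growthRate[k] > 0)
        msg <- c(msg, paste0(
          "terminal epoch must have growthRate <= 0: a population growing ",
          "without bound into the past never coalesces"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Infinite-sites mutation model
#'
#' @slot muSite mutations per site per generation (default 1e-8, with a
#'   generation time of one year assumed for any year conversion).
#' @slot locusLength locus length in base pairs.
#' @slot numLoci number of unlinked loci.
#'
#' @export
setClass("MutationModel",
  representation(
    muSite = "numeric",
    locusLength = "numeric",
    numLoci = "integer"
  )
)

setValidity("MutationModel", function(object) {
  msg <- character()
  if (object@muSite < 0 || !is.finite(object@muSite))
    msg <- c(msg, "muSite must be finite and >= 0")
  if (object@locusLength < 1) msg <- c(msg, "locusLength must be >= 1")
  if (object@numLoci < 1L) msg <- c(msg, "numLoci must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Demographic scenario
#'
#' A named demographic model: free parameters with finite uniform bounds and
#' a deterministic builder mapping a parameter vector to an
#' \linkS4class{EpochSchedule} over the model's time horizon.
#'
#' @slot name scenario name.
#' @slot paramNames names of the free parameters.
#' @slot lower,upper numeric parameter bounds (finite).
#' @slot logScale logical per parameter: optimize/draw on the log scale.
#' @slot builder function(par) -> EpochSchedule.
#'
#' @seealso [defaultScenarios()], [fitScenario()]
#' @export
setClass("Scenario",
  representation(
    name = "character",
    paramNames = "character",
    lower = "numeric",
    upper = "numeric",
    logScale = "logical",
    builder = "function"
  )
)

setValidity("Scenario", function(object) {
  k <- length(object@paramNames)
  msg <- character()
  if (k < 1L) msg <- c(msg, "at least one free parameter required")
  if (length(object@lower) != k || length(object@upper) != k ||
      length(object@logScale) != k)
    msg <- c(msg, "bounds and logScale must match paramNames in length")
  else {
    if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
      msg <- c(msg, "bounds must be finite")
    else if (any(object@upper <= object@lower))
      msg <- c(msg, "upper bounds must exceed lower bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted demographic scenario
#'
#' @slot name scenario name.
#' @slot estimate named numeric, maximum composite-likelihood parameters.
#' @slot logLik maximum composite log-likelihood.
#' @slot aic Akaike information criterion, 2k - 2 logLik.
#' @slot weight Akaike weight relative to the compared scenario set
#'   (NA until scenarios are compared).
#' @slot ci matrix of bootstrap percentile intervals (2.5%, 97.5% columns),
#'   one row per parameter; 0-row until [parametricBootstrap()] is run.
#' @slot details list of fit diagnostics (restarts, objective evaluations,
#'   dropped bootstrap replicates, ...).
#'
#' @export
setClass("ScenarioFit",
  representation(
    name = "character",
    estimate = "numeric",
    logLik = "numeric",
    aic = "numeric",
    weight = "numeric",
    ci = "matrix",
    details = "list"
  )
)

#' Hierarchical co-demographic prior
#'
#' Hyperprior for the co-demographic model over T taxa. The proportion of
#' synchronously contracting taxa, xi, lives on the discrete grid
#' \code{{z/T : z = 1..T}} with a uniform hyperprior. Each taxon follows a
#' growth-then-decline history: exponential growth from an ancestral size up
#' to a pre-decline size, then an instantaneous contraction to
#' \code{eps * preDeclineSize} at its pulse time (eps in (0,1] is the
#' bottleneck strength, post/pre size ratio). Synchronous taxa share one
#' pulse time; the rest draw independent times.
#'
#' @slot taxaCount integer T.
#' @slot neBounds uniform prior on current diploid Ne.
#' @slot epsBounds uniform prior on bottleneck strength eps (within (0,1]).
#' @slot timeBounds uniform prior on the shared pulse time (generations).
#' @slot asyncTimeBounds uniform prior on asynchronous-taxon pulse times.
#' @slot growthBounds uniform prior on the growth-phase magnitude
#'   (pre-decline size / ancestral size, >= 1).
#' @slot tAncient generations ago at which the history becomes the constant
#'   ancestral epoch (model horizon).
#'
#' @seealso [HyperPrior()], [drawCoDemography()], [simulateReferenceTable()]
#' @export
setClass("HyperPrior",
  representation(
    taxaCount = "integer",
    neBounds = "numeric",
    epsBounds = "numeric",
    timeBounds = "numeric",
    asyncTimeBounds = "numeric",
    growthBounds = "numeric",
    tAncient = "numeric"
  )
)

setValidity("HyperPrior", function(object) {
  msg <- character()
  if (object@taxaCount < 2L) msg <- c(msg, "taxaCount must be >= 2")
  chk <- function(b, nm, lo = -Inf, hi = Inf) {
    if (length(b) != 2L || anyNA(b) || any(!is.finite(b)) || b[2] <= b[1])
      return(sprintf("%s must be finite bounds (lo, hi) with hi > lo", nm))
    if (b[1] < lo || b[2] > hi)
      return(sprintf("%s must lie within [%g, %g]", nm, lo, hi))
    NULL
  }
  msg <- c(msg,
    chk(object@neBounds, "neBounds", 0),
    chk(object@epsBounds, "epsBounds", 0, 1),
    chk(object@timeBounds, "timeBounds", 0),
    chk(object@asyncTimeBounds, "asyncTimeBounds", 0),
    chk(object@growthBounds, "growthBounds", 1))
  if (object@tAncient <= max(object@timeBounds[2], object@asyncTimeBounds[2]))
    msg <- c(msg, "tAncient must exceed the latest possible pulse time")
  if (length(msg)) msg else TRUE
})

#' One draw from the co-demographic hierarchical model
#'
#' @slot xi proportion of taxa in the synchronous pulse (on the grid z/T).
#' @slot syncSet integer indices of the synchronously contracting taxa.
#' @slot sharedTime the shared pulse time (generations ago).
#' @slot taxa data.frame with one row per taxon: \code{ne}, \code{eps},
#'   \code{tPulse}, \code{growth}, \code{synchronous}.
#'
#' @export
setClass("CoDemDraw",
  representation(
    xi = "numeric",
    syncSet = "integer",
    sharedTime = "numeric",
    taxa = "data.frame"
  )
)

setValidity("CoDemDraw", function(object) {
  msg <- character()
  t_count <- nrow(object@taxa)
  if (length(object@syncSet) != round(object@xi * t_count))
    msg <- c(msg, "|syncSet| must equal round(xi * T)")
  ts <- object@taxa$tPulse[object@syncSet]
  if (length(ts) && any(ts != object@sharedTime))
    msg <- c(msg, "synchronous taxa must share the pulse time")
  if (length(msg)) msg else TRUE
})

#' hABC reference table
#'
#' Simulated draws from the co-demographic prior paired with their aggregate
#' SFS, the lookup table for rejection ABC.
#'
#' @slot params data.frame, one row per simulation: \code{xi},
#'   \code{sharedTime}, \code{meanNe}, \code{meanEps}, \code{dispEps}.
#' @slot asfs numeric matrix, one aggregate-SFS row per simulation.
#' @slot prior the generating \linkS4class{HyperPrior}.
#' @slot nHaploid haploid sample size of every per-taxon SFS.
#' @slot folded folding state of the per-taxon SFS.
#' @slot mutation the \linkS4class{MutationModel} used per taxon.
#' @slot seed integer seed the table was generated from (NA if none given).
#'
#' @seealso [simulateReferenceTable()], [abcReject()]
#' @export
setClass("ReferenceTable",
  representation(
    params = "data.frame",
    asfs = "matrix",
    prior = "HyperPrior",
    nHaploid = "integer",
    folded = "logical",
    mutation = "MutationModel",
    seed = "integer"
  )
)

setValidity("ReferenceTable", function(object) {
  if (nrow(object@params) != nrow(object@asfs))
    "params and asfs must have the same number of rows" else TRUE
})

#' Rejection-ABC result
#'
#' @slot acceptedIdx reference-table row indices of the k accepted draws, in
#'   non-decreasing distance order (ties broken by row index).
#' @slot distances the k accepted standardized Euclidean distances.
#' @slot posterior data.frame of accepted hyperparameter draws.
#' @slot xiCounts named integer, accepted count per xi grid value.
#' @slot xiGrid the xi grid of the prior.
#' @slot k number accepted.
#'
#' @seealso [abcReject()], [bayesFactorMatrix()], [estimateHyperposterior()]
#' @export
setClass("ABCResult",
  representation(
    acceptedIdx = "integer",
    distances = "numeric",
    posterior = "data.frame",
    xiCounts = "integer",
    xiGrid = "numeric",
    k = "integer"
  )
)

setValidity("ABCResult", function(object) {
  msg <- character()
  if (length(object@acceptedIdx) != object@k)
    msg <- c(msg, "accepted count must equal k")
  if (is.unsorted(object@distances))
    msg <- c(msg, "distances must be non-decreasing in acceptance order")
  if (length(msg)) msg else TRUE
})

#' Two-group comparison
#'
#' Result of a species-level comparison of per-population statistics:
#' pooled-variance t, Welch t, or Wilcoxon rank-sum. The t statistic is
#' reported as an absolute value.
#'
#' @slot method one of "pooled", "welch", "wilcoxon".
#' @slot statistic absolute test statistic (t, or Wilcoxon W).
#' @slot df degrees of freedom (NA for Wilcoxon).
#' @slot pValue two-sided p-value.
#' @slot variancePValue p-value of the F-test of equal variances that drove
#'   automatic method selection (NA when the method was forced).
#'
#' @seealso [compareGroups()]
#' @export
setClass("GroupComparison",
  representation(
    method = "character",
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    variancePValue = "numeric"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!object@method %in% c("pooled", "welch", "wilcoxon"))
    msg <- c(msg, "unknown method")
  if (!is.finite(object@statistic)) msg <- c(msg, "statistic must be finite")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
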