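#' Construct a demographic scenario
#'
#' @param name scenario name.
#' @param paramNames free parameter names.
#' @param lower,upper finite bounds (uniform priors / optimization box).
#' @param builder function mapping a named parameter vector to an
#'   \linkS4class{EpochSchedule}.
#' @param logScale logical per parameter; \code{TRUE} (the default for all)
#'   means the parameter is handled on the log scale during optimization and
#'   prior draws, appropriate for sizes, times and ratios.
#' @return A \linkS4class{Scenario}.
#' @export
Scenario <- function(name, paramNames, lower, upper, builder,
                     logScale = rep(TRUE, length(paramNames))) {
  new("Scenario", name = name, paramNames = paramNames,
    lower = as.numeric(lower), upper = as.numeric(upper),
    logScale = logScale, builder = builder)
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s' (%d parameter(s))\n", object@name,
    length(object@paramNames)))
  print(data.frame(param = object@paramNames, lower = object@lower,
    upper = object@upper))
  invisible(object)
})

#' The five default demographic scenarios
#'
#' Candidate single-population histories over the last \code{tAncient}
#' generations (default 30,000, i.e. the post-onset-of-last-glacial window at
#' one generation per year):
#' \describe{
#'   \item{constant}{one constant size, N in [1000, 100000].}
#'   \item{growth}{exponential growth to the present: current size
#'     \code{nCur}, ancestral/current ratio in [0.02, 0.5], change spread
#'     over the whole window.}
#'   \item{constantLow}{one constant, but small, size: N in [50, 1000].
#'     Distinguishable from \code{constant} only through the absolute
#'     mutational input (see [fitScenario()]).}
#'   \item{growthDecline}{exponential growth from an ancestral size to a
#'     peak at \code{tPeak}, then exponential decline to the present.}
#'   \item{decline}{exponential decline to the present beginning
#'     \code{tOnset} generations ago (constant ancestral size before):
#'     ancestral/current ratio in [2, 50].}
#' }
#' The set is a configurable default: any list of \linkS4class{Scenario}
#' objects can be fit in its place.
#'
#' @param tAncient time horizon in generations.
#' @return named list of \linkS4class{Scenario} objects.
#' @export
defaultScenarios <- function(tAncient = 30000) {
  list(
    constant = Scenario("constant", "ne", 1000, 1e5,
      function(par) EpochSchedule(0, par[["ne"]], 0)),
    growth = Scenario("growth", c("ne", "ratio"),
      c(1000, 0.02), c(1e5, 0.5),
      function(par) {
        g <- log(par[["ratio"]]) / tAncient
        EpochSchedule(c(0, tAncient),
          c(par[["ne"]], par[["ne"]] * par[["ratio"]]), c(g, 0))
      }),
    constantLow = Scenario("constantLow", "ne", 50, 1000,
      function(par) EpochSchedule(0, par[["ne"]], 0)),
    growthDecline = Scenario("growthDecline",
      c("ne", "peakRatio", "ancRatio", "tPeak"),
      c(100, 2, 0.02, 2000), c(20000, 50, 0.5, 15000),
      function(par) {
        nPeak <- par[["ne"]] * par[["peakRatio"]]
        growthDeclineSchedule(par[["ne"]], nPeak,
          nPeak * par[["ancRatio"]], par[["tPeak"]], tAncient)
      }),
    decline = Scenario("decline", c("ne", "ratio", "tOnset"),
      c(50, 2, 1000), c(20000, 50, 15000),
      function(par) {
        # decline begins tOnset generations ago; constant ancestral before
        g <- log(par[["ratio"]]) / par[["tOnset"]]
        EpochSchedule(c(0, par[["tOnset"]]),
          c(par[["ne"]], par[["ne"]] * par[["ratio"]]), c(g, 0))
      })
  )
}

#' Composite log-likelihood of an observed SFS
#'
#' Multinomial composite log-likelihood treating sites as independent:
#' \code{sum_i O_i * log(p_i)} with expected class proportions floored at
#' \code{floorProb} and renormalized. By default the sum runs over the
#' segregating classes only and \code{expected} holds their proportions.
#' With \code{monomorphic = TRUE}, \code{expected} additionally carries the
#' expected monomorphic proportion as its first element and the observed
#' class-0 count enters the sum; this ties the spectrum to the absolute
#' mutational input and is what identifies the population-size scale when
#' the mutation rate is fixed.
#'
#' @param observed an \linkS4class{SFS} with at least one segregating site.
#' @param expected numeric vector of expected proportions over the observed
#'   spectrum's segregating classes (plus, if \code{monomorphic}, a leading
#'   monomorphic proportion).
#' @param floorProb minimum probability per class before renormalization.
#' @param monomorphic include the monomorphic class in the likelihood?
#' @return the composite log-likelihood (natural log).
#' @examples
#' compositeLogLik(SFS(c(0, 5, 3, 2, 0)),
#'                 c(0.5, 0.3, 0.2))  # 5 log .5 + 3 log .3 + 2 log .2
#' @export
compositeLogLik <- function(observed, expected, floorProb = 1e-10,
                            monomorphic = FALSE) {
  stopifnot(is(observed, "SFS"))
  segIdx <- .segIdx(observed)
  obs <- observed@counts[segIdx]
  if (sum(obs) <= 0) stop("observed SFS has no segregating sites")
  nExp <- length(segIdx) + if (monomorphic) 1L else 0L
  if (length(expected) != nExp)
    stop(sprintf("expected proportions have length %d, need %d",
      length(expected), nExp))
  if (monomorphic) obs <- c(observed@counts[1L], obs)
  p <- pmax(expected, floorProb)
  p <- p / sum(p)
  sum(obs * log(p))
}

#' Akaike information criterion from a log-likelihood
#'
#' @param logLik maximized (composite) log-likelihood, natural log.
#' @param k number of free parameters.
#' @return \code{2 * k - 2 * logLik}.
#' @export
aicScore <- function(logLik, k) {
  if (k < 0) stop("k must be >= 0")
  2 * k - 2 * logLik
}

#' Akaike weights
#'
#' \code{w_i = exp(-(AIC_i - min AIC)/2)}, normalized to sum to 1: the
#' relative support for each candidate model.
#'
#' @param aics numeric vector of AIC values.
#' @return numeric vector of weights summing to 1.
#' @examples
#' akaikeWeights(c(100, 102))  # 0.7311, 0.2689
#' @export
akaikeWeights <- function(aics) {
  if (!length(aics)) stop("at least one AIC value required")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

# box transform: bounded (optionally log-scaled) parameter <-> unconstrained
.toUnconstrained <- function(par, sc) {
  lo <- ifelse(sc@logScale, log(sc@lower), sc@lower)
  hi <- ifelse(sc@logScale, log(sc@upper), sc@upper)
  x <- ifelse(sc@logScale, log(par), par)
  u <- (x - lo) / (hi - lo)
  u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
  qlogis(u)
}

.fromUnconstrained <- function(z, sc) {
  lo <- ifelse(sc@logScale, log(sc@lower), sc@lower)
  hi <- ifelse(sc@logScale, log(sc@upper), sc@upper)
  x <- lo + plogis(z) * (hi - lo)
  par <- ifelse(sc@logScale, exp(x), x)
  names(par) <- sc@paramNames
  par
}

# evaluate a function under a fixed RNG substream, restoring the caller's
# stream afterwards (common random numbers for a deterministic objective)
.withFixedSeed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

#' Fit a demographic scenario to an observed SFS
#'
#' Maximizes the composite log-likelihood over the scenario's parameter box
#' by Nelder-Mead simplex on transformed (log/logit) coordinates, with
#' \code{cycles} restarts from jittered incumbents. The expected spectrum at
#' each candidate parameter vector is computed exactly by default
#' (\code{expectedMethod = "exact"}, see [expectedBranchLengthsExact()]),
#' giving a deterministic, noise-free objective. The alternative
#' \code{"mc"} estimates it from \code{repsPerEval} genealogies using common
#' random numbers (the same RNG substream for every evaluation), which keeps
#' the objective deterministic for a given \code{seed} but leaves a
#' Monte-Carlo bias that can tip model comparisons at large SNP counts.
#'
#' With \code{monomorphic = TRUE} (default) the likelihood includes the
#' invariant class: expected per-site class probabilities are
#' \code{muSite * E[branch length of class i]} with the monomorphic
#' remainder, so the absolute size scale is identified by the fixed mutation
#' rate — the reason a constant-size model can be told apart from a smaller
#' constant-size model. With \code{monomorphic = FALSE} only the spectrum
#' shape is fit.
#'
#' @param observed an \linkS4class{SFS}; may be folded (expected proportions
#'   are folded to match). Class 0 must hold the invariant retained sites
#'   when \code{monomorphic = TRUE}.
#' @param scenario a \linkS4class{Scenario}.
#' @param mutation the \linkS4class{MutationModel} of the data (fixed, not
#'   estimated).
#' @param cycles simplex restarts.
#' @param repsPerEval genealogies per objective evaluation.
#' @param seed integer seed driving the common random numbers and restart
#'   jitter; \code{NULL} leaves the RNG state alone (the CRN substream is
#'   then drawn once from it).
#' @param monomorphic include the invariant class in the likelihood?
#' @param expectedMethod "exact" (closed-form/quadrature expectation) or
#'   "mc" (Monte Carlo with common random numbers).
#' @return A \linkS4class{ScenarioFit} (without confidence intervals; see
#'   [parametricBootstrap()]).
#' @export
fitScenario <- function(observed, scenario, mutation,
                        cycles = 3, repsPerEval = 300, seed = NULL,
                        monomorphic = TRUE,
                        expectedMethod = c("exact", "mc")) {
  stopifnot(is(observed, "SFS"), is(scenario, "Scenario"),
    is(mutation, "MutationModel"))
  expectedMethod <- match.arg(expectedMethod)
  if (cycles < 1 || repsPerEval < 1) stop("settings must be positive")
  if (!is.null(seed)) set.seed(seed)
  crnSeed <- sample.int(.Machine$integer.max, 1L)
  n <- observed@nHaploid
  folded <- observed@folded
  evals <- 0L

  expectedProbs <- function(par) {
    ep <- scenario@builder(par)
    len <- if (expectedMethod == "exact") {
      expectedBranchLengthsExact(n, ep, relTol = 1e-8)
    } else {
      .withFixedSeed(crnSeed, function()
        .cppMeanLengths(n, .epochMatrix(ep), as.integer(repsPerEval)))
    }
    pSite <- mutation@muSite * len  # per-site expected count: mu * E[L_i]
    if (folded) {
      half <- floor(n / 2)
      pf <- numeric(half)
      for (i in seq_len(n - 1L)) {
        j <- min(i, n - i)
        pf[j] <- pf[j] + pSite[i]
      }
      pSite <- pf
    }
    if (monomorphic) c(max(1 - sum(pSite), 0), pSite) else pSite / sum(pSite)
  }
  objective <- function(z) {
    par <- .fromUnconstrained(z, scenario)
    evals <<- evals + 1L
    -compositeLogLik(observed, expectedProbs(par), monomorphic = monomorphic)
  }

  nPar <- length(scenario@paramNames)
  z0 <- rep(0, nPar)  # box midpoint in transformed coordinates
  best <- NULL
  for (cy in seq_len(cycles)) {
    zs <- if (cy == 1L) z0 else best$par + rnorm(nPar, sd = 0.5)
    o <- if (nPar == 1L) {
      optim(zs, objective, method = "Brent", lower = -16, upper = 16,
        control = list(reltol = 1e-10))
    } else {
      optim(zs, objective, method = "Nelder-Mead",
        control = list(maxit = 400, reltol = 1e-8))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  est <- .fromUnconstrained(best$par, scenario)
  ll <- -best$value
  k <- length(scenario@paramNames)
  new("ScenarioFit", name = scenario@name, estimate = est,
    logLik = ll, aic = aicScore(ll, k), weight = NA_real_,
    ci = matrix(numeric(0), nrow = 0, ncol = 2,
      dimnames = list(NULL, c("2.5%", "97.5%"))),
    details = list(evaluations = evals, cycles = cycles,
      repsPerEval = repsPerEval, crnSeed = crnSeed,
      convergence = best$convergence, monomorphic = monomorphic,
      expectedMethod = expectedMethod, nHaploid = n, folded = folded))
}

setMethod("show", "ScenarioFit", function(object) {
  cat(sprintf("ScenarioFit '%s': logLik = %.3f, AIC = %.3f%s\n",
    object@name, object@logLik, object@aic,
    if (is.na(object@weight)) "" else sprintf(", weight = %.3f",
      object@weight)))
  print(object@estimate)
  if (nrow(object@ci)) print(object@ci)
  invisible(object)
})

#' Fit and rank several scenarios on one observed SFS
#'
#' Fits each scenario with [fitScenario()] (same settings and seed policy),
#' then fills Akaike weights across the compared set.
#'
#' @inheritParams fitScenario
#' @param scenarios list of \linkS4class{Scenario} objects.
#' @return named list of \linkS4class{ScenarioFit}s with \code{weight} set;
#'   the attribute \code{"selected"} names the minimum-AIC scenario.
#' @export
compareScenarios <- function(observed, scenarios, mutation,
                             cycles = 3, repsPerEval = 300, seed = NULL,
                             monomorphic = TRUE,
                             expectedMethod = c("exact", "mc")) {
  expectedMethod <- match.arg(expectedMethod)
  if (!is.null(seed)) set.seed(seed)
  # one seed for every scenario: under "mc" this gives common random numbers
  # across models, so Monte-Carlo error largely cancels out of the AIC
  # comparison; under "exact" it only fixes the restart jitter
  sharedSeed <- sample.int(.Machine$integer.max, 1L)
  fits <- lapply(scenarios, function(sc) fitScenario(observed, sc, mutation,
    cycles = cycles, repsPerEval = repsPerEval, seed = sharedSeed,
    monomorphic = monomorphic, expectedMethod = expectedMethod))
  w <- akaikeWeights(vapply(fits, slot, numeric(1), "aic"))
  fits <- Map(function(f, wi) { f@weight <- wi; f }, fits, w)
  names(fits) <- vapply(fits, slot, character(1), "name")
  attr(fits, "selected") <- names(fits)[which.min(
    vapply(fits, slot, numeric(1), "aic"))]
  fits
}

#' Parametric-bootstrap confidence intervals for a fitted scenario
#'
#' Simulates \code{B} spectra at the maximum-likelihood estimate, refits the
#' scenario on each, and reports per-parameter percentile intervals (2.5%
#' and 97.5%, linear interpolation between order statistics). Replicates
#' whose refit fails are dropped and counted.
#'
#' @param fit a \linkS4class{ScenarioFit}.
#' @param scenario the \linkS4class{Scenario} that produced it.
#' @param mutation the data's \linkS4class{MutationModel}.
#' @param B bootstrap replicates (>= 2).
#' @param folded fold each simulated spectrum before refitting?
#' @param seed integer seed.
#' @param ... further arguments passed to [fitScenario()] for the refits.
#' @return the fit with its \code{ci} slot filled; \code{details$bootstrap}
#'   records replicate estimates and the dropped count.
#' @export
parametricBootstrap <- function(fit, scenario, mutation, B = 100,
                                folded = TRUE, seed = NULL, ...) {
  stopifnot(is(fit, "ScenarioFit"), is(scenario, "Scenario"))
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ep <- scenario@builder(fit@estimate)
  n0 <- fit@details$nHaploid %||% 8L
  reps <- matrix(NA_real_, nrow = B, ncol = length(scenario@paramNames),
    dimnames = list(NULL, scenario@paramNames))
  dropped <- 0L
  for (b in seq_len(B)) {
    sim <- simulateSFS(n0, ep, mutation)
    if (folded) sim <- fold(sim)
    est <- tryCatch({
      rf <- fitScenario(sim, scenario, mutation,
        seed = sample.int(.Machine$integer.max, 1L), ...)
      rf@estimate
    }, error = function(e) NULL)
    if (is.null(est)) dropped <- dropped + 1L else reps[b, ] <- est
  }
  ok <- stats::complete.cases(reps)
  if (!any(ok)) stop("all bootstrap refits failed")
  fit@ci <- .percentileCI(reps[ok, , drop = FALSE])
  fit@details$bootstrap <- list(estimates = reps[ok, , drop = FALSE],
    dropped = dropped)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2.5% / 97.5% percentile intervals per column, linear interpolation
# between order statistics (quantile type 7)
.percentileCI <- function(estimates) {
  ci <- t(apply(estimates, 2L, quantile, probs = c(0.025, 0.975),
    type = 7, names = FALSE))
  colnames(ci) <- c("2.5%", "97.5%")
  ci
}
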