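#' Construct a piecewise-exponential demographic history
#'
#' @param tStart numeric, epoch start times in generations before present,
#'   strictly increasing, first must be 0.
#' @param NStart numeric, diploid effective size at each epoch start.
#' @param growthRate numeric, backward exponential rate g per epoch:
#'   \code{N(t) = NStart * exp(g * (t - tStart))} within the epoch. The
#'   terminal epoch must have \code{g <= 0}.
#' @return An \linkS4class{EpochSchedule}.
#' @examples
#' EpochSchedule(0, 10000, 0)  # constant size
#' @export
EpochSchedule <- function(tStart, NStart, growthRate = rep(0, length(tStart))) {
  new("EpochSchedule", tStart = as.numeric(tStart),
    NStart = as.numeric(NStart), growthRate = as.numeric(growthRate))
}

#' EpochSchedule accessors
#'
#' @param x an \linkS4class{EpochSchedule}.
#' @param t time in generations before present.
#' @return \code{nEpochs}: number of epochs; \code{popSizeAt}: diploid
#'   effective size N(t).
#' @name epoch-accessors
NULL

#' @rdname epoch-accessors
#' @export
setMethod("nEpochs", "EpochSchedule", function(x) length(x@tStart))

#' @rdname epoch-accessors
#' @export
setMethod("popSizeAt", "EpochSchedule", function(x, t) {
  vapply(t, function(ti) {
    e <- findInterval(ti, x@tStart)
    e <- max(e, 1L)
    x@NStart[e] * exp(x@growthRate[e] * (ti - x@tStart[e]))
  }, numeric(1))
})

setMethod("show", "EpochSchedule", function(object) {
  cat(sprintf("EpochSchedule: %d epoch(s), backwards in generations\n",
    nEpochs(object)))
  print(data.frame(tStart = object@tStart, NStart = object@NStart,
    growthRate = object@growthRate))
  invisible(object)
})

# epoch matrix handed to the C++ kernel
.epochMatrix <- function(epochs) {
  cbind(epochs@tStart, epochs@NStart, epochs@growthRate)
}

#' Growth-then-decline history from forward-time language
#'
#' Builds the canonical comparative-demography history: in forward time the
#' population grows exponentially from an ancestral size to a peak, then
#' declines exponentially to its current size. Translated to backward time
#' this is: current size growing back to the peak at \code{tPeak}, then
#' shrinking back to the ancestral size at \code{tAncient}, constant before
#' that.
#'
#' @param nCur current diploid size.
#' @param nPeak peak diploid size at \code{tPeak} generations ago.
#' @param nAnc ancestral diploid size (constant before \code{tAncient}).
#' @param tPeak generations ago at which the decline began (forward-time
#'   peak).
#' @param tAncient generations ago at which the growth phase began.
#' @return An \linkS4class{EpochSchedule} with three epochs.
#' @export
growthDeclineSchedule <- function(nCur, nPeak, nAnc, tPeak,
                                  tAncient = 30000) {
  stopifnot(tPeak > 0, tAncient > tPeak)
  g1 <- log(nPeak / nCur) / tPeak
  g2 <- log(nAnc / nPeak) / (tAncient - tPeak)
  EpochSchedule(
    tStart = c(0, tPeak, tAncient),
    NStart = c(nCur, nPeak, nAnc),
    growthRate = c(g1, g2, 0))
}

#' Bottleneck-atop-growth history for the co-demographic model
#'
#' Per-taxon history of the hierarchical co-demographic model: constant at
#' the current size until the pulse time, where the size jumps
#' instantaneously by 1/eps (the forward-time contraction of strength eps =
#' post/pre size ratio); behind the pulse, the pre-decline size decays
#' exponentially back to the ancestral size \code{preDecline / growth} at
#' \code{tAncient} (the forward-time growth phase), constant before that.
#'
#' @param ne current diploid size.
#' @param eps bottleneck strength in (0, 1].
#' @param tPulse pulse (contraction) time, generations ago.
#' @param growth growth-phase magnitude, pre-decline size over ancestral
#'   size, >= 1.
#' @param tAncient model horizon in generations.
#' @return An \linkS4class{EpochSchedule}.
#' @export
bottleneckSchedule <- function(ne, eps, tPulse, growth, tAncient = 30000) {
  stopifnot(eps > 0, eps <= 1, tPulse > 0, tAncient > tPulse, growth >= 1)
  nPre <- ne / eps
  g2 <- -log(growth) / (tAncient - tPulse)
  EpochSchedule(
    tStart = c(0, tPulse, tAncient),
    NStart = c(ne, nPre, nPre / growth),
    growthRate = c(0, g2, 0))
}

#' Construct a mutation model
#'
#' @param muSite mutations per site per generation.
#' @param locusLength locus length in base pairs.
#' @param numLoci number of unlinked loci.
#' @return A \linkS4class{MutationModel}.
#' @export
MutationModel <- function(muSite = 1e-8, locusLength = 100, numLoci = 5000) {
  new("MutationModel", muSite = as.numeric(muSite),
    locusLength = as.numeric(locusLength), numLoci = as.integer(numLoci))
}

setMethod("show", "MutationModel", function(object) {
  cat(sprintf(
    "MutationModel: mu = %g /site/generation, %d loci x %g bp\n",
    object@muSite, object@numLoci, object@locusLength))
  invisible(object)
})

#' Time of the next coalescence under piecewise-exponential demography
#'
#' Draws the waiting time until the next coalescence for k lineages starting
#' at \code{tNow}, by inverting the integrated coalescent intensity
#' \code{choose(k,2) * integral dt / (2 N(t))} against a unit-exponential
#' deviate, in closed form within each exponential epoch with carry-over at
#' epoch boundaries.
#'
#' @param k number of extant lineages (>= 2).
#' @param tNow current time, generations before present.
#' @param epochs an \linkS4class{EpochSchedule}.
#' @return the coalescence time (> tNow), in generations.
#' @examples
#' set.seed(1)
#' mean(replicate(500, coalescenceTime(2, 0, EpochSchedule(0, 100, 0))))
#' # close to 2N = 200
#' @export
coalescenceTime <- function(k, tNow, epochs) {
  stopifnot(is(epochs, "EpochSchedule"))
  if (k < 2) stop("k must be >= 2")
  .cppCoalTime(as.integer(k), as.numeric(tNow), .epochMatrix(epochs))
}

#' Simulate one genealogy and return per-class branch lengths
#'
#' Runs the single-population Kingman coalescent for n tips under the given
#' demography and returns, for each class i = 1..n-1, the total branch
#' length subtending exactly i tips (generations). Their sum is the total
#' tree length; under the infinite-sites model a mutation on a class-i
#' branch produces a site at derived frequency i/n.
#'
#' @param n haploid sample size (>= 2).
#' @param epochs an \linkS4class{EpochSchedule}.
#' @return numeric vector of length n - 1, named by class.
#' @export
simulateGenealogy <- function(n, epochs) {
  stopifnot(is(epochs, "EpochSchedule"))
  out <- .cppGenealogyLengths(as.integer(n), .epochMatrix(epochs))
  names(out) <- as.character(seq_len(n - 1L))
  out
}

#' Simulate an unfolded SFS over unlinked loci
#'
#' One genealogy per locus; per-locus mutation count is Poisson with mean
#' \code{muSite * locusLength * total tree length}, and each mutation falls
#' on frequency class i with probability proportional to the class-i branch
#' length (infinite sites). Class 0 receives the invariant remainder
#' \code{numLoci * locusLength - S}, so the spectrum accounts for every
#' simulated site; class n stays 0 (no mutation above the root).
#'
#' @param n haploid sample size.
#' @param epochs an \linkS4class{EpochSchedule}.
#' @param mutation a \linkS4class{MutationModel}.
#' @return An unfolded, polarized \linkS4class{SFS}.
#' @examples
#' set.seed(42)
#' simulateSFS(8, EpochSchedule(0, 5000, 0), MutationModel(numLoci = 500))
#' @export
simulateSFS <- function(n, epochs, mutation) {
  stopifnot(is(epochs, "EpochSchedule"), is(mutation, "MutationModel"))
  seg <- .cppSimulateSfs(as.integer(n), .epochMatrix(epochs),
    mutation@numLoci, mutation@muSite * mutation@locusLength)
  total <- mutation@numLoci * mutation@locusLength
  counts <- c(max(total - sum(seg), 0), seg, 0)
  SFS(counts, folded = FALSE, polarized = TRUE)
}

#' Monte-Carlo expected SFS under a demography
#'
#' Mean per-class branch-length proportions over \code{reps} simulated
#' genealogies: the expected shape of the unfolded SFS over segregating
#' classes (normalized to sum to 1). Deterministic for a fixed RNG state.
#'
#' @param n haploid sample size.
#' @param epochs an \linkS4class{EpochSchedule}.
#' @param reps number of genealogies to average over.
#' @return numeric vector of expected proportions for classes 1..n-1.
#' @seealso [expectedBranchLengths()] for the unnormalized version used by
#'   absolute-rate likelihoods.
#' @export
expectedSFS <- function(n, epochs, reps = 1000) {
  len <- expectedBranchLengths(n, epochs, reps)
  len / sum(len)
}

#' Monte-Carlo expected per-class branch lengths
#'
#' Mean branch length (generations) subtending exactly i tips, i = 1..n-1,
#' over \code{reps} genealogies. Multiplying by the per-site mutation rate
#' gives the expected per-site count of sites at each derived frequency;
#' this absolute scale is what identifies Ne in full-spectrum likelihoods.
#'
#' @inheritParams expectedSFS
#' @return numeric vector of length n - 1, named by class.
#' @export
expectedBranchLengths <- function(n, epochs, reps = 1000) {
  stopifnot(is(epochs, "EpochSchedule"))
  if (reps < 1) stop("reps must be >= 1")
  out <- .cppMeanLengths(as.integer(n), .epochMatrix(epochs),
    as.integer(reps))
  names(out) <- as.character(seq_len(n - 1L))
  out
}

# signed coefficient matrix of Tavare's ancestral lineage-count
# distribution: P(A(tau) = k | A(0) = n) = sum_j C[k, j] * exp(-j(j-1)/2 tau)
.lineageCountCoefs <- function(n) {
  C <- matrix(0, n, n)
  for (k in seq_len(n)) {
    for (j in seq.int(k, n)) {
      # (2j-1) * k_(j-1) * n_[j] / (k! * (j-k)! * n_(j)), rising/falling
      lc <- log(2 * j - 1) +
        (lgamma(k + j - 1) - lgamma(k)) +          # k rising (j-1)
        (lgamma(n + 1) - lgamma(n - j + 1)) -      # n falling j
        (lgamma(k + 1) + lgamma(j - k + 1)) -
        (lgamma(n + j) - lgamma(n))                # n rising j
      C[k, j] <- (-1)^(j - k) * exp(lc)
    }
  }
  C
}

# P(A(tau) = k | A(0) = n); tau may be a vector
.lineageCountProb <- function(n, k, tau) {
  C <- .lineageCountCoefs(n)
  rates <- seq_len(n) * (seq_len(n) - 1) / 2
  as.numeric(C[k, , drop = FALSE] %*% exp(outer(-rates, tau)))
}

# 12-point Gauss-Legendre nodes/weights on [-1, 1]
.gl12 <- local({
  m <- 12L
  i <- seq_len(m - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
})

#' Exact expected per-class branch lengths
#'
#' Deterministic counterpart of [expectedBranchLengths()]: under any
#' piecewise-exponential history the coalescent is a deterministic time
#' change of the standard Kingman process, so the expected time spent with k
#' ancestral lineages is an integral of Tavare's lineage-count distribution
#' against the (closed-form) inverse time change, evaluated here by adaptive
#' quadrature per epoch. Class lengths follow from the classical uniform-
#' partition probability that one of k lineages subtends exactly i of n
#' tips. Exact up to quadrature tolerance and free of Monte-Carlo noise —
#' the default objective inside [fitScenario()].
#'
#' @inheritParams expectedSFS
#' @param relTol retained for interface stability; the composite
#'   Gauss-Legendre rule used is accurate well beyond 1e-8 relative error.
#' @return numeric vector of length n - 1, named by class: expected branch
#'   length (generations) subtending exactly i tips.
#' @export
expectedBranchLengthsExact <- function(n, epochs, relTol = 1e-9) {
  stopifnot(is(epochs, "EpochSchedule"))
  .expectedLengthsCore(as.integer(n), epochs@tStart, epochs@NStart,
    epochs@growthRate)
}

# workhorse behind expectedBranchLengthsExact, on plain epoch vectors
.expectedLengthsCore <- function(n, ts, Ns, gs) {
  if (n < 2L) stop("n must be >= 2")
  ne <- length(ts)
  # cumulative coalescent-scale time at epoch starts:
  # tau(t) - tau(t0) = (1 - exp(-g dt)) / (2 N0 g)
  tauStart <- numeric(ne)
  for (e in seq_len(ne - 1L)) {
    dt <- ts[e + 1L] - ts[e]
    dTau <- if (gs[e] == 0) dt / (2 * Ns[e]) else
      (1 - exp(-gs[e] * dt)) / (2 * Ns[e] * gs[e])
    tauStart[e + 1L] <- tauStart[e] + dTau
  }
  tauAt <- function(t, e) {
    d <- t - ts[e]
    tauStart[e] + if (gs[e] == 0) d / (2 * Ns[e]) else
      (1 - exp(-gs[e] * d)) / (2 * Ns[e] * gs[e])
  }
  # natural time at coalescent-scale tau within epoch e (inverse of tauAt)
  tAt <- function(tau, e) {
    dTau <- tau - tauStart[e]
    ts[e] + if (gs[e] == 0) dTau * 2 * Ns[e] else
      -log(1 - 2 * Ns[e] * gs[e] * dTau) / gs[e]
  }
  # E[T_k] = integral over natural time of P(A(t) = k). Beyond tau = 40
  # every P(A >= 2) is below exp(-40), so the time axis is partitioned at
  # the epoch boundaries and at a geometric grid of tau values up to 40,
  # giving segments on which the integrand is smooth and slowly varying;
  # 12-point Gauss-Legendre per segment then integrates all k at once.
  tauCut <- 40
  tauBreaks <- sort(unique(pmin(c(0, 10^seq(-4, log10(tauCut),
    length.out = 48L), tauStart), tauCut)))
  tBreaks <- vapply(tauBreaks, function(tv) {
    e <- max(1L, findInterval(tv, tauStart, rightmost.closed = FALSE))
    # guard: place tau exactly at an epoch start in that epoch
    while (e > 1L && tauStart[e] > tv) e <- e - 1L
    tAt(tv, e)
  }, numeric(1))
  tBreaks <- sort(unique(tBreaks))
  C <- .lineageCountCoefs(n)[-1L, , drop = FALSE]  # rows k = 2..n
  rates <- seq_len(n) * (seq_len(n) - 1) / 2
  a <- tBreaks[-length(tBreaks)]
  b <- tBreaks[-1L]
  ok <- b > a
  a <- a[ok]; b <- b[ok]
  mids <- (a + b) / 2
  eIdx <- pmax(1L, findInterval(mids, ts))
  # all quadrature nodes and weights at once: segments x 12 nodes
  tn <- rep(mids, each = 12L) + rep((b - a) / 2, each = 12L) * .gl12$x
  wn <- rep((b - a) / 2, each = 12L) * .gl12$w
  eAll <- rep(eIdx, each = 12L)
  d <- tn - ts[eAll]
  gAll <- gs[eAll]; NAll <- Ns[eAll]
  taus <- tauStart[eAll] + ifelse(gAll == 0, d / (2 * NAll),
    (1 - exp(-gAll * d)) / (2 * NAll * gAll))
  P <- C %*% exp(outer(-rates, taus))       # (n-1) x nodes
  expT <- as.numeric(P %*% wn)
  ks <- 2:n
  out <- vapply(seq_len(n - 1L), function(i) {
    # P(a given one of k lineages subtends i of n tips)
    p <- exp(lchoose(n - i - 1, ks - 2) - lchoose(n - 1, ks - 1))
    sum(ks * expT * p)
  }, numeric(1))
  names(out) <- as.character(seq_len(n - 1L))
  out
}
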