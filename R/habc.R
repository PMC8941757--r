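#' Construct the co-demographic hyperprior
#'
#' Defaults express the hypothesis the hierarchical model is built to test —
#' a pronounced post-glacial contraction whose timing is the unknown of
#' interest — with moderate cross-taxon heterogeneity in the nuisance
#' parameters, in the spirit of informing the co-demographic stage from the
#' preceding per-population scenario fits. Synchrony detection from an
#' aggregate SFS of few taxa degrades quickly as the nuisance priors widen
#' or the bottleneck prior admits near-flat histories (the pulse then
#' leaves no imprint to correlate taxa), so override these bounds
#' deliberately.
#'
#' @param taxaCount number of co-analysed taxa T.
#' @param neBounds current diploid Ne bounds.
#' @param epsBounds bottleneck-strength bounds within (0, 1].
#' @param timeBounds shared pulse-time bounds (generations).
#' @param asyncTimeBounds pulse-time bounds for asynchronous taxa.
#' @param growthBounds growth-phase magnitude bounds (>= 1).
#' @param tAncient model horizon (generations).
#' @return A \linkS4class{HyperPrior}.
#' @export
HyperPrior <- function(taxaCount = 6L,
                       neBounds = c(4000, 12000),
                       epsBounds = c(0.02, 0.08),
                       timeBounds = c(500, 10000),
                       asyncTimeBounds = timeBounds,
                       growthBounds = c(1, 3),
                       tAncient = 30000) {
  new("HyperPrior", taxaCount = as.integer(taxaCount),
    neBounds = as.numeric(neBounds), epsBounds = as.numeric(epsBounds),
    timeBounds = as.numeric(timeBounds),
    asyncTimeBounds = as.numeric(asyncTimeBounds),
    growthBounds = as.numeric(growthBounds),
    tAncient = as.numeric(tAncient))
}

#' The discrete grid of the synchrony hyperparameter
#'
#' xi, the proportion of taxa contracting synchronously, lives on
#' \code{{z/T : z = 1..T}}: at least one taxon always carries the shared
#' pulse, and xi = 1/T is the fully asynchronous model.
#'
#' @param x a \linkS4class{HyperPrior}.
#' @return numeric vector of admissible xi values.
#' @examples
#' xiGrid(HyperPrior(taxaCount = 6))  # 0.167 ... 1
#' @rdname xiGrid
#' @export
setMethod("xiGrid", "HyperPrior", function(x) {
  seq_len(x@taxaCount) / x@taxaCount
})

setMethod("show", "HyperPrior", function(object) {
  cat(sprintf("HyperPrior over %d taxa, horizon %g generations\n",
    object@taxaCount, object@tAncient))
  cat(sprintf("  Ne ~ U(%g, %g); eps ~ U(%g, %g); pulse ~ U(%g, %g)\n",
    object@neBounds[1], object@neBounds[2], object@epsBounds[1],
    object@epsBounds[2], object@timeBounds[1], object@timeBounds[2]))
  invisible(object)
})

.runif2 <- function(n, b) runif(n, b[1], b[2])

#' Draw one co-demography from the hierarchical prior
#'
#' Samples xi uniformly on its grid (unless fixed), picks the synchronous
#' subset uniformly without replacement, draws one shared pulse time, and
#' gives every taxon independent Ne, bottleneck strength and growth
#' magnitude; asynchronous taxa get independent pulse times.
#'
#' @param prior a \linkS4class{HyperPrior}.
#' @param fixedXi optional xi value; must lie on the grid.
#' @return A \linkS4class{CoDemDraw}.
#' @export
drawCoDemography <- function(prior, fixedXi = NULL) {
  stopifnot(is(prior, "HyperPrior"))
  d <- .drawCoDemographyRaw(prior, fixedXi)
  taxa <- data.frame(ne = d$ne, eps = d$eps, tPulse = d$tPulse,
    growth = d$growth,
    synchronous = seq_len(prior@taxaCount) %in% d$syncSet)
  new("CoDemDraw", xi = d$xi, syncSet = d$syncSet,
    sharedTime = d$sharedTime, taxa = taxa)
}

# the sampling logic behind drawCoDemography, on plain vectors (also the
# fast path for reference-table simulation)
.drawCoDemographyRaw <- function(prior, fixedXi = NULL) {
  grid <- xiGrid(prior)
  t_count <- prior@taxaCount
  if (is.null(fixedXi)) {
    xi <- grid[sample.int(length(grid), 1L)]
  } else {
    hit <- which(abs(grid - fixedXi) < 1e-9)
    if (!length(hit)) stop(sprintf("fixedXi must lie on the grid {z/%d}",
      t_count))
    xi <- grid[hit]
  }
  nSync <- as.integer(round(xi * t_count))
  syncSet <- sort(sample.int(t_count, nSync))
  sharedTime <- .runif2(1L, prior@timeBounds)
  tPulse <- .runif2(t_count, prior@asyncTimeBounds)
  tPulse[syncSet] <- sharedTime
  list(xi = xi, syncSet = syncSet, sharedTime = sharedTime,
    ne = .runif2(t_count, prior@neBounds),
    eps = .runif2(t_count, prior@epsBounds),
    tPulse = tPulse,
    growth = .runif2(t_count, prior@growthBounds))
}

# epoch matrix of the bottleneck-atop-growth taxon history (fast path;
# mirrors bottleneckSchedule)
.bottleneckEpochMatrix <- function(ne, eps, tPulse, growth, tAncient) {
  nPre <- ne / eps
  cbind(c(0, tPulse, tAncient),
    c(ne, nPre, nPre / growth),
    c(0, -log(growth) / (tAncient - tPulse), 0))
}

# aggregate-SFS value vector from a taxa x segregating-classes count matrix
# (fast path; mirrors buildASFS with allowZero = TRUE)
.asfsFromCounts <- function(counts) {
  tot <- rowSums(counts)
  props <- counts / ifelse(tot > 0, tot, 1)
  as.numeric(apply(props, 2L, sort, decreasing = TRUE))
}

# folded segregating-class counts (classes 1..floor(n/2)) from unfolded
# segregating counts (classes 1..n-1)
.foldSegCounts <- function(seg) {
  n <- length(seg) + 1L
  half <- floor(n / 2)
  out <- numeric(half)
  for (i in seq_along(seg)) {
    j <- min(i, n - i)
    out[j] <- out[j] + seg[i]
  }
  out
}

setMethod("show", "CoDemDraw", function(object) {
  cat(sprintf("CoDemDraw: xi = %.3f, shared pulse %.0f generations ago\n",
    object@xi, object@sharedTime))
  print(object@taxa)
  invisible(object)
})

# hyper-summaries of one draw across its taxa
.drawSummary <- function(draw) {
  data.frame(
    xi = draw@xi,
    sharedTime = draw@sharedTime,
    meanNe = mean(draw@taxa$ne),
    meanEps = mean(draw@taxa$eps),
    dispEps = dispersionIndex(draw@taxa$eps))
}

# simulate the aggregate SFS of one draw
.simulateDrawASFS <- function(draw, prior, nHaploid, mutation,
                              folded = TRUE) {
  spectra <- lapply(seq_len(nrow(draw@taxa)), function(i) {
    p <- draw@taxa[i, ]
    ep <- bottleneckSchedule(p$ne, p$eps, p$tPulse, p$growth,
      tAncient = prior@tAncient)
    s <- simulateSFS(nHaploid, ep, mutation)
    if (folded) fold(s) else s
  })
  buildASFS(spectra, allowZero = TRUE)
}

#' Simulate an hABC reference table
#'
#' Draws \code{nSims} co-demographies from the prior, simulates one SFS per
#' taxon under its bottleneck-atop-growth history, folds (by default),
#' builds each draw's aggregate SFS, and stores hyperparameter summaries
#' next to the aSFS rows. Deterministic given \code{seed}; generation is
#' chunked so large tables can be built in seeded pieces and row-bound with
#' [bindReferenceTables()].
#'
#' Two simulation methods are available. \code{"expected"} (default)
#' exploits the sparse-unlinked-SNP regime of ddRAD data (far fewer than
#' one SNP per locus, loci independent): the total SNP number is Poisson
#' with mean \code{mu * totalSites * E[tree length]} and, conditional on
#' it, class counts are multinomial on the exact normalized expected branch
#' lengths ([expectedBranchLengthsExact()]) — the exact aggregate law of
#' Poisson mutations on thousands of independent genealogies, at a cost
#' independent of the locus count. \code{"locus"} simulates every locus
#' genealogy explicitly ([simulateSFS()]); the two agree in distribution in
#' the sparse regime (tested), but "locus" scales with the locus count.
#'
#' @param prior a \linkS4class{HyperPrior}.
#' @param nSims number of simulations.
#' @param nHaploid per-taxon haploid sample size (after any projection).
#' @param mutation per-taxon \linkS4class{MutationModel}.
#' @param seed integer seed (NA recorded if NULL).
#' @param fixedXi optional fixed xi for estimation-stage tables.
#' @param folded fold each per-taxon SFS?
#' @param method \code{"expected"} or \code{"locus"} (see Details).
#' @return A \linkS4class{ReferenceTable}.
#' @export
simulateReferenceTable <- function(prior, nSims, nHaploid = 8L,
                                   mutation = MutationModel(numLoci = 5000,
                                     locusLength = 300),
                                   seed = NULL, fixedXi = NULL,
                                   folded = TRUE,
                                   method = c("expected", "locus")) {
  stopifnot(is(prior, "HyperPrior"))
  method <- match.arg(method)
  if (nSims < 1) stop("nSims must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  t_count <- prior@taxaCount
  nClasses <- if (folded) floor(nHaploid / 2) else nHaploid - 1L
  asfs <- matrix(NA_real_, nrow = nSims, ncol = t_count * nClasses)
  params <- matrix(NA_real_, nrow = nSims, ncol = 5L,
    dimnames = list(NULL, c("xi", "sharedTime", "meanNe", "meanEps",
      "dispEps")))
  theta <- mutation@muSite * mutation@locusLength
  muTotal <- mutation@muSite * mutation@locusLength * mutation@numLoci
  nH <- as.integer(nHaploid)
  for (i in seq_len(nSims)) {
    d <- .drawCoDemographyRaw(prior, fixedXi = fixedXi)
    cnt <- matrix(0, t_count, nClasses)
    for (tx in seq_len(t_count)) {
      ep <- .bottleneckEpochMatrix(d$ne[tx], d$eps[tx], d$tPulse[tx],
        d$growth[tx], prior@tAncient)
      seg <- if (method == "expected") {
        lens <- .expectedLengthsCore(nH, ep[, 1L], ep[, 2L], ep[, 3L])
        S <- rpois(1L, muTotal * sum(lens))
        if (S > 0) as.numeric(rmultinom(1L, S, lens / sum(lens)))
        else numeric(nH - 1L)
      } else {
        .cppSimulateSfs(nH, ep, mutation@numLoci, theta)
      }
      cnt[tx, ] <- if (folded) .foldSegCounts(seg) else seg
    }
    asfs[i, ] <- .asfsFromCounts(cnt)
    params[i, ] <- c(d$xi, d$sharedTime, mean(d$ne), mean(d$eps),
      dispersionIndex(d$eps))
  }
  new("ReferenceTable", params = as.data.frame(params), asfs = asfs,
    prior = prior, nHaploid = as.integer(nHaploid), folded = folded,
    mutation = mutation, seed = if (is.null(seed)) NA_integer_
    else as.integer(seed))
}

#' Combine reference-table chunks
#'
#' @param ... \linkS4class{ReferenceTable} objects built under the same
#'   prior, sample size and mutation model (e.g. seeded chunks).
#' @return the row-bound \linkS4class{ReferenceTable}; its seed is the first
#'   chunk's.
#' @export
bindReferenceTables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, is, logical(1),
    "ReferenceTable")))
  first <- tabs[[1L]]
  new("ReferenceTable",
    params = do.call(rbind, lapply(tabs, slot, "params")),
    asfs = do.call(rbind, lapply(tabs, slot, "asfs")),
    prior = first@prior, nHaploid = first@nHaploid, folded = first@folded,
    mutation = first@mutation, seed = first@seed)
}

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf(
    "ReferenceTable: %d simulations, %d taxa, n = %d (%s), %d bins\n",
    nrow(object@params), object@prior@taxaCount, object@nHaploid,
    if (object@folded) "folded" else "unfolded", ncol(object@asfs)))
  invisible(object)
})

# standardized bins: divide by reference-table SD, dropping zero-variance
# bins; returns list(obs, table, keep)
.standardizeBins <- function(obs, tabM) {
  sds <- apply(tabM, 2L, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) stop("all reference-table bins have zero variance")
  list(obs = obs[keep] / sds[keep],
    table = sweep(tabM[, keep, drop = FALSE], 2L, sds[keep], "/"),
    keep = keep)
}

#' Rejection ABC on the aggregate SFS
#'
#' Euclidean distance between the observed and each simulated aggregate SFS
#' after standardizing every bin by its reference-table standard deviation
#' (zero-variance bins dropped); the k smallest-distance draws are retained,
#' ties broken by row index.
#'
#' @param observed an \linkS4class{AggregateSFS} or a numeric bin vector.
#' @param table a \linkS4class{ReferenceTable}.
#' @param k number of draws to accept (0 < k <= table size).
#' @return An \linkS4class{ABCResult}.
#' @export
abcReject <- function(observed, table, k) {
  stopifnot(is(table, "ReferenceTable"))
  obs <- if (is(observed, "AggregateSFS")) asfsValues(observed)
  else as.numeric(observed)
  if (length(obs) != ncol(table@asfs))
    stop("observed bin vector does not match the reference table")
  k <- as.integer(k)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(table@asfs)) stop("k exceeds the table size")
  st <- .standardizeBins(obs, table@asfs)
  d <- sqrt(colSums((t(st$table) - st$obs)^2))
  ord <- order(d)[seq_len(k)]  # order() breaks ties by row index
  grid <- xiGrid(table@prior)
  cnt <- vapply(grid, function(g)
    sum(abs(table@params$xi[ord] - g) < 1e-9), integer(1))
  names(cnt) <- sprintf("%.3f", grid)
  new("ABCResult", acceptedIdx = as.integer(ord), distances = d[ord],
    posterior = table@params[ord, , drop = FALSE], xiCounts = cnt,
    xiGrid = grid, k = k)
}

setMethod("show", "ABCResult", function(object) {
  cat(sprintf("ABCResult: %d accepted draws, max distance %.4f\n",
    object@k, max(object@distances)))
  print(object@xiCounts)
  invisible(object)
})

#' Bayes-factor matrix over the xi grid
#'
#' Cell (row b, column a) compares the column model against the row model:
#' \code{BF = (n_a / n_b) * (pi_b / pi_a)} with accepted counts n and prior
#' masses pi (uniform on the grid here, so the prior ratio is 1). If any
#' count is zero, 0.5 is added to every count — a documented continuity
#' correction that keeps finite-sample Bayes factors finite and preserves
#' the antisymmetry \code{BF(a,b) * BF(b,a) = 1}.
#'
#' @param result an \linkS4class{ABCResult}.
#' @param prior the \linkS4class{HyperPrior} (supplies the uniform grid
#'   masses).
#' @return square matrix over the xi grid, columns = model compared,
#'   rows = model compared against.
#' @export
bayesFactorMatrix <- function(result, prior) {
  stopifnot(is(result, "ABCResult"), is(prior, "HyperPrior"))
  cnt <- as.numeric(result@xiCounts)
  if (sum(cnt) == 0) stop("accepted set is empty")
  if (any(cnt == 0)) cnt <- cnt + 0.5
  piMass <- rep(1 / length(cnt), length(cnt))
  bf <- outer(seq_along(cnt), seq_along(cnt), function(b, a)
    (cnt[a] / cnt[b]) * (piMass[b] / piMass[a]))
  dimnames(bf) <- list(names(result@xiCounts), names(result@xiCounts))
  bf
}

#' Hyperparameter posteriors from accepted draws
#'
#' Returns the accepted draws' hyper-summaries — mean bottleneck strength
#' E(eps), its dispersion index Var(eps)/Mean(eps), the shared pulse time
#' and the mean Ne, each computed across the T taxa of a draw at simulation
#' time. With \code{adjust = "local-linear"}, accepted summaries are
#' corrected by a distance-weighted (Epanechnikov kernel) linear regression
#' on the standardized bins, shifting each accepted value to the observed
#' summary-statistic point; this requires \code{k >= bins + 2} accepted
#' draws and otherwise falls back to plain rejection with a warning.
#'
#' @param result an \linkS4class{ABCResult}.
#' @param table the \linkS4class{ReferenceTable} behind it.
#' @param observed the observed aggregate SFS (needed for adjustment).
#' @param adjust \code{"none"} or \code{"local-linear"}.
#' @return data.frame of posterior samples with columns \code{meanEps},
#'   \code{dispEps}, \code{sharedTime}, \code{meanNe}.
#' @export
estimateHyperposterior <- function(result, table = NULL, observed = NULL,
                                   adjust = c("none", "local-linear")) {
  adjust <- match.arg(adjust)
  stopifnot(is(result, "ABCResult"))
  if (result@k == 0) stop("accepted set is empty")
  cols <- c("meanEps", "dispEps", "sharedTime", "meanNe")
  post <- result@posterior[, cols]
  rownames(post) <- NULL
  if (adjust == "none") return(post)
  if (is.null(table) || is.null(observed))
    stop("local-linear adjustment needs the reference table and observed aSFS")
  obs <- if (is(observed, "AggregateSFS")) asfsValues(observed)
  else as.numeric(observed)
  st <- .standardizeBins(obs, table@asfs)
  X <- st$table[result@acceptedIdx, , drop = FALSE]
  if (result@k < ncol(X) + 2L) {
    warning("too few accepted draws for local-linear adjustment; ",
      "falling back to rejection")
    return(post)
  }
  dmax <- max(result@distances)
  w <- if (dmax > 0) 1 - (result@distances / dmax)^2 else rep(1, result@k)
  w[w <= 0] <- min(w[w > 0], 1e-6)
  Xc <- sweep(X, 2L, st$obs)  # regression centred on the observed point
  for (cl in cols) {
    fitlm <- lm(post[[cl]] ~ Xc, weights = w)
    post[[cl]] <- post[[cl]] - (fitlm$fitted.values - coef(fitlm)[1L])
  }
  post
}

#' Dispersion index of bottleneck strength
#'
#' \code{Var(x)/Mean(x)} with the n-1 denominator sample variance: 0 when
#' all taxa share one bottleneck strength, growing with cross-taxon
#' heterogeneity. Scales linearly with the values.
#'
#' @param values numeric vector (e.g. per-taxon eps); mean must be positive.
#' @return the dispersion index.
#' @examples
#' dispersionIndex(c(0.1, 0.3))  # 0.02 / 0.2 = 0.1
#' @export
dispersionIndex <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean of values must be positive")
  v <- if (length(values) < 2L) 0 else var(values)
  v / m
}

#' Leave-one-out confusion matrix from pseudo-observed datasets
#'
#' For every xi value on the grid, \code{podsPerModel} reference-table rows
#' of that stratum are treated as pseudo-observed datasets (PODs). Each POD
#' is classified against the table with its own row removed: rejection ABC
#' keeps the top \code{k} draws and assigns the xi with the highest accepted
#' count (ties to the smaller xi). Cell (true, assigned) is the fraction of
#' PODs so classified; rows sum to 1.
#'
#' @param table a \linkS4class{ReferenceTable}.
#' @param podsPerModel PODs per xi value (>= 1); a stratum with fewer rows
#'   is an error.
#' @param k accepted draws per classification.
#' @param seed optional integer seed for the POD sampling.
#' @return square matrix over the xi grid, rows = true xi,
#'   columns = assigned xi.
#' @export
podConfusionMatrix <- function(table, podsPerModel = 50L, k = 1500L,
                               seed = NULL) {
  stopifnot(is(table, "ReferenceTable"))
  if (podsPerModel < 1) stop("podsPerModel must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  grid <- xiGrid(table@prior)
  nm <- sprintf("%.3f", grid)
  xi <- table@params$xi
  cm <- matrix(0, length(grid), length(grid), dimnames = list(nm, nm))
  # standardize once from the full table; removing one row perturbs the
  # bin SDs negligibly for any realistic table size
  sds <- apply(table@asfs, 2L, stats::sd)
  keep <- which(sds > 0)
  stTab <- sweep(table@asfs[, keep, drop = FALSE], 2L, sds[keep], "/")
  for (gi in seq_along(grid)) {
    rows <- which(abs(xi - grid[gi]) < 1e-9)
    if (length(rows) < podsPerModel)
      stop(sprintf("xi stratum %s has %d rows, fewer than podsPerModel = %d",
        nm[gi], length(rows), podsPerModel))
    pods <- sample(rows, podsPerModel)
    for (r in pods) {
      d <- sqrt(colSums((t(stTab) - stTab[r, ])^2))
      d[r] <- Inf  # leave the POD's own row out
      ord <- order(d)[seq_len(min(k, nrow(stTab) - 1L))]
      cnt <- vapply(grid, function(g)
        sum(abs(xi[ord] - g) < 1e-9), integer(1))
      cm[gi, which.max(cnt)] <- cm[gi, which.max(cnt)] + 1
    }
  }
  cm / podsPerModel
}

#' Overlap coefficient of two posterior samples
#'
#' Histogram-based overlap of two density estimates on a shared grid:
#' \code{sum_b min(p_a(b), p_b(b))}, between 0 (disjoint supports) and 1
#' (identical distributions).
#'
#' @param a,b numeric sample vectors.
#' @param bins number of histogram bins spanning the pooled range.
#' @return overlap coefficient in [0, 1].
#' @export
posteriorOverlap <- function(a, b, bins = 64L) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(1)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  pa <- tabulate(findInterval(a, brk, rightmost.closed = TRUE,
    all.inside = TRUE), nbins = bins) / length(a)
  pb <- tabulate(findInterval(b, brk, rightmost.closed = TRUE,
    all.inside = TRUE), nbins = bins) / length(b)
  sum(pmin(pa, pb))
}
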