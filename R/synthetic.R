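# One locus genealogy with explicit tip sets: returns a list of branches,
# each branch a list(tips = integer vector, len = generations). Used by the
# genotype emitter, which needs to know WHICH tips carry each mutation, not
# just how many.
.simulateTipsetTree <- function(n, epochs) {
  sets <- as.list(seq_len(n))
  lens <- numeric(n)
  branches <- list()
  k <- n
  t <- 0
  while (k > 1L) {
    tn <- coalescenceTime(k, t, epochs)
    lens[seq_len(k)] <- lens[seq_len(k)] + (tn - t)
    pair <- sample.int(k, 2L)
    a <- min(pair); b <- max(pair)
    branches[[length(branches) + 1L]] <- list(tips = sets[[a]],
      len = lens[a])
    branches[[length(branches) + 1L]] <- list(tips = sets[[b]],
      len = lens[b])
    sets[[a]] <- sort(c(sets[[a]], sets[[b]]))
    lens[a] <- 0
    sets[[b]] <- sets[[k]]
    lens[b] <- lens[k]
    sets[[k]] <- NULL
    lens <- lens[-k]
    k <- k - 1L
    t <- tn
  }
  branches
}

#' Generate a ddRAD-like population dataset with known truth
#'
#' Simulates one population of unlinked short loci under a known demography:
#' per locus, a coalescent genealogy for 2 * nDiploids genes, Poisson
#' infinite-sites mutations on its branches, and biallelic genotypes with
#' zero missingness (the complete-data filter is emulated by construction).
#' Haploid genes 2j-1 and 2j form diploid individual j. The emitted
#' genotype table, the SFS and the truth manifest are mutually consistent:
#' tallying the genotypes with [sfsFromGenotypes()] (adding the manifest's
#' invariant-site count to class 0) reproduces the returned SFS exactly.
#'
#' @param nDiploids diploid sample size (>= 2).
#' @param epochs the true \linkS4class{EpochSchedule}.
#' @param mutation a \linkS4class{MutationModel}.
#' @param seed integer seed; the manifest plus seed fully determine the
#'   output.
#' @return list with \code{genotypes} (polymorphic sites x individuals,
#'   rownames \code{locus_<i>:<pos>}), \code{sfs} (unfolded, class 0 =
#'   invariant sites), and \code{manifest} (list: seed, sizes, demography,
#'   mutation model, invariant-site count).
#' @export
generatePopulation <- function(nDiploids, epochs, mutation, seed = NULL) {
  stopifnot(is(epochs, "EpochSchedule"), is(mutation, "MutationModel"))
  if (nDiploids < 2) stop("nDiploids must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * as.integer(nDiploids)
  theta <- mutation@muSite * mutation@locusLength
  rows <- list()
  counts <- numeric(n + 1L)
  for (l in seq_len(mutation@numLoci)) {
    branches <- .simulateTipsetTree(n, epochs)
    if (theta == 0) next
    pos <- 0L
    for (br in branches) {
      s <- rpois(1L, theta * br$len)
      if (s == 0) next
      for (m in seq_len(s)) {
        if (pos >= mutation@locusLength) break  # infinite-sites guard
        pos <- pos + 1L
        geno <- tabulate(ceiling(br$tips / 2), nbins = nDiploids)
        rows[[length(rows) + 1L]] <- c(locus = l, geno)
        counts[length(br$tips) + 1L] <- counts[length(br$tips) + 1L] + 1
      }
    }
  }
  totalSites <- mutation@numLoci * mutation@locusLength
  nSeg <- length(rows)
  counts[1L] <- totalSites - nSeg
  geno <- if (nSeg) {
    m <- do.call(rbind, rows)
    g <- m[, -1L, drop = FALSE]
    # position = running index within each locus
    posWithin <- stats::ave(m[, 1L], m[, 1L], FUN = seq_along)
    rownames(g) <- sprintf("locus_%d:%d", m[, 1L], as.integer(posWithin))
    colnames(g) <- paste0("ind", seq_len(nDiploids))
    g
  } else {
    matrix(numeric(0), nrow = 0L, ncol = nDiploids,
      dimnames = list(NULL, paste0("ind", seq_len(nDiploids))))
  }
  manifest <- list(
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    nDiploids = as.integer(nDiploids),
    epochs = list(tStart = epochs@tStart, NStart = epochs@NStart,
      growthRate = epochs@growthRate),
    mutation = list(muSite = mutation@muSite,
      locusLength = mutation@locusLength, numLoci = mutation@numLoci),
    totalSites = totalSites,
    invariantSites = totalSites - nSeg,
    segregatingSites = nSeg)
  list(genotypes = geno,
    sfs = SFS(counts, folded = FALSE, polarized = TRUE),
    manifest = manifest)
}

#' Generate co-distributed taxa with a known synchrony truth
#'
#' Draws T per-taxon demographies from the hyperprior honouring a fixed true
#' xi (so exactly \code{round(xi * T)} taxa share one pulse time), generates
#' each taxon's dataset with [generatePopulation()], and builds the observed
#' aggregate SFS from the per-taxon spectra. The manifest records the full
#' hierarchical truth.
#'
#' @param prior a \linkS4class{HyperPrior}; its \code{taxaCount} is T.
#' @param xi true proportion of synchronously contracting taxa (on the
#'   grid z/T).
#' @param nDiploids diploid sample size per taxon.
#' @param mutation per-taxon \linkS4class{MutationModel}.
#' @param seed integer seed.
#' @param folded fold per-taxon spectra before aggregating?
#' @return list with \code{taxa} (list of [generatePopulation()] results),
#'   \code{asfs} (the observed \linkS4class{AggregateSFS}),
#'   \code{draw} (the \linkS4class{CoDemDraw} truth) and \code{manifest}.
#' @export
generateCodistributed <- function(prior, xi = 1, nDiploids = 4L,
                                  mutation = MutationModel(numLoci = 200,
                                    locusLength = 500),
                                  seed = NULL, folded = TRUE) {
  stopifnot(is(prior, "HyperPrior"))
  if (!is.null(seed)) set.seed(seed)
  draw <- drawCoDemography(prior, fixedXi = xi)
  taxa <- lapply(seq_len(prior@taxaCount), function(i) {
    p <- draw@taxa[i, ]
    ep <- bottleneckSchedule(p$ne, p$eps, p$tPulse, p$growth,
      tAncient = prior@tAncient)
    generatePopulation(nDiploids, ep, mutation)
  })
  spectra <- lapply(taxa, function(tx)
    if (folded) fold(tx$sfs) else tx$sfs)
  asfs <- buildASFS(spectra, allowZero = TRUE)
  manifest <- list(
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    xi = draw@xi,
    sharedTime = draw@sharedTime,
    taxa = draw@taxa,
    nDiploids = as.integer(nDiploids),
    folded = folded)
  list(taxa = taxa, asfs = asfs, draw = draw, manifest = manifest)
}

#' Write a truth manifest as JSON
#'
#' @param manifest a manifest list from [generatePopulation()] or
#'   [generateCodistributed()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(path)
}
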