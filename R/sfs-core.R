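#' Construct a site frequency spectrum
#'
#' @param counts numeric vector of per-class site counts, length n + 1
#'   (classes 0..n, class index = allele copy number).
#' @param folded logical; is this a minor-allele (folded) spectrum?
#' @param polarized logical; is the ancestral state assumed known? Only
#'   meaningful for unfolded spectra.
#'
#' @return An \linkS4class{SFS} object.
#' @examples
#' SFS(c(0, 6, 2, 3, 0))                  # unfolded, n = 4
#' SFS(c(10, 9, 2, 0, 0), folded = TRUE)  # folded, n = 4
#' @export
SFS <- function(counts, folded = FALSE, polarized = FALSE) {
  new("SFS",
    counts = as.numeric(counts),
    nHaploid = as.integer(length(counts) - 1L),
    folded = isTRUE(folded),
    polarized = isTRUE(polarized))
}

#' SFS accessors
#'
#' @param x an \linkS4class{SFS}.
#' @return \code{sfsCounts}: the per-class counts; \code{nHaploid}: the
#'   haploid sample size; \code{isFolded}, \code{isPolarized}: logicals;
#'   \code{segregatingSites}: total count over segregating classes
#'   (1..n-1 unfolded, 1..floor(n/2) folded).
#' @name sfs-accessors
NULL

#' @rdname sfs-accessors
#' @export
setMethod("sfsCounts", "SFS", function(x) x@counts)

#' @rdname sfs-accessors
#' @export
setMethod("nHaploid", "SFS", function(x) x@nHaploid)

#' @rdname sfs-accessors
#' @export
setMethod("isFolded", "SFS", function(x) x@folded)

#' @rdname sfs-accessors
#' @export
setMethod("isPolarized", "SFS", function(x) x@polarized)

# 1-based index positions of the segregating classes of an SFS
.segIdx <- function(x) {
  n <- x@nHaploid
  if (x@folded) seq.int(2L, floor(n / 2) + 1L) else seq.int(2L, n)
}

#' @rdname sfs-accessors
#' @export
setMethod("segregatingSites", "SFS", function(x) sum(x@counts[.segIdx(x)]))

setMethod("show", "SFS", function(object) {
  cat(sprintf("SFS: n = %d haploids, %s%s, %g segregating sites\n",
    object@nHaploid,
    if (object@folded) "folded" else "unfolded",
    if (object@polarized) " (polarized)" else "",
    segregatingSites(object)))
  cts <- object@counts
  names(cts) <- as.character(seq_along(cts) - 1L)
  print(cts)
  invisible(object)
})

#' Fold an unfolded SFS
#'
#' Merges derived-allele class i with class n - i into the minor-allele class
#' min(i, n - i). For even n the central class n/2 maps onto itself and is
#' not doubled. Monomorphic classes 0 and n are merged into class 0.
#'
#' @param x an unfolded \linkS4class{SFS}.
#' @return A folded \linkS4class{SFS} with the same total count.
#' @examples
#' fold(SFS(c(0, 6, 2, 3, 0)))  # counts (0, 9, 2, 0, 0)
#' @rdname fold
#' @export
setMethod("fold", "SFS", function(x) {
  if (x@folded) stop("SFS is already folded")
  n <- x@nHaploid
  out <- numeric(n + 1L)
  for (i in 0:n) {
    j <- min(i, n - i)
    out[j + 1L] <- out[j + 1L] + x@counts[i + 1L]
  }
  SFS(out, folded = TRUE)
})

#' Hypergeometric down-projection of an SFS
#'
#' Projects an unfolded spectrum from n to m haploid samples: the projected
#' count for class j is \code{sum_i counts[i] * H(j; n, i, m)} where H is the
#' hypergeometric probability of observing j derived copies in a subsample of
#' m genes drawn from n genes carrying i derived copies. Mass that projects
#' to frequency 0 or m (sites monomorphic in the subsample) is retained in
#' those classes, so the total count is conserved; the gain is also reported
#' in the \code{"monomorphicGain"} attribute as \code{c(class0, classM)}.
#'
#' Used to equalize sample sizes across populations before building the
#' aggregate SFS (fold afterwards if a folded spectrum is needed).
#'
#' @param x an unfolded \linkS4class{SFS}.
#' @param m target haploid sample size, \code{2 <= m <= nHaploid(x)}.
#' @return An unfolded \linkS4class{SFS} with n = m.
#' @examples
#' projectSFS(SFS(c(0, 6, 0, 0, 0)), 2)  # class 1 keeps 3.0, class 0 gains 3.0
#' @rdname projectSFS
#' @export
setMethod("projectSFS", "SFS", function(x, m) {
  if (x@folded) stop("project before folding, not after")
  m <- as.integer(m)
  n <- x@nHaploid
  if (m < 2L) stop("m must be >= 2")
  if (m > n) stop("m must not exceed nHaploid")
  if (m == n) {
    out <- SFS(x@counts, folded = FALSE, polarized = x@polarized)
    attr(out, "monomorphicGain") <- c(0, 0)
    return(out)
  }
  out <- numeric(m + 1L)
  for (i in 0:n) {
    ci <- x@counts[i + 1L]
    if (ci == 0) next
    j <- 0:m
    # P(j derived in m draws | i derived among n) without replacement
    h <- dhyper(j, i, n - i, m)
    out <- out + ci * h
  }
  res <- SFS(out, folded = FALSE, polarized = x@polarized)
  # mass newly projected into the monomorphic classes 0 and m
  attr(res, "monomorphicGain") <-
    c(out[1L] - x@counts[1L], out[m + 1L] - x@counts[n + 1L])
  res
})

#' Normalize an SFS over its segregating classes
#'
#' Returns the proportions of segregating sites per frequency class
#' (monomorphic classes 0 and n excluded); the result sums to 1.
#'
#' @param x an \linkS4class{SFS} with at least one segregating site.
#' @return numeric vector of proportions, one per segregating class.
#' @examples
#' normalizeSFS(SFS(c(0, 1, 2, 3, 0)))  # 1/6, 2/6, 3/6
#' @rdname normalizeSFS
#' @export
setMethod("normalizeSFS", "SFS", function(x) {
  seg <- x@counts[.segIdx(x)]
  tot <- sum(seg)
  if (tot <= 0) stop("cannot normalize an SFS with zero segregating sites")
  p <- seg / tot
  names(p) <- as.character(.segIdx(x) - 1L)
  p
})

#' Build the aggregate SFS across taxa
#'
#' Each taxon's SFS is normalized over its segregating classes; then, within
#' every frequency class, the T taxon proportions are sorted in
#' non-increasing order and the classes concatenated in ascending frequency
#' order. The result is invariant to the input taxon order.
#'
#' @param spectra list of \linkS4class{SFS} sharing \code{nHaploid} and
#'   folding state; at least two.
#' @param allowZero if \code{TRUE}, a taxon with zero segregating sites
#'   contributes all-zero proportions instead of an error (used when
#'   simulating reference tables under weak mutational input).
#' @return An \linkS4class{AggregateSFS}.
#' @examples
#' a <- SFS(c(0, 5, 3, 2, 0)); b <- SFS(c(0, 6, 2, 2, 0))
#' buildASFS(list(a, b))
#' @export
buildASFS <- function(spectra, allowZero = FALSE) {
  if (length(spectra) < 2L) stop("at least two taxa required")
  n <- vapply(spectra, nHaploid, integer(1))
  fl <- vapply(spectra, isFolded, logical(1))
  if (length(unique(n)) != 1L)
    stop("all spectra must share the same haploid sample size")
  if (length(unique(fl)) != 1L)
    stop("all spectra must share the same folding state")
  props <- lapply(spectra, function(s) {
    if (allowZero && segregatingSites(s) == 0)
      setNames(numeric(length(.segIdx(s))), as.character(.segIdx(s) - 1L))
    else normalizeSFS(s)
  })
  pm <- do.call(rbind, props)  # taxa x classes
  t_count <- nrow(pm)
  classes <- as.integer(colnames(pm))
  vals <- numeric(0)
  layout <- NULL
  for (j in seq_along(classes)) {
    v <- sort(pm[, j], decreasing = TRUE)
    vals <- c(vals, unname(v))
    layout <- rbind(layout,
      data.frame(class = classes[j], rank = seq_len(t_count)))
  }
  new("AggregateSFS",
    values = vals,
    taxaCount = as.integer(t_count),
    nHaploid = unique(n),
    folded = unique(fl),
    binLayout = layout)
}

#' Aggregate-SFS accessors
#'
#' @param x an \linkS4class{AggregateSFS}.
#' @return \code{asfsValues}: the concatenated sorted proportions;
#'   \code{taxaCount}: T; \code{binLayout}: the position-to-(class, rank)
#'   map; \code{nHaploid}, \code{isFolded} as for [SFS].
#' @name asfs-accessors
NULL

#' @rdname asfs-accessors
#' @export
setMethod("asfsValues", "AggregateSFS", function(x) x@values)

#' @rdname asfs-accessors
#' @export
setMethod("taxaCount", "AggregateSFS", function(x) x@taxaCount)

#' @rdname asfs-accessors
#' @export
setMethod("binLayout", "AggregateSFS", function(x) x@binLayout)

#' @rdname asfs-accessors
#' @export
setMethod("nHaploid", "AggregateSFS", function(x) x@nHaploid)

#' @rdname asfs-accessors
#' @export
setMethod("isFolded", "AggregateSFS", function(x) x@folded)

setMethod("show", "AggregateSFS", function(object) {
  cat(sprintf("AggregateSFS: %d taxa, n = %d (%s), %d bins\n",
    object@taxaCount, object@nHaploid,
    if (object@folded) "folded" else "unfolded",
    length(object@values)))
  invisible(object)
})

#' Tally an SFS from diploid genotypes
#'
#' Counts allele copies per biallelic site into frequency classes for one
#' population. Sites with any missing genotype are excluded (the
#' complete-data filter that prevents missingness from biasing the SFS); the
#' number excluded is reported in the \code{"sitesExcluded"} attribute.
#' Invariant retained sites are counted into class 0. With
#' \code{polarized = TRUE} the alternate allele is taken as the derived state
#' and an unfolded spectrum is returned; otherwise minor-allele copies are
#' counted and the spectrum is folded.
#'
#' @param genotypes numeric matrix, sites x individuals, entries 0/1/2 =
#'   copies of the alternate (derived) allele, NA = missing.
#' @param polarized is the ancestral state known?
#' @param invariantSites additional invariant retained sites to add to
#'   class 0 (e.g. monomorphic sites not emitted in a genotype table).
#' @return An \linkS4class{SFS} with n = 2 * number of individuals.
#' @examples
#' g <- rbind(c(1, 1, 1), c(0, 2, 0))  # 2 sites, 3 diploids
#' sfsFromGenotypes(g)
#' @export
sfsFromGenotypes <- function(genotypes, polarized = FALSE,
                             invariantSites = 0) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) < 1L) stop("at least one individual required")
  bad <- matrix(!(genotypes %in% c(0, 1, 2, NA)), nrow = nrow(genotypes))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "genotype at site %s, individual %d is not biallelic diploid (0/1/2)",
      if (is.null(rownames(genotypes))) as.character(w[1L])
      else rownames(genotypes)[w[1L]], w[2L]))
  }
  n <- 2L * ncol(genotypes)
  complete <- rowSums(is.na(genotypes)) == 0
  excluded <- sum(!complete)
  g <- genotypes[complete, , drop = FALSE]
  counts <- numeric(n + 1L)
  if (nrow(g)) {
    alt <- rowSums(g)
    cls <- if (polarized) alt else pmin(alt, n - alt)
    tab <- tabulate(cls + 1L, nbins = n + 1L)
    counts <- counts + tab
  }
  counts[1L] <- counts[1L] + invariantSites
  out <- SFS(counts, folded = !polarized, polarized = polarized)
  attr(out, "sitesExcluded") <- excluded
  out
}
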