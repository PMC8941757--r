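#' Read and write SFS text files
#'
#' dadi-style one-dimensional SFS text: a header line \code{"<n+1> folded"}
#' or \code{"<n+1> unfolded"}, one line of n + 1 whitespace-separated class
#' counts, and an optional mask line of n + 1 zeros and ones (1 = masked;
#' masked entries are read back as written but not interpreted). Counts are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param path file path.
#' @param x an \linkS4class{SFS}.
#' @return \code{readSFS}: an \linkS4class{SFS}; \code{writeSFS}: \code{path},
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".sfs")
#' writeSFS(SFS(c(0, 5, 3, 2, 0)), f)
#' readSFS(f)
#' @export
readSFS <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("SFS file needs a header and a counts line")
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  len <- as.integer(hdr[1L])
  if (is.na(len) || len < 3L) stop("malformed SFS header")
  folded <- length(hdr) > 1L && identical(tolower(hdr[2L]), "folded")
  counts <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  if (length(counts) != len)
    stop(sprintf("expected %d counts, found %d", len, length(counts)))
  SFS(counts, folded = folded, polarized = !folded)
}

#' @rdname readSFS
#' @export
writeSFS <- function(x, path) {
  stopifnot(is(x, "SFS"))
  hdr <- sprintf("%d %s", x@nHaploid + 1L,
    if (x@folded) "folded" else "unfolded")
  writeLines(c(hdr, paste(sprintf("%.17g", x@counts), collapse = " ")), path)
  invisible(path)
}

#' Read diploid genotypes from a VCF
#'
#' Reads a VCF (v4.x) and returns the alternate-allele dosage matrix
#' consumed by [sfsFromGenotypes()]: sites x individuals, entries 0/1/2, NA
#' for missing. Only the GT field is consulted; phasing is ignored. A
#' non-biallelic record is an error naming the offending site.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return numeric matrix with rownames \code{"CHROM:POS"}.
#' @export
readVCFGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
    dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  site <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] %in% c(".", "")
  if (any(multi))
    stop(sprintf("non-biallelic site encountered: %s", site[which(multi)[1L]]))
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, 2L, function(col) {
    col <- gsub("|", "/", col, fixed = TRUE)
    out <- rep(NA_real_, length(col))
    out[col %in% c("0/0")] <- 0
    out[col %in% c("0/1", "1/0")] <- 1
    out[col %in% c("1/1")] <- 2
    out
  })
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(gt))
  rownames(dose) <- site
  colnames(dose) <- colnames(gt)
  dose
}

#' Write diploid genotypes to a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only records from an alternate-allele dosage
#' matrix (sites x individuals; rownames \code{"contig:pos"}, or synthetic
#' \code{locus_<i>:<pos>} names are generated). Records are sorted by contig
#' then position. Reading the file back with [readVCFGenotypes()] and
#' tallying with [sfsFromGenotypes()] reproduces the SFS of the input.
#'
#' @param genotypes numeric matrix, entries 0/1/2 or NA.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(genotypes, path) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  ns <- nrow(genotypes)
  if (is.null(rownames(genotypes)) && ns)
    rownames(genotypes) <- paste0("locus_", seq_len(ns), ":1")
  if (is.null(colnames(genotypes)) && ncol(genotypes))
    colnames(genotypes) <- paste0("ind", seq_len(ncol(genotypes)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=codemog",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", colnames(genotypes)), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (ns == 0L) return(invisible(path))
  parts <- strsplit(rownames(genotypes), ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  ord <- order(chrom, pos)
  gtchar <- matrix("./.", nrow = ns, ncol = ncol(genotypes))
  gtchar[genotypes == 0] <- "0/0"
  gtchar[genotypes == 1] <- "0/1"
  gtchar[genotypes == 2] <- "1/1"
  for (i in ord) {
    writeLines(paste(c(chrom[i], pos[i], ".", "A", "T", ".", "PASS", ".",
      "GT", gtchar[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}
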