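# Orchestration layer: config-driven wrappers tying the pipeline stages
# together. The interface is function-based (this is an analysis package,
# not a shell tool); each wrapper accepts a RunConfig list, logs JSON lines
# to stderr, and is deterministic under the config's seed.

.configDefaults <- list(
  seed = 1L,
  outDir = ".",
  nHaploid = 8L,            # common projection size across taxa
  muSite = 1e-8,            # mutations / site / generation
  generationTime = 1,       # years per generation (reporting only)
  locusLength = 100,
  numLoci = 5000,
  nSims = 50000L,           # hABC reference-table size
  kModelChoice = 1500L,     # accepted draws for xi model choice
  kEstimation = 100L,       # accepted draws for hyperparameter posteriors
  pods = 50L,               # pseudo-observed datasets per xi value
  taxaCount = 6L,
  folded = TRUE,
  cycles = 3L,
  repsPerEval = 300L,
  bootstrapB = 100L)

#' Assemble a run configuration
#'
#' Returns the pipeline's configuration list: defaults mirror the study
#' design this package automates (mutation rate 1e-8 per site per
#' generation, one-year generation time, projection to n = 8 haploids, top
#' 1,500 accepted simulations for synchrony model choice, top 100 for
#' hyperparameter estimation, 50 pseudo-observed datasets per model), all
#' overridable. Unknown fields are an error naming the field.
#'
#' @param ... overrides of the default fields.
#' @return named list (class \code{"RunConfig"}).
#' @examples
#' cfg <- runConfig(seed = 7, numLoci = 1000)
#' @export
runConfig <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.configDefaults))
  if (length(bad))
    stop(sprintf("unknown config field: %s", bad[1L]))
  cfg <- utils::modifyList(.configDefaults, over)
  for (f in c("seed", "nHaploid", "nSims", "kModelChoice", "kEstimation",
    "pods", "taxaCount", "numLoci", "cycles", "repsPerEval", "bootstrapB"))
    cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [runConfig()] fields; see
#'   \code{system.file("extdata", "example-config.yaml", package =
#'   "codemog")} for a template.
#' @return a \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(runConfig, vals)
}

# single-line JSON log record on stderr
.logJSON <- function(stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    list(...))
  message(jsonlite::toJSON(rec, auto_unbox = TRUE))
  invisible(NULL)
}

.mutationFromConfig <- function(config) {
  MutationModel(muSite = config$muSite, locusLength = config$locusLength,
    numLoci = config$numLoci)
}

#' Simulate a synthetic dataset from a config
#'
#' Wraps [generatePopulation()]: writes the VCF, the dadi-style SFS and the
#' truth manifest under \code{config$outDir}, logging the seed and paths.
#'
#' @param config a [runConfig()] list.
#' @param epochs true demography (default: constant N = 5000).
#' @param nDiploids diploid sample size.
#' @return invisibly, list of written paths plus the generation result.
#' @export
runSimulate <- function(config = runConfig(), epochs = NULL,
                        nDiploids = 4L) {
  if (is.null(epochs)) epochs <- EpochSchedule(0, 5000, 0)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  gen <- generatePopulation(nDiploids, epochs, .mutationFromConfig(config),
    seed = config$seed)
  paths <- list(
    vcf = file.path(config$outDir, "population.vcf"),
    sfs = file.path(config$outDir, "population.sfs"),
    manifest = file.path(config$outDir, "manifest.json"))
  writeVCF(gen$genotypes, paths$vcf)
  writeSFS(gen$sfs, paths$sfs)
  gen$manifest$paths <- paths
  writeManifest(gen$manifest, paths$manifest)
  .logJSON("simulate", seed = config$seed, manifest = paths$manifest,
    segregating = gen$manifest$segregatingSites)
  invisible(c(paths, list(result = gen)))
}

#' VCF to (projected, folded) SFS file
#'
#' Chains [readVCFGenotypes()], [sfsFromGenotypes()], [projectSFS()] and
#' [fold()], writing a dadi-style SFS file. The number of sites excluded by
#' the complete-data filter is logged.
#'
#' @param vcf input VCF path.
#' @param out output SFS path.
#' @param projectTo haploid size m to down-project to (NULL = no
#'   projection).
#' @param foldSpectrum fold the spectrum?
#' @param polarized treat the alternate allele as derived?
#' @param invariantSites invariant retained sites to add to class 0.
#' @return the written \linkS4class{SFS}, invisibly.
#' @export
runSfs <- function(vcf, out, projectTo = NULL, foldSpectrum = TRUE,
                   polarized = !foldSpectrum, invariantSites = 0) {
  geno <- readVCFGenotypes(vcf)
  s <- sfsFromGenotypes(geno, polarized = TRUE,
    invariantSites = invariantSites)
  excluded <- attr(s, "sitesExcluded")
  if (!is.null(projectTo) && projectTo != nHaploid(s))
    s <- projectSFS(s, projectTo)
  if (foldSpectrum) s <- fold(s)
  if (!polarized && !foldSpectrum)
    s@polarized <- FALSE
  writeSFS(s, out)
  .logJSON("sfs", vcf = vcf, out = out, excluded = excluded,
    segregating = segregatingSites(s))
  invisible(s)
}

#' Fit the demographic scenario set to SFS files
#'
#' Runs [compareScenarios()] per population SFS and writes a JSON fit
#' report plus a CSV summary (one row per population x scenario, Akaike
#' weights summing to 1 within population, the selected scenario flagged).
#'
#' @param sfsFiles named character vector of dadi-style SFS paths.
#' @param config a [runConfig()] list.
#' @param scenarios scenario list (default [defaultScenarios()]).
#' @return invisibly, the per-population fit lists.
#' @export
runFit <- function(sfsFiles, config = runConfig(),
                   scenarios = defaultScenarios()) {
  if (is.null(names(sfsFiles)))
    names(sfsFiles) <- basename(sfsFiles)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  mut <- .mutationFromConfig(config)
  set.seed(config$seed)
  popSeeds <- sample.int(.Machine$integer.max, length(sfsFiles))
  all <- Map(function(path, sd) {
    obs <- readSFS(path)
    compareScenarios(obs, scenarios, mut, cycles = config$cycles,
      repsPerEval = config$repsPerEval, seed = sd)
  }, sfsFiles, popSeeds)
  rows <- do.call(rbind, lapply(names(all), function(popn) {
    fits <- all[[popn]]
    do.call(rbind, lapply(fits, function(f) data.frame(
      population = popn, scenario = f@name, logLik = f@logLik,
      aic = f@aic, weight = f@weight,
      selected = f@name == attr(fits, "selected"))))
  }))
  write.csv(rows, file.path(config$outDir, "scenario_fits.csv"),
    row.names = FALSE)
  jsonlite::write_json(
    lapply(all, function(fits) lapply(fits, function(f) list(
      scenario = f@name, estimate = as.list(f@estimate),
      logLik = f@logLik, aic = f@aic, weight = f@weight))),
    file.path(config$outDir, "scenario_fits.json"),
    auto_unbox = TRUE, digits = NA)
  .logJSON("fit", seed = config$seed, populations = length(all))
  invisible(all)
}

#' Hierarchical ABC over an observed aggregate SFS
#'
#' Builds (or reuses) a reference table, runs rejection ABC for synchrony
#' model choice (Bayes-factor matrix over the xi grid) and hyperparameter
#' estimation, and optionally a leave-one-out POD confusion matrix.
#'
#' @param observed observed \linkS4class{AggregateSFS} or bin vector.
#' @param config a [runConfig()] list.
#' @param prior a \linkS4class{HyperPrior} (default built from the config).
#' @param table optional pre-built \linkS4class{ReferenceTable} (resume
#'   support); must match the prior.
#' @param confusion also compute the POD confusion matrix?
#' @return list with \code{table}, \code{modelChoice}
#'   (\linkS4class{ABCResult}), \code{bayesFactors}, \code{posterior}
#'   (top-\code{kEstimation} hyperposterior), and optionally
#'   \code{confusion}.
#' @export
runHabc <- function(observed, config = runConfig(), prior = NULL,
                    table = NULL, confusion = FALSE) {
  if (is.null(prior)) prior <- HyperPrior(taxaCount = config$taxaCount)
  mut <- .mutationFromConfig(config)
  if (is.null(table)) {
    table <- simulateReferenceTable(prior, config$nSims,
      nHaploid = config$nHaploid, mutation = mut, seed = config$seed,
      folded = config$folded)
  }
  mc <- abcReject(observed, table, config$kModelChoice)
  bf <- bayesFactorMatrix(mc, prior)
  est <- abcReject(observed, table, config$kEstimation)
  post <- estimateHyperposterior(est)
  out <- list(table = table, modelChoice = mc, bayesFactors = bf,
    posterior = post)
  if (confusion)
    out$confusion <- podConfusionMatrix(table, podsPerModel = config$pods,
      k = config$kModelChoice, seed = config$seed)
  .logJSON("habc", seed = config$seed, nSims = nrow(table@params),
    kModelChoice = config$kModelChoice)
  out
}

#' Per-population diversity report
#'
#' With \code{fixture = TRUE}, reproduces the packaged pygmy-perch
#' species-comparison table ([nannopercaDiversity()]); otherwise computes
#' SNP counts from the supplied VCFs. Writes a CSV mirroring the diversity
#' table plus the species comparisons.
#'
#' @param config a [runConfig()] list.
#' @param fixture use the packaged published per-population values?
#' @param vcfFiles named per-population VCF paths (when
#'   \code{fixture = FALSE}); names "<species>|<population>".
#' @return invisibly, the [diversityComparisons()] result.
#' @export
runDiversity <- function(config = runConfig(), fixture = TRUE,
                         vcfFiles = NULL) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  if (fixture) {
    tab <- nannopercaDiversity()
  } else {
    if (is.null(vcfFiles) || is.null(names(vcfFiles)))
      stop("vcfFiles with '<species>|<population>' names required")
    rows <- lapply(names(vcfFiles), function(nm) {
      parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
      geno <- readVCFGenotypes(vcfFiles[[nm]])
      s <- sfsFromGenotypes(geno)
      data.frame(population = parts[2L], species = parts[1L],
        snps = segregatingSites(s))
    })
    tab <- do.call(rbind, rows)
  }
  write.csv(tab, file.path(config$outDir, "diversity.csv"),
    row.names = FALSE)
  res <- if (fixture) diversityComparisons(tab)
  else diversityComparisons(tab, stats = "snps")
  cmpRows <- do.call(rbind, lapply(names(res$comparisons), function(s) {
    g <- res$comparisons[[s]]
    data.frame(statistic = s, method = g@method, value = g@statistic,
      p = g@pValue)
  }))
  write.csv(cmpRows, file.path(config$outDir, "comparisons.csv"),
    row.names = FALSE)
  .logJSON("diversity", fixture = fixture,
    statistics = nrow(cmpRows))
  invisible(res)
}
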