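#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom utils packageVersion
NULL

#' Assemble a pipeline configuration
#'
#' Either a `synthetic` block (a [syntheticConfig()]) or the input paths
#' (`expression`, `sampleSheet`, and optionally `phenotypes`, `vcf`,
#' `bed`, `popMap`) must be given.
#'
#' @param synthetic a [syntheticConfig()], or NULL when reading files.
#' @param paths named list of input paths (ignored when `synthetic` is
#'   given).
#' @param tau relative plasticity threshold (default 0.5).
#' @param boundaries magnitude-category boundaries.
#' @param binWidths magnitude bin widths to report.
#' @param nRep,supportMin parametric-bootstrap settings.
#' @param alpha regulator significance threshold.
#' @param nPerm,fluctuation FST permutation settings.
#' @param runCoexpression run the co-expression stage (skipped for very
#'   small gene sets).
#' @param moduleMinSize,beta,cutHeight co-expression settings, see
#'   [detectModules()].
#' @param seed master seed for the bootstrap and permutation stages.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = NULL, paths = list(), tau = 0.5,
                           boundaries = c(0.5, 1, 1.5, 2),
                           binWidths = c(0.2, 0.4, 0.6),
                           nRep = 1000, supportMin = 950, alpha = 0.05,
                           nPerm = 100, fluctuation = 0.05,
                           runCoexpression = TRUE, moduleMinSize = 30,
                           beta = 6, cutHeight = 0.25, seed = 1) {
  if (is.null(synthetic) &&
      !all(c("expression", "sampleSheet") %in% names(paths)))
    stop("need either a synthetic block or expression + sampleSheet paths")
  if (tau <= 0 || nRep < 1 || nPerm < 1) stop("thresholds must be positive")
  structure(list(
    synthetic = synthetic, paths = paths, tau = tau,
    boundaries = boundaries, binWidths = binWidths, nRep = nRep,
    supportMin = supportMin, alpha = alpha, nPerm = nPerm,
    fluctuation = fluctuation, runCoexpression = runCoexpression,
    moduleMinSize = moduleMinSize, beta = beta, cutHeight = cutHeight,
    seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a
#' `synthetic:` mapping is passed to [syntheticConfig()], a `paths:`
#' mapping gives input files.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(syntheticConfig, y$synthetic)
  args <- y[setdiff(names(y), c("synthetic", "paths"))]
  do.call(pipelineConfig,
          c(list(synthetic = syn, paths = if (is.null(y$paths)) list()
                 else y$paths), args))
}

.writeTsv <- function(x, path)
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)

#' Run the full plasticity pipeline
#'
#' Orchestrates expression QC, co-expression hub-gene detection,
#' reinforcement/reversion classification with bootstrap support,
#' binomial excess tests over magnitude categories and bins, regulator
#' and adaptive/maladaptive calls, and the FST permutation test per
#' magnitude category and region type.  All stage outputs are written as
#' TSV under `outDir` together with a JSON summary and a plain-text log
#' (versions, seeds, filter counts); outputs carry no timestamps so a
#' rerun with the same config is byte-identical.
#'
#' @param config a [pipelineConfig()] or the path to a YAML config.
#' @param outDir output directory.
#' @return invisibly, a list with every stage result.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  log <- c(sprintf("plastfirst %s", as.character(packageVersion("plastfirst"))),
           sprintf("seed: %d", config$seed))
  res <- list(config = config)

  # ---- inputs -------------------------------------------------------
  pheno <- NULL; gd <- NULL; genes <- NULL
  if (!is.null(config$synthetic)) {
    sim <- simulateExpression(config$synthetic)
    ph <- simulatePhenotypes(sim, config$synthetic)
    gn <- simulateGenotypes(ph$truth, config$synthetic)
    se <- sim$se; pheno <- ph$phenotypes; gd <- gn$gd; genes <- gn$genes
    res$truth <- ph$truth; res$snpTruth <- gn$snpTruth
    log <- c(log, sprintf("synthetic data: %d genes, %s samples, %d SNPs",
                          nrow(se), paste(config$synthetic$nPerStage,
                                          collapse = "/"), length(gd)))
  } else {
    se <- readExpression(config$paths$expression, config$paths$sampleSheet)
    if (!is.null(config$paths$phenotypes))
      pheno <- read.delim(config$paths$phenotypes)
    if (!is.null(config$paths$vcf)) {
      pm <- read.delim(config$paths$popMap)
      gd <- readVariants(config$paths$vcf, pm)
      genes <- rtracklayer::import(config$paths$bed)
      names(genes) <- S4Vectors::mcols(genes)$name
    }
    log <- c(log, sprintf("inputs: %d genes x %d samples", nrow(se), ncol(se)))
  }
  res$se <- se

  # ---- expression QC ------------------------------------------------
  qc <- conservedGeneCheck(se)
  res$qc <- qc
  log <- c(log, sprintf("conserved genes: %d; median check min p: %.3g",
                        length(qc$conserved),
                        if (!is.null(qc$pairwise)) min(qc$pairwise$p) else NA))
  if (!is.null(qc$pairwise)) .writeTsv(qc$pairwise, file.path(outDir, "qc_median_tests.tsv"))

  # ---- co-expression ------------------------------------------------
  if (config$runCoexpression && nrow(se) >= config$moduleMinSize) {
    gs <- geneSignificance(se)
    mods <- detectModules(se, beta = config$beta,
                          minSize = config$moduleMinSize,
                          cutHeight = config$cutHeight)
    ma <- mergeAndAssociate(se, mods)
    hubs <- hubGenes(gs, ma$modules, ma$association, alpha = config$alpha)
    res$coexpression <- list(gs = gs, modules = ma$modules,
                             association = ma$association, hubs = hubs)
    log <- c(log, sprintf("modules: %d (%d stage-associated); hub genes: %d",
                          sum(levels(ma$modules) != "unassigned"),
                          sum(ma$association$associated), length(hubs)))
    .writeTsv(data.frame(gene = names(ma$modules),
                         module = as.character(ma$modules)),
              file.path(outDir, "modules.tsv"))
    .writeTsv(ma$association, file.path(outDir, "module_association.tsv"))
    writeLines(hubs, file.path(outDir, "hub_genes.txt"))
  }

  # ---- plasticity + bootstrap --------------------------------------
  summ <- summarizeStages(se)
  calls <- classifyPlasticity(summ, tau = config$tau,
                              boundaries = config$boundaries)
  boot <- bootstrapSupport(summ, tau = config$tau, nRep = config$nRep,
                           supportMin = config$supportMin,
                           seed = config$seed)
  calls <- addBootstrapSupport(calls, boot)
  res$summary <- summ; res$calls <- calls
  log <- c(log, sprintf(
    "plasticity (tau=%.2f): %d reinforcement, %d reversion, %d none, %d excluded (zero ancestral); %d bootstrap-supported calls",
    config$tau, sum(calls$class == "reinforcement"),
    sum(calls$class == "reversion"), sum(calls$class == "none"),
    length(metadata(calls)$excluded),
    sum(calls$supported & calls$class != "none")))
  .writeTsv(calls, file.path(outDir, "plasticity_calls.tsv"))
  res$classSummary <- plasticitySummary(calls)
  .writeTsv(res$classSummary, file.path(outDir, "class_counts.tsv"))
  res$bins <- lapply(config$binWidths, function(w) binCategories(calls, w))
  names(res$bins) <- sprintf("bin%g", config$binWidths)
  for (nm in names(res$bins))
    .writeTsv(res$bins[[nm]], file.path(outDir, sprintf("%s.tsv", nm)))

  # ---- regulators ---------------------------------------------------
  if (!is.null(pheno)) {
    corr <- phenotypeCorrelation(se, pheno)
    regs <- classifyRegulators(corr, alpha = config$alpha)
    adap <- classifyAdaptive(calls, regs$perGene)
    res$regulators <- regs; res$adaptive <- adap
    log <- c(log, sprintf(
      "regulators: %d (of which %d conflicting); adaptive %d, maladaptive %d",
      nrow(regs$perGene), sum(regs$perGene$conflict),
      sum(adap$adaptive == "adaptive"), sum(adap$adaptive == "maladaptive")))
    .writeTsv(regs$perGene, file.path(outDir, "regulators.tsv"))
    .writeTsv(adap, file.path(outDir, "adaptive_calls.tsv"))
  } else {
    log <- c(log, "regulator stage skipped: no phenotype table")
    warning("no phenotype table; regulator stage skipped")
  }

  # ---- FST permutation ---------------------------------------------
  if (!is.null(gd)) {
    comp <- wcFst(gd)
    rmap <- assignRegions(genes, gd)
    cats <- levels(calls$category)
    fst <- list()
    for (ci in seq_along(cats)) {
      cgenes <- calls$gene[!is.na(calls$category) &
                             calls$category == cats[ci] &
                             calls$class != "none"]
      if (!length(cgenes)) next
      fst[[cats[ci]]] <- tryCatch(
        fstByRegion(comp, rmap, cgenes, nPerm = config$nPerm,
                    fluctuation = config$fluctuation,
                    seed = config$seed + 100L * ci),
        error = function(e) {
          log <<- c(log, sprintf("FST skipped for %s: %s", cats[ci],
                                 conditionMessage(e)))
          NULL
        })
    }
    res$fst <- fst
    tab <- do.call(rbind, lapply(names(fst), function(cat)
      do.call(rbind, lapply(fst[[cat]], function(r)
        data.frame(category = cat, region = r@region, n_snps = r@nSnps,
                   empirical_fst = r@empirical, p = r@p,
                   significant = r@significant)))))
    if (!is.null(tab)) .writeTsv(tab, file.path(outDir, "fst_permutation.tsv"))
    log <- c(log, sprintf("FST: %d SNPs (%d with defined estimate)",
                          length(gd), sum(!is.na(comp$theta))))
  }

  # ---- summary ------------------------------------------------------
  summary <- list(
    n_genes = nrow(se), n_samples = ncol(se), tau = config$tau,
    seed = config$seed,
    counts = as.list(table(calls$class)),
    excluded_zero_ancestral = length(metadata(calls)$excluded),
    binomial_p_overall = res$classSummary$p[res$classSummary$category == "all"]
  )
  write_json(summary, file.path(outDir, "summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(outDir, "pipeline_log.txt"))
  invisible(res)
}
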