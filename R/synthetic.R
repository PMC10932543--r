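#' @importFrom stats rnorm rlnorm rbeta rbinom runif
NULL

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every parameter of the ground-truth generator:
#' how many genes carry planted reinforcement or reversion plasticity and
#' at what magnitude, the log-normal expression noise, the
#' phenotype-regulator coupling, and the two-population Balding-Nichols
#' genotype model with elevated divergence in candidate-gene flanks.
#'
#' Defaults emulate a realistic acclimation/colonization design: three
#' stages with five samples each, 12 lowland and 11 highland resequenced
#' individuals, and three muscle phenotypes.
#'
#' @param nGenes number of genes.
#' @param nPerStage samples per stage (length-1 or named length-3).
#' @param fracReinforcement,fracReversion fractions of genes with planted
#'   reinforcement / reversion plasticity (the rest are null); must sum
#'   to at most 1.
#' @param effectMagnitude planted magnitude m as a multiple of the
#'   ancestral mean: reinforcement genes have stage means
#'   (mu, mu(1+m), mu(1+2m)); reversion genes revert past the threshold
#'   with overshoot m' = `reversionOvershoot` * m.
#' @param reversionOvershoot overshoot factor (default 1.5) so both
#'   changes of a reversion gene exceed the threshold.
#' @param noiseCv coefficient of variation of the per-sample log-normal
#'   noise on the TPM scale.
#' @param nPhenotypes number of phenotypes (default 3, as for the flight
#'   muscle).
#' @param regulatorFraction fraction of genes acting as phenotype
#'   regulators.
#' @param coupling regulator coupling strength on the standardized
#'   expression scale.
#' @param phenotypeNoiseSd sd of the Gaussian noise added to phenotypes.
#' @param nSnps number of SNPs.
#' @param nIndividualsPerPop individuals per population, default
#'   `c(lowland = 12, highland = 11)`.
#' @param fstBackground,fstCandidateFlank Balding-Nichols F for
#'   background SNPs and for SNPs in candidate-gene 2 kb flanks; both in
#'   (0, 1).
#' @param geneLength gene-body length in bp on the pseudo-chromosome.
#' @param flankWidth flank width in bp (default 2000).
#' @param seed integer seed; one global stream makes whole-dataset
#'   generation reproducible.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 1000,
                            nPerStage = c(ancestral = 5, plastic = 5,
                                          colonized = 5),
                            fracReinforcement = 0.1,
                            fracReversion = 0.3,
                            effectMagnitude = 0.8,
                            reversionOvershoot = 1.5,
                            noiseCv = 0.1,
                            nPhenotypes = 3,
                            regulatorFraction = 0.05,
                            coupling = 1,
                            phenotypeNoiseSd = 0.5,
                            nSnps = 5000,
                            nIndividualsPerPop = c(lowland = 12,
                                                   highland = 11),
                            fstBackground = 0.05,
                            fstCandidateFlank = 0.05,
                            geneLength = 3000,
                            flankWidth = 2000,
                            seed = 1) {
  if (length(nPerStage) == 1) nPerStage <- rep(nPerStage, 3)
  if (is.null(names(nPerStage))) names(nPerStage) <- STAGES
  cfg <- list(
    nGenes = as.integer(nGenes), nPerStage = nPerStage,
    fracReinforcement = fracReinforcement, fracReversion = fracReversion,
    effectMagnitude = effectMagnitude,
    reversionOvershoot = reversionOvershoot, noiseCv = noiseCv,
    nPhenotypes = as.integer(nPhenotypes),
    regulatorFraction = regulatorFraction, coupling = coupling,
    phenotypeNoiseSd = phenotypeNoiseSd, nSnps = as.integer(nSnps),
    nIndividualsPerPop = nIndividualsPerPop,
    fstBackground = fstBackground, fstCandidateFlank = fstCandidateFlank,
    geneLength = as.integer(geneLength), flankWidth = as.integer(flankWidth),
    seed = as.integer(seed)
  )
  if (cfg$fracReinforcement < 0 || cfg$fracReversion < 0 ||
      cfg$fracReinforcement + cfg$fracReversion > 1)
    stop("class fractions must be non-negative and sum to at most 1")
  counts <- c(cfg$nGenes, cfg$nPerStage, cfg$nPhenotypes, cfg$nSnps,
              cfg$nIndividualsPerPop, cfg$geneLength)
  if (any(counts <= 0)) stop("all counts must be positive")
  for (f in c(cfg$fstBackground, cfg$fstCandidateFlank))
    if (f <= 0 || f >= 1) stop("FST parameters must lie in (0, 1)")
  if (cfg$noiseCv < 0) stop("noiseCv must be non-negative")
  if (cfg$effectMagnitude < 0) stop("effectMagnitude must be non-negative")
  structure(cfg, class = "SyntheticConfig")
}

# multiplicative log-normal noise with mean 1 and the requested CV
.lnNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a three-stage expression data set with known truth
#'
#' Baseline means are log-uniform over 2..512 TPM.  A planted
#' reinforcement gene with magnitude m has stage means
#' (mu, mu(1+m), mu(1+2m)); a reversion gene (mu, mu(1+m),
#' mu(1+m) - mu m') with m' = overshoot * m, so the plastic and evolved
#' changes exceed the threshold in opposite directions; null genes keep
#' mu at every stage.  Per-sample values multiply the stage mean by
#' log-normal noise with the configured CV, so the zero-noise limit
#' reproduces the stage means exactly.
#'
#' @param config a [syntheticConfig()].
#' @return list with `se` (expression `SummarizedExperiment`) and `truth`
#'   (`DataFrame`: gene, class, magnitude, baseline mu; regulator columns
#'   are added by [simulatePhenotypes()]).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  ng <- config$nGenes
  nR <- round(ng * config$fracReinforcement)
  nV <- round(ng * config$fracReversion)
  cls <- rep("none", ng)
  planted <- sample.int(ng, nR + nV)
  cls[planted[seq_len(nR)]] <- "reinforcement"
  cls[planted[nR + seq_len(nV)]] <- "reversion"
  mu <- 2^runif(ng, 1, 9)
  m <- config$effectMagnitude
  mp <- config$reversionOvershoot * m
  stageMean <- cbind(ancestral = mu, plastic = mu, colonized = mu)
  isR <- cls == "reinforcement"
  isV <- cls == "reversion"
  stageMean[isR, "plastic"] <- mu[isR] * (1 + m)
  stageMean[isR, "colonized"] <- mu[isR] * (1 + 2 * m)
  stageMean[isV, "plastic"] <- mu[isV] * (1 + m)
  stageMean[isV, "colonized"] <- pmax(mu[isV] * (1 + m - mp), 0)
  nps <- config$nPerStage
  stage <- rep(STAGES, times = nps[STAGES])
  tpm <- matrix(0, ng, length(stage))
  for (j in seq_along(stage))
    tpm[, j] <- stageMean[, stage[j]] * .lnNoise(ng, config$noiseCv)
  rownames(tpm) <- sprintf("g%04d", seq_len(ng))
  colnames(tpm) <- sprintf("s_%s_%d", stage,
                           unlist(lapply(nps[STAGES], seq_len)))
  design <- data.frame(
    sample_id = colnames(tpm), stage = stage, tissue = "flight",
    individual = sprintf("ind_%02d", seq_along(stage))
  )
  truth <- DataFrame(
    gene = rownames(tpm),
    class = factor(cls, levels = c("reinforcement", "reversion", "none")),
    magnitude = ifelse(cls == "none", 0, m),
    mu = mu,
    row.names = rownames(tpm)
  )
  list(se = makeExpressionSE(tpm, design), truth = truth)
}

#' Simulate phenotypes coupled to regulator genes
#'
#' Marks a fraction of genes as phenotype regulators with random signs,
#' partitions them round-robin across the phenotypes, and builds each
#' phenotype as the sum of sign * coupling * standardized regulator
#' expression plus Gaussian noise, over the ancestral and colonized
#' samples (the groups for which muscle phenotypes are measured in the
#' field).  Positive regulators therefore correlate positively with
#' their phenotype by construction.
#'
#' @param sim output of [simulateExpression()].
#' @param config the same [syntheticConfig()].
#' @return list with `phenotypes` (data.frame `sample_id` + one column
#'   per phenotype, rows = ancestral and colonized samples) and `truth`
#'   (the input truth with `regulator_sign` and `regulator_phenotype`
#'   columns added).
#' @export
simulatePhenotypes <- function(sim, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  se <- sim$se
  truth <- sim$truth
  set.seed(config$seed + 1L)
  ng <- nrow(truth)
  nReg <- max(1, round(ng * config$regulatorFraction))
  regIdx <- sample.int(ng, nReg)
  signs <- sample(c(1, -1), nReg, replace = TRUE)
  phAssign <- rep_len(seq_len(config$nPhenotypes), nReg)
  truth$regulator_sign <- factor(rep("none", ng),
                                 levels = c("positive", "negative", "none"))
  truth$regulator_sign[regIdx] <- ifelse(signs > 0, "positive", "negative")
  truth$regulator_phenotype <- rep(NA_character_, ng)
  truth$regulator_phenotype[regIdx] <- sprintf("pheno%d", phAssign)
  keep <- colData(se)$stage %in% c("ancestral", "colonized")
  samples <- colnames(se)[keep]
  x <- assay(se, "tpm")[, samples, drop = FALSE]
  ph <- data.frame(sample_id = samples)
  for (k in seq_len(config$nPhenotypes)) {
    idx <- regIdx[phAssign == k]
    sg <- signs[phAssign == k]
    signal <- rep(0, length(samples))
    for (j in seq_along(idx)) {
      z <- as.numeric(scale(x[idx[j], ]))
      if (anyNA(z)) z <- rep(0, length(samples))
      signal <- signal + sg[j] * config$coupling * z
    }
    ph[[sprintf("pheno%d", k)]] <-
      signal + rnorm(length(samples), 0, config$phenotypeNoiseSd)
  }
  list(phenotypes = ph, truth = truth)
}

#' Simulate two-population genotypes and a gene annotation
#'
#' Genes are laid head-to-tail on one pseudo-chromosome with enough
#' spacing that bodies and 2 kb flanks never overlap.  SNP positions are
#' drawn uniformly over the union of all gene bodies and flanks (the
#' genic background).  Allele frequencies follow the Balding-Nichols
#' model: ancestral frequency p ~ Uniform(0.05, 0.95) and each
#' population's frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F), with
#' F = `fstBackground` everywhere except SNPs falling in the 2 kb flanks
#' of candidate genes (the planted reinforcement/reversion genes), which
#' use F = `fstCandidateFlank`.  Genotypes are Binomial(2, freq) per
#' individual.
#'
#' @param truth truth table from [simulateExpression()] (its planted
#'   classes define the candidate genes).
#' @param config the same [syntheticConfig()].
#' @return list with `gd` (a [GenotypeData-class]), `genes` (`GRanges`
#'   of gene bodies, names = gene ids), and `snpTruth` (`DataFrame`:
#'   per-SNP F used and whether it lies in a candidate flank).
#' @export
simulateGenotypes <- function(truth, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed + 2L)
  ng <- nrow(truth)
  gl <- config$geneLength
  fw <- config$flankWidth
  pitch <- gl + 2L * fw + 2000L
  starts <- fw + 1000L + pitch * (seq_len(ng) - 1L)
  chromLen <- pitch * ng + 2L * fw
  genes <- GRanges("chr1", IRanges(starts, width = gl), strand = "+")
  names(genes) <- truth$gene
  seqlengths(genes) <- c(chr1 = chromLen)
  regs <- flankRegions(genes, fw)
  universe <- GenomicRanges::reduce(unlist(regs), ignore.strand = TRUE)
  offsets <- cumsum(c(0, width(universe)))
  total <- offsets[length(offsets)]
  pos1 <- sort(sample.int(total, config$nSnps))
  seg <- findInterval(pos1, offsets + 1)
  pos <- start(universe)[seg] + (pos1 - offsets[seg]) - 1L
  snps <- GRanges("chr1", IRanges(pos, width = 1))
  candGenes <- truth$gene[truth$class != "none"]
  candFlanks <- c(regs$upstream[regs$upstream$gene %in% candGenes],
                  regs$downstream[regs$downstream$gene %in% candGenes])
  inFlank <- overlapsAny(snps, candFlanks, ignore.strand = TRUE)
  Fs <- ifelse(inFlank, config$fstCandidateFlank, config$fstBackground)
  nInd <- config$nIndividualsPerPop
  p0 <- runif(config$nSnps, 0.05, 0.95)
  geno <- matrix(NA_integer_, config$nSnps, sum(nInd))
  col0 <- 0L
  for (pp in c("lowland", "highland")) {
    fr <- rbeta(config$nSnps, p0 * (1 - Fs) / Fs, (1 - p0) * (1 - Fs) / Fs)
    for (i in seq_len(nInd[[pp]]))
      geno[, col0 + i] <- rbinom(config$nSnps, 2, fr)
    col0 <- col0 + nInd[[pp]]
  }
  colnames(geno) <- c(sprintf("low_%02d", seq_len(nInd[["lowland"]])),
                      sprintf("high_%02d", seq_len(nInd[["highland"]])))
  S4Vectors::mcols(snps)$ref <- rep("A", config$nSnps)
  S4Vectors::mcols(snps)$alt <- rep("G", config$nSnps)
  gd <- new("GenotypeData", geno = geno, snps = snps,
            pop = factor(rep(c("lowland", "highland"), nInd),
                         levels = c("lowland", "highland")))
  snpTruth <- DataFrame(F = Fs, candidate_flank = inFlank)
  list(gd = gd, genes = genes, snpTruth = snpTruth)
}

#' Write a synthetic data set to plain-text files
#'
#' Writes the expression TSV and sample sheet, the phenotype TSV, a
#' GT-only VCF v4.2, a BED6 gene annotation, a population map and the
#' truth table into a directory.
#'
#' @param sim output of [simulateExpression()].
#' @param pheno output of [simulatePhenotypes()] (or NULL to skip).
#' @param geno output of [simulateGenotypes()] (or NULL to skip).
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the written paths.
#' @export
writeSyntheticData <- function(sim, pheno = NULL, geno = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"))
  writeExpressionTSV(sim$se, paths["expression"], paths["samples"])
  truth <- if (!is.null(pheno)) pheno$truth else sim$truth
  paths["truth"] <- file.path(dir, "truth.tsv")
  write.table(as.data.frame(truth), paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(pheno)) {
    paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
    write.table(pheno$phenotypes, paths["phenotypes"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(geno)) {
    paths["vcf"] <- file.path(dir, "genotypes.vcf")
    writeGenotypeVCF(geno$gd, paths["vcf"])
    paths["bed"] <- file.path(dir, "genes.bed")
    bed <- geno$genes
    S4Vectors::mcols(bed)$name <- names(bed)
    S4Vectors::mcols(bed)$score <- 0L
    rtracklayer::export.bed(bed, paths["bed"])
    paths["popmap"] <- file.path(dir, "popmap.tsv")
    write.table(
      data.frame(sample_id = colnames(genotypes(geno$gd)),
                 population = as.character(populations(geno$gd))),
      paths["popmap"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Write GenotypeData as a minimal VCF v4.2
#'
#' GT-only records with QUAL 100 and an INFO/MQ of 60, so the default
#' site filters of [readVariants()] keep every site.
#'
#' @param gd a [GenotypeData-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGenotypeVCF <- function(gd, path) {
  g <- genotypes(gd)
  snps <- snpRanges(gd)
  con <- file(path, "w")
  on.exit(close(con))
  sl <- seqlengths(snps)
  ctg <- if (!anyNA(sl) && length(sl))
    sprintf("##contig=<ID=%s,length=%d>", names(sl), sl)
  else sprintf("##contig=<ID=%s>", unique(as.character(seqnames(snps))))
  writeLines(c(
    "##fileformat=VCFv4.2",
    ctg,
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")), con)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gtStr[is.na(g)] <- "./."
  body <- paste(
    as.character(seqnames(snps)), start(snps), ".",
    S4Vectors::mcols(snps)$ref, S4Vectors::mcols(snps)$alt,
    "100", "PASS", "MQ=60", "GT",
    apply(gtStr, 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(body, con)
  invisible(path)
}
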