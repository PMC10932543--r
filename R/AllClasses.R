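#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

STAGES <- c("ancestral", "plastic", "colonized")

#' Per-gene, per-stage expression summary
#'
#' Holds, for every gene, the mean TPM, the standard error of the mean and
#' the sample count in each of the three colonization stages (ancestral,
#' plastic, colonized).  This triple of stage means is the input to the
#' plasticity classifier and the parametric bootstrap.
#'
#' @slot mean genes x 3 matrix of stage mean TPM.
#' @slot se genes x 3 matrix of standard errors (sd / sqrt(n); 0 when n = 1).
#' @slot n genes x 3 matrix of per-stage sample counts.
#' @slot degenerate logical; TRUE for genes where any stage has n = 1 so the
#'   SE is undefined and reported as 0.
#'
#' @seealso [summarizeStages()], [classifyPlasticity()], [bootstrapSupport()]
#' @export
setClass("StageSummary",
  representation(
    mean = "matrix",
    se = "matrix",
    n = "matrix",
    degenerate = "logical"
  )
)

setValidity("StageSummary", function(object) {
  msg <- NULL
  dims <- list(object@mean, object@se, object@n)
  if (!all(vapply(dims, ncol, 0L) == 3L))
    msg <- c(msg, "mean, se and n must have one column per stage")
  if (!all(vapply(dims, function(m) identical(colnames(m), STAGES), FALSE)))
    msg <- c(msg, sprintf("stage columns must be: %s",
                          paste(STAGES, collapse = ", ")))
  if (length(unique(vapply(dims, nrow, 0L))) != 1L)
    msg <- c(msg, "mean, se and n must have the same number of genes")
  if (any(object@se < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (any(object@n < 1))
    msg <- c(msg, "every stage needs at least one sample")
  if (any(!is.finite(object@mean)))
    msg <- c(msg, "stage means must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn StageSummary number of genes
#' @param x,object a `StageSummary`
#' @export
setMethod("length", "StageSummary", function(x) nrow(x@mean))

#' @describeIn StageSummary gene identifiers
#' @export
setMethod("names", "StageSummary", function(x) rownames(x@mean))

#' Construct a StageSummary from matrices
#'
#' Mainly useful for building toy inputs; [summarizeStages()] is the
#' usual route from expression data.
#'
#' @param mean,se genes x 3 matrices (columns ancestral, plastic,
#'   colonized) of stage means and standard errors.
#' @param n per-stage sample counts: a genes x 3 matrix or a length-3
#'   vector recycled across genes.
#' @return a [StageSummary-class].
#' @export
StageSummary <- function(mean, se, n = 2) {
  mean <- as.matrix(mean)
  se <- as.matrix(se)
  if (length(n) %in% c(1L, 3L))
    n <- matrix(n, nrow(mean), 3, byrow = TRUE)
  fix <- function(m) {
    colnames(m) <- STAGES
    if (is.null(rownames(m))) rownames(m) <- rownames(mean)
    m
  }
  if (is.null(rownames(mean)))
    rownames(mean) <- sprintf("g%03d", seq_len(nrow(mean)))
  new("StageSummary", mean = fix(mean), se = fix(se), n = fix(n),
      degenerate = apply(n == 1, 1, any))
}

#' Stage-summary accessors
#'
#' @param x a [StageSummary-class] object.
#' @return `stageMeans`, `stageSE` and `stageN` return genes x 3 matrices
#'   (columns ancestral, plastic, colonized).
#' @export
stageMeans <- function(x) x@mean

#' @rdname stageMeans
#' @export
stageSE <- function(x) x@se

#' @rdname stageMeans
#' @export
stageN <- function(x) x@n

setMethod("show", "StageSummary", function(object) {
  cat("StageSummary with", length(object), "genes\n")
  cat("  stages:", paste(STAGES, collapse = ", "), "\n")
  cat("  samples per stage:",
      paste(apply(object@n, 2, max), collapse = "/"), "\n")
  if (any(object@degenerate))
    cat("  ", sum(object@degenerate),
        "gene(s) with a single-sample stage (SE set to 0)\n")
})

#' Diploid genotypes for two populations
#'
#' Biallelic SNP genotypes coded as alternate-allele dosage (0/1/2, NA for
#' missing) for individuals assigned to a lowland and a highland population,
#' with SNP coordinates as a [GenomicRanges::GRanges] (ref/alt alleles in
#' the metadata columns).
#'
#' @slot geno integer matrix, SNPs x individuals, values 0/1/2/NA.
#' @slot snps `GRanges` of width-1 SNP positions with `ref` and `alt`
#'   metadata columns.
#' @slot pop factor of length `ncol(geno)` with levels
#'   `c("lowland", "highland")`.
#'
#' @seealso [readVariants()], [simulateGenotypes()], [wcFst()]
#' @export
setClass("GenotypeData",
  representation(
    geno = "matrix",
    snps = "GRanges",
    pop = "factor"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (nrow(object@geno) != length(object@snps))
    msg <- c(msg, "one genotype row per SNP required")
  if (ncol(object@geno) != length(object@pop))
    msg <- c(msg, "one population label per individual required")
  bad <- !(object@geno %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    msg <- c(msg, "genotypes must be alt-allele dosages 0/1/2 or NA")
  if (!identical(levels(object@pop), c("lowland", "highland")))
    msg <- c(msg, "population levels must be lowland, highland")
  if (any(table(object@pop) == 0))
    msg <- c(msg, "both populations must be non-empty")
  if (!all(c("ref", "alt") %in% colnames(S4Vectors::mcols(object@snps))))
    msg <- c(msg, "snps must carry ref and alt metadata columns")
  if (is.null(msg)) TRUE else msg
})

#' GenotypeData accessors
#'
#' @param x a [GenotypeData-class] object.
#' @return `genotypes` the SNP x individual dosage matrix; `snpRanges` the
#'   SNP `GRanges`; `populations` the per-individual population factor.
#' @export
genotypes <- function(x) x@geno

#' @rdname genotypes
#' @export
snpRanges <- function(x) x@snps

#' @rdname genotypes
#' @export
populations <- function(x) x@pop

#' @describeIn GenotypeData number of SNPs
#' @param x,object a `GenotypeData`
#' @export
setMethod("length", "GenotypeData", function(x) length(x@snps))

setMethod("show", "GenotypeData", function(object) {
  tab <- table(object@pop)
  cat("GenotypeData:", length(object), "biallelic SNPs,",
      ncol(object@geno), "individuals",
      sprintf("(%d lowland, %d highland)\n", tab[["lowland"]],
              tab[["highland"]]))
  cat("  missing genotype rate:",
      signif(mean(is.na(object@geno)), 3), "\n")
})

#' Result of the FST background-resampling permutation test
#'
#' @slot setId identifier of the candidate gene set / magnitude category.
#' @slot region region type the SNPs were drawn from
#'   (genic / upstream / downstream).
#' @slot nSnps number of candidate SNPs with a defined FST.
#' @slot empirical empirical weighted mean Weir-Cockerham FST of the
#'   candidate SNPs.
#' @slot permuted vector of weighted mean FST values from the background
#'   resamplings.
#' @slot p empirical p-value, (1 + #\{permuted >= empirical\}) / (n_perm + 1).
#' @slot significant TRUE when the empirical value exceeds the 95th
#'   percentile of the permuted distribution.
#'
#' @seealso [fstPermutationTest()]
#' @export
setClass("FstPermResult",
  representation(
    setId = "character",
    region = "character",
    nSnps = "integer",
    empirical = "numeric",
    permuted = "numeric",
    p = "numeric",
    significant = "logical"
  )
)

setValidity("FstPermResult", function(object) {
  msg <- NULL
  if (object@p < 0 || object@p > 1)
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(object@permuted) < 1)
    msg <- c(msg, "permuted distribution must be non-empty")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FstPermResult", function(object) {
  cat(sprintf(
    "FstPermResult [%s / %s]: empirical FST %.4f over %d SNPs\n",
    object@setId, object@region, object@empirical, object@nSnps))
  cat(sprintf("  %d permutations, p = %.4g, %ssignificant (95%% rule)\n",
              length(object@permuted), object@p,
              if (object@significant) "" else "not "))
})

#' FstPermResult accessors
#'
#' @param x a [FstPermResult-class] object.
#' @return `empiricalFst` the empirical weighted FST; `permutedFst` the
#'   permuted mean-FST vector; `permP` the empirical p-value;
#'   `isSignificant` the percentile-rule decision.
#' @export
empiricalFst <- function(x) x@empirical

#' @rdname empiricalFst
#' @export
permutedFst <- function(x) x@permuted

#' @rdname empiricalFst
#' @export
permP <- function(x) x@p

#' @rdname empiricalFst
#' @export
isSignificant <- function(x) x@significant
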