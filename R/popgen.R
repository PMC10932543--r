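#' @import GenomicRanges
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<-
#' @importFrom stats quantile runif
NULL

#' Read biallelic SNP genotypes from a VCF
#'
#' Loads GT genotypes with [VariantAnnotation::readVcf], keeps biallelic
#' SNPs, and applies the site filters used for the resequencing data:
#' QUAL at least `qualMin`, root-mean-square mapping quality (INFO/MQ,
#' when present) at least `mqMin`, and a minimum spacing between adjacent
#' SNPs (the first SNP of any closer pair is kept).
#'
#' @param vcfPath path to a VCF (v4.x) with a GT field.
#' @param popMap data.frame with columns `sample_id` and `population`
#'   (lowland / highland); every mapped sample must be in the VCF.
#' @param qualMin minimum QUAL (default 30); sites with missing QUAL pass.
#' @param mqMin minimum INFO/MQ (default 20), applied only when the field
#'   exists.
#' @param minSpacing minimum distance between adjacent SNPs in bp
#'   (default 5).
#' @return a [GenotypeData-class]; the number of sites dropped by each
#'   filter is reported in a message.
#' @export
readVariants <- function(vcfPath, popMap, qualMin = 30, mqMin = 20,
                         minSpacing = 5) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  miss <- setdiff(popMap$sample_id, colnames(gt))
  if (length(miss))
    stop("sample(s) in the population map but not in the VCF: ",
         paste(miss, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  fx <- VariantAnnotation::fixed(vcf)
  ref <- as.character(fx$REF)
  altList <- fx$ALT
  nAlt <- lengths(altList)
  snp <- nAlt == 1 & nchar(ref) == 1 &
    nchar(as.character(unlist(altList))[cumsum(nAlt)]) == 1
  dropped <- sum(!snp)
  qual <- fx$QUAL
  passQ <- is.na(qual) | qual >= qualMin
  mq <- if ("MQ" %in% colnames(VariantAnnotation::info(vcf)))
    VariantAnnotation::info(vcf)$MQ else rep(NA_real_, length(rr))
  passM <- is.na(mq) | mq >= mqMin
  keep <- snp & passQ & passM
  message(sprintf(
    "readVariants: %d sites; dropped %d non-biallelic/non-SNP, %d QUAL<%g, %d MQ<%g",
    length(rr), dropped, sum(snp & !passQ), qualMin,
    sum(snp & passQ & !passM), mqMin))
  rr <- rr[keep]
  gt <- gt[keep, popMap$sample_id, drop = FALSE]
  ref <- ref[keep]
  alt <- as.character(unlist(altList))[cumsum(nAlt)][keep]
  # spacing filter per chromosome, greedy from the left
  ord <- order(as.character(seqnames(rr)), start(rr))
  spKeep <- logical(length(rr))
  lastChr <- ""
  lastPos <- -Inf
  for (i in ord) {
    chr <- as.character(seqnames(rr))[i]
    pos <- start(rr)[i]
    if (chr != lastChr || pos - lastPos >= minSpacing) {
      spKeep[i] <- TRUE
      lastChr <- chr
      lastPos <- pos
    }
  }
  if (any(!spKeep))
    message(sprintf("readVariants: dropped %d SNPs closer than %d bp",
                    sum(!spKeep), minSpacing))
  rr <- rr[spKeep]
  gt <- gt[spKeep, , drop = FALSE]
  dos <- .gtToDosage(gt)
  snps <- GRanges(seqnames(rr), IRanges(start(rr), width = 1),
                  ref = ref[spKeep], alt = alt[spKeep])
  names(snps) <- NULL
  new("GenotypeData", geno = dos, snps = snps,
      pop = factor(popMap$population, levels = c("lowland", "highland")))
}

# "0/0", "0|1", "./." ... -> alt dosage
.gtToDosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  bad <- nchar(gt) != 3 & gt != "."
  if (any(bad)) stop("non-diploid GT value(s), e.g. ", gt[bad][1])
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  d
}

#' Per-site Weir-Cockerham FST components
#'
#' Computes the Weir & Cockerham (1984) variance components for every SNP
#' between the two populations: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), and the
#' per-site estimate theta = a / (a + b + c).  Missing genotypes are
#' excluded per site from the allele frequencies, observed
#' heterozygosities and sample sizes.  Sites monomorphic in the pooled
#' sample (or with fewer than 2 called individuals in a population) are
#' undefined (NA) and excluded from averages.
#'
#' @param gd a [GenotypeData-class].
#' @return `DataFrame` with `a`, `b`, `c`, `theta` per SNP.
#' @export
wcFst <- function(gd) {
  g <- genotypes(gd)
  pops <- populations(gd)
  stats <- lapply(levels(pops), function(pp) {
    sub <- unname(g[, pops == pp, drop = FALSE])
    n <- rowSums(!is.na(sub))
    list(n = n,
         p = rowSums(sub, na.rm = TRUE) / (2 * pmax(n, 1)),
         h = rowSums(sub == 1L, na.rm = TRUE) / pmax(n, 1))
  })
  n1 <- stats[[1]]$n; n2 <- stats[[2]]$n
  p1 <- stats[[1]]$p; p2 <- stats[[2]]$p
  h1 <- stats[[1]]$h; h2 <- stats[[2]]$h
  comp <- wcFstComponents(p1, p2, h1, h2, n1, n2)
  pooled <- (n1 * p1 + n2 * p2) / (n1 + n2)
  undef <- n1 < 2 | n2 < 2 | pooled <= 0 | pooled >= 1
  for (k in c("a", "b", "c", "theta")) comp[[k]][undef] <- NA_real_
  comp
}

#' Weir-Cockerham components from per-population summaries
#'
#' Direct evaluation of the WC84 estimator for two populations (r = 2)
#' from allele frequencies, observed heterozygosity proportions and
#' called sample sizes.  All arguments are vectorized over sites.
#'
#' @param p1,p2 alternate-allele frequencies per population.
#' @param h1,h2 observed heterozygote proportions per population.
#' @param n1,n2 called diploid individuals per population.
#' @return `DataFrame` with columns `a`, `b`, `c`, `theta`.
#' @export
wcFstComponents <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(tot == 0, NA_real_, a / tot)
  DataFrame(a = a, b = b, c = cc, theta = theta)
}

#' Average FST over sites
#'
#' The headline average is the weighted ratio-of-sums
#' sum(a) / sum(a + b + c) over sites with a defined estimate (the
#' weighted FST of vcftools); the unweighted mean of per-site theta is
#' available as an option.
#'
#' @param comp `DataFrame` from [wcFst()] (or a subset of its rows).
#' @param weighted use the ratio-of-sums (default) or the per-site mean.
#' @return a single FST value.
#' @export
meanFst <- function(comp, weighted = TRUE) {
  ok <- !is.na(comp$theta)
  if (!any(ok)) stop("no site with a defined FST estimate")
  if (weighted) {
    sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  } else {
    mean(comp$theta[ok])
  }
}

#' Genic and 2 kb flank regions of genes
#'
#' Expands gene bodies into three region sets: `genic` (the body),
#' `upstream` (2 kb 5' of the start, strand-aware) and `downstream`
#' (2 kb 3' of the end).  Flanks are truncated at chromosome edges when
#' sequence lengths are known.
#'
#' @param genes `GRanges` of gene bodies (strand used for flank
#'   orientation; `*` is treated as `+`).
#' @param flankWidth flank width in bp (default 2000).
#' @return named `GRangesList` with elements `genic`, `upstream`,
#'   `downstream`, each carrying the gene name in `mcols()$gene`.
#' @export
flankRegions <- function(genes, flankWidth = 2000) {
  gn <- if (!is.null(names(genes))) names(genes) else
    as.character(seq_along(genes))
  body <- granges(genes)
  strand(body)[strand(body) == "*"] <- "+"
  # flank() warns when a flank runs over a chromosome edge; trim() is the
  # intended resolution, so the interim warning is silenced
  up <- suppressWarnings(trim(flank(body, flankWidth, start = TRUE)))
  down <- suppressWarnings(trim(flank(body, flankWidth, start = FALSE)))
  out <- list(genic = body, upstream = up, downstream = down)
  GRangesList(lapply(out, function(g) {
    S4Vectors::mcols(g)$gene <- gn
    g
  }))
}

#' Assign SNPs to gene regions
#'
#' Maps every SNP to each (gene, region) interval containing it; a SNP
#' overlapping several genes is reported once per gene.  The genic
#' background is the set of SNPs hitting any gene body or flank
#' (deduplicated).
#'
#' @param genes `GRanges` of gene bodies (names = gene ids).
#' @param gd a [GenotypeData-class].
#' @param flankWidth flank width in bp (default 2000).
#' @return list with `map` (`DataFrame`: `snp` index, `gene`, `region`)
#'   and `background` (sorted unique SNP indices in any region).
#' @export
assignRegions <- function(genes, gd, flankWidth = 2000) {
  regs <- flankRegions(genes, flankWidth)
  snps <- snpRanges(gd)
  maps <- lapply(names(regs), function(rt) {
    hits <- findOverlaps(snps, regs[[rt]], ignore.strand = TRUE)
    DataFrame(snp = S4Vectors::queryHits(hits),
              gene = S4Vectors::mcols(regs[[rt]])$gene[
                S4Vectors::subjectHits(hits)],
              region = rt)
  })
  map <- do.call(rbind, maps)
  list(map = map, background = sort(unique(map$snp)))
}

#' FST permutation test against the genic background
#'
#' Compares the empirical weighted mean FST of a candidate SNP set with a
#' null distribution built by repeatedly resampling SNP sets of matched
#' size from the genic background.  Each replicate draws N' SNPs without
#' replacement, N' uniform in [ceil((1-f)N), floor((1+f)N)] with
#' f = `fluctuation` (default 5 percent) and N the candidate count.  The
#' empirical p uses the add-one convention
#' (1 + #\{permuted >= empirical\}) / (nPerm + 1); the significance flag
#' follows the percentile rule: empirical above the 95th percentile of
#' the permuted values.
#'
#' @param comp per-site WC84 components from [wcFst()].
#' @param candidate integer indices (rows of `comp`) of candidate SNPs.
#' @param background integer indices of the background pool; candidate
#'   SNPs are removed from it unless `excludeCandidate = FALSE`.
#' @param nPerm number of resamplings (default 100).
#' @param fluctuation allowed relative fluctuation of the resampled SNP
#'   count (default 0.05; use 0 for fixed-N resampling).
#' @param seed integer seed.
#' @param excludeCandidate drop candidate SNPs from the background pool
#'   before resampling (default TRUE).
#' @param setId,region labels stored in the result.
#' @return a [FstPermResult-class].
#' @export
fstPermutationTest <- function(comp, candidate, background, nPerm = 100,
                               fluctuation = 0.05, seed = 1,
                               excludeCandidate = TRUE,
                               setId = "candidates", region = "all") {
  candidate <- unique(candidate)
  candidate <- candidate[!is.na(comp$theta[candidate])]
  if (!length(candidate)) stop("no candidate SNP with a defined FST")
  background <- unique(background)
  background <- background[!is.na(comp$theta[background])]
  if (excludeCandidate) background <- setdiff(background, candidate)
  n <- length(candidate)
  hi <- floor((1 + fluctuation) * n)
  lo <- ceiling((1 - fluctuation) * n)
  if (length(background) < hi)
    stop("background (", length(background), " SNPs) smaller than the ",
         "largest resample (", hi, "); reduce candidates or fluctuation")
  emp <- meanFst(comp[candidate, , drop = FALSE])
  set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i) {
    k <- if (hi > lo) sample(lo:hi, 1) else lo
    meanFst(comp[sample(background, k), , drop = FALSE])
  }, 0)
  p <- (1 + sum(perm >= emp)) / (nPerm + 1)
  new("FstPermResult", setId = setId, region = region,
      nSnps = length(candidate), empirical = emp, permuted = perm,
      p = p, significant = emp > quantile(perm, 0.95, type = 7,
                                          names = FALSE))
}

#' Run the FST permutation test per region type for a gene set
#'
#' Convenience wrapper running [fstPermutationTest()] separately for the
#' genic, upstream and downstream SNPs of a candidate gene set, each
#' against the background of the same region assignment.
#'
#' @param comp per-site WC84 components from [wcFst()].
#' @param regionMap output of [assignRegions()].
#' @param candidateGenes character vector of candidate gene ids.
#' @param nPerm,fluctuation,seed,excludeCandidate see
#'   [fstPermutationTest()].
#' @param setId label for the candidate set.
#' @return named list of [FstPermResult-class] (one per region type with
#'   at least one defined candidate SNP).
#' @export
fstByRegion <- function(comp, regionMap, candidateGenes, nPerm = 100,
                        fluctuation = 0.05, seed = 1,
                        excludeCandidate = TRUE, setId = "candidates") {
  map <- regionMap$map
  res <- list()
  for (rt in c("genic", "upstream", "downstream")) {
    cand <- unique(map$snp[map$region == rt & map$gene %in% candidateGenes])
    cand <- cand[!is.na(comp$theta[cand])]
    if (!length(cand)) next
    res[[rt]] <- fstPermutationTest(
      comp, cand, regionMap$background, nPerm = nPerm,
      fluctuation = fluctuation, seed = seed + match(rt, c(
        "genic", "upstream", "downstream")),
      excludeCandidate = excludeCandidate, setId = setId, region = rt)
  }
  res
}
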