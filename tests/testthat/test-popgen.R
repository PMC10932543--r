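# GenotypeData straight from a dosage matrix (rows = SNPs at 1-based pos)
toyGD <- function(geno, pos = NULL, pops = NULL) {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 100
  if (is.null(pops))
    pops <- rep(c("lowland", "highland"), each = ncol(geno) / 2)
  snps <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(pos, width = 1),
                                 ref = "A", alt = "G")
  colnames(geno) <- sprintf("i%02d", seq_len(ncol(geno)))
  new("GenotypeData", geno = geno, snps = snps,
      pop = factor(pops, levels = c("lowland", "highland")))
}

test_that("WC84 components match hand-evaluated cases exactly", {
  # fixed difference, 10 diploids per population
  comp <- wcFstComponents(1, 0, 0, 0, 10, 10)
  expect_equal(comp$a, 0.5, tolerance = 1e-12)
  expect_equal(comp$b, 0, tolerance = 1e-12)
  expect_equal(comp$c, 0, tolerance = 1e-12)
  expect_equal(comp$theta, 1, tolerance = 1e-12)
  # no divergence, full heterozygosity: theta = -1/18
  comp2 <- wcFstComponents(0.5, 0.5, 0.5, 0.5, 10, 10)
  expect_equal(comp2$theta, -1 / 18, tolerance = 1e-12)
})

test_that("per-site FST flags monomorphic sites undefined", {
  g <- rbind(fixeddiff = c(2, 2, 2, 0, 0, 0),
             mono = c(0, 0, 0, 0, 0, 0),
             allhet = c(1, 1, 1, 1, 1, 1))
  comp <- wcFst(toyGD(g))
  expect_equal(comp$theta[1], 1)
  expect_true(is.na(comp$theta[2]))
  expect_equal(comp$theta[3], wcFstComponents(0.5, 0.5, 1, 1, 3, 3)$theta,
               tolerance = 1e-12)
  expect_false(is.na(comp$theta[3]))
})

test_that("theta is invariant to allele-label swap and bounded by 1", {
  set.seed(31)
  g <- matrix(rbinom(200 * 20, 2, runif(200, 0.1, 0.9)), 200, 20)
  gd1 <- toyGD(g)
  gd2 <- toyGD(2 - g)
  c1 <- wcFst(gd1)
  c2 <- wcFst(gd2)
  expect_equal(c1$theta, c2$theta, tolerance = 1e-12)
  expect_true(all(c1$theta <= 1, na.rm = TRUE))
})

test_that("missing genotypes are excluded per site", {
  g <- rbind(c(2, 2, NA, 0, 0, 0))
  comp <- wcFst(toyGD(g))
  # same as a fixed difference with n1 = 2, n2 = 3
  byhand <- wcFstComponents(1, 0, 0, 0, 2, 3)
  expect_equal(comp$theta, byhand$theta, tolerance = 1e-12)
})

test_that("weighted mean FST is the ratio of sums", {
  comp <- S4Vectors::DataFrame(a = c(0.5, 0), b = c(0, 0.05),
                               c = c(0, 0.2), theta = c(1, 0))
  expect_equal(meanFst(comp), 0.5 / 0.75)
  expect_equal(meanFst(comp, weighted = FALSE), 0.5)
  one <- comp[1, ]
  expect_equal(meanFst(one), one$theta)
  comp$theta <- NA_real_
  expect_error(meanFst(comp), "no site")
})

test_that("mean FST over Balding-Nichols SNPs tracks the F parameter", {
  for (f in c(0.05, 0.2)) {
    cfg <- syntheticConfig(nGenes = 60, nSnps = 10000,
                           fracReinforcement = 0, fracReversion = 0,
                           nIndividualsPerPop = c(lowland = 25,
                                                  highland = 25),
                           fstBackground = f, fstCandidateFlank = f,
                           seed = 19)
    sim <- simulateExpression(cfg)
    gn <- simulateGenotypes(sim$truth, cfg)
    est <- meanFst(wcFst(gn$gd))
    expect_lt(abs(est - f), 0.03)
  }
})

test_that("gene flanks respect strand and chromosome edges", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1001, 5001),
                                                   width = 1000),
                                  strand = c("+", "-"))
  names(genes) <- c("gplus", "gminus")
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = 8000)
  regs <- flankRegions(genes, 2000)
  up <- regs$upstream
  expect_equal(GenomicRanges::start(up[up$gene == "gplus"]), 1)
  expect_equal(GenomicRanges::end(up[up$gene == "gplus"]), 1000)
  # minus-strand upstream sits 3' of the body in genome coordinates
  expect_equal(GenomicRanges::start(up[up$gene == "gminus"]), 6001)
  expect_equal(GenomicRanges::end(up[up$gene == "gminus"]), 8000)
  down <- regs$downstream
  expect_equal(GenomicRanges::start(down[down$gene == "gplus"]), 2001)
  expect_equal(GenomicRanges::end(down[down$gene == "gminus"]), 5000)
  expect_true(all(GenomicRanges::width(regs$genic) == 1000))
})

test_that("SNPs map to genic and flank intervals with exact boundaries", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
                                  strand = "+")
  names(genes) <- "g"
  # 1-based positions: 1000 = last upstream base, 1001 = first genic,
  # 2000 = last genic, 2001 = first downstream
  gd <- toyGD(matrix(c(0, 2), 4, 2,
                     dimnames = list(NULL, c("a", "b"))),
              pos = c(1000, 1001, 2000, 2001),
              pops = c("lowland", "highland"))
  map <- assignRegions(genes, gd)$map
  reg <- map$region[order(map$snp)]
  expect_equal(reg, c("upstream", "genic", "genic", "downstream"))
  expect_equal(assignRegions(genes, gd)$background, 1:4)
})

test_that("permutation test is exact in the degenerate all-candidate case", {
  set.seed(41)
  g <- matrix(rbinom(80 * 10, 2, 0.4), 80, 10)
  comp <- wcFst(toyGD(g))
  ok <- which(!is.na(comp$theta))
  res <- fstPermutationTest(comp, ok, ok, nPerm = 50, fluctuation = 0,
                            seed = 1, excludeCandidate = FALSE)
  expect_equal(permutedFst(res), rep(empiricalFst(res), 50))
  expect_equal(permP(res), 1)
  expect_false(isSignificant(res))
  # background too small for the requested fluctuation
  expect_error(fstPermutationTest(comp, ok[1:40], ok[1:41], nPerm = 10,
                                  fluctuation = 0.05, seed = 1,
                                  excludeCandidate = FALSE),
               "smaller than")
})

test_that("permutation test is reproducible and detects planted divergence", {
  cfg <- syntheticConfig(nGenes = 80, nSnps = 4000,
                         fracReinforcement = 0.1, fracReversion = 0.15,
                         fstBackground = 0.05, fstCandidateFlank = 0.4,
                         seed = 23)
  sim <- simulateExpression(cfg)
  gn <- simulateGenotypes(sim$truth, cfg)
  comp <- wcFst(gn$gd)
  rmap <- assignRegions(gn$genes, gn$gd)
  cand <- which(gn$snpTruth$candidate_flank)
  r1 <- fstPermutationTest(comp, cand, rmap$background, seed = 9)
  r2 <- fstPermutationTest(comp, cand, rmap$background, seed = 9)
  expect_identical(permutedFst(r1), permutedFst(r2))
  expect_true(isSignificant(r1))
  expect_lte(permP(r1), 0.05)
  # region-wise wrapper: elevated flanks, quiet gene bodies
  candGenes <- sim$truth$gene[sim$truth$class != "none"]
  byreg <- fstByRegion(comp, rmap, candGenes, seed = 3)
  expect_true(byreg$upstream@significant)
  expect_true(byreg$downstream@significant)
  expect_false(byreg$genic@significant)
})

test_that("VCF round-trip and site filters behave as specified", {
  cfg <- syntheticConfig(nGenes = 30, nSnps = 400, seed = 3)
  sim <- simulateExpression(cfg)
  gn <- simulateGenotypes(sim$truth, cfg)
  tmp <- tempfile(); dir.create(tmp)
  paths <- writeSyntheticData(sim, geno = gn, dir = tmp)
  pm <- read.delim(paths[["popmap"]])
  gd2 <- suppressMessages(readVariants(paths[["vcf"]], pm, minSpacing = 1))
  expect_equal(length(gd2), length(gn$gd))
  expect_equal(unname(genotypes(gd2)), unname(genotypes(gn$gd)))
  expect_equal(GenomicRanges::start(snpRanges(gd2)),
               GenomicRanges::start(snpRanges(gn$gd)))
  # spacing filter keeps the first of any too-close pair
  vcf2 <- file.path(tmp, "spaced.vcf")
  gdToy <- toyGD(matrix(c(0, 1, 2, 0, 1, 2, 0, 1), 4, 2),
                 pos = c(100, 103, 120, 124),
                 pops = c("lowland", "highland"))
  writeGenotypeVCF(gdToy, vcf2)
  pm2 <- data.frame(sample_id = c("i01", "i02"),
                    population = c("lowland", "highland"))
  gd3 <- suppressMessages(readVariants(vcf2, pm2, minSpacing = 5))
  expect_equal(GenomicRanges::start(snpRanges(gd3)), c(100, 120))
  expect_error(suppressMessages(
    readVariants(vcf2, data.frame(sample_id = "zz",
                                  population = "lowland"))),
    "not in the VCF")
  # BED annotation round-trips through rtracklayer
  genes2 <- rtracklayer::import(paths[["bed"]])
  expect_equal(GenomicRanges::start(genes2),
               GenomicRanges::start(gn$genes))
  expect_equal(genes2$name, names(gn$genes))
})
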