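# planted-module expression set: each module follows its own profile with
# small independent noise; extra genes are pure noise
plantedModules <- function(nPerMod = 35, nNoise = 20, nSamp = 12, sd = 0.2,
                           seed = 1) {
  set.seed(seed)
  profiles <- lapply(list(sin(seq_len(nSamp)), cos(seq_len(nSamp)),
                          seq_len(nSamp)),
                     function(p) as.numeric(scale(p)))
  rows <- lapply(seq_along(profiles), function(k)
    t(replicate(nPerMod, 10 + profiles[[k]] + rnorm(nSamp, 0, sd))))
  noise <- matrix(10 + rnorm(nNoise * nSamp), nNoise, nSamp)
  tpm <- rbind(do.call(rbind, rows), noise)
  truth <- c(rep(paste0("T", seq_along(profiles)), each = nPerMod),
             rep("noise", nNoise))
  se <- toySE(tpm, rep(c("ancestral", "plastic", "colonized"),
                       each = nSamp / 3))
  list(se = se, truth = truth)
}

test_that("gene significance handles exact, noisy and constant genes", {
  code <- rep(0:2, each = 2)
  tpm <- rbind(exact = code, flat = rep(3, 6),
               steps = c(1, 1, 2, 2, 3, 3))
  se <- toySE(tpm, rep(c("ancestral", "plastic", "colonized"), each = 2))
  gs <- geneSignificance(se)
  expect_equal(gs["exact", "GS"], 1)
  expect_equal(gs["flat", "GS"], 0)
  expect_equal(gs["flat", "p"], 1)
  expect_equal(gs["steps", "GS"], 1)
  expect_lt(gs["steps", "p"], 0.001)
  # p-values agree with cor.test
  set.seed(2)
  x <- rnorm(6, mean = 10) + code
  se2 <- toySE(rbind(g = x), rep(c("ancestral", "plastic", "colonized"),
                                 each = 2))
  gs2 <- geneSignificance(se2)
  ct <- cor.test(x, code)
  expect_equal(gs2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(gs2$p, ct$p.value, tolerance = 1e-9)
})

test_that("block-diagonal correlation structure is recovered exactly", {
  sim <- plantedModules(nPerMod = 30, nNoise = 0, sd = 0)
  mods <- detectModules(sim$se, beta = 2, minSize = 10, cutHeight = 0.3)
  tab <- table(mods, sim$truth)
  expect_equal(sum(levels(mods) != "unassigned"), 3)
  # each planted block maps to exactly one detected module
  expect_true(all(apply(tab[rownames(tab) != "unassigned", ] > 0, 2,
                        sum) == 1))
})

test_that("planted noisy modules are recovered and noise left unassigned", {
  sim <- plantedModules(sd = 0.25, seed = 42)
  mods <- detectModules(sim$se, beta = 6, minSize = 25, cutHeight = 0.6)
  found <- mods[sim$truth != "noise"]
  agree <- table(found, sim$truth[sim$truth != "noise"])
  # every planted module recovered nearly intact
  expect_gte(sum(apply(agree, 2, max)), 0.9 * sum(sim$truth != "noise"))
  expect_gte(mean(mods[sim$truth == "noise"] == "unassigned"), 0.8)
  expect_error(detectModules(sim$se, beta = 0), "beta")
})

test_that("module eigengene matches the shared profile and fixes sign", {
  nSamp <- 9
  prof <- sin(seq_len(nSamp))
  tpm <- t(replicate(10, 5 + 2 * prof))
  rownames(tpm) <- sprintf("g%02d", 1:10)
  se <- toySE(tpm, rep(c("ancestral", "plastic", "colonized"), each = 3))
  eg <- moduleEigengene(se, rownames(tpm))
  zprof <- as.numeric(scale(prof))
  expect_equal(abs(cor(eg, zprof)), 1, tolerance = 1e-10)
  expect_gt(cor(eg, rowMeans(scale(t(tpm)))), 0)
  # flipping all gene values leaves the sign convention intact
  eg2 <- moduleEigengene(toySE(-tpm + 30,
                               rep(c("ancestral", "plastic", "colonized"),
                                   each = 3)),
                         rownames(tpm))
  expect_gt(sum(eg2 * scale(-prof)), 0)
  expect_error(moduleEigengene(se, rownames(tpm)[1]), "two genes")
})

test_that("two-gene eigengene is the closed-form sum of profiles", {
  set.seed(8)
  z1 <- rnorm(12); z2 <- 0.8 * z1 + 0.3 * rnorm(12)
  tpm <- rbind(a = 5 + z1, b = 7 + z2)
  se <- toySE(tpm, rep(c("ancestral", "plastic", "colonized"), each = 4))
  eg <- moduleEigengene(se, c("a", "b"))
  want <- as.numeric(scale(z1)) + as.numeric(scale(z2))
  expect_equal(abs(cor(eg, want)), 1, tolerance = 1e-10)
})

test_that("eigengene is invariant to gene order and per-gene rescaling", {
  sim <- plantedModules(nPerMod = 12, nNoise = 0, sd = 0.3, seed = 5)
  genes <- rownames(sim$se)[1:12]
  eg1 <- moduleEigengene(sim$se, genes)
  eg2 <- moduleEigengene(sim$se, rev(genes))
  expect_equal(eg1, eg2, tolerance = 1e-10)
  tpm <- SummarizedExperiment::assay(sim$se, "tpm")
  tpm[genes[1], ] <- tpm[genes[1], ] * 50
  se2 <- toySE(tpm, rep(c("ancestral", "plastic", "colonized"), each = 4))
  eg3 <- moduleEigengene(se2, genes)
  expect_equal(unname(eg1), unname(eg3), tolerance = 1e-8)
})

test_that("identical modules merge and stage-linked modules are flagged", {
  nSamp <- 12
  code <- rep(0:2, each = 4)
  set.seed(13)
  stageProf <- code
  m1 <- t(replicate(10, 5 + stageProf + rnorm(nSamp, 0, 0.05)))
  m2 <- t(replicate(10, 9 + 2 * stageProf + rnorm(nSamp, 0, 0.05)))
  m3 <- t(replicate(10, 5 + rep(c(1, -1), 6) + rnorm(nSamp, 0, 0.05)))
  tpm <- rbind(m1, m2, m3)
  se <- toySE(tpm, rep(c("ancestral", "plastic", "colonized"), each = 4))
  mods <- factor(rep(c("M1", "M2", "M3"), each = 10),
                 levels = c("M1", "M2", "M3", "unassigned"))
  names(mods) <- rownames(SummarizedExperiment::assay(se))
  ma <- mergeAndAssociate(se, mods)
  # the two stage-tracking modules share an eigengene and merge
  expect_equal(nrow(ma$association), 2)
  expect_equal(sum(ma$association$associated), 1)
  assocMod <- ma$association$module[ma$association$associated]
  expect_equal(sum(ma$modules == assocMod), 20)
})

test_that("hub filter applies the strict quartile and the p rule", {
  gs <- S4Vectors::DataFrame(
    gene = paste0("g", 1:4), GS = c(0.1, 0.2, 0.3, 0.4),
    r = c(0.1, 0.2, 0.3, 0.4), p = rep(0.01, 4),
    row.names = paste0("g", 1:4))
  mods <- factor(rep("M1", 4), levels = c("M1", "unassigned"))
  names(mods) <- paste0("g", 1:4)
  assoc <- data.frame(module = "M1", size = 4, r = 0.9, p = 0.001,
                      associated = TRUE)
  # type-7 first quartile of (0.1..0.4) is 0.175
  expect_equal(sort(hubGenes(gs, mods, assoc)), c("g2", "g3", "g4"))
  # ties at the quartile are excluded by the strict inequality
  gs$GS <- rep(0.3, 4)
  expect_equal(hubGenes(gs, mods, assoc), character())
  # significant GS but non-significant p is excluded
  gs$GS <- c(0.1, 0.2, 0.3, 0.9)
  gs$p <- c(0.01, 0.01, 0.01, 0.2)
  expect_equal(sort(hubGenes(gs, mods, assoc)), c("g2", "g3"))
  # no associated module -> empty
  assoc$associated <- FALSE
  expect_equal(hubGenes(gs, mods, assoc), character())
})
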