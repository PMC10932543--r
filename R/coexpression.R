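#' @importFrom stats cor cor.test hclust cutree as.dist quantile pt
NULL

.stageCodes <- function(se, coding = c(ancestral = 0, plastic = 1,
                                       colonized = 2)) {
  unname(coding[as.character(colData(se)$stage)])
}

# two-sided p for a Pearson r at n observations (t distribution, df n - 2)
.corP <- function(r, n) {
  r <- pmax(pmin(r, 1), -1)  # argument order keeps any dim() of r
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  ifelse(abs(r) >= 1, 0, p)
}

#' Gene significance against the stage gradient
#'
#' GS is the absolute Pearson correlation between a gene's expression and
#' a numeric coding of the three stages (default ancestral 0, plastic 1,
#' colonized 2), with the two-sided correlation p-value.  Zero-variance
#' genes get GS 0 and p 1.
#'
#' @param se expression `SummarizedExperiment`.
#' @param coding named numeric stage coding.
#' @return `DataFrame` with `gene`, `GS`, `r` (signed), `p`.
#' @export
geneSignificance <- function(se, coding = c(ancestral = 0, plastic = 1,
                                            colonized = 2)) {
  x <- assay(se, "tpm")
  if (ncol(x) < 3) stop("need at least three samples")
  code <- .stageCodes(se, coding)
  v <- apply(x, 1, sd)
  r <- rep(0, nrow(x))
  r[v > 0] <- as.numeric(cor(t(x[v > 0, , drop = FALSE]), code))
  p <- unname(ifelse(v > 0, .corP(r, ncol(x)), 1))
  DataFrame(gene = rownames(x), GS = abs(r), r = r, p = p,
            row.names = rownames(x))
}

#' Detect co-expression modules
#'
#' A simplified correlation-network clustering: adjacency is the absolute
#' Pearson correlation between gene expression profiles raised to the
#' soft power `beta`; genes are clustered by average-linkage hierarchical
#' clustering of the dissimilarity 1 - adjacency and the tree is cut at a
#' fixed height.  Clusters smaller than `minSize` are left unassigned.
#'
#' @param se expression `SummarizedExperiment`.
#' @param beta soft power (default 6).
#' @param minSize minimum module size (default 30).
#' @param cutHeight tree-cut height on the dissimilarity scale
#'   (default 0.25).
#' @return named factor over genes: module labels `"M1"`, `"M2"`, ...
#'   (decreasing size) or `"unassigned"`.
#' @export
detectModules <- function(se, beta = 6, minSize = 30, cutHeight = 0.25) {
  if (beta <= 0) stop("beta must be positive")
  x <- assay(se, "tpm")
  if (nrow(x) < minSize)
    stop("fewer genes than the minimum module size")
  suppressWarnings(adj <- abs(cor(t(x)))^beta)
  adj[!is.finite(adj)] <- 0   # zero-variance genes correlate with nothing
  diag(adj) <- 1
  hc <- hclust(as.dist(1 - adj), method = "average")
  raw <- cutree(hc, h = cutHeight)
  tab <- sort(table(raw), decreasing = TRUE)
  keep <- names(tab)[tab >= minSize]
  lab <- rep("unassigned", nrow(x))
  for (k in seq_along(keep))
    lab[raw == as.integer(keep[k])] <- paste0("M", k)
  factor(stats::setNames(lab, rownames(x)),
         levels = c(paste0("M", seq_along(keep)), "unassigned"))
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized (z-scored)
#' module submatrix, reported as one value per sample.  The sign is fixed
#' so the eigengene correlates positively with the module's mean
#' standardized profile, making it a summary of the shared expression
#' trend.
#'
#' @param se expression `SummarizedExperiment`.
#' @param genes character vector of module member genes (>= 2).
#' @return numeric vector of per-sample eigengene values (unit norm).
#' @export
moduleEigengene <- function(se, genes) {
  if (length(genes) < 2) stop("a module needs at least two genes")
  x <- assay(se, "tpm")[genes, , drop = FALSE]
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  ref <- colMeans(z)
  if (sum(eg * ref) < 0) eg <- -eg
  stats::setNames(eg, colnames(x))
}

#' Merge correlated modules and report stage-associated ones
#'
#' Iteratively merges the module pair whose eigengene correlation is most
#' significant while it clears `mergeP` (default 0.1), recomputing the
#' merged eigengene each time, then reports modules whose eigengene-stage
#' correlation has p below `assocP` (default 0.01).
#'
#' @param se expression `SummarizedExperiment`.
#' @param modules factor from [detectModules()].
#' @param coding stage coding, see [geneSignificance()].
#' @param mergeP p-value threshold for merging module eigengenes.
#' @param assocP p-value threshold for the stage association.
#' @return list with `modules` (merged assignment factor), `eigengenes`
#'   (sample x module matrix) and `association` (data.frame module, r, p,
#'   associated).
#' @export
mergeAndAssociate <- function(se, modules, coding = c(ancestral = 0,
                                                      plastic = 1,
                                                      colonized = 2),
                              mergeP = 0.1, assocP = 0.01) {
  members <- split(names(modules), modules)
  members <- members[names(members) != "unassigned" &
                       lengths(members) > 0]
  if (!length(members))
    return(list(modules = modules, eigengenes = NULL,
                association = data.frame()))
  egs <- lapply(members, function(g) moduleEigengene(se, g))
  n <- ncol(se)
  repeat {
    if (length(egs) < 2) break
    em <- do.call(cbind, egs)
    cm <- cor(em)
    pm <- .corP(cm, n)
    diag(pm) <- 1
    best <- which(pm == min(pm), arr.ind = TRUE)[1, ]
    if (min(pm) >= mergeP) break
    i <- min(best); j <- max(best)
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    egs <- lapply(members, function(g) moduleEigengene(se, g))
  }
  code <- .stageCodes(se, coding)
  assoc <- data.frame(
    module = names(members),
    size = lengths(members),
    r = vapply(egs, function(e) cor(e, code), 0),
    row.names = NULL
  )
  assoc$p <- .corP(assoc$r, n)
  assoc$associated <- assoc$p < assocP
  merged <- rep("unassigned", length(modules))
  names(merged) <- names(modules)
  for (k in seq_along(members)) merged[members[[k]]] <- names(members)[k]
  list(
    modules = factor(merged, levels = c(names(members), "unassigned")),
    eigengenes = do.call(cbind, egs),
    association = assoc
  )
}

#' Hub genes of stage-associated modules
#'
#' Within the genes belonging to stage-associated modules, hub genes are
#' those whose gene significance exceeds the first quartile of GS
#' (type-7 linearly interpolated quartile, strict inequality) and whose
#' stage-correlation p is below `alpha`.
#'
#' @param gs `DataFrame` from [geneSignificance()].
#' @param modules merged module assignment (factor over genes).
#' @param association association table from [mergeAndAssociate()].
#' @param alpha correlation p threshold (default 0.05).
#' @return character vector of hub gene ids.
#' @export
hubGenes <- function(gs, modules, association, alpha = 0.05) {
  if (!nrow(association) || !any(association$associated))
    return(character())
  keepMods <- association$module[association$associated]
  inMod <- names(modules)[modules %in% keepMods]
  sub <- gs[gs$gene %in% inMod, , drop = FALSE]
  if (!nrow(sub)) return(character())
  q1 <- quantile(sub$GS, 0.25, type = 7, names = FALSE)
  sub$gene[sub$GS > q1 & sub$p < alpha]
}
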