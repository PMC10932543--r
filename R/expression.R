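#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats sd median wilcox.test
#' @importFrom utils read.delim write.table
NULL

#' Build an expression SummarizedExperiment
#'
#' Wraps a genes x samples TPM matrix and its sample design (stage, tissue,
#' individual) into a [SummarizedExperiment::SummarizedExperiment] with a
#' single `tpm` assay.  Stage labels must be one of `ancestral`, `plastic`,
#' `colonized`.
#'
#' @param tpm numeric matrix of non-negative TPM values, genes in rows
#'   (unique rownames), samples in columns.
#' @param design data.frame with one row per column of `tpm` and columns
#'   `sample_id`, `stage`, `tissue`, `individual`.
#' @return a `SummarizedExperiment` with assay `tpm` and the design as
#'   `colData`.
#' @export
makeExpressionSE <- function(tpm, design) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || anyDuplicated(rownames(tpm)))
    stop("gene identifiers (rownames) must be present and unique")
  if (any(tpm < 0))
    stop("TPM values must be non-negative")
  design <- as.data.frame(design)
  req <- c("sample_id", "stage", "tissue", "individual")
  if (!all(req %in% colnames(design)))
    stop("design needs columns: ", paste(req, collapse = ", "))
  miss <- setdiff(design$sample_id, colnames(tpm))
  if (length(miss))
    stop("sample(s) in the sheet but absent from the matrix: ",
         paste(miss, collapse = ", "))
  bad <- setdiff(design$stage, STAGES)
  if (length(bad))
    stop("unknown stage label(s): ", paste(unique(bad), collapse = ", "),
         "; allowed: ", paste(STAGES, collapse = ", "))
  tpm <- tpm[, design$sample_id, drop = FALSE]
  cd <- S4Vectors::DataFrame(
    stage = factor(design$stage, levels = STAGES),
    tissue = design$tissue,
    individual = design$individual,
    row.names = design$sample_id
  )
  SummarizedExperiment(assays = list(tpm = tpm), colData = cd)
}

#' Read an expression matrix and its sample sheet
#'
#' Reads a tab-separated TPM table (first column gene id, one column per
#' sample) and a sample sheet (`sample_id`, `stage`, `tissue`,
#' `individual`) and returns the assembled expression object.
#'
#' @param path path to the expression TSV.
#' @param sampleSheetPath path to the sample-sheet TSV.
#' @return a `SummarizedExperiment`, see [makeExpressionSE()].
#' @export
readExpression <- function(path, sampleSheetPath) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("malformed expression TSV: need a gene column plus samples")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate gene id(s) in ", path)
  tpm <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(tpm))
    stop("malformed expression TSV: non-numeric expression values")
  rownames(tpm) <- tab[[1]]
  sheet <- read.delim(sampleSheetPath, stringsAsFactors = FALSE)
  makeExpressionSE(tpm, sheet)
}

#' Summarize expression by colonization stage
#'
#' Computes per gene and per stage the arithmetic mean TPM, the standard
#' error of the mean (sample sd with the n-1 denominator over sqrt(n)) and
#' the sample count.  Stages with a single sample get SE = 0 and the gene
#' is flagged degenerate.
#'
#' @param se expression `SummarizedExperiment` from [makeExpressionSE()].
#' @return a [StageSummary-class] object.
#' @export
summarizeStages <- function(se) {
  stage <- colData(se)$stage
  if (any(table(stage) == 0))
    stop("every stage needs at least one sample; missing: ",
         paste(STAGES[table(stage) == 0], collapse = ", "))
  tpm <- assay(se, "tpm")
  m <- s <- n <- matrix(0, nrow(tpm), 3, dimnames = list(rownames(tpm), STAGES))
  for (st in STAGES) {
    x <- tpm[, stage == st, drop = FALSE]
    k <- ncol(x)
    m[, st] <- rowMeans(x)
    s[, st] <- if (k > 1) apply(x, 1, sd) / sqrt(k) else 0
    n[, st] <- k
  }
  degen <- rep(any(table(stage) == 1), nrow(tpm))
  new("StageSummary", mean = m, se = s, n = n, degenerate = degen)
}

#' Conserved-gene batch-effect check
#'
#' Identifies genes whose expression is conserved across all samples
#' (coefficient of variation of log2(TPM+1) at most `cvMax` and mean TPM at
#' least `tpmMin`) and compares the per-stage median expression of those
#' genes between every stage pair with an unpaired rank-based test.  Stable
#' medians (all pairwise p above the usual 0.05) indicate that batch
#' effects between sequencing groups are negligible.
#'
#' @param se expression `SummarizedExperiment`.
#' @param cvMax maximum CV of log2(TPM+1) across samples (default 0.3).
#' @param tpmMin minimum mean TPM across samples (default 1).
#' @return list with `conserved` (gene ids), `medians` (named per-stage
#'   median of conserved-gene expression) and `pairwise` (data.frame of
#'   stage pairs with rank-sum p-values).  Genes with zero mean expression
#'   are dropped before the CV is computed.
#' @export
conservedGeneCheck <- function(se, cvMax = 0.3, tpmMin = 1) {
  stage <- colData(se)$stage
  if (any(table(stage) < 2))
    stop("need at least two samples per stage")
  tpm <- assay(se, "tpm")
  lt <- log2(tpm + 1)
  mu <- rowMeans(lt)
  keep <- mu > 0
  cv <- rep(Inf, nrow(tpm))
  cv[keep] <- apply(lt[keep, , drop = FALSE], 1, sd) / mu[keep]
  conserved <- rownames(tpm)[cv <= cvMax & rowMeans(tpm) >= tpmMin]
  if (!length(conserved)) {
    warning("no gene passed the conserved-gene filter")
    return(list(conserved = character(), medians = NULL, pairwise = NULL))
  }
  sub <- tpm[conserved, , drop = FALSE]
  medians <- vapply(STAGES, function(st)
    median(sub[, stage == st, drop = FALSE]), 0)
  pairs <- utils::combn(STAGES, 2)
  pw <- data.frame(
    stage_a = pairs[1, ], stage_b = pairs[2, ],
    p = apply(pairs, 2, function(pr) {
      a <- as.numeric(sub[, stage == pr[1], drop = FALSE])
      b <- as.numeric(sub[, stage == pr[2], drop = FALSE])
      suppressWarnings(wilcox.test(a, b)$p.value)
    })
  )
  list(conserved = conserved, medians = medians, pairwise = pw)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param se expression `SummarizedExperiment`.
#' @param exprPath,sheetPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionTSV <- function(se, exprPath, sheetPath) {
  tpm <- assay(se, "tpm")
  tab <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  write.table(tab, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- colData(se)
  sheet <- data.frame(sample_id = rownames(cd), stage = as.character(cd$stage),
                      tissue = cd$tissue, individual = cd$individual)
  write.table(sheet, sheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(exprPath, sheetPath))
}
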