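#' @importFrom stats complete.cases p.adjust
NULL

#' Correlate gene expression with muscle phenotypes
#'
#' Pearson correlation (and its two-sided p-value) between every gene's
#' TPM profile and every phenotype, computed over the samples for which
#' phenotypes were measured — by default the ancestral and colonized
#' individuals, since phenotypes are collected in the field populations
#' and not in the acclimation chamber.
#'
#' @param se expression `SummarizedExperiment`.
#' @param phenotypes data.frame with a `sample_id` column plus one numeric
#'   column per phenotype; NA rows are dropped per phenotype.
#' @param samples sample ids to use; defaults to all ancestral and
#'   colonized samples present in both tables.
#' @return `DataFrame` with `gene`, `phenotype`, `r`, `p`, `n`.  Zero
#'   variance genes/phenotypes are excluded.
#' @export
phenotypeCorrelation <- function(se, phenotypes, samples = NULL) {
  if (!"sample_id" %in% colnames(phenotypes))
    stop("phenotype table needs a sample_id column")
  if (is.null(samples)) {
    st <- colData(se)$stage
    samples <- colnames(se)[st %in% c("ancestral", "colonized")]
  }
  if (length(setdiff(samples, colnames(se))))
    stop("sample id(s) absent from the expression matrix: ",
         paste(setdiff(samples, colnames(se)), collapse = ", "))
  samples <- intersect(samples, phenotypes$sample_id)
  if (length(samples) < 3)
    stop("need phenotype values for at least three expression samples")
  x <- assay(se, "tpm")[, samples, drop = FALSE]
  ph <- phenotypes[match(samples, phenotypes$sample_id), , drop = FALSE]
  pnames <- setdiff(colnames(ph), "sample_id")
  res <- lapply(pnames, function(pn) {
    y <- ph[[pn]]
    ok <- !is.na(y)
    if (sum(ok) < 3 || sd(y[ok]) == 0) return(NULL)
    xs <- x[, ok, drop = FALSE]
    v <- apply(xs, 1, sd) > 0
    r <- as.numeric(cor(t(xs[v, , drop = FALSE]), y[ok]))
    DataFrame(gene = rownames(xs)[v], phenotype = pn, r = r,
              p = .corP(r, sum(ok)), n = sum(ok))
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    stop("no phenotype with variance over at least three samples")
  out
}

#' Call positive and negative regulators
#'
#' A gene is a positive (negative) regulator of a phenotype when its
#' expression correlates positively (negatively) with that phenotype at
#' p below `alpha`.  Genes significant for several phenotypes with
#' conflicting signs are flagged; the gene-level summary keeps the
#' phenotype with the smallest p.
#'
#' @param correlations output of [phenotypeCorrelation()].
#' @param alpha significance threshold on the raw correlation p
#'   (default 0.05).
#' @param adjust optional multiple-testing adjustment method passed to
#'   [stats::p.adjust] (applied per phenotype across genes); `"none"` by
#'   default, matching raw-p regulator calling.
#' @return list with `perPhenotype` (significant gene x phenotype calls
#'   with `sign`) and `perGene` (one row per regulator gene: best
#'   phenotype, r, p, sign, `conflict` flag).
#' @export
classifyRegulators <- function(correlations, alpha = 0.05,
                               adjust = "none") {
  cc <- correlations
  cc$p_use <- if (identical(adjust, "none")) cc$p else {
    unsplit(lapply(split(cc$p, cc$phenotype), p.adjust, method = adjust),
            cc$phenotype)
  }
  sig <- cc[cc$p_use < alpha, , drop = FALSE]
  sig$sign <- factor(ifelse(sig$r > 0, "positive", "negative"),
                     levels = c("positive", "negative"))
  if (!nrow(sig))
    return(list(perPhenotype = sig,
                perGene = DataFrame(gene = character(), phenotype = character(),
                                    r = numeric(), p = numeric(),
                                    sign = factor(levels = c("positive", "negative")),
                                    conflict = logical())))
  ord <- order(sig$gene, sig$p_use)
  sig <- sig[ord, , drop = FALSE]
  first <- !duplicated(sig$gene)
  conflict <- vapply(split(as.character(sig$sign), sig$gene),
                     function(s) length(unique(s)) > 1, TRUE)
  per <- sig[first, c("gene", "phenotype", "r", "p", "sign"), drop = FALSE]
  per$conflict <- unname(conflict[per$gene])
  rownames(per) <- per$gene
  list(perPhenotype = sig, perGene = per)
}

#' Adaptive versus maladaptive plasticity
#'
#' For regulator genes with an excess plastic change, the direction of the
#' plastic change is compared with the regulator's sign: plasticity is
#' adaptive when a positive regulator increases (or a negative regulator
#' decreases) expression at the plastic stage, and maladaptive in the
#' opposite configuration.  Genes without an excess plastic change
#' (|PC| <= tau * ancestral mean) get `none`.
#'
#' @param calls output of [classifyPlasticity()] (provides PC and the
#'   relative plastic change; its tau is reused).
#' @param regulators `perGene` table from [classifyRegulators()].
#' @return `DataFrame` over regulator genes present in `calls`: `gene`,
#'   `sign`, `PC`, `rel_PC`, `adaptive` factor
#'   (adaptive / maladaptive / none).
#' @export
classifyAdaptive <- function(calls, regulators) {
  tau <- metadata(calls)$tau
  idx <- match(regulators$gene, calls$gene)
  keep <- !is.na(idx)
  reg <- regulators[keep, , drop = FALSE]
  sub <- calls[idx[keep], , drop = FALSE]
  excess <- sub$rel_PC > tau
  up <- sub$PC > 0
  lab <- rep("none", nrow(reg))
  pos <- as.character(reg$sign) == "positive"
  lab[excess & ((pos & up) | (!pos & !up))] <- "adaptive"
  lab[excess & ((pos & !up) | (!pos & up))] <- "maladaptive"
  DataFrame(
    gene = reg$gene,
    sign = reg$sign,
    PC = sub$PC,
    rel_PC = sub$rel_PC,
    adaptive = factor(lab, levels = c("adaptive", "maladaptive", "none")),
    row.names = reg$gene
  )
}
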