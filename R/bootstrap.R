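#' @importFrom stats rnorm
NULL

# order-invariant 32-bit seed per gene, derived from the global seed and the
# gene identifier (FNV-style string hash)
.geneSeed <- function(seed, id) {
  h <- 2166136261
  for (k in utf8ToInt(id)) h <- ((h * 16777619) %% 2147483647 + k) %% 2147483647
  as.integer((h + seed) %% 2147483647)
}

#' Parametric-bootstrap support for plasticity calls
#'
#' Guards each gene's reinforcement/reversion call against random sampling
#' error.  For every replicate one Gaussian value is drawn per stage with
#' mean equal to the observed stage mean and standard deviation equal to
#' the standard error of that mean; the three draws are reclassified with
#' the same rule as the point estimate.  Support is the number of
#' replicates reproducing the point call; a call is supported when support
#' reaches `supportMin` of `nRep` (default 950 of 1000, a 5 percent
#' error rate).
#'
#' Gaussian draws can be negative; draws are used as-is except replicates
#' whose ancestral draw is non-positive (the relative threshold would be
#' undefined), which are redrawn wholly a bounded number of times.
#'
#' @param summary a [StageSummary-class].
#' @param tau relative threshold used for the point calls.
#' @param nRep number of bootstrap replicates (default 1000).
#' @param supportMin replicates required to flag a call supported
#'   (default 95 percent of `nRep`, i.e. 950 of 1000).
#' @param seed integer seed; per-gene substreams are derived from it so
#'   results do not depend on gene order.
#' @param mode `"class"` counts replicates reproducing the gene's specific
#'   point class; `"any"` counts replicates landing in either classified
#'   group.
#' @return `DataFrame` with `gene`, `class` (point call), `support`,
#'   `supported`.
#' @export
bootstrapSupport <- function(summary, tau = 0.5, nRep = 1000,
                             supportMin = ceiling(0.95 * nRep), seed = 1,
                             mode = c("class", "any")) {
  mode <- match.arg(mode)
  if (nRep < 1) stop("nRep must be at least 1")
  if (supportMin > nRep) stop("supportMin cannot exceed nRep")
  calls <- classifyPlasticity(summary, tau = tau)
  m <- stageMeans(summary)[calls$gene, , drop = FALSE]
  s <- stageSE(summary)[calls$gene, , drop = FALSE]
  support <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- calls$gene[i]
    set.seed(.geneSeed(seed, g))
    el <- rnorm(nRep, m[i, "ancestral"], s[i, "ancestral"])
    eh <- rnorm(nRep, m[i, "plastic"], s[i, "plastic"])
    ec <- rnorm(nRep, m[i, "colonized"], s[i, "colonized"])
    for (it in seq_len(50)) {
      bad <- el <= 0
      if (!any(bad)) break
      el[bad] <- rnorm(sum(bad), m[i, "ancestral"], s[i, "ancestral"])
      eh[bad] <- rnorm(sum(bad), m[i, "plastic"], s[i, "plastic"])
      ec[bad] <- rnorm(sum(bad), m[i, "colonized"], s[i, "colonized"])
    }
    ok <- el > 0
    cls <- .classifyCore(el[ok], eh[ok], ec[ok], tau)$class
    support[i] <- if (mode == "class")
      sum(cls == as.character(calls$class[i]))
    else if (calls$class[i] == "none") sum(cls == "none")
    else sum(cls != "none")
  }
  DataFrame(
    gene = calls$gene,
    class = calls$class,
    support = support,
    supported = support >= supportMin,
    row.names = calls$gene
  )
}

#' Merge bootstrap support into a plasticity-call table
#'
#' @param calls output of [classifyPlasticity()].
#' @param boot output of [bootstrapSupport()] for the same genes.
#' @return `calls` with `support` and `supported` columns appended.
#' @export
addBootstrapSupport <- function(calls, boot) {
  idx <- match(calls$gene, boot$gene)
  if (anyNA(idx)) stop("bootstrap table is missing genes present in calls")
  calls$support <- boot$support[idx]
  calls$supported <- boot$supported[idx]
  calls
}
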