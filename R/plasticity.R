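#' @importFrom stats binom.test
NULL

# vectorized three-stage classifier shared with the bootstrap; El must be > 0
.classifyCore <- function(El, Eh, Ec, tau) {
  pc <- Eh - El
  ec <- Ec - Eh
  excess <- abs(pc) > tau * El & abs(ec) > tau * El
  sp <- sign(pc)
  sev <- sign(ec)
  cls <- rep.int("none", length(El))
  cls[excess & sp != 0 & sp == sev] <- "reinforcement"
  cls[excess & sp != 0 & sev != 0 & sp == -sev] <- "reversion"
  list(pc = pc, ec = ec, class = cls, M = pmin(abs(pc), abs(ec)) / El)
}

#' Classify reinforcement and reversion expression plasticity
#'
#' For each gene the plastic change PC = E_plastic - E_ancestral and the
#' evolved change EC = E_colonized - E_plastic are compared to a relative
#' threshold `tau` of the ancestral mean.  A gene shows an excess plastic
#' change when |PC| > tau * E_ancestral and an excess evolved change when
#' |EC| > tau * E_ancestral.  Genes with both excesses in the same
#' direction are reinforcement; in opposite directions, reversion; all
#' others are unclassified.  The magnitude M = min(|PC|, |EC|) /
#' E_ancestral is the binding constraint that guarantees both changes
#' clear a category's lower bound.
#'
#' Genes with a non-positive ancestral mean are excluded (the relative
#' threshold is undefined) and counted in the `excluded` attribute.
#'
#' @param summary a [StageSummary-class] from [summarizeStages()].
#' @param tau relative threshold (default 0.5, i.e. 50 percent of the
#'   ancestral level).
#' @param boundaries increasing magnitude-category boundaries passed to
#'   [magnitudeCategory()].
#' @return a `DataFrame` with one row per retained gene: `gene`, `PC`,
#'   `EC`, `rel_PC`, `rel_EC`, `class`, `M`, `category`.  Attribute
#'   `excluded` holds the ids of dropped zero-ancestral genes.
#' @export
classifyPlasticity <- function(summary, tau = 0.5,
                               boundaries = c(0.5, 1, 1.5, 2)) {
  stopifnot(is(summary, "StageSummary"))
  if (tau <= 0) stop("tau must be positive")
  m <- stageMeans(summary)
  if (any(m < 0)) stop("negative stage means are not valid TPM summaries")
  keep <- m[, "ancestral"] > 0
  excluded <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  cc <- .classifyCore(m[, "ancestral"], m[, "plastic"], m[, "colonized"], tau)
  M <- unname(ifelse(cc$class == "none", NA_real_, cc$M))
  out <- DataFrame(
    gene = rownames(m),
    PC = unname(cc$pc),
    EC = unname(cc$ec),
    rel_PC = unname(abs(cc$pc) / m[, "ancestral"]),
    rel_EC = unname(abs(cc$ec) / m[, "ancestral"]),
    class = factor(cc$class, levels = c("reinforcement", "reversion", "none")),
    M = M,
    category = magnitudeCategory(M, boundaries),
    row.names = rownames(m)
  )
  metadata(out) <- list(tau = tau, boundaries = boundaries,
                        excluded = excluded)
  attr(out, "excluded") <- excluded
  out
}

#' Magnitude category of a plasticity call
#'
#' Assigns magnitudes to disjoint half-open intervals (b_i, b_(i+1)] over
#' the configured boundaries, with an unbounded top category.  The
#' half-open convention matches the strict inequality of the excess rule
#' at the lower edge, and the disjoint intervals give independent gene
#' sets per category.
#'
#' @param M numeric vector of magnitudes (NA for unclassified genes).
#' @param boundaries strictly increasing boundaries, default
#'   `c(0.5, 1, 1.5, 2)` i.e. 50/100/150/200 percent.
#' @return factor with levels like `"(50%,100%]"`, ..., `">200%"`; NA for
#'   NA input.
#' @export
magnitudeCategory <- function(M, boundaries = c(0.5, 1, 1.5, 2)) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  pct <- function(b) sprintf("%g%%", 100 * b)
  nb <- length(boundaries)
  labs <- c(sprintf("(%s,%s]", pct(boundaries[-nb]), pct(boundaries[-1])),
            sprintf(">%s", pct(boundaries[nb])))
  if (any(!is.na(M) & M <= boundaries[1]))
    stop("internal error: classified magnitude at or below the base threshold")
  cut(M, breaks = c(boundaries, Inf), labels = labs, right = TRUE)
}

#' Bin classified genes by plasticity magnitude
#'
#' Groups classified genes into consecutive magnitude bins of a fixed
#' width starting at the base threshold, and counts reinforcement and
#' reversion genes per bin.  Alternative bin widths (20, 40, 60 percent)
#' probe the robustness of the reversion excess to the categorization
#' scheme.
#'
#' @param calls output of [classifyPlasticity()].
#' @param binWidth bin width on the magnitude scale, one of 0.2, 0.4, 0.6.
#' @param base lower edge of the first bin (defaults to the tau used for
#'   the calls).
#' @return data.frame with `bin` label, `lower`, `upper`, counts
#'   `reinforcement` and `reversion`, and the two-tailed binomial p-value
#'   per non-empty bin.
#' @export
binCategories <- function(calls, binWidth = c(0.2, 0.4, 0.6), base = NULL) {
  binWidth <- binWidth[1]
  if (!binWidth %in% c(0.2, 0.4, 0.6))
    stop("binWidth must be one of 0.2, 0.4, 0.6")
  if (is.null(base)) base <- metadata(calls)$tau
  cl <- calls[calls$class != "none", , drop = FALSE]
  mx <- if (nrow(cl)) max(cl$M) else base + binWidth
  nb <- max(1, ceiling((mx - base) / binWidth - 1e-9))
  breaks <- base + binWidth * (0:nb)
  breaks[nb + 1] <- max(breaks[nb + 1], mx)  # guard against FP shortfall
  idx <- if (nrow(cl)) cut(cl$M, breaks = breaks, right = TRUE) else factor()
  lev <- levels(cut(numeric(), breaks = breaks, right = TRUE))
  cnt <- function(klass) {
    tab <- table(factor(idx[cl$class == klass], levels = lev))
    as.integer(tab)
  }
  out <- data.frame(
    bin = lev,
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    reinforcement = cnt("reinforcement"),
    reversion = cnt("reversion")
  )
  out$p <- mapply(function(a, b)
    if (a + b > 0) binomialExcessTest(a, b) else NA_real_,
    out$reinforcement, out$reversion)
  out
}

#' Exact two-tailed binomial excess test
#'
#' Tests whether the split of genes between two classes (for example
#' reversion versus reinforcement) deviates from a null proportion, using
#' the exact two-tailed binomial test in its minimum-likelihood
#' convention: the p-value sums the probabilities of all outcomes whose
#' point probability does not exceed that of the observed count.
#'
#' @param kA count in the first class.
#' @param kB count in the second class.
#' @param p0 null proportion for the first class (default 0.5).
#' @return the two-tailed p-value.
#' @export
binomialExcessTest <- function(kA, kB, p0 = 0.5) {
  n <- kA + kB
  if (n < 1) stop("need at least one observation")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  binom.test(kA, n, p = p0, alternative = "two.sided")$p.value
}

#' Per-class and per-category counts with excess tests
#'
#' @param calls output of [classifyPlasticity()].
#' @param p0 null proportion, see [binomialExcessTest()].
#' @return data.frame with one row per magnitude category (plus an overall
#'   row): reinforcement count, reversion count, binomial p.
#' @export
plasticitySummary <- function(calls, p0 = 0.5) {
  cl <- calls[calls$class != "none", , drop = FALSE]
  levs <- levels(calls$category)
  rows <- lapply(c("all", levs), function(cat) {
    sub <- if (cat == "all") cl else cl[!is.na(cl$category) &
                                          cl$category == cat, , drop = FALSE]
    ka <- sum(sub$class == "reinforcement")
    kb <- sum(sub$class == "reversion")
    data.frame(category = cat, reinforcement = ka, reversion = kb,
               p = if (ka + kb > 0) binomialExcessTest(ka, kb, p0) else NA_real_)
  })
  do.call(rbind, rows)
}
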