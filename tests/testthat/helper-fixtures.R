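# small in-code fixtures shared across test files

# expression object from a bare matrix; samples split evenly over stages
toySE <- function(tpm, stages = NULL, tissue = "flight") {
  if (is.null(rownames(tpm)))
    rownames(tpm) <- sprintf("g%02d", seq_len(nrow(tpm)))
  if (is.null(stages)) {
    k <- ncol(tpm) / 3
    stages <- rep(c("ancestral", "plastic", "colonized"), each = k)
  }
  colnames(tpm) <- sprintf("s%02d", seq_len(ncol(tpm)))
  design <- data.frame(sample_id = colnames(tpm), stage = stages,
                       tissue = tissue,
                       individual = sprintf("i%02d", seq_len(ncol(tpm))))
  makeExpressionSE(tpm, design)
}

# one-gene summary from a (ancestral, plastic, colonized) mean triple
toySummary <- function(means, ses = 0, n = 5) {
  means <- matrix(means, ncol = 3, byrow = length(means) == 3)
  ses <- matrix(ses, nrow(means), 3)
  StageSummary(means, ses, n)
}

# independent brute-force reimplementation of the three-branch
# classification rule; deliberately scalar and literal
oracleClassify <- function(el, eh, ec, tau) {
  pc <- eh - el
  ec2 <- ec - eh
  if (!(abs(pc) > tau * el)) return("none")
  if (!(abs(ec2) > tau * el)) return("none")
  if (pc > 0 && ec2 > 0) return("reinforcement")
  if (pc < 0 && ec2 < 0) return("reinforcement")
  if (pc > 0 && ec2 < 0) return("reversion")
  if (pc < 0 && ec2 > 0) return("reversion")
  "none"
}

# exact two-tailed binomial p by direct enumeration (minlike convention)
oracleBinomP <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}
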