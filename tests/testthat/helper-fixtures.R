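# small in-code fixtures shared across test files

# three tiny aligned blocks with deterministic content
makeToyBlocks <- function(n = 12, p = 4, seed = 42) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  expr <- matrix(rnorm(n * p), n, p,
                 dimnames = list(ids, paste0("gene", seq_len(p))))
  geno <- matrix(rbinom(n * p, 2, 0.3), n, p,
                 dimnames = list(ids, paste0("snp", seq_len(p))))
  meth <- matrix(plogis(rnorm(n * p)), n, p,
                 dimnames = list(ids, paste0("cpg", seq_len(p))))
  list(expression = OmicsBlock(expr, "expression"),
       genotype = OmicsBlock(geno, "genotype"),
       methylation = OmicsBlock(meth, "methylation"))
}

# proportional-hazards survival data driven by a given linear predictor
makePHSurvival <- function(eta, censRate = 0.3, seed = 7) {
  set.seed(seed)
  n <- length(eta)
  tt <- rexp(n, exp(eta))
  cc <- if (censRate > 0) rexp(n, censRate) else rep(Inf, n)
  SurvivalData(sprintf("s%02d", seq_len(n)), pmin(tt, cc), as.numeric(tt <= cc))
}

# brute-force concordance oracle: explicit double loop over pairs
bruteForceC <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Mann-Whitney AUC by explicit pair enumeration (oracle)
mannWhitneyAuc <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
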