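# Independent oracles, coded without reference to the package internals.

# Brute-force chi-square homogeneity score: builds the 2 x K contingency
# table over the union of observed letters explicitly, computes expected
# counts from the margins cell by cell, and normalizes by sqrt(chi2 / N).
oracle_chi_score <- function(s1, s2) {
  l1 <- strsplit(s1, "")[[1]]
  l2 <- strsplit(s2, "")[[1]]
  letters_seen <- sort(unique(c(l1, l2)))
  O <- rbind(vapply(letters_seen, function(a) sum(l1 == a), 0),
             vapply(letters_seen, function(a) sum(l2 == a), 0))
  O <- O[, colSums(O) > 0, drop = FALSE]
  N <- sum(O)
  chi2 <- 0
  for (i in 1:2) {
    for (j in seq_len(ncol(O))) {
      E <- sum(O[i, ]) * sum(O[, j]) / N
      chi2 <- chi2 + (O[i, j] - E)^2 / E
    }
  }
  unname(sqrt(chi2 / N))
}

# Closed-form ordinary least squares via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Textbook Welch two-sample two-tailed t-test.
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# Random canonical-alphabet sequence (test fixture helper).
random_sequence <- function(L, seed) {
  set.seed(seed)
  paste(sample(comphom::AMINO_ACIDS, L, replace = TRUE), collapse = "")
}
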