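AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeq <- function(L, prob = NULL) {
  paste(sample(AA, L, replace = TRUE, prob = prob), collapse = "")
}

writeTempFasta <- function(headers, seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), f)
  f
}

## Independent Needleman-Wunsch oracle (match = 1, mismatch = 0, linear gap
## -1) returning the number of exactly matching positions on an optimal
## global alignment. Plain DP with traceback; desk-scale strings only.
bruteForceNWMatches <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0, n + 1, m + 1)  # matches on the best path
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    diag <- S[i, j] + as.integer(x[i] == y[j])
    up <- S[i, j + 1] - 1
    left <- S[i + 1, j] - 1
    best <- max(diag, up, left)
    S[i + 1, j + 1] <- best
    M[i + 1, j + 1] <- max(
      if (diag == best) M[i, j] + as.integer(x[i] == y[j]) else -Inf,
      if (up == best) M[i, j + 1] else -Inf,
      if (left == best) M[i + 1, j] else -Inf)
  }
  M[n + 1, m + 1]
}

## A balanced binary HbL/non-HbL dataset: one HbL profile vs the non-HbL
## profile, n sequences each.
balancedBinaryDataset <- function(n, seed, separation) {
  profs <- defaultProfiles(separation)[c("nonHbL", "fg_cyto_FAD_NAD")]
  generateDataset(nPerClass = n, seed = seed, profiles = profs)
}

## Tie-corrected Mann-Whitney AUC oracle from pooled ranks, independent of
## the package's threshold-sweep implementation.
mannWhitneyAUC <- function(scores, truth) {
  r <- rank(scores)  # midranks handle ties
  nPos <- sum(truth == 1); nNeg <- sum(truth == -1)
  (sum(r[truth == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
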