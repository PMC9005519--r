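# Independent brute-force affine-gap local alignment oracle.
#
# Plain three-matrix Gotoh DP written directly from the scoring definition
# (gap of length k costs open + k * extend; local alignment may start and
# end anywhere; 'N' never matches). Returns the best score over both
# strands, 0 if no positive-scoring alignment exists. Kept deliberately
# simple and separate from the package's aligner.

oracle_local_score_one <- function(q, r, match, mismatch, open, extend) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in ref (consumes query)
  F <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes ref)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (qs[i] == rs[j] && qs[i] != "N") match else -mismatch
      E[i + 1, j + 1] <- max(H[i, j + 1] - open - extend,
                             E[i, j + 1] - extend)
      F[i + 1, j + 1] <- max(H[i + 1, j] - open - extend,
                             F[i + 1, j] - extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + s,
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_local_score <- function(q, r, params) {
  max(oracle_local_score_one(q, r, params$match, params$mismatch_penalty,
                             params$gap_open, params$gap_extend),
      oracle_local_score_one(oracle_revcomp(q), r, params$match,
                             params$mismatch_penalty, params$gap_open,
                             params$gap_extend))
}
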