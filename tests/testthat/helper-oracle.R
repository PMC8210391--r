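# Seeded related pairs (mutated / truncated copies) whose global-alignment
# identity has a unique optimum. Expected identities were computed once with
# an independent Needleman-Wunsch implementation (Biopython PairwiseAligner,
# BLOSUM62, gap cost 10 + 0.5 per residue, terminal gaps penalized) and
# frozen below.
oracle_pairs <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(7)
  pairs <- list()
  for (i in 1:10) {
    n <- sample(60:120, 1)
    s <- sample(aa, n, replace = TRUE)
    t <- s
    nmut <- sample(3:12, 1)
    pos <- sample(n, nmut)
    t[pos] <- sample(aa, nmut, replace = TRUE)
    if (runif(1) < 0.5) t <- t[-sample(length(t), sample(1:4, 1))]
    pairs[[i]] <- c(paste(s, collapse = ""), paste(t, collapse = ""))
  }
  pairs
}

ORACLE_IDENTITY <- c(86.138614, 90.625000, 88.392857, 89.108911, 90.476190,
                     88.311688, 88.983051, 92.222222, 86.666667, 85.000000)
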