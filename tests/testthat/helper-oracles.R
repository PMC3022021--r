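# Independent oracles, coded separately from the package implementation.

# Gotoh affine-gap local alignment score, plain dynamic programming.
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)      # best ending in match/mismatch or start
  E <- matrix(NEG, n + 1, m + 1)    # gap in b (deletion from a)
  F <- matrix(NEG, n + 1, m + 1)    # gap in a
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                   E[i - 1, j] - gap_extend)
    F[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                   F[i, j - 1] - gap_extend)
    s <- mat[av[i - 1], bv[j - 1]]
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

# NG86 synonymous site count of one codon, by direct enumeration:
# fraction of the nine single-base changes that are synonymous (changes
# to stop codons count as nonsynonymous opportunity).
oracle_syn_sites <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (nb in setdiff(bases, substring(codon, pos, pos))) {
      new <- codon
      substring(new, pos, pos) <- nb
      if (code[[new]] != "*" && code[[new]] == code[[codon]]) syn <- syn + 1
    }
  }
  syn / 3
}

# NG86 difference counts between two codons by explicit recursive
# enumeration of every mutation order; orders passing through a stop are
# discarded (all orders used if every one is blocked).
oracle_pair_counts <- function(c1, c2, code) {
  walk <- function(cur, remaining, allow_stop) {
    if (!length(remaining)) return(list(c(non = 0, syn = 0)))
    out <- list()
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      if (!allow_stop && code[[nxt]] == "*") next
      step <- if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*")
        c(non = 0, syn = 1) else c(non = 1, syn = 0)
      for (rest in walk(nxt, remaining[-k], allow_stop))
        out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffs)) return(c(non = 0, syn = 0))
  paths <- walk(c1, diffs, allow_stop = FALSE)
  if (!length(paths)) paths <- walk(c1, diffs, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}
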