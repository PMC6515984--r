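## Independent reference implementations used to cross-check the package.
## These are deliberately naive (brute force, enumeration, closed form)
## and share no code with the implementations they verify.

## naive substring peptide-to-protein mapping
oracleClassify <- function(peptides, proteome) {
  seqs <- as.character(proteome)
  names(seqs) <- names(proteome)
  lapply(peptides, function(p) {
    ids <- sort(names(seqs)[vapply(seqs, function(s)
      grepl(p, s, fixed = TRUE), logical(1))])
    cls <- if (length(ids) == 1L) "1a"
      else if (length(ids) > 1L && length(unique(seqs[ids])) == 1L) "3a"
      else if (length(ids) > 1L) "ambiguous" else "unmapped"
    list(ids = ids, class = cls)
  })
}

## brute-force tryptic fragments with <= mc retained internal sites
oracleDigest <- function(sequence, mc) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n & res[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  out <- character()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:length(bounds[-1L])) {
      if (j - i > mc) next
      if (j > length(bounds) - 1L) next
      out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  out
}

## exhaustive scan over every candidate FDR cutoff
oracleFdrThreshold <- function(score, isDecoy, target) {
  best <- Inf
  for (t in sort(unique(score))) {
    nt <- sum(!isDecoy & score >= t)
    nd <- sum(isDecoy & score >= t)
    if (nt > 0 && nd / nt <= target) {
      best <- t
      break
    }
  }
  best
}

## plain-R affine-gap Smith-Waterman (three-state DP), independent of
## Biostrings
oracleSW <- function(a, b, mat, gapOpen, gapExtend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExtend,
                     X[i - 1, j] - gapExtend)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExtend,
                     Y[i, j - 1] - gapExtend)
      best <- max(best, M[i, j])
    }
  }
  best
}

## full enumeration of the hypergeometric 2x2 distribution at fixed margins
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  pr <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)),
    numeric(1))
  obs <- pr[xs == a]
  list(pmf = setNames(pr, xs),
       two_sided = sum(pr[pr <= obs * (1 + 1e-7)]),
       greater = sum(pr[xs >= a]),
       less = sum(pr[xs <= a]))
}

## hand-applied BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## hand-applied Holm-Sidak step-down
oracleHolmSidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

## small random protein for fixtures
randomAA <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                     "G", "H", "I", "L", "K", "M", "F",
                                     "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
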