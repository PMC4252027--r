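# Independent brute-force oracles. These deliberately avoid the package's
# code paths: the step-up definition is evaluated literally, the Fisher tail
# is summed term by term, motif matching enumerates offsets position by
# position, and uORFs are enumerated per reading frame.

# Literal step-up BH: q_(i) = min_{k >= i} p_(k) * m / k, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# One-tailed (enrichment) Fisher p by direct hypergeometric summation:
# drawing n1 from N = n1 + n2 genes of which K = k1 + k2 carry a hit,
# P(X >= k1) summed over exact table probabilities.
oracle_fisher_tail <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  N <- n1 + n2
  ks <- k1:min(K, n1)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1)))
}

# Position-by-position motif enumeration on one sequence.
oracle_scan <- function(seq, consensus) {
  sets <- list()
  i <- 1L
  chars <- strsplit(consensus, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      while (chars[j] != "]") j <- j + 1L
      sets[[length(sets) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      sets[[length(sets) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  s <- strsplit(seq, "")[[1]]
  k <- length(sets)
  hits <- 0L
  if (length(s) < k) return(0L)
  for (off in 0:(length(s) - k)) {
    ok <- TRUE
    for (p in seq_len(k)) {
      if (!s[off + p] %in% sets[[p]]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# Exhaustive per-frame uORF enumeration: codonise each of the 3 frames,
# pair every ATG codon with the first downstream in-frame stop, keep the
# outermost ATG per stop, apply the peptide-length filter.
oracle_uorfs <- function(utr5, min_codons = 1L) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(utr5)
  res <- NULL
  for (f in 0:2) {
    starts_nt <- seq(1 + f, L - 2, by = 3)
    if (length(starts_nt) == 0 || starts_nt[1] > L - 2) next
    codons <- substring(utr5, starts_nt, starts_nt + 2)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    used_stops <- integer(0)
    for (a in atg) {
      after <- stp[stp > a]
      if (length(after) == 0) next
      s <- after[1]
      if (s %in% used_stops) next
      n_codons <- s - a
      if (n_codons < min_codons) next
      used_stops <- c(used_stops, s)
      res <- rbind(res, data.frame(start = starts_nt[a],
                                   end = starts_nt[s] + 2L,
                                   length_codons = n_codons))
    }
  }
  if (is.null(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length_codons = integer(0)))
  }
  res[order(res$start), , drop = FALSE]
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
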