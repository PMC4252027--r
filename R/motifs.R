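# Degenerate-consensus motif scanning and Fisher enrichment.

#' Parse a bracket-notation consensus motif
#'
#' A consensus is a string of literal bases and bracketed alternative sets,
#' e.g. `"[GA][GA]AGA[GA]"`: each position allows one base (literal) or any
#' base from a nonempty subset of {A, C, G, T}.
#'
#' @param consensus Nonempty consensus string.
#' @return Object of class `motif_pattern` with fields `consensus`, `length`
#'   and `sets` (list of allowed-base character vectors per position).
#' @export
parse_consensus <- function(consensus) {
  stop_if(!is.character(consensus) || length(consensus) != 1L ||
            nchar(consensus) == 0, "consensus must be a nonempty string")
  chars <- strsplit(consensus, "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      repeat {
        stop_if(j > length(chars),
                sprintf("unbalanced bracket opened at position %d", i))
        if (chars[j] == "]") break
        stop_if(!chars[j] %in% c("A", "C", "G", "T"),
                sprintf("invalid character '%s' at position %d (allowed: ACGT)",
                        chars[j], j))
        set <- c(set, chars[j])
        j <- j + 1L
      }
      stop_if(length(set) == 0, sprintf("empty bracket at position %d", i))
      sets[[length(sets) + 1L]] <- unique(set)
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("unmatched ']' at position %d", i), call. = FALSE)
    } else {
      stop_if(!ch %in% c("A", "C", "G", "T"),
              sprintf("invalid character '%s' at position %d (allowed: ACGT)", ch, i))
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    }
  }
  structure(list(consensus = consensus, length = length(sets), sets = sets),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern %s: %d positions>\n", x$consensus, x$length))
  invisible(x)
}

scan_one <- function(seq, pattern) {
  L <- nchar(seq)
  k <- pattern$length
  if (L < k) return(0L)
  chars <- strsplit(seq, "")[[1]]
  n_off <- L - k + 1L
  ok <- rep(TRUE, n_off)
  for (p in seq_len(k)) {
    ok <- ok & chars[seq.int(p, p + n_off - 1L)] %in% pattern$sets[[p]]
    if (!any(ok)) return(0L)
  }
  sum(ok)
}

#' Scan sequences for a degenerate consensus motif
#'
#' Counts exact degenerate-consensus matches on the given (sense) strand:
#' an offset matches iff every motif position's allowed set contains the
#' base there. Overlapping matches all count; `N` never matches.
#'
#' @param seqs Named character vector (gene -> region sequence, uppercase
#'   ACGTN).
#' @param pattern A [motif_pattern()] or consensus string.
#' @return List with `counts` (named integer vector of per-gene hit counts)
#'   and `genes_with_hit` (character vector).
#' @export
motif_scan <- function(seqs, pattern) {
  if (is.character(pattern)) pattern <- parse_consensus(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  stop_if(is.null(names(seqs)) && length(seqs) > 1,
          "seqs must be named by gene")
  seqs <- toupper(seqs)
  for (s in seqs) valid_dna(s, "sequence")
  counts <- vapply(seqs, scan_one, integer(1), pattern = pattern)
  list(counts = counts, genes_with_hit = names(counts)[counts > 0])
}

#' Motif enrichment of a target list versus the background
#'
#' Fold enrichment `(k_target/n_target) / (k_bg/n_bg)` and a one-tailed
#' (enrichment-direction) Fisher's exact p-value on the 2x2 table of genes
#' with >= 1 hit versus genes without. By the package convention the
#' background counts exclude the target genes; pass counts accordingly (the
#' helper [motif_table()] does).
#'
#' @param k_target,n_target Genes with a hit / genes scanned in the target
#'   list.
#' @param k_bg,n_bg Same for the background.
#' @return Object of class `enrichment_result`: list with the four counts,
#'   `fold` (Inf flagged when the background rate is 0) and `p`.
#' @export
motif_enrichment <- function(k_target, n_target, k_bg, n_bg) {
  for (v in c("k_target", "n_target", "k_bg", "n_bg")) {
    assert_scalar_number(get(v), v, lower = 0, integer = TRUE)
  }
  stop_if(k_target > n_target || k_bg > n_bg, "k must be <= n on both sides")
  stop_if(n_target == 0 || n_bg == 0, "n must be > 0 on both sides")
  fold <- if (k_bg == 0) {
    if (k_target == 0) NaN else Inf
  } else {
    (k_target / n_target) / (k_bg / n_bg)
  }
  # one-tailed hypergeometric upper tail: P(X >= k_target) drawing n_target
  # genes from n_target + n_bg of which k_target + k_bg carry a hit
  p <- stats::phyper(k_target - 1, k_target + k_bg,
                     n_target + n_bg - k_target - k_bg, n_target,
                     lower.tail = FALSE)
  structure(list(k_target = k_target, n_target = n_target,
                 k_bg = k_bg, n_bg = n_bg, fold = fold, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment: %d/%d target vs %d/%d background, fold %.3g, p = %.3g>\n",
              x$k_target, x$n_target, x$k_bg, x$n_bg, x$fold, x$p))
  invisible(x)
}

#' Motif enrichment table for a list of consensi
#'
#' Scans every gene's region sequence for each consensus and tabulates
#' gene-level (>= 1 hit) enrichment of the target list versus the rest of
#' the universe (background excludes targets), with occurrence totals
#' reported alongside.
#'
#' @param seqs Named character vector, gene -> region sequence (the whole
#'   universe).
#' @param target_ids Gene ids in the target list.
#' @param consensi Character vector of bracket-notation consensus motifs.
#' @param region Label recorded in the output (e.g. `"utr5"`).
#' @return Data.frame with one row per consensus: counts, fold, p, and
#'   occurrence totals per side.
#' @export
motif_table <- function(seqs, target_ids, consensi, region = NA_character_) {
  stop_if(!all(target_ids %in% names(seqs)),
          "target_ids must be a subset of names(seqs)")
  is_t <- names(seqs) %in% target_ids
  rows <- lapply(consensi, function(cs) {
    sc <- motif_scan(seqs, cs)
    hit <- sc$counts > 0
    er <- motif_enrichment(sum(hit[is_t]), sum(is_t),
                           sum(hit[!is_t]), sum(!is_t))
    data.frame(consensus = cs, region = region,
               k_target = er$k_target, n_target = er$n_target,
               k_bg = er$k_bg, n_bg = er$n_bg,
               occurrences_target = sum(sc$counts[is_t]),
               occurrences_bg = sum(sc$counts[!is_t]),
               fold = er$fold, p_value = er$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
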