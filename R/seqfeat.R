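# Transcript sequence features: region lengths, GC content, effective
# number of codons (Nc), uORFs, start-codon context, and
# target-vs-background comparisons.

valid_dna <- function(x, name) {
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  stop_if(length(bad) > 0 && nchar(bad) > 0,
          sprintf("invalid character '%s' in %s (allowed: A, C, G, T, N)", bad, name))
  invisible(x)
}

#' Construct a transcript annotation
#'
#' Holds the 5'UTR, CDS and 3'UTR nucleotide sequences of one transcript
#' (uppercase, alphabet ACGTN). The CDS must be at least one codon and a
#' multiple of 3 unless `lenient = TRUE`, in which case offending records are
#' kept but flagged (never silently truncated).
#'
#' @param gene_id Identifier.
#' @param utr5,cds,utr3 Nucleotide strings (may be empty except `cds`).
#' @param lenient Keep a CDS whose length is not a multiple of 3, flagging it.
#' @return Object of class `transcript_annotation` with a `cds_valid` flag.
#' @export
transcript_annotation <- function(gene_id, utr5 = "", cds, utr3 = "",
                                  lenient = FALSE) {
  utr5 <- toupper(utr5); cds <- toupper(cds); utr3 <- toupper(utr3)
  valid_dna(utr5, "utr5"); valid_dna(cds, "cds"); valid_dna(utr3, "utr3")
  ok <- nchar(cds) >= 3 && nchar(cds) %% 3 == 0
  stop_if(!ok && !lenient,
          sprintf("CDS of %s has length %d (must be >= 3 and divisible by 3)",
                  gene_id, nchar(cds)))
  structure(list(gene_id = as.character(gene_id), utr5 = utr5, cds = cds,
                 utr3 = utr3, cds_valid = ok),
            class = "transcript_annotation")
}

#' Region lengths and GC content
#'
#' Lengths in nt and GC fraction per region (5'UTR, CDS, 3'UTR) and for the
#' full transcript. GC is computed over unambiguous bases only; an empty
#' region has length 0 and undefined (NA) GC.
#'
#' @param ann A [transcript_annotation()].
#' @return Data.frame with columns `region`, `length`, `gc`.
#' @export
region_features <- function(ann) {
  stopifnot(inherits(ann, "transcript_annotation"))
  gc_of <- function(s) {
    if (nchar(s) == 0) return(NA_real_)
    n <- nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))
    unamb <- nchar(s) - n
    if (unamb == 0) return(NA_real_)
    gc <- nchar(s) - nchar(gsub("[GC]", "", s))
    gc / unamb
  }
  full <- paste0(ann$utr5, ann$cds, ann$utr3)
  data.frame(region = c("utr5", "cds", "utr3", "transcript"),
             length = c(nchar(ann$utr5), nchar(ann$cds), nchar(ann$utr3),
                        nchar(full)),
             gc = c(gc_of(ann$utr5), gc_of(ann$cds), gc_of(ann$utr3),
                    gc_of(full)),
             stringsAsFactors = FALSE)
}

# Standard genetic code grouped by synonymous-family degeneracy.
# Ile is the single 3-fold family; Leu/Ser/Arg are 6-fold.
codon_families <- function() {
  list(
    Phe = c("TTT", "TTC"), Tyr = c("TAT", "TAC"), Cys = c("TGT", "TGC"),
    His = c("CAT", "CAC"), Gln = c("CAA", "CAG"), Asn = c("AAT", "AAC"),
    Lys = c("AAA", "AAG"), Asp = c("GAT", "GAC"), Glu = c("GAA", "GAG"),
    Ile = c("ATT", "ATC", "ATA"),
    Val = c("GTT", "GTC", "GTA", "GTG"), Pro = c("CCT", "CCC", "CCA", "CCG"),
    Thr = c("ACT", "ACC", "ACA", "ACG"), Ala = c("GCT", "GCC", "GCA", "GCG"),
    Gly = c("GGT", "GGC", "GGA", "GGG"),
    Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
}

#' Effective number of codons (Nc)
#'
#' Wright's codon-usage-bias estimator. For each amino acid with n observed
#' codons and synonymous-codon proportions p, the codon homozygosity is
#' `F = (n * sum(p^2) - 1) / (n - 1)`; Nc sums the degeneracy-class means:
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (2 non-degenerate amino acids, 9
#' two-fold, 1 three-fold, 5 four-fold and 3 six-fold families; the 6-fold
#' families Leu/Ser/Arg are treated as single families). Nc runs from 20
#' (one codon per family, maximal bias) to 61 (uniform synonymous usage);
#' estimates are clamped to that range.
#'
#' Amino acids observed fewer than `min_count` times are excluded from their
#' class mean; a class with no usable amino acid borrows the mean F of the
#' observed classes. Stop codons are excluded. With no usable class at all
#' the estimate is undefined (`NA`).
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param min_count Minimal codons per amino acid to contribute (default 2).
#' @return Nc in \[20, 61\], or `NA` if undefined.
#' @export
effective_number_of_codons <- function(cds, min_count = 2L) {
  cds <- toupper(cds)
  valid_dna(cds, "cds")
  stop_if(nchar(cds) %% 3 != 0, "CDS length must be divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  codons <- codons[!grepl("N", codons)]
  fams <- codon_families()
  degree <- lengths(fams)
  f_hat <- rep(NA_real_, length(fams))
  for (k in seq_along(fams)) {
    cnt <- table(factor(codons, levels = fams[[k]]))
    n <- sum(cnt)
    if (n >= min_count) {
      p <- as.numeric(cnt) / n
      f_hat[k] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  class_sizes <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  f_bar <- vapply(names(class_sizes), function(d) {
    v <- f_hat[degree == as.integer(d)]
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (all(is.na(f_bar))) return(NA_real_)
  f_bar[is.na(f_bar)] <- mean(f_bar, na.rm = TRUE)
  nc <- 2 + sum(class_sizes / f_bar)
  min(max(nc, 20), 61)
}

#' Find upstream open reading frames in a 5'UTR
#'
#' Scans the 5'UTR (5'->3') for ATG codons; a uORF is an ATG with an
#' in-frame stop codon (TAA/TAG/TGA) before the main start, or — with
#' `allow_overlap = TRUE` — extending into the CDS. Peptide length counts
#' codons from the ATG up to (excluding) the stop, so `min_codons = 1`
#' admits a bare start codon immediately followed by a stop. Same-frame
#' ATGs nested inside a longer uORF (sharing its stop) are reported once,
#' at the outermost start. Coordinates are 1-based within the 5'UTR; `end`
#' is the last base of the stop codon (or of the overlapping segment).
#'
#' @param utr5 5'UTR nucleotide string.
#' @param min_codons Minimal peptide length in codons (default 1).
#' @param allow_overlap Count ATGs whose ORF runs into the CDS (needs `cds`).
#' @param cds Downstream CDS sequence, required when `allow_overlap = TRUE`.
#' @return Data.frame with `start`, `end`, `length_codons`, `overlaps_cds`.
#' @export
find_uorfs <- function(utr5, min_codons = 1L, allow_overlap = FALSE, cds = "") {
  utr5 <- toupper(utr5)
  valid_dna(utr5, "utr5")
  stop_if(allow_overlap && nchar(cds) == 0,
          "allow_overlap = TRUE requires the downstream CDS")
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(utr5)
  hits <- data.frame(start = integer(0), end = integer(0),
                     length_codons = integer(0), overlaps_cds = logical(0))
  if (L < 3) return(hits)
  seq_ext <- if (allow_overlap) paste0(utr5, toupper(cds)) else utr5
  starts <- gregexpr("ATG", utr5, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(hits)
  claimed <- character(0) # "frame:stop_end" keys already reported
  for (st in starts) {
    # walk codons from this ATG; stop must start within the UTR for the
    # non-overlapping case, else anywhere in utr5+cds
    pos <- st + 3L
    stop_end <- NA_integer_
    while (pos + 2L <= nchar(seq_ext)) {
      cod <- substr(seq_ext, pos, pos + 2L)
      if (cod %in% stops) { stop_end <- pos + 2L; break }
      pos <- pos + 3L
    }
    if (is.na(stop_end)) next
    overlaps <- stop_end > L
    if (overlaps && !allow_overlap) next
    n_codons <- (stop_end - 2L - st) %/% 3L # codons before the stop, incl. ATG
    if (n_codons < min_codons) next
    key <- paste(st %% 3L, stop_end, sep = ":")
    if (key %in% claimed) next
    claimed <- c(claimed, key)
    hits <- rbind(hits, data.frame(start = st, end = stop_end,
                                   length_codons = n_codons,
                                   overlaps_cds = overlaps))
  }
  hits
}

#' Start-codon sequence context (-5..+8)
#'
#' Returns the 13-nt context around the main start codon: positions -5..-1
#' (the last five 5'UTR bases) followed by +1..+8 (the first eight CDS
#' bases; +1 is the A of the ATG — there is no position 0). A short 5'UTR is
#' left-padded with `N`; a CDS shorter than 8 nt is right-padded with `N`
#' with a warning.
#'
#' @param ann A [transcript_annotation()].
#' @return A 13-character string.
#' @export
start_context <- function(ann) {
  stopifnot(inherits(ann, "transcript_annotation"))
  up <- ann$utr5
  nu <- nchar(up)
  left <- if (nu >= 5) substr(up, nu - 4, nu) else
    paste0(strrep("N", 5 - nu), up)
  right <- substr(ann$cds, 1, 8)
  if (nchar(right) < 8) {
    warning(sprintf("CDS of %s shorter than 8 nt; right-padding context with N",
                    ann$gene_id))
    right <- paste0(right, strrep("N", 8 - nchar(right)))
  }
  paste0(left, right)
}

#' Feature table for a set of annotations
#'
#' One row per gene: region lengths and GC, transcript length/GC, Nc of the
#' CDS (stop codon trimmed when the terminal codon is a stop), uORF count
#' and presence, start context.
#'
#' @param annotations List of [transcript_annotation()].
#' @param min_codons,allow_overlap Passed to [find_uorfs()].
#' @return Data.frame, one row per transcript.
#' @export
feature_table <- function(annotations, min_codons = 1L, allow_overlap = FALSE) {
  rows <- lapply(annotations, function(ann) {
    rf <- region_features(ann)
    g <- function(region, what) rf[[what]][rf$region == region]
    cds_nostop <- ann$cds
    last <- substr(cds_nostop, nchar(cds_nostop) - 2, nchar(cds_nostop))
    if (last %in% c("TAA", "TAG", "TGA")) {
      cds_nostop <- substr(cds_nostop, 1, nchar(cds_nostop) - 3)
    }
    u <- find_uorfs(ann$utr5, min_codons = min_codons,
                    allow_overlap = allow_overlap, cds = ann$cds)
    data.frame(gene_id = ann$gene_id,
               len_utr5 = g("utr5", "length"), len_cds = g("cds", "length"),
               len_utr3 = g("utr3", "length"),
               len_transcript = g("transcript", "length"),
               gc_utr5 = g("utr5", "gc"), gc_cds = g("cds", "gc"),
               gc_utr3 = g("utr3", "gc"), gc_transcript = g("transcript", "gc"),
               nc = if (ann$cds_valid && nchar(cds_nostop) >= 3)
                 effective_number_of_codons(cds_nostop) else NA_real_,
               n_uorfs = nrow(u), has_uorf = nrow(u) > 0,
               start_context = start_context(ann),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare features between a target list and the background
#'
#' For each continuous feature (lengths, GC, Nc, uORF count) a two-sided
#' Wilcoxon rank-sum test compares target genes against the background
#' (exact when both sides have <= 25 defined values and no ties; normal
#' approximation with continuity and tie correction otherwise). uORF
#' presence is compared by a one-tailed Fisher's exact test (enrichment
#' direction). By convention the background excludes the target genes.
#'
#' @param features Output of [feature_table()] for the whole universe.
#' @param target_ids Gene ids of the target list (subset of the universe).
#' @param min_n Minimal defined values per side (default 5); features below
#'   are skipped with a warning.
#' @return Data.frame with `feature`, `statistic`, `p_value`,
#'   `median_target`, `median_background`, `test`.
#' @export
compare_features <- function(features, target_ids, min_n = 5L) {
  stop_if(!all(target_ids %in% features$gene_id),
          "target_ids must be a subset of the feature table")
  is_t <- features$gene_id %in% target_ids
  cont <- c("len_utr5", "len_cds", "len_utr3", "len_transcript",
            "gc_utr5", "gc_cds", "gc_utr3", "gc_transcript", "nc", "n_uorfs")
  rows <- list()
  for (f in cont) {
    x <- features[[f]][is_t]; y <- features[[f]][!is_t]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < min_n || length(y) < min_n) {
      warning(sprintf("feature '%s' skipped: fewer than %d defined values on one side",
                      f, min_n))
      next
    }
    exact <- length(x) <= 25 && length(y) <= 25
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    rows[[f]] <- data.frame(feature = f, statistic = unname(wt$statistic),
                            p_value = wt$p.value,
                            median_target = stats::median(x),
                            median_background = stats::median(y),
                            test = "wilcoxon", stringsAsFactors = FALSE)
  }
  kt <- sum(features$has_uorf[is_t]); nt <- sum(is_t)
  kb <- sum(features$has_uorf[!is_t]); nb <- sum(!is_t)
  ft <- stats::fisher.test(matrix(c(kt, nt - kt, kb, nb - kb), 2),
                           alternative = "greater")
  rows[["has_uorf"]] <- data.frame(feature = "has_uorf",
                                   statistic = kt / nt / (kb / nb),
                                   p_value = ft$p.value,
                                   median_target = kt / nt,
                                   median_background = kb / nb,
                                   test = "fisher_one_tailed",
                                   stringsAsFactors = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
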