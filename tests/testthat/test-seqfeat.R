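# Sequence features: region stats, Nc codon bias, uORFs, start context,
# target-vs-background comparisons.

test_that("region features compute lengths and GC over unambiguous bases", {
  ann <- transcript_annotation("g", utr5 = "GCGC", cds = "ATGTAA",
                               utr3 = "ATAT")
  rf <- region_features(ann)
  g <- function(region, what) rf[[what]][rf$region == region]
  expect_equal(g("utr5", "gc"), 1)
  expect_equal(g("utr3", "gc"), 0)
  expect_equal(g("transcript", "length"), 14)

  ann2 <- transcript_annotation("g2", utr5 = "GCAN", cds = "ATGTAA")
  rf2 <- region_features(ann2)
  expect_equal(rf2$gc[rf2$region == "utr5"], 2 / 3) # N excluded
  expect_equal(rf2$length[rf2$region == "utr3"], 0)
  expect_true(is.na(rf2$gc[rf2$region == "utr3"]))

  expect_error(transcript_annotation("g3", cds = "ATGXAA"), "invalid character 'X'")
  expect_error(transcript_annotation("g4", cds = "ATGT"), "divisible")
  lenient <- transcript_annotation("g4", cds = "ATGT", lenient = TRUE)
  expect_false(lenient$cds_valid)
})

test_that("Nc hits its theoretical limits and matches the frozen oracle", {
  fams <- list(
    c("TTT", "TTC"), c("TAT", "TAC"), c("TGT", "TGC"), c("CAT", "CAC"),
    c("CAA", "CAG"), c("AAT", "AAC"), c("AAA", "AAG"), c("GAT", "GAC"),
    c("GAA", "GAG"), c("ATT", "ATC", "ATA"),
    c("GTT", "GTC", "GTA", "GTG"), c("CCT", "CCC", "CCA", "CCG"),
    c("ACT", "ACC", "ACA", "ACG"), c("GCT", "GCC", "GCA", "GCG"),
    c("GGT", "GGC", "GGA", "GGG"),
    c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))

  # uniform synonymous usage, ~6000 codons: Nc -> 61
  uniform <- paste(rep(unlist(fams), each = 100), collapse = "")
  expect_gte(effective_number_of_codons(uniform), 60.5)

  # one codon per family: maximal bias, Nc = 20 exactly
  biased <- paste(rep(vapply(fams, `[`, character(1), 1), each = 3),
                  collapse = "")
  expect_identical(effective_number_of_codons(biased), 20)

  # frozen independent transcription of the estimator (60 random codons)
  cds60 <- paste0(
    "GGGCACTTCTCTGAGGACGATCAATCTCATCTTTCTAGAGCCTGCGGTCCATATTTCTGC",
    "AAGGATACGGGCTTCGCAAAACTATTACTCGCCCCCGATCCGGGTGAGAGTCGATTTTCC",
    "AGTAATCTCCCAGTTGAGCAGAAGTCCGTTCATTGCGTGCATGTCCGCGTCGGCGAAAGT")
  expect_equal(effective_number_of_codons(cds60), 60.70461424880028,
               tolerance = 1e-9)

  # synonymous relabeling within a family leaves Nc unchanged
  set.seed(7)
  cds <- paste(sample(unlist(fams), 200, replace = TRUE), collapse = "")
  swapped <- chartr("X", "X", cds) # placeholder; swap TTT <-> TTC codon-wise
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  codons[codons == "TTT"] <- "XXX"
  codons[codons == "TTC"] <- "TTT"
  codons[codons == "XXX"] <- "TTC"
  swapped <- paste(codons, collapse = "")
  expect_equal(effective_number_of_codons(swapped),
               effective_number_of_codons(cds), tolerance = 1e-12)

  # range clamp holds on random coding sequences
  for (i in 1:20) {
    cds_i <- paste(sample(unlist(fams), 40, replace = TRUE), collapse = "")
    nc <- effective_number_of_codons(cds_i)
    expect_true(is.na(nc) || (nc >= 20 && nc <= 61))
  }
  expect_error(effective_number_of_codons("ATGT"), "divisible")
})

test_that("uORF detection matches the scan rules and coordinates", {
  expect_equal(nrow(find_uorfs("AAAAAA")), 0)

  u <- find_uorfs("CCATGTAACC")
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 3L)
  expect_equal(u$end, 8L) # last base of the TAA stop
  expect_equal(u$length_codons, 1L) # the bare start codon counts
  expect_false(u$overlaps_cds)

  # min_codons filters the bare-ATG case
  expect_equal(nrow(find_uorfs("CCATGTAACC", min_codons = 2)), 0)

  # no stop in the UTR: only counted when overlap into the CDS is allowed
  expect_equal(nrow(find_uorfs("CCATGGGG")), 0)
  ov <- find_uorfs("CCATGGGG", allow_overlap = TRUE, cds = "ATGCCTAAATAG")
  expect_equal(nrow(ov), 1)
  expect_true(ov$overlaps_cds)

  # nested same-frame ATGs sharing a stop are reported once, outermost
  nested <- find_uorfs("ATGATGCCCTAA")
  expect_equal(nrow(nested), 1)
  expect_equal(nested$start, 1L)

  # different frames are independent
  two <- find_uorfs("ATGTAAAATGCCCTGA")
  expect_equal(nrow(two), 2)

  # oracle equivalence on random UTRs
  set.seed(8)
  for (i in 1:60) {
    utr <- random_seq(sample(30:200, 1))
    got <- find_uorfs(utr)
    want <- oracle_uorfs(utr)
    expect_equal(got[order(got$start), c("start", "end", "length_codons")],
                 want, ignore_attr = TRUE)
  }
})

test_that("start context extracts -5..+8 with N padding", {
  ann <- transcript_annotation("g", utr5 = "AAAAACCCCC",
                               cds = "ATGGCGGCGGCATAA")
  expect_equal(start_context(ann), "CCCCCATGGCGGC")

  short_utr <- transcript_annotation("g", utr5 = "GG",
                                     cds = "ATGGCGGCGGCATAA")
  expect_equal(start_context(short_utr), "NNNGGATGGCGGC")

  short_cds <- transcript_annotation("g", utr5 = "AAAAA", cds = "ATGTAA")
  expect_warning(ctx <- start_context(short_cds), "right-padding")
  expect_equal(ctx, "AAAAAATGTAANN")
  expect_equal(nchar(ctx), 13)
})

test_that("feature comparisons are rank-based with the documented tests", {
  # fully separated target vs background, n = 10 vs 10: exact two-sided
  # rank-sum p = 2 * (10! 10! / 20!) = 2 / choose(20, 10)
  n <- 20
  feats <- data.frame(
    gene_id = sprintf("g%02d", 1:n),
    len_utr5 = c(101:110, 1:10), len_cds = rep(300, n),
    len_utr3 = rep(200, n), len_transcript = rep(600, n),
    gc_utr5 = rep(0.4, n), gc_cds = rep(0.45, n), gc_utr3 = rep(0.3, n),
    gc_transcript = rep(0.4, n), nc = rep(50, n),
    n_uorfs = rep(0, n), has_uorf = rep(c(TRUE, FALSE), each = 10))
  res <- suppressWarnings(compare_features(feats, feats$gene_id[1:10]))
  expect_equal(res$p_value[res$feature == "len_utr5"], 2 / choose(20, 10),
               tolerance = 1e-12)
  # all-target uORFs vs none: one-tailed Fisher
  expect_equal(res$p_value[res$feature == "has_uorf"],
               1 / choose(20, 10), tolerance = 1e-12)

  # identical multisets: p -> 1 (continuity correction keeps it just below)
  feats2 <- feats
  feats2$len_utr5 <- rep(1:10, 2)
  res2 <- suppressWarnings(compare_features(feats2, feats2$gene_id[1:10]))
  expect_gte(res2$p_value[res2$feature == "len_utr5"], 0.95)

  # rank-based: invariant to monotone transformation
  feats3 <- feats
  feats3$len_utr5 <- feats$len_utr5^3
  res3 <- suppressWarnings(compare_features(feats3, feats3$gene_id[1:10]))
  expect_equal(res3$p_value[res3$feature == "len_utr5"],
               res$p_value[res$feature == "len_utr5"])
  expect_error(compare_features(feats, "nope"), "subset")
})

test_that("feature_table summarises annotations end to end", {
  tx <- simulate_transcripts(sprintf("g%02d", 1:12), cds_len_codons = 80,
                             utr5_len = 60, utr3_len = 90, seed = 10)
  anns <- mapply(transcript_annotation, tx$gene_id, tx$utr5, tx$cds, tx$utr3,
                 SIMPLIFY = FALSE)
  ft <- feature_table(anns)
  expect_equal(nrow(ft), 12)
  expect_true(all(ft$len_cds == 3 * 81)) # 80 codons + stop
  expect_true(all(ft$len_transcript == ft$len_utr5 + ft$len_cds + ft$len_utr3))
  expect_true(all(is.na(ft$nc) | (ft$nc >= 20 & ft$nc <= 61)))
  expect_true(all(nchar(ft$start_context) == 13))
  expect_true(all(substr(ft$start_context, 6, 8) == "ATG"))
})
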