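# Plain-text exchange formats: TSV matrices/tables, CSV traces (gradient.R),
# FASTA transcript regions.

#' Write / read an expression matrix as TSV
#'
#' Gene rows, sample columns named `condition.light.level.rep`; a leading
#' `gene_id` column carries the rownames.
#'
#' @param mat Numeric matrix with rownames.
#' @param path File path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv` returns a numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "gene_id", "expected first column 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Write / read transcript regions as FASTA
#'
#' One record per region with ids suffixed `.utr5` / `.cds` / `.utr3`
#' (e.g. `gene_00001.cds`). Empty regions are skipped on write and read back
#' as empty strings.
#'
#' @param regions Data.frame with columns `gene_id`, `utr5`, `cds`, `utr3`.
#' @param path FASTA file path.
#' @export
write_regions_fasta <- function(regions, path) {
  recs <- character(0)
  for (r in c("utr5", "cds", "utr3")) {
    keep <- nchar(regions[[r]]) > 0
    v <- regions[[r]][keep]
    names(v) <- paste0(regions$gene_id[keep], ".", r)
    recs <- c(recs, v)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), path, width = 70)
  invisible(path)
}

#' @rdname write_regions_fasta
#' @return `read_regions_fasta` returns a data.frame with columns `gene_id`,
#'   `utr5`, `cds`, `utr3`.
#' @export
read_regions_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  stop_if(!all(grepl("\\.(utr5|cds|utr3)$", ids)),
          "FASTA ids must be suffixed .utr5/.cds/.utr3")
  gene <- sub("\\.(utr5|cds|utr3)$", "", ids)
  region <- sub("^.*\\.", "", ids)
  genes <- unique(gene)
  out <- data.frame(gene_id = genes, utr5 = "", cds = "", utr3 = "",
                    stringsAsFactors = FALSE)
  seqs <- as.character(ss)
  for (i in seq_along(ids)) {
    out[[region[i]]][out$gene_id == gene[i]] <- seqs[i]
  }
  out
}

#' Write fraction profiles as TSV
#'
#' Long-per-sample layout: `gene_id`, `sample`, `spike`,
#' `fraction_1..fraction_12`.
#'
#' @param profiles Data.frame as produced by [simulate_experiment()].
#' @param path File path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
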