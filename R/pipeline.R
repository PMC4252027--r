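# Pipeline orchestration: simulate -> gradient -> differential analysis ->
# fraction metrics -> sequence features -> motifs, with a manifest and a
# report.

#' Build a pipeline configuration
#'
#' Collects the simulation design, fraction scheme, call thresholds and seed
#' into one validated object. Every default is echoed into the run manifest
#' so a finished run documents the exact thresholds that produced it.
#' Configurations can also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param design An [experiment_design()].
#' @param scheme A [fraction_scheme()].
#' @param padj,lfc,ro_lfc Call thresholds, see [classify_regulation()].
#' @param consensi Consensus motifs scanned in 5'UTRs (defaults to the two
#'   purine-rich / CG-rich consensi the package ships as examples).
#' @param n_profile_genes Fraction profiles and sequence features are
#'   computed for at most this many genes (default 200) to keep runs small;
#'   the expression-level analysis always covers all genes.
#' @param out_dir Output directory (created); `NULL` keeps results in memory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design, scheme = fraction_scheme(),
                            padj = 0.05, lfc = 1, ro_lfc = 1,
                            consensi = c("[GA][GA]AGA[GA]",
                                         "[TCA]CG[GCA]CG[GA][CA]G"),
                            n_profile_genes = 200L, out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(scheme, "fraction_scheme"))
  assert_scalar_number(padj, "padj", lower = 0, upper = 1)
  assert_scalar_number(lfc, "lfc", lower = 0)
  assert_scalar_number(ro_lfc, "ro_lfc", lower = 0)
  for (cs in consensi) parse_consensus(cs)
  structure(list(design = design, scheme = scheme, padj = padj, lfc = lfc,
                 ro_lfc = ro_lfc, consensi = consensi,
                 n_profile_genes = as.integer(n_profile_genes),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `design` (fields of [experiment_design()],
#' including a named `class_mixture` map — quote the `"null"` scenario key,
#' since bare `null` is a YAML null literal), optional `scheme`
#' (fields of [fraction_scheme()]) and optional `thresholds`
#' (`padj`, `lfc`, `ro_lfc`), `consensi`, `n_profile_genes`, `out_dir`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  stop_if(is.null(y$design), "config must have a 'design' block")
  d <- y$design
  if (!is.null(seed)) d$seed <- seed
  design <- do.call(experiment_design, d)
  scheme <- if (is.null(y$scheme)) fraction_scheme() else {
    if (!is.null(y$scheme$domain)) y$scheme$domain <- unlist(y$scheme$domain)
    do.call(fraction_scheme, y$scheme)
  }
  th <- y$thresholds %||% list()
  pipeline_config(design, scheme,
                  padj = th$padj %||% 0.05, lfc = th$lfc %||% 1,
                  ro_lfc = th$ro_lfc %||% 1,
                  consensi = unlist(y$consensi) %||%
                    c("[GA][GA]AGA[GA]", "[TCA]CG[GCA]CG[GA][CA]G"),
                  n_profile_genes = y$n_profile_genes %||% 200L,
                  out_dir = y$out_dir)
}

#' Run the full analysis pipeline
#'
#' Simulates the experiment from the config's design, then runs every stage:
#' per-sample gradient quantification (polysomal-area percentages), the
#' three-contrast differential analysis with regulation calls,
#' fraction-resolved density metrics with scenario classification for a
#' subset of genes, sequence-feature comparison of the called gene list
#' against the background, and motif enrichment. Reruns with an identical
#' config are bit-identical; when `out_dir` is set all stage outputs plus a
#' manifest are written as plain-text files.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result` with elements `sim`, `gradient`
#'   (per-sample polysomal percentages), `diff`, `calls`, `fractions`
#'   (per-gene density metrics and scenario label), `features`,
#'   `feature_tests`, `motifs`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  scheme <- config$scheme

  sim <- simulate_experiment(design, scheme = scheme,
                             with_profiles = TRUE, with_traces = TRUE)

  # gradient stage: polysomal-area percentage per polysomal sample trace
  grad <- data.frame(sample = names(sim$traces),
                     polysomal_pct = vapply(sim$traces, function(tr) {
                       polysomal_area_pct(tr, scheme)
                     }, numeric(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
  grad$np_pct <- 100 - grad$polysomal_pct

  # differential stage on spike-normalised intensities
  mat <- spike_normalize(sim$matrix, sim$samples$spike)
  diff <- differential_all(mat, sim$samples)
  calls <- classify_regulation(diff, padj = config$padj, lfc = config$lfc,
                               ro_lfc = config$ro_lfc)

  # fraction stage: density metrics per gene, control vs sucrose
  # (replicate-averaged profiles), on a capped subset for tractability
  n_sub <- min(config$n_profile_genes, design$n_genes)
  sub_ids <- sim$truth$gene_id[seq_len(n_sub)]
  areas <- vapply(names(sim$traces), function(s) {
    trace_area(sim$traces[[s]])
  }, numeric(1))
  frac_rows <- lapply(sub_ids, function(g) {
    prof_of <- function(cond) {
      p <- sim$profiles[sim$profiles$gene_id == g &
                          grepl(paste0("^", cond, "\\."), sim$profiles$sample), ]
      raw <- colMeans(p[, scheme$labels, drop = FALSE])
      normalize_profile(raw, p$spike[1], mean(areas[p$sample]))
    }
    mc <- density_metrics(prof_of("control"), scheme)
    mt <- density_metrics(prof_of("sucrose"), scheme)
    data.frame(gene_id = g,
               np_pct_control = mc$np_pct, pl_pct_control = mc$pl_pct,
               index_control = mc$weighted_index,
               np_pct_sucrose = mt$np_pct, pl_pct_sucrose = mt$pl_pct,
               index_sucrose = mt$weighted_index,
               scenario_called = scenario_classify(mc, mt),
               stringsAsFactors = FALSE)
  })
  fractions <- do.call(rbind, frac_rows)

  # sequence stage: synthetic transcripts for the subset, target = genes
  # called RO_changed, motif planted into the true positives so enrichment
  # has ground truth
  true_ro <- sim$truth$gene_id[abs(sim$truth$delta_log2_ro) > 1e-9 &
                                 sim$truth$gene_id %in% sub_ids]
  cds_lens <- vapply(sim$models[seq_len(n_sub)],
                     function(g) g$control$cds_len_codons, integer(1))
  set.seed(substream_seed(design$seed, 0L, 3L))
  regions <- simulate_transcripts(sub_ids,
                                  cds_len_codons = cds_lens,
                                  utr5_len = sample(60:250, n_sub, replace = TRUE),
                                  utr3_len = sample(100:400, n_sub, replace = TRUE),
                                  plant_motif = config$consensi[1],
                                  plant_in = true_ro,
                                  seed = design$seed)
  anns <- mapply(transcript_annotation, regions$gene_id, regions$utr5,
                 regions$cds, regions$utr3, SIMPLIFY = FALSE)
  features <- feature_table(anns)
  target <- intersect(calls$gene_id[calls$class == "RO_changed"], sub_ids)
  feature_tests <- if (length(target) >= 5 && length(sub_ids) - length(target) >= 5) {
    suppressWarnings(compare_features(features, target))
  } else NULL
  utr5 <- regions$utr5
  names(utr5) <- regions$gene_id
  motifs <- if (length(target) >= 1) {
    motif_table(utr5, target, config$consensi, region = "utr5")
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("polyoccu")),
    seed = design$seed, n_genes = design$n_genes,
    n_replicates = design$n_replicates,
    noise_sd_log2 = design$noise_sd_log2,
    class_mixture = as.list(design$class_mixture),
    thresholds = list(padj = config$padj, lfc = config$lfc,
                      ro_lfc = config$ro_lfc),
    scheme = list(n_fractions = scheme$n_fractions,
                  polysome_start_fraction = scheme$polysome_start_fraction,
                  monosome_fraction = scheme$monosome_fraction,
                  pools = lapply(scheme$pools, as.integer)),
    consensi = config$consensi, n_profile_genes = n_sub)

  result <- structure(list(sim = sim, gradient = grad, diff = diff,
                           calls = calls, fractions = fractions,
                           features = features,
                           feature_tests = feature_tests,
                           motifs = motifs, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' Write all stage outputs of a pipeline run
#'
#' Emits the expression matrix, truth table, differential results, calls,
#' gradient percentages, fraction metrics, features, motif table, traces,
#' FASTA regions, the manifest (JSON) and the markdown report into
#' `out_dir`. All files are plain text and reproducible byte-for-byte from
#' the same config.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_expression_tsv(result$sim$matrix, p("expression_matrix.tsv"))
  wt(result$sim$truth, "truth_table.tsv")
  wt(result$diff, "differential.tsv")
  wt(result$calls, "regulation_calls.tsv")
  wt(result$gradient, "gradient_summary.tsv")
  wt(result$fractions, "fraction_metrics.tsv")
  wt(result$features, "sequence_features.tsv")
  if (!is.null(result$feature_tests)) wt(result$feature_tests, "feature_tests.tsv")
  if (!is.null(result$motifs)) wt(result$motifs, "motif_enrichment.tsv")
  if (!is.null(result$sim$profiles)) {
    write_profiles_tsv(result$sim$profiles, p("fraction_profiles.tsv"))
  }
  for (s in names(result$sim$traces)) {
    write_trace_csv(result$sim$traces[[s]], p(sprintf("trace_%s.csv", s)))
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(pipeline_report(result), p("report.md"))
  invisible(out_dir)
}

#' Render a markdown report for a pipeline run
#'
#' Summarises the run: polysomal-area percentages per arm, the SL/PL/RO
#' regulation tally, the scenario-class table for the profiled subset, the
#' feature comparison and the motif table.
#'
#' @param result A `pipeline_result`.
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(result) {
  fmt_tab <- function(tab) {
    if (length(tab) == 0) return("(none)")
    paste(sprintf("- %s: %d", names(tab), as.integer(tab)), collapse = "\n")
  }
  cls_tab <- table(result$calls$class)
  scen_tab <- table(result$fractions$scenario_called)
  arm <- sub("\\..*$", "", result$gradient$sample)
  arm_mean <- tapply(result$gradient$polysomal_pct, arm, mean)
  lines <- c(
    "# Polysome profiling pipeline report", "",
    sprintf("Genes: %d; replicates: %d; seed: %d",
            result$manifest$n_genes, result$manifest$n_replicates,
            result$manifest$seed), "",
    "## Gradient quantification",
    sprintf("- mean polysomal area, %s: %.1f%%", names(arm_mean), arm_mean), "",
    "## Regulation calls (SL / PL / RO)",
    fmt_tab(cls_tab), "",
    "## Scenario classes (profiled subset)",
    fmt_tab(scen_tab), "")
  if (!is.null(result$feature_tests)) {
    ok <- !is.na(result$feature_tests$p_value)
    sig <- result$feature_tests$feature[ok & result$feature_tests$p_value < 0.05]
    lines <- c(lines, "## Sequence features",
               sprintf("- features at p < 0.05: %s",
                       if (length(sig)) paste(sig, collapse = ", ") else "none"),
               "")
  }
  if (!is.null(result$motifs)) {
    lines <- c(lines, "## Motif enrichment (5'UTR)",
               sprintf("- %s: fold %.2f, p = %.3g",
                       result$motifs$consensus, result$motifs$fold,
                       result$motifs$p_value), "")
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(pipeline_report(x), collapse = "\n"), "\n")
  invisible(x)
}
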