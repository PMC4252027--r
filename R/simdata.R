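# Synthetic-data generator: two-pool ribosome-loading model.
#
# Each mRNA copy is either sequestered (probability s, zero ribosomes) or
# active; active copies carry min(Poisson(lambda), C) ribosomes where
# C = floor(cds_len_codons / footprint_codons) is the packing capacity.
# The two pools decouple polysomal occupancy (fraction of copies carrying
# ribosomes) from ribosome density (ribosomes per engaged copy): occupancy
# responds to both s and lambda, density on engaged copies only to lambda.
# A single-parameter Poisson model cannot raise occupancy while lowering
# density, because both are increasing in lambda; the second pool is the
# minimal extension that can.

#' Kinetic parameters of one transcript under the two-pool loading model
#'
#' @param gene_id Character identifier.
#' @param cds_len_codons CDS length in codons (positive integer).
#' @param loading_intensity Mean ribosome load lambda per active copy before
#'   capacity truncation (>= 0).
#' @param sequestered_fraction Fraction s of copies withheld from the
#'   translatable pool, in \[0, 1\].
#' @param abundance mRNA copies per cell-equivalent (> 0).
#' @param footprint_codons Codons occluded per ribosome (default 10); the
#'   packing capacity is `floor(cds_len_codons / footprint_codons)` and must
#'   be >= 1.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, cds_len_codons, loading_intensity,
                             sequestered_fraction, abundance = 1,
                             footprint_codons = 10L) {
  assert_scalar_number(cds_len_codons, "cds_len_codons", lower = 1, integer = TRUE)
  assert_scalar_number(footprint_codons, "footprint_codons", lower = 1, integer = TRUE)
  assert_scalar_number(loading_intensity, "loading_intensity", lower = 0)
  assert_scalar_number(sequestered_fraction, "sequestered_fraction",
                       lower = 0, upper = 1)
  assert_scalar_number(abundance, "abundance", lower = 1e-12)
  capacity <- floor(cds_len_codons / footprint_codons)
  stop_if(capacity < 1, "capacity floor(cds_len_codons / footprint_codons) must be >= 1")
  structure(list(gene_id = as.character(gene_id),
                 cds_len_codons = as.integer(cds_len_codons),
                 footprint_codons = as.integer(footprint_codons),
                 capacity = as.integer(capacity),
                 loading_intensity = loading_intensity,
                 sequestered_fraction = sequestered_fraction,
                 abundance = abundance),
            class = "transcript_model")
}

#' Simulate per-copy ribosome counts
#'
#' Draws `n_copies` mRNA copies of a transcript: each copy is sequestered
#' independently with probability `s` (count forced to 0); active copies
#' draw Poisson(lambda) ribosomes, clamped at the packing capacity `C`
#' (clamping rather than resampling keeps the load monotone in lambda).
#' Deterministic given `seed`.
#'
#' @param model A [transcript_model()].
#' @param n_copies Number of copies to draw (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of ribosome counts in `0..C`.
#' @export
simulate_loading <- function(model, n_copies, seed) {
  stopifnot(inherits(model, "transcript_model"))
  assert_scalar_number(n_copies, "n_copies", lower = 1, integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  set.seed(seed)
  sequestered <- stats::runif(n_copies) < model$sequestered_fraction
  counts <- integer(n_copies)
  n_active <- sum(!sequestered)
  if (n_active > 0) {
    counts[!sequestered] <- pmin(stats::rpois(n_active, model$loading_intensity),
                                 model$capacity)
  }
  counts
}

#' Distribution of clamped ribosome counts
#'
#' Analytic probability mass of the two-pool load: `P(N = 0)` collects the
#' sequestered pool plus active copies drawing 0; `P(N = C)` collects the
#' clamped upper tail.
#'
#' @param model A [transcript_model()].
#' @return Numeric vector `p[1..C+1]` with `p[k] = P(N = k - 1)`.
#' @export
loading_pmf <- function(model) {
  lam <- model$loading_intensity
  s <- model$sequestered_fraction
  C <- model$capacity
  p <- stats::dpois(0:C, lam)
  p[C + 1] <- p[C + 1] + stats::ppois(C, lam, lower.tail = FALSE)
  p <- (1 - s) * p
  p[1] <- p[1] + s
  p
}

#' Expected occupancy of the polysomal pool
#'
#' Probability that a copy carries at least `n_min` ribosomes,
#' `(1 - s) * P(Poisson(lambda) >= n_min)` for `n_min <= C`. With
#' `n_min = 1` this is the fraction of ribosome-associated copies; with the
#' default pooling (`n_min = 2`) it is the fraction recovered in the
#' polysomal fractions (monosomes pool with non-polysomal material).
#'
#' @param model A [transcript_model()].
#' @param n_min Minimal ribosome count counted as occupied (default 2).
#' @return Probability in \[0, 1\].
#' @export
expected_occupancy <- function(model, n_min = 2L) {
  if (n_min > model$capacity) return(0)
  (1 - model$sequestered_fraction) *
    stats::ppois(n_min - 1, model$loading_intensity, lower.tail = FALSE)
}

#' Expected ribosomes per copy and per engaged copy
#'
#' `per_copy` is `(1 - s) * E[min(Poisson(lambda), C)]`; `per_engaged` is the
#' mean load conditional on carrying at least one ribosome, the model's
#' ribosome-density analogue (ignoring truncation it equals
#' `lambda / (1 - exp(-lambda))`).
#'
#' @param model A [transcript_model()].
#' @return List with `per_copy` and `per_engaged`.
#' @export
expected_load <- function(model) {
  p <- loading_pmf(model)
  n <- seq_along(p) - 1
  per_copy <- sum(n * p)
  engaged <- sum(p[-1])
  list(per_copy = per_copy,
       per_engaged = if (engaged > 0) per_copy / engaged else NA_real_)
}

#' Bin ribosome counts into a fraction profile
#'
#' Maps each copy's ribosome count to a gradient fraction via the scheme's
#' count-to-fraction rule (0 ribosomes to fraction 1, monosomes to the
#' monosome fraction, deeper fractions for larger loads) and tallies copies
#' per fraction. Conserves the total copy number exactly.
#'
#' @param counts Integer ribosome counts (from [simulate_loading()]).
#' @param scheme A [fraction_scheme()].
#' @return Numeric vector of length `n_fractions` summing to `length(counts)`.
#' @export
counts_to_profile <- function(counts, scheme = fraction_scheme()) {
  idx <- count_to_fraction(counts, scheme)
  as.numeric(tabulate(idx, nbins = scheme$n_fractions))
}

#' Render an A254 trace from a simulated mRNA population
#'
#' Places one bell-shaped (Gaussian) peak per ribosome class `n >= 1` at a
#' depth increasing with `log(n + 1)`, with peak area proportional to
#' `n * (copies carrying n ribosomes)` — A254 mass is proportional to
#' ribosome content. A small-subunit peak shallower than the monosome adds
#' the 40S/60S signal. Rendering choices (positions, widths) affect only the
#' visual trace, not any downstream statistic.
#'
#' @param class_counts Named or plain numeric vector; `class_counts[k]` is
#'   the number of copies carrying `k` ribosomes (`k = 1, 2, ...`).
#' @param scheme A [fraction_scheme()] fixing the trace domain.
#' @param peak_width Gaussian sd of each peak in position units (> 0).
#' @param baseline Constant baseline absorbance (>= 0).
#' @param n_points Number of sampled positions (>= 50).
#' @param subunit_area Subunit-peak area per mRNA copy (default 3): the free
#'   40S/60S/80S material that dominates the top of a real gradient,
#'   calibrated so a typical simulated population (roughly 70% of copies
#'   ribosome-associated) shows about 40% of its area in the polysomal
#'   region.
#' @param total_copies Population size the subunit peak scales with
#'   (defaults to the engaged copies in `class_counts`; pass the full copy
#'   number including free mRNPs when known — the free-subunit pool belongs
#'   to the lysate, not to the engaged transcripts).
#' @return A [gradient_trace()], strictly positive when the population is
#'   nonempty or baseline > 0.
#' @export
synthesize_trace <- function(class_counts, scheme = fraction_scheme(),
                             peak_width = 0.18, baseline = 0.02,
                             n_points = 600L, subunit_area = 3,
                             total_copies = sum(class_counts)) {
  assert_scalar_number(peak_width, "peak_width", lower = 1e-12)
  assert_scalar_number(baseline, "baseline", lower = 0)
  assert_scalar_number(n_points, "n_points", lower = 50, integer = TRUE)
  lo <- scheme$boundaries[1]
  hi <- scheme$boundaries[length(scheme$boundaries)]
  x <- seq(lo, hi, length.out = n_points)
  y <- rep(baseline, n_points)
  n_max <- length(class_counts)
  if (n_max > 0 && sum(class_counts) > 0) {
    # peak for ribosome class n sits at the centre of its destination
    # fraction; log spacing compresses deep polysome classes like a real
    # gradient does
    frac_centre <- (scheme$boundaries[-1] + scheme$boundaries[-length(scheme$boundaries)]) / 2
    pos <- frac_centre[count_to_fraction(seq_len(n_max), scheme)] +
      0.15 * log(seq_len(n_max) + 1)
    pos <- pmin(pos, hi - 2 * peak_width)
    for (n in seq_len(n_max)) {
      a <- n * class_counts[n]
      if (a > 0) y <- y + a * stats::dnorm(x, pos[n], peak_width)
    }
    # 40S/60S subunit signal shallow of the monosome
    sub_pos <- frac_centre[max(1L, scheme$monosome_fraction - 2L)]
    y <- y + subunit_area * total_copies * stats::dnorm(x, sub_pos, peak_width)
  }
  gradient_trace(x, y)
}

# ---- experiment-level simulation -------------------------------------------

#' Mechanistic scenario specification
#'
#' A scenario perturbs a transcript's control parameters: `delta_log2_abundance`
#' shifts the mRNA level, `delta_lambda` the loading intensity, `delta_s` the
#' sequestered fraction. Named scenarios carry defaults that realise the
#' classic mechanisms: pure transcriptional change, concordant
#' transcription+translation change, increased initiation (occupancy and
#' density both rise), sequestration release (more copies engaged at lower
#' per-copy load: occupancy up, density down), elongation stall and ribosome
#' runoff (both shift engaged copies to lighter polysomes). Magnitudes are
#' package defaults; no kinetic rates are implied.
#'
#' @param name One of `"null"`, `"transcriptional"`, `"concordant"`,
#'   `"initiation_up"`, `"sequestration_release"`, `"elongation_stall"`,
#'   `"runoff"`.
#' @param delta_log2_abundance,delta_lambda,delta_s Optional overrides of the
#'   named defaults.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, delta_log2_abundance = NULL,
                          delta_lambda = NULL, delta_s = NULL) {
  defaults <- list(
    null                  = c(0,    0,    0),
    transcriptional       = c(2,    0,    0),
    concordant            = c(1,    1,    0),
    initiation_up         = c(0,    1.5,  0),
    sequestration_release = c(0,   -1,   -0.4),
    elongation_stall      = c(0,   -0.8, -0.25),
    runoff                = c(0,   -1,    0))
  stop_if(!name %in% names(defaults),
          sprintf("unknown scenario '%s'", name))
  d <- defaults[[name]]
  spec <- list(name = name,
               delta_log2_abundance = if (is.null(delta_log2_abundance)) d[1] else delta_log2_abundance,
               delta_lambda = if (is.null(delta_lambda)) d[2] else delta_lambda,
               delta_s = if (is.null(delta_s)) d[3] else delta_s)
  if (name == "null") {
    stop_if(spec$delta_log2_abundance != 0 || spec$delta_lambda != 0 || spec$delta_s != 0,
            "the null scenario must have all deltas = 0")
  }
  if (name == "sequestration_release") {
    stop_if(spec$delta_s >= 0 || spec$delta_lambda > 0,
            "sequestration_release requires delta_s < 0 and delta_lambda <= 0")
  }
  structure(spec, class = "scenario_spec")
}

#' Experiment design for the synthetic study
#'
#' Describes a two-arm (control vs. sucrose) simulated experiment measured at
#' two levels (steady-state and polysomal RNA). `class_mixture` assigns
#' scenario proportions across genes; priors draw per-gene control
#' parameters. Defaults: 3 biological replicates; lambda ~ U\[1.5, 4\] and
#' s ~ U\[0.05, 0.35\], calibrated so that on average roughly 70% of a
#' transcript's copies are ribosome-associated in the control arm; CDS length
#' ~ uniform integer \[100, 800\] codons; abundance log-normal.
#'
#' @param n_genes Number of genes (>= 1).
#' @param class_mixture Named numeric vector/list mapping scenario name to
#'   proportion; must sum to 1 within 1e-9.
#' @param n_replicates Biological replicates per arm and level (>= 2,
#'   default 3).
#' @param noise_sd_log2 SD of the multiplicative log-normal measurement noise
#'   on the log2 scale (default 0.2).
#' @param spike_true True spike-in signal written per sample (default 100).
#' @param seed Integer seed; all draws derive from it via per-gene
#'   substreams, so gene order never changes a gene's draws.
#' @param scenarios Optional named list of [scenario_spec()] overriding the
#'   named defaults for the mixture components.
#' @param priors List overriding the default parameter priors; see Details.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_genes, class_mixture = c(null = 1),
                              n_replicates = 3L, noise_sd_log2 = 0.2,
                              spike_true = 100, seed = 1L,
                              scenarios = NULL, priors = list()) {
  assert_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  assert_scalar_number(n_replicates, "n_replicates", lower = 2, integer = TRUE)
  assert_scalar_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  assert_scalar_number(spike_true, "spike_true", lower = 1e-12)
  assert_scalar_number(seed, "seed", integer = TRUE)
  mix <- unlist(class_mixture)
  stop_if(is.null(names(mix)) || any(names(mix) == ""),
          "class_mixture must be named by scenario")
  stop_if(abs(sum(mix) - 1) > 1e-9, "class_mixture proportions must sum to 1")
  stop_if(any(mix < 0), "class_mixture proportions must be nonnegative")
  spec_list <- lapply(names(mix), function(nm) {
    if (!is.null(scenarios[[nm]])) scenarios[[nm]] else scenario_spec(nm)
  })
  names(spec_list) <- names(mix)
  default_priors <- list(cds_len_codons = c(100L, 800L),
                         lambda = c(1.5, 4),
                         s = c(0.05, 0.35),
                         log2_abundance_mean = 6,
                         log2_abundance_sd = 1.5,
                         footprint_codons = 10L)
  priors <- utils::modifyList(default_priors, priors)
  structure(list(n_genes = as.integer(n_genes), class_mixture = mix,
                 scenarios = spec_list,
                 n_replicates = as.integer(n_replicates),
                 noise_sd_log2 = noise_sd_log2, spike_true = spike_true,
                 seed = as.integer(seed), priors = priors),
            class = "experiment_design")
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

draw_gene <- function(design, i) {
  # substream 0: scenario + control parameters (one stream per gene, so the
  # draws for gene i do not depend on n_genes or gene order)
  set.seed(substream_seed(design$seed, i, 0L))
  pr <- design$priors
  scen_name <- sample(names(design$class_mixture), 1, prob = design$class_mixture)
  scen <- design$scenarios[[scen_name]]
  cds_len <- sample(pr$cds_len_codons[1]:pr$cds_len_codons[2], 1)
  lam_c <- runif1(pr$lambda)
  s_c <- runif1(pr$s)
  ab_c <- 2^stats::rnorm(1, pr$log2_abundance_mean, pr$log2_abundance_sd)
  ctrl <- transcript_model(sprintf("gene_%05d", i), cds_len, lam_c, s_c, ab_c,
                           pr$footprint_codons)
  trt <- transcript_model(ctrl$gene_id, cds_len,
                          max(lam_c + scen$delta_lambda, 0),
                          min(max(s_c + scen$delta_s, 0), 1),
                          ab_c * 2^scen$delta_log2_abundance,
                          pr$footprint_codons)
  list(scenario = scen_name, control = ctrl, treated = trt)
}

#' Simulate a full polysome-profiling experiment
#'
#' For each gene, control parameters are drawn from the design priors and the
#' treated arm applies the gene's scenario deltas. Expected signals are:
#' steady-state proportional to abundance; polysomal proportional to
#' abundance times the polysomal-pool occupancy (copies with >= 2 ribosomes
#' under the default pooling, where monosomes sediment with non-polysomal
#' material). Per-replicate multiplicative log-normal noise with sd
#' `noise_sd_log2` is applied on the log2 scale. Fully reproducible from the
#' design seed.
#'
#' @param design An [experiment_design()].
#' @param scheme A [fraction_scheme()] used for pooling, profiles and traces.
#' @param with_profiles,with_traces Generate per-sample fraction profiles /
#'   A254 traces (analytic expected masses with per-replicate noise). Off by
#'   default for large calibration runs; the expression matrix and truth
#'   table are always produced.
#' @return A list of class `sim_experiment` with elements
#'   \describe{
#'     \item{matrix}{numeric matrix genes x samples, linear scale; sample
#'       columns named `condition.light.level.rep`}
#'     \item{samples}{data.frame of sample annotations incl. spike signal}
#'     \item{truth}{data.frame: per gene the scenario and the true
#'       `delta_log2_sl`, `delta_log2_pl`, `delta_log2_ro`
#'       (`ro = pl - sl` exactly)}
#'     \item{profiles}{(optional) data.frame gene x fraction abundances with
#'       spike and sample columns}
#'     \item{traces}{(optional) named list of [gradient_trace()] per sample}
#'     \item{models}{per-gene control/treated [transcript_model()] pairs}
#'   }
#' @export
simulate_experiment <- function(design, scheme = fraction_scheme(),
                                with_profiles = FALSE, with_traces = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  n_min <- 2L # counts pooled as polysomal under the default fraction scheme
  genes <- lapply(seq_len(design$n_genes), function(i) draw_gene(design, i))
  gene_ids <- vapply(genes, function(g) g$control$gene_id, character(1))

  occ <- function(m) expected_occupancy(m, n_min)
  occ_c <- vapply(genes, function(g) occ(g$control), numeric(1))
  occ_t <- vapply(genes, function(g) occ(g$treated), numeric(1))
  ab_c <- vapply(genes, function(g) g$control$abundance, numeric(1))
  ab_t <- vapply(genes, function(g) g$treated$abundance, numeric(1))

  truth <- data.frame(
    gene_id = gene_ids,
    scenario = vapply(genes, function(g) g$scenario, character(1)),
    delta_log2_sl = log2(ab_t) - log2(ab_c),
    delta_log2_pl = (log2(ab_t) + log2(occ_t)) - (log2(ab_c) + log2(occ_c)),
    stringsAsFactors = FALSE)
  truth$delta_log2_ro <- truth$delta_log2_pl - truth$delta_log2_sl

  conditions <- c("control", "sucrose")
  levels_ <- c("steady_state", "polysomal")
  reps <- seq_len(design$n_replicates)
  samples <- expand.grid(rep = reps, level = levels_, condition = conditions,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$light <- "light"
  samples$sample <- with(samples, paste(condition, light, level, rep, sep = "."))
  samples$spike <- design$spike_true

  signal_for <- function(cond, level) {
    ab <- if (cond == "control") ab_c else ab_t
    oc <- if (cond == "control") occ_c else occ_t
    if (level == "steady_state") ab else ab * oc
  }
  mat <- matrix(NA_real_, design$n_genes, nrow(samples),
                dimnames = list(gene_ids, samples$sample))
  # substream 1: measurement noise, one stream per gene covering all samples
  noise <- matrix(NA_real_, design$n_genes, nrow(samples))
  for (i in seq_len(design$n_genes)) {
    set.seed(substream_seed(design$seed, i, 1L))
    noise[i, ] <- stats::rnorm(nrow(samples), 0, design$noise_sd_log2)
  }
  for (j in seq_len(nrow(samples))) {
    mu <- signal_for(samples$condition[j], samples$level[j])
    mat[, j] <- mu * 2^noise[, j]
  }

  out <- structure(list(matrix = mat, samples = samples, truth = truth,
                        models = genes, scheme = scheme, design = design),
                   class = "sim_experiment")

  if (with_profiles || with_traces) {
    prof_samples <- samples[samples$level == "polysomal", ]
    pmf_c <- lapply(genes, function(g) loading_pmf(g$control))
    pmf_t <- lapply(genes, function(g) loading_pmf(g$treated))
    frac_mass <- function(pmf, scheme) {
      idx <- count_to_fraction(seq_along(pmf) - 1L, scheme)
      as.numeric(tapply(pmf, factor(idx, levels = seq_len(scheme$n_fractions)),
                        sum, default = 0))
    }
    if (with_profiles) {
      rows <- list()
      for (j in seq_len(nrow(prof_samples))) {
        cond <- prof_samples$condition[j]
        pmfs <- if (cond == "control") pmf_c else pmf_t
        ab <- if (cond == "control") ab_c else ab_t
        jj <- match(prof_samples$sample[j], samples$sample)
        m <- t(vapply(pmfs, frac_mass, numeric(scheme$n_fractions),
                      scheme = scheme))
        m <- m * (ab * 2^noise[, jj])
        df <- as.data.frame(m)
        names(df) <- scheme$labels
        df <- cbind(data.frame(gene_id = gene_ids,
                               sample = prof_samples$sample[j],
                               spike = design$spike_true,
                               stringsAsFactors = FALSE), df)
        rows[[j]] <- df
      }
      out$profiles <- do.call(rbind, rows)
    }
    if (with_traces) {
      traces <- list()
      for (j in seq_len(nrow(prof_samples))) {
        cond <- prof_samples$condition[j]
        pmfs <- if (cond == "control") pmf_c else pmf_t
        ab <- if (cond == "control") ab_c else ab_t
        jj <- match(prof_samples$sample[j], samples$sample)
        ab_noisy <- ab * 2^noise[, jj]
        n_max <- max(vapply(pmfs, length, integer(1))) - 1L
        cls <- numeric(n_max)
        for (i in seq_along(pmfs)) {
          p <- pmfs[[i]][-1] # classes n >= 1
          cls[seq_along(p)] <- cls[seq_along(p)] + ab_noisy[i] * p
        }
        traces[[prof_samples$sample[j]]] <-
          synthesize_trace(cls, scheme = scheme,
                           total_copies = sum(ab_noisy))
      }
      out$traces <- traces
    }
  }
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment: %d genes x %d samples, scenarios: %s>\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%.2f", names(x$design$class_mixture),
                            x$design$class_mixture), collapse = ", ")))
  invisible(x)
}

# ---- synthetic transcript sequences ----------------------------------------

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate transcript region sequences
#'
#' Generates 5'UTR / CDS / 3'UTR nucleotide sequences per gene with
#' configurable GC content per region, a valid reading frame (ATG start,
#' single terminal stop, no internal stops), and optional planting of a
#' degenerate consensus motif into the 5'UTRs of a designated target subset —
#' giving sequence sets with known motif-enrichment ground truth.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param cds_len_codons Integer vector (recycled) of CDS lengths in codons,
#'   including the start but not the stop codon.
#' @param utr5_len,utr3_len Integer vectors (recycled) of UTR lengths in nt.
#' @param gc Named numeric: GC fraction per region
#'   (default `c(utr5 = 0.38, cds = 0.44, utr3 = 0.32)`).
#' @param plant_motif Optional consensus string (bracket notation) to embed.
#' @param plant_in Gene ids receiving a planted motif instance in the 5'UTR.
#' @param plant_prob_bg Probability that a non-target gene also receives one
#'   (background rate, default 0.05).
#' @param seed Integer seed.
#' @return A data.frame with columns `gene_id`, `utr5`, `cds`, `utr3`.
#' @export
simulate_transcripts <- function(gene_ids, cds_len_codons = 300L,
                                 utr5_len = 120L, utr3_len = 200L,
                                 gc = c(utr5 = 0.38, cds = 0.44, utr3 = 0.32),
                                 plant_motif = NULL, plant_in = character(0),
                                 plant_prob_bg = 0.05, seed = 1L) {
  n <- length(gene_ids)
  cds_len_codons <- rep_len(as.integer(cds_len_codons), n)
  utr5_len <- rep_len(as.integer(utr5_len), n)
  utr3_len <- rep_len(as.integer(utr3_len), n)
  stop_if(any(cds_len_codons < 2), "cds_len_codons must be >= 2")
  pat <- if (!is.null(plant_motif)) parse_consensus(plant_motif) else NULL
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  out <- data.frame(gene_id = gene_ids, utr5 = "", cds = "", utr3 = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i, 2L))
    utr5 <- random_dna(utr5_len[i], gc[["utr5"]])
    # body codons drawn GC-weighted from the 60 non-start sense codons
    w <- vapply(sense, function(cd) {
      g <- sum(strsplit(cd, "")[[1]] %in% c("G", "C"))
      gc[["cds"]]^g * (1 - gc[["cds"]])^(3 - g)
    }, numeric(1))
    body <- sample(sense, cds_len_codons[i] - 1L, replace = TRUE, prob = w)
    cds <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
    utr3 <- random_dna(utr3_len[i], gc[["utr3"]])
    if (!is.null(pat)) {
      planted <- gene_ids[i] %in% plant_in || stats::runif(1) < plant_prob_bg
      if (planted && utr5_len[i] >= length(pat$sets) + 2L) {
        inst <- paste(vapply(pat$sets, function(s) sample(s, 1), character(1)),
                      collapse = "")
        at <- sample.int(utr5_len[i] - nchar(inst) + 1L, 1)
        substr(utr5, at, at + nchar(inst) - 1L) <- inst
      }
    }
    out$utr5[i] <- utr5; out$cds[i] <- cds; out$utr3[i] <- utr3
  }
  out
}
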