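# Differential analysis on three levels: steady-state mRNA (SL), polysomal
# mRNA (PL), and polysomal occupancy (RO = PL/SL), plus the spike-in and
# GC-MS internal-standard normalisations.

#' Spike-in normalisation of an expression matrix
#'
#' Divides each sample's intensities by its spike-in signal (an exogenous
#' reference RNA added at a fixed amount before extraction, making the
#' normalisation independent of the sample's own RNA content), then rescales
#' by the geometric mean of the spike signals so the overall magnitude of the
#' matrix is preserved.
#'
#' @param mat Numeric matrix, genes x samples, linear scale.
#' @param spike_signal Positive numeric vector, one value per sample.
#' @return Matrix of the same shape.
#' @export
spike_normalize <- function(mat, spike_signal) {
  stop_if(length(spike_signal) != ncol(mat),
          "need one spike signal per sample")
  stop_if(any(!is.finite(spike_signal)) || any(spike_signal <= 0),
          "spike signals must be positive")
  sweep(mat, 2, spike_signal / geometric_mean(spike_signal), "/")
}

#' Internal-standard (PCA-t1) normalisation of metabolite peak areas
#'
#' Normalises GC-MS peak areas by the first principal-component score of the
#' internal-standard submatrix, then by sample weight. The PC1 loading is
#' computed on the mean-centered standards; each sample's normalisation
#' factor is the *uncentered* projection of its standard areas onto that
#' loading, sign-fixed to correlate positively with the mean standard
#' intensity and scaled to geometric mean 1 (so a pure sample-size effect —
#' all standards scaled by a common per-sample factor — cancels exactly).
#' A degenerate standards submatrix (zero variance) falls back to
#' mean-of-standards normalisation with a warning.
#'
#' @param peak_areas Numeric matrix, samples x compounds, positive.
#' @param standard_ids Column names (or indices) of the internal standards;
#'   >= 2 required.
#' @param sample_weights Positive numeric vector, one per sample (default 1).
#' @return Matrix of normalised areas (samples x compounds), with the
#'   per-sample factors in attribute `"t1_factor"`.
#' @export
internal_standard_normalize <- function(peak_areas, standard_ids,
                                        sample_weights = rep(1, nrow(peak_areas))) {
  stop_if(nrow(peak_areas) < 2, "need >= 2 samples")
  stop_if(length(standard_ids) < 2, "need >= 2 internal standards")
  stop_if(any(peak_areas <= 0), "peak areas must be positive")
  stop_if(any(sample_weights <= 0), "sample weights must be positive")
  std <- peak_areas[, standard_ids, drop = FALSE]
  centered <- scale(std, center = TRUE, scale = FALSE)
  if (sum(centered^2) < 1e-12) {
    warning("degenerate standards submatrix; falling back to mean-of-standards normalisation")
    f <- rowMeans(std)
  } else {
    w <- stats::prcomp(std, center = TRUE, scale. = FALSE)$rotation[, 1]
    f <- as.numeric(std %*% w)
    if (stats::cor(f, rowMeans(std)) < 0) f <- -f
    if (any(f <= 0)) {
      warning("nonpositive t1 projections shifted to be strictly positive")
      f <- f - min(f) + 0.01 * diff(range(f))
    }
  }
  f <- f / geometric_mean(f)
  out <- peak_areas / (f * sample_weights)
  attr(out, "t1_factor") <- f
  out
}

#' Fold-change table between treatment groups
#'
#' Downstream arithmetic on normalised peak areas: per-compound mean ratio of
#' each treatment group to a reference group.
#'
#' @param normalized Numeric matrix, samples x compounds.
#' @param groups Factor/character of group labels per sample.
#' @param reference Reference group label.
#' @return Matrix of fold changes, groups (minus reference) x compounds.
#' @export
fold_change_table <- function(normalized, groups, reference) {
  groups <- as.character(groups)
  stop_if(!reference %in% groups, "reference group not present")
  ref_mean <- colMeans(normalized[groups == reference, , drop = FALSE])
  other <- setdiff(unique(groups), reference)
  t(vapply(other, function(g) {
    colMeans(normalized[groups == g, , drop = FALSE]) / ref_mean
  }, numeric(ncol(normalized))))
}

# Vectorised two-sided two-sample t-test on the rows of two matrices.
# Pooled variance by default (exact under homoscedastic normal noise, the
# regime the simulator produces and the only tractable one at n = 3);
# var_equal = FALSE gives the Welch-Satterthwaite test, which is valid under
# unequal variances but conservative at very small n.
ttest_rows <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  stop_if(na < 2 || nb < 2, "need >= 2 replicates per group")
  ma <- row_means(a); mb <- row_means(b)
  if (var_equal) {
    sp2 <- ((na - 1) * row_vars(a) + (nb - 1) * row_vars(b)) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, nrow(a))
  } else {
    va <- row_vars(a) / na; vb <- row_vars(b) / nb
    se2 <- va + vb
    df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # exact-separation guard: zero variance in both groups
  degen <- se2 == 0
  p[degen & (ma == mb)] <- 1
  p[degen & (ma != mb)] <- 0
  list(estimate = ma - mb, statistic = tstat, df = df, p = p)
}

#' Per-gene differential test between two groups
#'
#' log2 fold change = mean(treated) - mean(control) on the log2 scale, with
#' a two-sided two-sample t-test p-value per gene. The default pools the
#' within-group variances (classical two-sample t, exact under equal noise
#' variance — the regime a spike-normalised replicate design aims for, and
#' the only well-estimated one at 3 replicates); `var_equal = FALSE`
#' switches to the Welch test for unequal variances, which is conservative
#' at very small n. Linear-scale input is log2-transformed first when
#' `log2_input = FALSE`.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param treated,control Column names or indices of the two groups
#'   (>= 2 each).
#' @param log2_input Is `mat` already on the log2 scale? Default `FALSE`
#'   (linear intensities).
#' @param var_equal Pool the variances (default `TRUE`); `FALSE` = Welch.
#' @return A data.frame with `gene_id`, `log2fc`, `t`, `df`, `p_value`.
#' @export
differential <- function(mat, treated, control, log2_input = FALSE,
                         var_equal = TRUE) {
  if (!log2_input) {
    stop_if(any(mat <= 0), "linear intensities must be positive (or pass log2_input = TRUE)")
    mat <- log2(mat)
  }
  a <- mat[, treated, drop = FALSE]
  b <- mat[, control, drop = FALSE]
  res <- ttest_rows(a, b, var_equal = var_equal)
  data.frame(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             log2fc = res$estimate, t = res$statistic, df = res$df,
             p_value = res$p, row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p ascending, take
#' `q_(i) = min over k >= i of p_(k) * m / k` capped at 1, and map back to
#' input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvals) {
  stop_if(any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Occupancy contrast from matched SL and PL measurements
#'
#' Polysomal occupancy is tested on per-replicate log-ratios: for replicate
#' j, `o_j = log2(PL_j) - log2(SL_j)`; the occupancy log2 fold change is
#' `mean(o, treated) - mean(o, control)` with a two-sample t-test on the o
#' values (pooled variance by default, see [differential()]). On balanced
#' replicate structures the identity `log2FC_RO = log2FC_PL - log2FC_SL`
#' holds exactly.
#'
#' @param pl_treated,pl_control,sl_treated,sl_control Numeric matrices
#'   (genes x replicates) of polysomal and steady-state intensities; PL and
#'   SL columns are matched by position (replicate pairing is explicit, never
#'   guessed).
#' @param log2_input Are the matrices already log2?
#' @param var_equal Pool the variances (default `TRUE`); `FALSE` = Welch.
#' @return A data.frame with `gene_id`, `log2fc`, `t`, `df`, `p_value`.
#' @export
occupancy_contrast <- function(pl_treated, sl_treated, pl_control, sl_control,
                               log2_input = FALSE, var_equal = TRUE) {
  stop_if(!all(dim(pl_treated) == dim(sl_treated)) ||
            !all(dim(pl_control) == dim(sl_control)),
          "PL and SL replicate structures do not match")
  if (!log2_input) {
    stop_if(any(pl_treated <= 0) || any(sl_treated <= 0) ||
              any(pl_control <= 0) || any(sl_control <= 0),
            "linear intensities must be positive")
    pl_treated <- log2(pl_treated); sl_treated <- log2(sl_treated)
    pl_control <- log2(pl_control); sl_control <- log2(sl_control)
  }
  o_t <- pl_treated - sl_treated
  o_c <- pl_control - sl_control
  res <- ttest_rows(o_t, o_c, var_equal = var_equal)
  data.frame(gene_id = rownames(pl_treated) %||% as.character(seq_len(nrow(pl_treated))),
             log2fc = res$estimate, t = res$statistic, df = res$df,
             p_value = res$p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Three-contrast differential analysis of a simulated or assembled matrix
#'
#' Runs the SL, PL and RO contrasts (sucrose vs. control at the steady-state
#' level, at the polysomal level, and on per-replicate PL/SL log-ratios) on a
#' genes x samples matrix whose columns are annotated with condition, level
#' and replicate, and applies Benjamini-Hochberg adjustment per contrast.
#'
#' @param mat Numeric matrix, genes x samples, linear scale unless
#'   `log2_input`.
#' @param samples Data.frame with columns `sample`, `condition`
#'   (`control`/`sucrose`), `level` (`steady_state`/`polysomal`), `rep`;
#'   rows match the matrix columns.
#' @param log2_input Is the matrix already on log2 scale?
#' @param mode Occupancy test mode: `"ratio"` (default; t-test on
#'   per-replicate log-ratios) or `"interaction"` (condition x level
#'   interaction term of a per-gene linear model on log2 values).
#' @param var_equal Pool the variances (default `TRUE`); `FALSE` = Welch.
#' @return A data.frame with one row per gene x contrast: `gene_id`,
#'   `contrast` (`SL`/`PL`/`RO`), `log2fc`, `p_value`, `padj`.
#' @export
differential_all <- function(mat, samples, log2_input = FALSE,
                             mode = c("ratio", "interaction"),
                             var_equal = TRUE) {
  mode <- match.arg(mode)
  need <- c("sample", "condition", "level", "rep")
  stop_if(!all(need %in% names(samples)), "samples must have columns sample, condition, level, rep")
  stop_if(nrow(samples) != ncol(mat), "sample annotation rows must match matrix columns")
  cols <- function(cond, lev) {
    sel <- samples$condition == cond & samples$level == lev
    samples$sample[sel][order(samples$rep[sel])]
  }
  sl_t <- cols("sucrose", "steady_state"); sl_c <- cols("control", "steady_state")
  pl_t <- cols("sucrose", "polysomal");    pl_c <- cols("control", "polysomal")
  stop_if(min(lengths(list(sl_t, sl_c, pl_t, pl_c))) < 2,
          "every condition x level cell needs >= 2 replicates")
  sl <- differential(mat, sl_t, sl_c, log2_input = log2_input,
                     var_equal = var_equal)
  pl <- differential(mat, pl_t, pl_c, log2_input = log2_input,
                     var_equal = var_equal)
  if (mode == "ratio") {
    stop_if(length(pl_t) != length(sl_t) || length(pl_c) != length(sl_c),
            "ratio mode needs matched SL/PL replicate counts")
    ro <- occupancy_contrast(mat[, pl_t, drop = FALSE], mat[, sl_t, drop = FALSE],
                             mat[, pl_c, drop = FALSE], mat[, sl_c, drop = FALSE],
                             log2_input = log2_input, var_equal = var_equal)
  } else {
    lm2 <- if (log2_input) mat else log2(mat)
    cond <- factor(samples$condition, c("control", "sucrose"))
    lev <- factor(samples$level, c("steady_state", "polysomal"))
    X <- stats::model.matrix(~ cond * lev)
    fit <- stats::lm.fit(X, t(lm2))
    cf <- t(fit$coefficients)
    rss <- colSums(fit$residuals^2)
    dfres <- nrow(X) - ncol(X)
    XtXi <- solve(crossprod(X))
    se <- sqrt(rss / dfres * XtXi[4, 4])
    tstat <- cf[, 4] / se
    ro <- data.frame(gene_id = sl$gene_id, log2fc = cf[, 4], t = tstat,
                     df = dfres,
                     p_value = 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE),
                     row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- rbind(cbind(sl, contrast = "SL"),
               cbind(pl, contrast = "PL"),
               cbind(ro, contrast = "RO"))
  res$padj <- stats::ave(res$p_value, res$contrast,
                         FUN = benjamini_hochberg)
  res[, c("gene_id", "contrast", "log2fc", "p_value", "padj")]
}

#' Classify genes from the three contrasts
#'
#' Applies the significance rule (BH-adjusted p <= `padj` AND
#' |log2FC| >= `lfc`, i.e. at least a 2-fold change at the default
#' `lfc = 1`) per contrast, then assigns one class per gene with documented
#' precedence: `RO_changed` if the occupancy contrast is significant (fold
#' gate `ro_lfc`, default 1); otherwise `concordant` if both SL and PL are
#' significant; otherwise `SL_only` / `PL_only`; otherwise `unchanged`.
#'
#' @param diff Output of [differential_all()] (long data.frame, three rows
#'   per gene).
#' @param padj Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold for SL and PL (default 1).
#' @param ro_lfc Absolute log2 fold-change threshold for RO (default 1).
#' @return A data.frame with `gene_id`, `class`, and per-contrast direction
#'   columns `dir_SL`, `dir_PL`, `dir_RO` in {-1, 0, 1}.
#' @export
classify_regulation <- function(diff, padj = 0.05, lfc = 1, ro_lfc = 1) {
  need <- c("SL", "PL", "RO")
  stop_if(!all(need %in% diff$contrast), "diff must contain SL, PL and RO contrasts")
  wide <- lapply(need, function(ct) diff[diff$contrast == ct, ])
  names(wide) <- need
  ids <- wide$SL$gene_id
  stop_if(!identical(ids, wide$PL$gene_id) || !identical(ids, wide$RO$gene_id),
          "contrast blocks must cover identical genes in identical order")
  sig <- function(ct, th) wide[[ct]]$padj <= padj & abs(wide[[ct]]$log2fc) >= th
  dir_of <- function(ct, s) ifelse(s, sign(wide[[ct]]$log2fc), 0L)
  s_sl <- sig("SL", lfc); s_pl <- sig("PL", lfc); s_ro <- sig("RO", ro_lfc)
  class <- rep("unchanged", length(ids))
  class[s_sl & !s_pl] <- "SL_only"
  class[s_pl & !s_sl] <- "PL_only"
  class[s_sl & s_pl] <- "concordant"
  class[s_ro] <- "RO_changed"
  data.frame(gene_id = ids, class = class,
             dir_SL = dir_of("SL", s_sl), dir_PL = dir_of("PL", s_pl),
             dir_RO = dir_of("RO", s_ro),
             row.names = NULL, stringsAsFactors = FALSE)
}
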