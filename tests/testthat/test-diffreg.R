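# Normalisation and the three-contrast differential analysis.

test_that("spike normalisation rescales samples and preserves magnitude", {
  set.seed(1)
  m <- matrix(2^rnorm(60, 8), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(spike_normalize(m, rep(3, 6)), m, tolerance = 1e-12)

  spikes <- c(2, 1, 1, 1, 1, 1)
  norm <- spike_normalize(m, spikes)
  gm <- exp(mean(log(spikes)))
  expect_equal(norm[, 1], m[, 1] / 2 * gm, tolerance = 1e-12)
  expect_equal(norm[, 2], m[, 2] * gm, tolerance = 1e-12)

  # a gene behaving exactly like the spike becomes constant
  m2 <- rbind(m, spike = spikes * 5)
  expect_equal(unname(spike_normalize(m2, spikes)["spike", ]),
               rep(5 * gm, 6), tolerance = 1e-12)
  expect_error(spike_normalize(m, c(1, 1, 1, 1, 1, 0)), "positive")
})

test_that("internal-standard t1 normalisation cancels pure size effects", {
  set.seed(2)
  # identical standard profiles across samples: division by weight only
  areas <- matrix(2^rnorm(40, 10), 5, 8,
                  dimnames = list(paste0("smp", 1:5), paste0("c", 1:8)))
  areas[, 1:3] <- rep(c(100, 200, 150), each = 5)
  w <- c(1, 2, 1, 4, 1)
  expect_warning(res <- internal_standard_normalize(areas, 1:3, w),
                 "degenerate")
  expect_equal(res[, 4:8], areas[, 4:8] / w, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_warning(res1 <- internal_standard_normalize(areas, 1:3),
                 "degenerate")
  expect_equal(unclass(res1), unclass(areas), tolerance = 1e-9,
               ignore_attr = TRUE)

  # rank-1 size effect: standards = c_i * fixed vector
  ci <- c(0.6, 1.0, 1.4, 2.1, 0.8)
  v <- c(120, 80, 200, 50)
  areas2 <- cbind(outer(ci, v), matrix(2^rnorm(15, 9), 5, 3))
  colnames(areas2) <- paste0("c", 1:7)
  rownames(areas2) <- paste0("smp", 1:5)
  res2 <- internal_standard_normalize(areas2, 1:4)
  # the t1 factor recovers c_i up to the geometric-mean scale
  f <- attr(res2, "t1_factor")
  expect_equal(f, ci / exp(mean(log(ci))), tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigen-decomposition oracle: PC1 loading of the centered standards
  e <- eigen(cov(scale(areas2[, 1:4], center = TRUE, scale = FALSE)))
  wvec <- e$vectors[, 1]
  proj <- as.numeric(areas2[, 1:4] %*% wvec)
  if (cor(proj, ci) < 0) proj <- -proj
  expect_equal(f, proj / exp(mean(log(proj))), tolerance = 1e-9)
  expect_error(internal_standard_normalize(areas2, 1), "standards")
})

test_that("fold-change tables are plain group-mean ratios", {
  norm <- rbind(ctrl1 = c(10, 20), ctrl2 = c(12, 18),
                trt1 = c(22, 19), trt2 = c(22, 21))
  colnames(norm) <- c("met1", "met2")
  fc <- fold_change_table(norm, c("c", "c", "t", "t"), "c")
  expect_equal(unname(fc["t", ]), c(2, 20 / 19))
})

test_that("differential tests match hand oracles in both variance modes", {
  m <- rbind(g1 = c(5.1, 5.3, 5.2, 4.0, 4.1, 3.9),
             g2 = c(4.0, 4.2, 4.1, 4.0, 4.2, 4.1))
  colnames(m) <- paste0("s", 1:6)

  # identical groups: fc 0, p 1
  d0 <- differential(m[2, , drop = FALSE], 1:3, 4:6, log2_input = TRUE)
  expect_equal(d0$log2fc, 0)
  expect_equal(d0$p_value, 1)

  # exact 4-fold change on the linear scale
  lin <- rbind(g = c(8, 8, 8, 2, 2, 2) * c(1, 1.1, 0.9, 1, 1.1, 0.9))
  colnames(lin) <- paste0("s", 1:6)
  expect_equal(differential(lin, 1:3, 4:6)$log2fc, 2)

  # frozen Welch oracle (textbook formula computed independently)
  dw <- differential(m, 1:3, 4:6, log2_input = TRUE, var_equal = FALSE)
  expect_equal(dw$log2fc[1], 1.2)
  expect_equal(dw$p_value[1], 1.247260352415951e-4, tolerance = 1e-9)
  expect_equal(dw$df[1], 4, tolerance = 1e-9)

  # both modes agree with stats::t.test on random data
  set.seed(3)
  r <- matrix(rnorm(7 * 30), 30, 7, dimnames = list(NULL, paste0("s", 1:7)))
  for (ve in c(TRUE, FALSE)) {
    d <- differential(r, 1:4, 5:7, log2_input = TRUE, var_equal = ve)
    ref <- apply(r, 1, function(x) {
      stats::t.test(x[1:4], x[5:7], var.equal = ve)$p.value
    })
    expect_equal(d$p_value, ref, tolerance = 1e-12)
  }
  expect_error(differential(r, 1, 2:3, log2_input = TRUE), "replicates")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(benjamini_hochberg(0.02), 0.02)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-14)
  }
  # permutation equivariance
  p <- runif(50)
  perm <- sample(50)
  expect_identical(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
})

test_that("occupancy contrast obeys the PL - SL identity", {
  set.seed(5)
  n <- 50
  sl_t <- matrix(rnorm(3 * n, 8), n); sl_c <- matrix(rnorm(3 * n, 8), n)
  pl_t <- matrix(rnorm(3 * n, 7), n); pl_c <- matrix(rnorm(3 * n, 7), n)
  ro <- occupancy_contrast(pl_t, sl_t, pl_c, sl_c, log2_input = TRUE)
  sl_fc <- rowMeans(sl_t) - rowMeans(sl_c)
  pl_fc <- rowMeans(pl_t) - rowMeans(pl_c)
  expect_equal(ro$log2fc, pl_fc - sl_fc, tolerance = 1e-12)

  # PL response identical to SL response: RO = 0
  ro0 <- occupancy_contrast(sl_t + 1, sl_t, sl_c + 1, sl_c, log2_input = TRUE)
  expect_equal(ro0$log2fc, rep(0, n))
  expect_error(occupancy_contrast(pl_t[, 1:2], sl_t, pl_c, sl_c,
                                  log2_input = TRUE), "match")
})

test_that("ratio and interaction occupancy modes agree on balanced designs", {
  des <- experiment_design(120, c(null = 0.8, sequestration_release = 0.2),
                           seed = 11,
                           priors = list(lambda = c(3, 3), s = c(0.6, 0.6)))
  sim <- simulate_experiment(des)
  d_ratio <- differential_all(sim$matrix, sim$samples, mode = "ratio")
  d_int <- differential_all(sim$matrix, sim$samples, mode = "interaction")
  ro_r <- d_ratio[d_ratio$contrast == "RO", ]
  ro_i <- d_int[d_int$contrast == "RO", ]
  expect_equal(ro_r$log2fc, ro_i$log2fc, tolerance = 1e-9)
  # both modes separate release genes from nulls (df differ, so raw p differ)
  truth <- sim$truth$scenario == "sequestration_release"
  expect_lt(median(ro_r$p_value[truth]), median(ro_r$p_value[!truth]))
  expect_lt(median(ro_i$p_value[truth]), median(ro_i$p_value[!truth]))
  # release genes show a positive occupancy shift in nearly all cases
  expect_gte(mean(ro_r$log2fc[truth] > 0), 0.95)
})

test_that("regulation calls apply the significance rule with documented precedence", {
  mk <- function(sl_fc, sl_p, pl_fc, pl_p, ro_fc, ro_p) {
    data.frame(gene_id = rep("g", 3), contrast = c("SL", "PL", "RO"),
               log2fc = c(sl_fc, pl_fc, ro_fc),
               p_value = c(sl_p, pl_p, ro_p),
               padj = c(sl_p, pl_p, ro_p))
  }
  cls <- function(...) classify_regulation(mk(...))$class
  expect_equal(cls(2, 1, 2, 1, 0, 1), "unchanged")
  expect_equal(cls(2, 0.01, 2, 0.01, 0.1, 0.9), "concordant")
  expect_equal(cls(2, 0.01, 0.2, 0.9, -1.8, 0.01), "RO_changed")
  expect_equal(cls(2, 0.01, 0.2, 0.9, -1.8, 0.9), "SL_only")
  expect_equal(cls(0.2, 0.9, 2, 0.01, 1.8, 0.2), "PL_only")
  # fold gate: significant p but sub-threshold fold change stays unchanged
  expect_equal(cls(0.5, 0.001, 0.5, 0.001, 0.1, 0.9), "unchanged")
  expect_error(classify_regulation(mk(2, 1, 2, 1, 0, 1)[1:2, ]), "contrasts")
})

test_that("the default test is calibrated and Welch is conservative, never liberal", {
  # pooled-variance mode: exact under equal-variance normal noise
  set.seed(6)
  n <- 100000
  m <- matrix(rnorm(6 * n, sd = 0.2), n, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  d <- differential(m, 1:3, 4:6, log2_input = TRUE)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(d$p_value <= 0.05) - 0.05), 3 * se)
  dw <- differential(m, 1:3, 4:6, log2_input = TRUE, var_equal = FALSE)
  expect_lt(mean(dw$p_value <= 0.05), 0.05 + 3 * se)
})
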