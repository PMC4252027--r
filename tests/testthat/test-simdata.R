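# Two-pool loading model: per-copy draws, profiles, traces, experiment
# simulation, transcript sequences.

test_that("loading draws respect the two pools and the analytic mean", {
  m_seq <- transcript_model("g", 300, 2, 1)
  expect_true(all(simulate_loading(m_seq, 100, 1) == 0))

  m_off <- transcript_model("g", 300, 0, 0)
  expect_true(all(simulate_loading(m_off, 100, 1) == 0))

  # lambda = 1.2, s = 0.3, C = 30 >> lambda: truncation term negligible,
  # sample mean within 3 SE of (1 - s) * lambda = 0.84
  m <- transcript_model("g", 300, 1.2, 0.3)
  trunc_term <- sum(dpois(31:200, 1.2) * (31:200 - 30))
  expect_lt(trunc_term, 1e-6)
  counts <- simulate_loading(m, 1e5, 42)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 0.84), 3 * se)
  expect_true(all(counts >= 0 & counts <= m$capacity))

  expect_identical(simulate_loading(m, 1000, 7), simulate_loading(m, 1000, 7))
  expect_error(simulate_loading(m, 10.5, 1), "integer")
  expect_error(transcript_model("g", 300, 2, 1.2), "sequestered_fraction")
  expect_error(transcript_model("g", 5, 2, 0.2), "capacity")
})

test_that("analytic pmf matches Monte Carlo and clamps the upper tail", {
  m <- transcript_model("g", 60, 3, 0.25) # C = 6: clamping matters
  p <- loading_pmf(m)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  counts <- simulate_loading(m, 2e5, 11)
  emp <- tabulate(counts + 1L, nbins = m$capacity + 1L) / length(counts)
  expect_equal(emp, p, tolerance = 0.01)
  # clamped mass at C exceeds the raw Poisson mass there
  expect_gt(p[m$capacity + 1], (1 - 0.25) * dpois(m$capacity, 3))
})

test_that("counts_to_profile conserves copies and maps counts as documented", {
  sch <- fraction_scheme()
  expect_equal(counts_to_profile(rep(0L, 50), sch),
               c(50, rep(0, 11)))
  # n = 2 lands in the first polysomal fraction (5 by default)
  pr <- counts_to_profile(c(2L, 2L, 2L), sch)
  expect_equal(pr[5], 3)
  expect_equal(sum(pr), 3)
  # monosomes sediment in the scheme's monosome fraction
  expect_equal(counts_to_profile(c(1L, 1L), sch)[sch$monosome_fraction], 2)
  # deep classes saturate at the bottom fraction; conservation is exact
  m <- transcript_model("g", 800, 3, 0.3)
  counts <- simulate_loading(m, 1e4, 5)
  expect_identical(sum(counts_to_profile(counts, sch)), 1e4)
  # larger loads never map shallower
  expect_true(all(diff(count_to_fraction(0:20, sch)) >= 0))
})

test_that("trace rendering is linear with area proportional to ribosome content", {
  sch <- fraction_scheme()
  empty <- synthesize_trace(numeric(0), sch, baseline = 0.02)
  expect_equal(empty$absorbance, rep(0.02, length(empty$positions)))
  res <- polysomal_area_pct(subtract_baseline(empty, empty), sch)
  expect_true(is.na(res) && attr(res, "undefined"))

  # class n = 3 with m copies vs n = 1 with 3m copies: equal ribosome mass
  t3 <- synthesize_trace(c(0, 0, 100), sch, baseline = 0, subunit_area = 0)
  t1 <- synthesize_trace(c(300), sch, baseline = 0, subunit_area = 0)
  expect_equal(trace_area(t3), trace_area(t1), tolerance = 1e-6)

  # doubling every class count doubles trace - baseline pointwise
  cls <- c(10, 40, 80, 60, 30, 10)
  a <- synthesize_trace(cls, sch, baseline = 0.05)
  b <- synthesize_trace(2 * cls, sch, baseline = 0.05)
  expect_equal(b$absorbance - 0.05, 2 * (a$absorbance - 0.05),
               tolerance = 1e-9)
  expect_true(all(a$absorbance > 0))
  expect_error(synthesize_trace(cls, sch, peak_width = 0), "peak_width")
})

test_that("occupancy and density are monotone in lambda and s", {
  lams <- seq(0.5, 5, by = 0.5)
  occ <- vapply(lams, function(l) {
    expected_occupancy(transcript_model("g", 400, l, 0.3), n_min = 1)
  }, numeric(1))
  den <- vapply(lams, function(l) {
    expected_load(transcript_model("g", 400, l, 0.3))$per_engaged
  }, numeric(1))
  expect_true(all(diff(occ) >= 0))
  expect_true(all(diff(den) >= 0))

  ss <- seq(0, 0.9, by = 0.1)
  occ_s <- vapply(ss, function(s) {
    expected_occupancy(transcript_model("g", 400, 2.5, s), n_min = 1)
  }, numeric(1))
  den_s <- vapply(ss, function(s) {
    expected_load(transcript_model("g", 400, 2.5, s))$per_engaged
  }, numeric(1))
  expect_true(all(diff(occ_s) <= 0))
  # density on engaged copies does not depend on s
  expect_equal(den_s, rep(den_s[1], length(ss)), tolerance = 1e-12)

  # Monte Carlo agrees within 3 SE: occupancy at lambda 2 vs 3 (s fixed)
  mc_occ <- function(lam, seed) {
    counts <- simulate_loading(transcript_model("g", 400, lam, 0.3), 1e5, seed)
    mean(counts >= 1)
  }
  o2 <- mc_occ(2, 1); o3 <- mc_occ(3, 2)
  se <- sqrt(0.25 / 1e5)
  expect_gt(o3 - o2, -3 * se * 2)
  expect_gt(o3, o2)
})

test_that("simulated experiments honour the scenario deltas and the truth identity", {
  des0 <- experiment_design(30, c(null = 1), noise_sd_log2 = 0, seed = 5)
  sim0 <- simulate_experiment(des0)
  s <- sim0$samples
  for (lev in c("steady_state", "polysomal")) {
    a <- sim0$matrix[, s$sample[s$condition == "sucrose" & s$level == lev]]
    b <- sim0$matrix[, s$sample[s$condition == "control" & s$level == lev]]
    expect_equal(log2(a) - log2(b), matrix(0, 30, 3, dimnames = dimnames(a)),
                 tolerance = 1e-12)
  }
  expect_true(all(sim0$truth$scenario == "null"))
  expect_true(all(sim0$truth$delta_log2_ro == 0))

  dtx <- experiment_design(20, c(transcriptional = 1), seed = 6)
  ttx <- simulate_experiment(dtx)$truth
  expect_equal(ttx$delta_log2_sl, rep(2, 20))
  expect_equal(ttx$delta_log2_ro, rep(0, 20))

  # truth identity: RO = PL - SL exactly, any mixture
  dmix <- experiment_design(100, c(null = 0.5, concordant = 0.2,
                                   sequestration_release = 0.2, runoff = 0.1),
                            seed = 7)
  tt <- simulate_experiment(dmix)$truth
  expect_identical(tt$delta_log2_ro, tt$delta_log2_pl - tt$delta_log2_sl)

  # release scenario raises occupancy while engaged-copy density falls
  drel <- experiment_design(200, c(sequestration_release = 1), seed = 8,
                            priors = list(lambda = c(3, 3), s = c(0.6, 0.6)))
  srel <- simulate_experiment(drel)
  expect_gt(mean(srel$truth$delta_log2_ro), 0)
  dens <- vapply(srel$models, function(g) {
    expected_load(g$treated)$per_engaged - expected_load(g$control)$per_engaged
  }, numeric(1))
  expect_true(all(dens < 0))

  expect_error(experiment_design(10, c(null = 0.6, runoff = 0.3)), "sum to 1")
})

test_that("per-gene substreams decouple draws from cohort size and order", {
  d10 <- experiment_design(10, c(null = 0.7, initiation_up = 0.3), seed = 9)
  d25 <- experiment_design(25, c(null = 0.7, initiation_up = 0.3), seed = 9)
  s10 <- simulate_experiment(d10)
  s25 <- simulate_experiment(d25)
  expect_identical(s10$matrix, s25$matrix[1:10, ])
  expect_identical(s10$truth, s25$truth[1:10, ])

  # bit-identical rerun
  expect_identical(simulate_experiment(d10), s10)
})

test_that("synthetic transcripts have valid frames and plantable motifs", {
  ids <- sprintf("g%03d", 1:40)
  tx <- simulate_transcripts(ids, cds_len_codons = 120, seed = 3,
                             plant_motif = "[GA][GA]AGA[GA]",
                             plant_in = ids[1:20], plant_prob_bg = 0)
  expect_true(all(substr(tx$cds, 1, 3) == "ATG"))
  stops <- c("TAA", "TAG", "TGA")
  for (cds in tx$cds) {
    n <- nchar(cds)
    expect_equal(n %% 3, 0)
    codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
    expect_true(codons[length(codons)] %in% stops)
    expect_false(any(codons[-length(codons)] %in% stops))
  }
  utr5 <- tx$utr5; names(utr5) <- tx$gene_id
  hits <- motif_scan(utr5, "[GA][GA]AGA[GA]")$counts > 0
  expect_true(all(hits[1:20]))
})
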