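# polyoccu — polysome profiling and polysomal occupancy analysis

`polyoccu` is an R package for the quantitative side of polysome-profiling
studies: experiments that fractionate a cell's mRNA on sucrose density
gradients to ask not just *how much* of a transcript there is, but *how
actively it is being translated*. It is aimed at researchers analysing
gradient A254 traces, fraction-resolved RT-qPCR or array/sequencing data
from polysomal and total RNA, and at methodologists who want a fully
simulated test bed for translational-regulation statistics.

## What it computes

**Three-contrast differential analysis.** For a sucrose-vs-control design
measured at two levels (steady-state and polysomal RNA, 3 replicates
each), the package tests per gene:

- `SL` — steady-state (transcriptional) change,
- `PL` — polysomal-level change,
- `RO` — polysomal occupancy, defined as PL relative to SL and tested on
  per-replicate log-ratios `o_j = log2(PL_j) − log2(SL_j)`, so that
  `log2FC_RO = log2FC_PL − log2FC_SL` holds exactly on balanced designs.

P-values come from a pooled-variance two-sample t-test (Welch and an
interaction-model mode are available), are Benjamini–Hochberg adjusted per
contrast, and genes are called with the classic rule *adjusted p ≤ 0.05
and ≥ 2-fold change*, with classes `RO_changed` / `concordant` /
`SL_only` / `PL_only` / `unchanged`.

**Gradient quantification.** Blank-baseline subtraction, trapezoid
area-under-curve, polysomal-area percentages normalised to total area, a
configurable 12-fraction scheme with NP/SP/LP pools, and replicate-wise
treatment–control differences.

**Fraction-resolved density metrics.** Spike-in plus AUC normalisation of
12-fraction profiles, the NP/PL split (summing to 100%), an
abundance-weighted mean fraction index as ribosome-density proxy, and a
scenario classifier that separates *initiation up* (occupancy ↑, density
↑) from the *sequestration-release / stall / runoff* signature
(occupancy ↑, density ↓).

**Sequence features and motifs.** Region lengths and GC, Wright's
effective number of codons (Nc, 20–61), uORF detection, −5..+8
start-codon context, Wilcoxon/Fisher target-vs-background comparisons,
and degenerate bracket-notation consensus scanning (e.g.
`[GA][GA]AGA[GA]`) with one-tailed Fisher fold-enrichment tables.

**A generative model with known truth.** The simulator draws each mRNA
copy from a two-pool loading model — sequestered with probability `s`
(zero ribosomes) or active with `min(Poisson(λ), capacity)` ribosomes —
which is the minimal model in which polysomal occupancy
`(1−s)(1−e^{−λ})` and ribosome density `λ/(1−e^{−λ})` can move in
opposite directions. A single-parameter Poisson model cannot do this:
both quantities increase with λ. Scenario specifications perturb
abundance, λ and s to emulate transcriptional, initiation, release, stall
and runoff mechanisms, and the simulator emits expression matrices,
fraction profiles, A254 traces and transcript sequences with a truth
table.

## Worked example

Simulate 500 genes, 20% of which are released from sequestration under
"sucrose" (s 0.75 → 0.15 with λ 3 → 2, i.e. occupancy up ~2.5-fold while
per-copy ribosome load drops), then run the whole pipeline:

```r
library(polyoccu)

des <- experiment_design(
  n_genes = 500,
  class_mixture = c("null" = 0.8, sequestration_release = 0.2),
  n_replicates = 3, noise_sd_log2 = 0.2, seed = 42,
  priors = list(lambda = c(3, 3), s = c(0.75, 0.75)),
  scenarios = list(sequestration_release = scenario_spec(
    "sequestration_release", delta_lambda = -1, delta_s = -0.6)))

res <- run_pipeline(pipeline_config(des, n_profile_genes = 100))
print(res)
```

```
# Polysome profiling pipeline report

Genes: 500; replicates: 3; seed: 42

## Gradient quantification
- mean polysomal area, control: 19.0%
- mean polysomal area, sucrose: 22.1%

## Regulation calls (SL / PL / RO)
- PL_only: 28
- RO_changed: 75
- unchanged: 397

## Scenario classes (profiled subset)
- no_change: 84
- occupancy_up_density_down: 16

## Sequence features
- features at p < 0.05: none

## Motif enrichment (5'UTR)
- [GA][GA]AGA[GA]: fold 2.50, p = 0.000235
- [TCA]CG[GCA]CG[GA][CA]G: fold 0.00, p = 1
```

Reading the output: this cohort is deliberately heavily sequestered
(s = 0.75), so only ~19% of the control trace area is polysomal, rising
under treatment as copies are released. Of the 103 genes whose occupancy
truly changed, 75 pass the strict *p ≤ 0.05 and ≥ 2-fold* occupancy rule
(the true effect is 1.33 on the log2 scale, so the fold gate costs some
power; 28 more surface as `PL_only`) and none of the 397 null genes is
falsely called. All 16 release genes in the profiled subset classify as
`occupancy_up_density_down` — more transcript copies in polysomes, each
carrying fewer ribosomes. The first motif was planted into the 5'UTRs of
the truly regulated genes at 2.5-fold enrichment over background; the
second was not planted and comes back flat.

Every stage is also callable on its own (`subtract_baseline()`,
`polysomal_area_pct()`, `differential_all()`, `classify_regulation()`,
`density_metrics()`, `scenario_classify()`, `effective_number_of_codons()`,
`find_uorfs()`, `motif_table()`, …), and `read_pipeline_config()` loads a
YAML description of a run. See the methods vignette
(`vignettes/polyoccu-methods.Rmd`) for the model, parameter and threshold
documentation.

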