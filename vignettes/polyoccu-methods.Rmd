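---
title: "Models and methods behind polyoccu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyoccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyoccu)
```

# The problem

Polysome profiling separates a cell's mRNA by how many ribosomes each copy
carries: free messenger ribonucleoproteins (mRNPs) stay near the top of a
sucrose density gradient, monosomes sediment a little deeper, and polysomes
— mRNAs carrying two or more ribosomes — reach the densest fractions. Two
quantities summarise a transcript's translational state:

* **polysomal occupancy** — the share of a transcript's copies that are
  engaged in polysomes, operationalised as the ratio of polysomal level (PL)
  to steady-state level (SL);
* **ribosome density** — how many ribosomes each engaged copy carries,
  proxied by how deep in the polysomal region the transcript sediments.

The two are logically independent: a treatment can recruit previously
silent copies into polysomes (occupancy up) while each engaged copy carries
fewer ribosomes (density down). `polyoccu` implements the full quantitative
chain needed to detect and interpret that pattern — gradient trace
quantification, three-contrast differential statistics, fraction-resolved
density metrics, sequence-feature and motif enrichment — together with a
generative model that produces all four data types with known ground truth.

# The two-pool ribosome-loading model

Each mRNA copy of gene $g$ is either *sequestered* (probability $s$,
carrying zero ribosomes — withdrawn from the translatable pool without
degradation) or *active*. Active copies load

$$N \mid \text{active} \;=\; \min(\mathrm{Poisson}(\lambda),\, C), \qquad
C = \left\lfloor \frac{\text{CDS length in codons}}{\text{footprint codons}} \right\rfloor ,$$

where $\lambda$ is the loading intensity and $C$ the steric packing
capacity (default footprint 10 codons). Two useful closed forms:

* occupancy (fraction of copies with at least one ribosome):
  $(1-s)\,(1-e^{-\lambda})$;
* density on engaged copies (ignoring the usually negligible truncation):
  $\lambda / (1-e^{-\lambda})$.

A single-pool Poisson model cannot reproduce "occupancy up, density down":
both quantities are increasing in $\lambda$. The sequestered pool is the
minimal extension that decouples them — lowering $s$ raises occupancy
without touching per-engaged-copy density, and lowering $\lambda$ at the
same time drops the density. For example, moving from
$(\lambda=3, s=0.6)$ to $(\lambda=2, s=0.2)$ raises occupancy from
$0.4 \times 0.950 = 0.380$ to $0.8 \times 0.865 = 0.692$ while density
falls from $3.157$ to $2.313$ ribosomes per engaged copy:

```{r two-pool}
ctrl <- transcript_model("ex", cds_len_codons = 420,
                         loading_intensity = 3, sequestered_fraction = 0.6)
trt <- transcript_model("ex", 420, 2, 0.2)
c(control = expected_occupancy(ctrl, n_min = 1),
  treated = expected_occupancy(trt, n_min = 1))
c(control = expected_load(ctrl)$per_engaged,
  treated = expected_load(trt)$per_engaged)
```

Truncation at $C$ is handled by *clamping* (values above $C$ are set to
$C$), not resampling: clamping keeps the expected load monotone in
$\lambda$ and is simpler to reason about; for typical parameters
($C \ge 10$, $\lambda \le 5$) the clamped mass is far below $10^{-6}$.

## Mechanistic scenarios

`scenario_spec()` perturbs $(\log_2 \text{abundance}, \lambda, s)$. The
named defaults encode the classic interpretations of an
occupancy/density change; within a *static* loading model, sequestration
release, elongation stall and ribosome runoff are distinguishable only by
which of $\lambda$ and $s$ move and by how much — all three shift engaged
copies toward lighter polysomes. The defaults are package choices (no
kinetic rates are implied by the biology):

| scenario | Δlog2 abundance | Δλ | Δs | expected pattern |
|---|---|---|---|---|
| null | 0 | 0 | 0 | nothing |
| transcriptional | +2 | 0 | 0 | SL and PL up, RO flat |
| concordant | +1 | +1 | 0 | SL and PL up, PL more |
| initiation_up | 0 | +1.5 | 0 | occupancy **and** density up |
| sequestration_release | 0 | −1 | −0.4 | occupancy up, density down |
| elongation_stall | 0 | −0.8 | −0.25 | occupancy up, density down |
| runoff | 0 | −1 | 0 | density down, occupancy slightly down |

# The synthetic experiment

`simulate_experiment()` draws, for each gene, control parameters from
documented priors and applies its scenario's deltas to form the treated
arm. Defaults: CDS length uniform on 100–800 codons; $\lambda \sim
U[1.5, 4]$ and $s \sim U[0.05, 0.35]$, jointly calibrated so that roughly
70% of a typical transcript's copies are ribosome-associated in the
control arm (the textbook figure for unstressed seedlings); abundance
log-normal ($\log_2$ mean 6, sd 1.5); 3 biological replicates; measurement
noise multiplicative log-normal with sd 0.2 on the $\log_2$ scale.

Signals are analytic expectations under the model — steady-state signal
proportional to abundance, polysomal signal proportional to abundance
times the probability of carrying at least 2 ribosomes (under the default
fraction scheme monosomes sediment with the non-polysomal pool) — with
per-replicate noise applied on top. The returned truth table satisfies
$\Delta\log_2 RO = \Delta\log_2 PL - \Delta\log_2 SL$ exactly by
construction.

Reproducibility: one global seed expands into per-gene substreams via a
counter scheme (`substream_seed()`), so a gene's draws depend only on its
index and the seed — never on cohort size or gene order — and identical
designs reproduce byte-identical outputs.

What the generator does **not** emulate: probe-level microarray artifacts,
between-gene correlation, variance–mean trends, partial degradation during
fractionation, and fraction-to-fraction carryover. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to every artifact of deposited wet-lab
data.

# Gradient traces

Simulated A254 traces place one Gaussian peak per ribosome class $n \ge 1$
with area proportional to $n \times (\text{copies in class } n)$ — A254
mass is ribosome mass — plus a free 40S/60S subunit peak near the top of
the gradient whose area scales with the *total* copy population
(`subunit_area`, default 3 per copy, calibrated so the default-prior
population shows ≈40% of its area in the polysomal region, the range
reported for unstressed seedlings). Peak placement uses the destination
fraction centre plus a $\log(n+1)$ offset; rendering choices affect only
the visual trace, never a downstream statistic.

Quantification follows standard practice: a blank-gradient baseline is
subtracted (linear interpolation onto the trace grid; negative residuals
clipped to zero, since A254 is nonnegative and clipping keeps percentages
in $[0, 100]$), areas use the trapezoid rule (exact on piecewise-linear
traces), and the polysomal-area percentage is the polysomal share of the
total area, which compensates for uneven gradient loading. The default
fraction scheme cuts the domain into 12 equal-width fractions pooled as
NP = 1–4, SP = 5–8, LP = 9–12 with polysomes starting at fraction 5 and
monosomes in fraction 4; published gradient figures mark fractions without
printing pool indices, so all of this is configurable and echoed into
every run manifest.

# Differential analysis

Intensities are spike-normalised (division by each sample's spike-in
signal, rescaled by the spikes' geometric mean), log2-transformed, and
tested per gene:

* **SL**: sucrose vs control on steady-state samples;
* **PL**: sucrose vs control on polysomal samples;
* **RO**: per-replicate log-ratios $o_j = \log_2 PL_j - \log_2 SL_j$,
  tested sucrose vs control. On balanced designs
  $\log_2FC_{RO} = \log_2FC_{PL} - \log_2FC_{SL}$ exactly.

The default test pools the within-group variances (classical two-sample
t). This was a deliberate choice: with 3 replicates per arm there is no
information to estimate unequal variances, and the Welch–Satterthwaite
approximation is measurably conservative at that size (its true type-I
rate sits below the nominal level), whereas the pooled t is exact under
the homoscedastic log-normal noise the generator produces — and
equal-variance-after-normalisation is precisely what a spike-in design
aims for. Welch remains available (`var_equal = FALSE`) for data where
heteroscedasticity is a real concern, as does an interaction-term mode
(`mode = "interaction"`) that tests RO as the condition × level
coefficient of a per-gene linear model; the ratio test is the default
because it mirrors how occupancy is defined.

Benjamini–Hochberg adjustment is applied per contrast (not jointly across
contrasts). A gene is significant in a contrast when its adjusted
$p \le 0.05$ **and** $|\log_2FC| \ge 1$ (the 2-fold rule); the per-gene
class is assigned with documented precedence — `RO_changed` whenever the
occupancy contrast is significant, else `concordant` when SL and PL both
are, else `SL_only`/`PL_only`, else `unchanged`. The RO fold gate is a
separate threshold (`ro_lfc`, default 1) because reported occupancy
changes are often milder than transcriptional ones.

# Fraction-resolved metrics

Per-gene 12-fraction profiles are normalised by the sample's spike-in
signal and the polysomal A254 area of the same gradient. The NP/PL split
sets the summed signal to 100%; the ribosome-density proxy is the
abundance-weighted mean fraction index over the polysomal fractions
(`weighted_index`), with the argmax fraction (`peak_fraction`, ties to the
lowest index) reported alongside for fidelity to how density shifts are
read off gradient figures. `scenario_classify()` compares a treated
profile against its control with tolerances of 1 percentage point
(occupancy) and 0.25 index units (density): both up → `initiation_up`,
occupancy up with density down → `occupancy_up_density_down` (the
sequestration-release / stall / runoff class), both down → `repression`.

Monte-Carlo scenario checks draw 2000 copies per gene, which puts the
standard error of a per-gene occupancy estimate near one percentage point
— comfortably inside the classification tolerance for the effect sizes the
scenarios encode.

# Sequence features and motifs

* **Region features**: lengths and GC content per 5′UTR / CDS / 3′UTR and
  full transcript; GC is computed over unambiguous bases only.
* **Nc** (effective number of codons), Wright's estimator: per amino acid
  with $n$ observed codons and synonymous proportions $p_i$,
  $\hat F = (n \sum p_i^2 - 1)/(n-1)$; then
  $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$ over the
  degeneracy-class means, clamped to $[20, 61]$. Amino acids observed
  fewer than 2 times are excluded from their class mean; a class with no
  usable amino acid borrows the mean $\hat F$ of the observed classes (a
  common convention); the estimate is undefined only when every class is
  empty. The 6-fold families (Leu, Ser, Arg) are treated as single
  families.
* **uORFs**: every 5′UTR ATG with an in-frame stop upstream of the main
  start (optionally extending into the CDS) opens a uORF; peptide length
  counts codons from the ATG up to the stop, so `min_codons = 1` admits a
  bare start codon; nested same-frame starts sharing a stop are reported
  once at the outermost position. Coordinates are 1-based and `end` is the
  last base of the stop codon.
* **Start context**: the −5..+8 window around the main ATG (13 nt; +1 is
  the A, there is no position 0), N-padded when a region is short.
* **Comparisons**: continuous features use a two-sided Wilcoxon rank-sum
  test (exact for ≤25 defined values per side without ties, otherwise the
  normal approximation with tie and continuity corrections); uORF presence
  uses a one-tailed Fisher test. The background is the annotated universe
  minus the target list.
* **Motifs**: degenerate bracket-notation consensi (e.g.
  `[GA][GA]AGA[GA]`) are matched exactly — a position matches when the
  base belongs to its allowed set, overlaps all count, `N` never matches.
  Enrichment uses gene-level (≥1 hit) counting by default, with occurrence
  totals reported alongside, because published tables mix the two scales;
  the 2×2 one-tailed Fisher table excludes target genes from the
  background, and the fold enrichment is always recomputable from the
  reported counts — printed folds from other sources are never taken as
  truth.

# Numerical and design notes

* All validation errors are raised eagerly with the offending field named;
  degenerate inputs (zero total area, all-zero profiles, empty standards
  variance) are flagged `undefined` or fall back with a warning rather
  than silently returning 0.
* The brute-force oracles used by the test-suite (literal step-up BH,
  hypergeometric-tail summation, position-by-position motif enumeration,
  three-frame uORF enumeration) are implemented independently inside the
  tests, never shared with package code. Real-valued oracle comparisons
  use machine-precision tolerances ($10^{-12}$–$10^{-14}$); integer-valued
  ones are bit-exact.
* Problem sizes in the test-suite — 2000 genes × 50 seeds for the null
  calibration, 1000 random instances per oracle family, 100 genes × 2000
  copies for scenario signatures — were chosen once as the smallest sizes
  at which the asserted 3-standard-error bands are meaningfully tight.

# Known limitations

* The loading model is static: it has no elongation dynamics, so scenarios
  that differ kinetically (stall vs runoff) are encoded only through their
  equilibrium signatures.
* The pooled-variance default assumes post-normalisation
  homoscedasticity; strongly heteroscedastic data should use
  `var_equal = FALSE` (conservative) or an external moderated-variance
  framework.
* Motif scanning is exact degenerate-consensus matching; no
  position-weight-matrix scoring or de-novo discovery is provided.
* qRT-PCR preprocessing (Cq conversion, amplification efficiency) is out
  of scope — fraction profiles are assumed to be relative quantities
  already.
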