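# Example pipeline configuration: a mostly-null cohort in which 5% of the
# genes are released from sequestration under treatment. Load with
# read_pipeline_config(system.file("extdata", "release_study.yaml",
#                                  package = "polyoccu")).
design:
  n_genes: 200
  class_mixture: {"null": 0.95, sequestration_release: 0.05}
  n_replicates: 3
  noise_sd_log2: 0.2
  spike_true: 100
  seed: 1
  priors:
    lambda: [3, 3]
    s: [0.6, 0.6]
thresholds:
  padj: 0.05
  lfc: 1
  ro_lfc: 0.5
consensi:
  - "[GA][GA]AGA[GA]"
  - "[TCA]CG[GCA]CG[GA][CA]G"
n_profile_genes: 100
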