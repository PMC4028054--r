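# Demo study: fully synthetic, runs in seconds on one CPU.
seed: 42
synth:
  n_families: 800
  n_reads: 30000
  n_replicates: 2
  mean_len: 316
  sd_len: 80
  abundance_meanlog: 2.0
  abundance_sdlog: 1.5
  zero_fraction: 0.2
  chimera_fraction: 0.01
  utr_padding: true_utr
  completeness: auto
  miss_rate: 0.0
  spurious_rate: 0.0
annotate:
  min_segment: 100
  max_overlap: 30
  chimera_max_evalue: 1.0e-10
expression:
  min_count: 1
  exclude_chimeras: false
  reference_gene: auto
rarefaction:
  reps: 200
  theta: 1.0e-3
  grid_points: 40
lineages:
  evalue_cutoff: 1.0e-10
crossx:
  detection_threshold: 100
qpcr:
  n_panel: 14
  replicate_sd: 0.15
  plant_outlier: true
  outlier_fold: 8
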