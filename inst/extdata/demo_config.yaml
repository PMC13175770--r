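# Demo run configuration: a reduced-scale synthetic end-to-end run.
# All thresholds carry the pipeline defaults; see default_run_config().
seed: 7
genome:
  n_contigs: 1
  contig_length: 200000
  gc_fraction: 0.41
  tracts:
  - contig: 1
    start: 120200
    base: A
    length: 12
guide:
  name: synthetic_guide
  spacer: GACCTGCGGAAGATCGAGAC
  pam: NGG
  cut_offset: -3
sites:
- distance: 2
  region_class: intronic
  integration_rate: 0.004
  editing_fraction: 0.004
- distance: 4
  region_class: intergenic
  integration_rate: 0.002
  editing_fraction: 0.002
- distance: 6
  region_class: exonic
  integration_rate: 0.001
  editing_fraction: 0.0005
on_target:
  integration_rate: 0.02
  editing_fraction: 0.98
samples:
  n_treatment: 3
  n_control: 3
  depth: 8000
reads:
  umi_length: 8
  read_length: 150
  tag_sequence: ACGTCTGAGTCGGAGC
  mispriming_rate: 0.0
error_model:
  substitution_rate: 0.001
  base_indel_error_rate: 0.0012
  homopolymer_multiplier: 5.0
  min_tract_length: 6
  quality_mean: 36.0
  quality_sd: 3.0
thresholds:
  flank: 40
  max_lev: 7
  insilico_max_distance: 5
  insilico_priority_lev: 3
  fdr: 0.05
  castseq_p: 0.005
  af: 0.01
  coverage: [100, 1000, 10000]
  min_coverage: 1000
  merge_distance: 10
  window_halfwidth: 2
  cluster_window: 5
  flanking_width: 2000
  ddpcr_tolerance: 10.0
confirmation:
  depth: 200000
ddpcr:
  droplets_per_well: 20000
  copies_per_droplet_mean: 0.8
  control_levels: [50.0, 75.0, 100.0]
  sample_true_ko: 90.0
stages:
  simulate: true
  preprocess: true
  nominate: true
  insilico: true
  prioritize: true
  confirm: true
  ddpcr: true
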