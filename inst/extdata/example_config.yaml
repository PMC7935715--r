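# Example run configuration. Any key omitted here falls back to
# ffasim::default_config(); see ?default_config for units and meaning.

# scaled genome: 1/1000 of GRCh38 per chromosome, 50 kb-equivalent bins
genome_scale: 1000
bin_width: 50

# cohort
cohort_size: 200
n_batches: 2
depth: 500000            # fragments per sequenced sample
karyotype_freqs:
  euploid: 0.90
  T21: 0.03
  T18: 0.02
  T13: 0.01
  RAA: 0.01
  microdeletion: 0.01
  MX: 0.005
  TX: 0.005
  XXY: 0.005
  XYY: 0.005

# fragment-length mixture and size selection
fetal_len_mean: 143
fetal_len_sd: 18
maternal_len_mean: 167
maternal_len_sd: 20
target_mean_length: 140  # nt, post-selection mean
reamplify: true

# screening thresholds (directional z)
z_threshold:
  common_aneuploidy: 4
  raa: 4
  microdeletion: 4
  sca_x: 4

# ROC model
mcmc_burnin: 2000
mcmc_keep: 8000
seed: 1
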