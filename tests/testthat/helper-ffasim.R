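# shared fixtures: a coarse genome for cheap tests (1/10000 scale, ~6k bins)
# and fixed-profile constructors; everything is generated in code.

small_config <- function() {
  cfg <- default_config()
  cfg$genome_scale <- 1e4
  cfg$depth <- 1e5
  cfg$cohort_size <- 40
  cfg$mcmc_burnin <- 500
  cfg$mcmc_keep <- 1500
  cfg
}

fixed_profile <- function(ff = 0.10, karyotype = "euploid", sex = "XY",
                          id = "S1", batch = "B1") {
  list(sample_id = id, batch_id = batch, bmi = 27, true_ff = ff,
       karyotype = karyotype, fetal_sex = sex, protocol = "standard",
       control_type = "none")
}

# one sample's counts (list total/fetal/maternal) under a fixed profile
sim_sample <- function(profile, genome, config, depth = config$depth) {
  cm <- karyotype_to_copy_map(profile, genome)
  simulate_bin_counts(profile, cm, genome, depth = depth, config = config)
}

# mean region depth ratio of a single simulated sample
sample_region_ratio <- function(bc, genome, region) {
  r <- normalize_depth(bc$total, genome)
  mean(r[region_bin_index(genome, region), 1])
}
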