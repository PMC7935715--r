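#' Default run configuration
#'
#' Flat list of parameters controlling the whole pipeline. Key groups:
#'
#' * genome: `genome_scale` (simulate a genome 1/scale of GRCh38),
#'   `bin_width` (scaled bp; 50 = 50 kb-equivalent), `microdeletions`
#'   (named intervals in real bp).
#' * cohort: `cohort_size`, `n_batches`, `karyotype_freqs`,
#'   `depth` (fragments per sample), BMI lognormal (`bmi_meanlog`,
#'   `bmi_sdlog`), and the FF model `log(FF) = ff_intercept -
#'   ff_bmi_slope * BMI + N(0, ff_log_sd^2)` clipped to
#'   `[ff_min, ff_max]`. Defaults are calibrated so that ~3.7% of samples
#'   fall below 4% FF overall and ~16% do in the BMI >= 40 stratum.
#' * controls: `ntc_rate` (contamination fraction of nominal depth in
#'   no-template controls), `pooled_ff` (aggregate FF of the pooled XY
#'   control).
#' * regression signal: `tilt_strength`, `tilt_sd`, `tilt_seed` — a fixed
#'   mean-zero autosomal depth signature whose amplitude is proportional
#'   to FF, giving the ridge FF regression a learnable signal.
#' * size selection: truncated-normal fragment-length compartments
#'   (`fetal_len_mean/sd`, `maternal_len_mean/sd`), `target_mean_length`
#'   (post-selection mean, nt), `reamplify` (restore original depth).
#' * screening: per-class z thresholds, SCA tolerance band.
#' * ROC model: MCMC chain settings, half-normal prior scales,
#'   `ref_depth` (N0 in the z scaling law).
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    # genome
    genome_scale = 1000,
    bin_width = 50,
    microdeletions = list(
      "22q11.2" = list(chrom = "chr22", start = 18900000, end = 21900000),
      "5p15"    = list(chrom = "chr5",  start = 1000000,  end = 4000000)
    ),
    # cohort
    cohort_size = 200,
    n_batches = 2,
    depth = 5e5,
    karyotype_freqs = c(euploid = 0.90, T21 = 0.03, T18 = 0.02, T13 = 0.01,
                        RAA = 0.01, microdeletion = 0.01,
                        MX = 0.005, TX = 0.005, XXY = 0.005, XYY = 0.005),
    bmi_meanlog = log(26.5),
    bmi_sdlog = 0.22,
    ff_intercept = -1.6348,
    ff_bmi_slope = 0.0252,
    ff_log_sd = 0.478,
    ff_min = 0.005,
    ff_max = 0.5,
    overdispersion = 0,         # negative-binomial dispersion; 0 = Poisson
    ntc_per_batch = 1,
    pooled_xx_per_batch = 1,
    pooled_xy_per_batch = 1,
    ntc_rate = 1e-4,
    pooled_ff = 0.10,
    # chrY mapping background: per-sample relative depth on chrY bins from
    # mis-mapped reads (lognormal across libraries); gives female fetuses
    # the near-zero-but-dispersed FF_chrY the sex-call model fits
    chry_background_meanlog = log(0.002),
    chry_background_sdlog = 0.3,
    duplicate_samples = 0,
    library_oversample = 20,
    # positives are sourced from a repository of previously screened
    # samples, so their FF is floored at a screenable level (the cohort's
    # positives are FF-biased; the ROC model corrects for exactly this)
    positive_ff_min = 0.03,
    # planted FF-correlated autosomal depth signature
    tilt_strength = 6,
    tilt_sd = 0.15,
    tilt_seed = 20201115,
    # fragment-length mixture / size selection
    fetal_len_mean = 143, fetal_len_sd = 18,
    maternal_len_mean = 167, maternal_len_sd = 20,
    target_mean_length = 140,
    reamplify = TRUE,
    # screening
    z_threshold = c(common_aneuploidy = 4, raa = 4, microdeletion = 4,
                    sca_x = 4),
    sca_tolerance_frac = 0.35,
    sca_tolerance_floor = 0.01,
    # FF regression
    ridge_lambda = 0.1,
    # ROC model (MCMC)
    mcmc_chains = 4, mcmc_burnin = 2000, mcmc_keep = 8000,
    beta_prior_scale = 200, sigma_prior_scale = 2,
    ref_depth = 5e5,
    seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_config()]; `z_threshold` and
#' `karyotype_freqs` given as YAML maps are coerced to named numeric vectors.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    v <- user[[k]]
    if (k %in% c("z_threshold", "karyotype_freqs") && is.list(v))
      v <- unlist(v)
    cfg[[k]] <- v
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config Configuration list to validate.
#' @export
validate_config <- function(config) {
  with(config, {
    stopifnot(genome_scale >= 1, bin_width >= 1, depth > 0,
              cohort_size >= 1, n_batches >= 1)
    if (ff_bmi_slope < 0)
      stop("ff_bmi_slope must be >= 0: FF is negatively correlated with BMI")
    if (any(karyotype_freqs < 0) || abs(sum(karyotype_freqs) - 1) > 1e-6)
      stop("karyotype_freqs must be nonnegative and sum to 1")
    stopifnot(ff_min > 0, ff_max <= 1, ff_min < ff_max,
              ntc_rate >= 0, ntc_rate <= 1,
              pooled_ff > 0, pooled_ff < 1,
              all(is.finite(z_threshold)),
              seed >= 0, seed == floor(seed))
  })
  config
}
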